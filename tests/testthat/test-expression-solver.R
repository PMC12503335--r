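p_default <- sim_params()

test_that("promoter opening and expression follow the sigmoid chain", {
  # midpoint of the sigmoid
  expect_equal(opening_energy(-0.042, p_default), 0.5)
  # closed-form value at basal supercoiling
  expect_equal(opening_energy(-0.066, p_default), 1 / (1 + exp(-4.8)),
               tolerance = 1e-14)
  # saturation limits
  expect_equal(opening_energy(10, p_default), 0)
  expect_equal(opening_energy(-10, p_default), 1)
  # expression endpoints
  expect_equal(expression_from_opening(1, p_default), 1)
  expect_equal(expression_from_opening(0, p_default), exp(-2.5))
  # threshold
  expect_equal(activation_threshold(p_default), (exp(-2.5) + 1) / 2)
  expect_equal(activation_threshold(sim_params(m = 1e6)), 0.5,
               tolerance = 1e-9)
})

test_that("interaction signs match the hand-enumerated twin-domain table", {
  # all 8 (side, strand) configurations via the 4 orientation patterns of
  # an adjacent pair, each read in both directions
  for (o1 in c(1, -1)) {
    for (o2 in c(1, -1)) {
      g <- genome(
        data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                   length = 1000, orientation = c(o1, o2)),
        total_length = 67500
      )
      for (pair in list(c(1, 2), c(2, 1))) {
        i <- pair[1]; j <- pair[2]
        off <- ref_signed_offset(g, i, j)
        want <- ref_eta_table(off$side, g$orientation[i] == g$orientation[j])
        expect_identical(eta(g, i, j), want)
      }
    }
  }

  # headline cases: convergent pairs inhibit (+1 both ways), divergent
  # pairs activate (-1 both ways), tandem pairs are asymmetric
  gc <- genome(data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                          length = 1000, orientation = c(1, -1)),
               total_length = 67500)
  expect_identical(eta(gc, 1, 2), 1L)
  expect_identical(eta(gc, 2, 1), 1L)
  gd <- genome(data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                          length = 1000, orientation = c(-1, 1)),
               total_length = 67500)
  expect_identical(eta(gd, 1, 2), -1L)
  expect_identical(eta(gd, 2, 1), -1L)
  gt <- genome(data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                          length = 1000, orientation = c(1, 1)),
               total_length = 67500)
  expect_identical(eta(gt, 2, 1), 1L)   # left gene is upstream of right
  expect_identical(eta(gt, 1, 2), -1L)
})

test_that("interaction matrix entries are eta * c * linear distance decay", {
  gt <- genome(data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                          length = 1000, orientation = c(1, 1)),
               total_length = 67500)
  M <- build_interaction_matrix(gt, p_default)
  # d(promoter of right gene -> middle of left gene) = 625
  expect_equal(M[2, 1], 0.03 * (1 - 625 / 5000))
  expect_equal(abs(M[2, 1]), 0.02625)
  expect_equal(diag(M), c(0, 0))

  # beyond d_max the effect vanishes
  gfar <- genome(data.frame(id = 1:2, type = c("A", "B"),
                            begin = c(0, 10000), length = 1000,
                            orientation = c(1, 1)),
                 total_length = 67500)
  expect_equal(build_interaction_matrix(gfar, p_default),
               matrix(0, 2, 2), ignore_attr = TRUE)

  # single gene: 1x1 zero matrix
  g1 <- genome(data.frame(id = 1, type = "A", begin = 0, length = 1000,
                          orientation = 1), total_length = 67500)
  expect_equal(build_interaction_matrix(g1, p_default), matrix(0, 1, 1))

  # full matrix agrees with the R-level eta/offset oracle
  set.seed(3)
  g <- random_genome(5)
  M <- build_interaction_matrix(g, p_default)
  for (i in seq_len(n_genes(g))) {
    for (j in seq_len(n_genes(g))) {
      if (i == j) next
      off <- ref_signed_offset(g, i, j)
      want <- if (off$side == "tie" || off$distance >= 5000) {
        0
      } else {
        ref_eta_table(off$side, g$orientation[i] == g$orientation[j]) *
          0.03 * (1 - off$distance / 5000)
      }
      expect_equal(M[i, j], want)
    }
  }
})

test_that("local supercoiling is background plus linear coupling", {
  M <- matrix(0, 3, 3)
  e <- c(0.5, 0.9, 0.1)
  expect_equal(local_supercoiling(M, e, p_default, 0), rep(-0.066, 3))
  M[1, 2] <- 0.02
  s <- local_supercoiling(M, e, p_default, 0.01)
  expect_equal(s[1], -0.066 + 0.01 + 0.02 * 0.9)
  # linearity in a single entry
  e2 <- e; e2[2] <- 2 * e[2]
  expect_equal(local_supercoiling(M, e2, p_default, 0.01)[1] - s[1],
               0.02 * 0.9)
})

test_that("an isolated gene's equilibrium matches the closed form", {
  g1 <- genome(data.frame(id = 1, type = "AB", begin = 0, length = 1000,
                          orientation = 1), total_length = 67500)
  for (ds in c(-0.01, 0, 0.01)) {
    st <- solve_expression(g1, p_default, delta_sigma_env = ds)
    expect_true(st$converged)
    expect_equal(st$expression, closed_chain(ds), tolerance = 1e-12)
    expect_equal(isolated_expression(ds, p_default), closed_chain(ds),
                 tolerance = 1e-15)
  }
  # direction: relaxation (ds > 0) lowers expression
  grid <- seq(-0.02, 0.02, by = 0.002)
  expect_true(all(diff(isolated_expression(grid, p_default)) < 0))
})

test_that("pair interactions move expression in the twin-domain direction", {
  iso <- closed_chain(0)
  # divergent pair: mutual negative supercoiling -> both above isolated
  gd <- genome(data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                          length = 1000, orientation = c(-1, 1)),
               total_length = 67500)
  std <- solve_expression(gd, p_default)
  expect_true(all(std$expression > iso))
  # convergent pair: mutual positive supercoiling -> both below isolated
  gc <- genome(data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                          length = 1000, orientation = c(1, -1)),
               total_length = 67500)
  stc <- solve_expression(gc, p_default)
  expect_true(all(stc$expression < iso))
})

test_that("converged states are self-consistent and bounded", {
  set.seed(17)
  for (rep in 1:10) {
    g <- random_genome(20)
    for (env in c("A", "B")) {
      st <- suppressWarnings(solve_expression(g, p_default, env))
      if (!st$converged) next
      M <- build_interaction_matrix(g, p_default)
      sigma0 <- g$sigma_basal + environments(p_default)[[env]]
      resid <- max(abs(ref_update(st$expression, M, sigma0, p_default) -
                         st$expression))
      expect_lt(resid, 1e-9)
      expect_true(all(st$expression >= exp(-2.5) - 1e-12))
      expect_true(all(st$expression <= 1 + 1e-12))
    }
  }
})

test_that("knockouts pin expression to zero and full knockout kills the genome", {
  set.seed(19)
  g <- random_genome(3)
  st <- solve_expression(g, p_default, "A", knockouts = g$id)
  expect_equal(st$expression, rep(0, 9))
  expect_equal(st$sigma_local, rep(-0.066 + 0.01, 9))
  expect_equal(sum(st$activated), 0)

  st1 <- solve_expression(g, p_default, "A", knockouts = g$id[1])
  expect_equal(st1$expression[1], 0)
  expect_true(all(st1$expression[-1] > 0))
  expect_error(solve_expression(g, p_default, "A", knockouts = 999L),
               "existing gene ids")
})

test_that("equilibrium expression is rotation and mirror invariant", {
  set.seed(29)
  for (rep in 1:5) {
    g <- random_genome(10)
    st <- suppressWarnings(solve_expression(g, p_default, "A"))
    base <- st$expression[order(st$gene_id)]
    for (gt in list(rotate_genome(g, 13577), rotate_genome(g, 211.5),
                    mirror_genome(g))) {
      stt <- suppressWarnings(solve_expression(gt, p_default, "A"))
      expect_equal(stt$expression[order(stt$gene_id)], base,
                   tolerance = 1e-12)
    }
  }
})

test_that("the solver finds the same fixed point as a brute-force oracle", {
  set.seed(37)
  multistable <- 0
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    g <- genome(
      data.frame(id = seq_len(n), type = sample(c("A", "B", "AB"), n, TRUE),
                 begin = (seq_len(n) - 1) * 1125, length = 1000,
                 orientation = sample(c(1L, -1L), n, TRUE)),
      total_length = max(n * 1125, 3000)
    )
    st <- solve_expression(g, p_default)
    M <- build_interaction_matrix(g, p_default)
    # dual route: the naive damped oracle, started from the same
    # threshold state, must land on the same fixed point
    e_half <- activation_threshold(p_default)
    alt <- ref_fixed_point(rep(e_half, n), M, -0.066, p_default)
    expect_true(alt$converged)
    expect_lt(max(abs(alt$e - st$expression)), 1e-6)
    # uniqueness is an empirical claim only: random starts may expose
    # additional attractors (e.g. the two poles of a convergent toggle);
    # count them rather than hiding them
    for (s in 1:20) {
      e0 <- runif(n, exp(-2.5), 1)
      other <- ref_fixed_point(e0, M, -0.066, p_default)
      if (other$converged && max(abs(other$e - st$expression)) > 1e-6) {
        multistable <- multistable + 1
      }
    }
  }
  if (multistable > 0) {
    message(sprintf(
      "multistability: %d/100 random starts reached a different fixed point",
      multistable
    ))
  }
  succeed()
})

test_that("the recorded trajectory starts at the threshold and ends converged", {
  set.seed(43)
  g <- random_genome(3)
  st <- solve_expression(g, p_default, record_trajectory = TRUE)
  expect_false(is.null(st$trajectory))
  expect_equal(st$trajectory[1, ], rep(activation_threshold(p_default), 9))
  expect_equal(st$trajectory[nrow(st$trajectory), ], st$expression)
})
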