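p_default <- sim_params()

test_that("activation counts stratify by type and environment", {
  g1 <- genome(data.frame(id = 1, type = "AB", begin = 0, length = 1000,
                          orientation = 1), total_length = 67500)
  act <- activation_counts(g1, p_default)
  # an isolated gene is expressed above threshold in both environments
  expect_equal(act["AB", "A"], 1)
  expect_equal(act["AB", "B"], 1)
  expect_equal(sum(act), 2)

  set.seed(81)
  g <- random_genome(20)
  act <- activation_counts(g, p_default)
  expect_true(all(act >= 0 & act <= 20))
})

test_that("environment sweeps agree with direct evaluation and baselines", {
  set.seed(83)
  g <- random_genome(5)
  grid <- c(-0.01, 0, 0.01)
  sw <- environment_sweep(g, p_default, grid = grid)
  expect_setequal(unique(sw$group), c("A", "B", "AB", "isolated"))
  # isolated baseline matches the closed form and decreases with relaxation
  iso <- sw$mean_expression[sw$group == "isolated"]
  expect_equal(iso, closed_chain(grid), tolerance = 1e-12)
  expect_true(all(diff(iso) < 0))
  # sweep values at the two environments equal direct evaluation
  rec <- evaluate_genome(g, p_default)
  for (ty in c("A", "B", "AB")) {
    expect_equal(
      sw$mean_expression[sw$group == ty & sw$delta_sigma_env == 0.01],
      rec$mean_expression[ty, "A"], tolerance = 1e-9)
    expect_equal(
      sw$mean_expression[sw$group == ty & sw$delta_sigma_env == -0.01],
      rec$mean_expression[ty, "B"], tolerance = 1e-9)
  }
  # random-genome baseline column appears when requested
  set.seed(84)
  sw2 <- environment_sweep(g, p_default, grid = 0, n_random = 2)
  expect_true("random" %in% sw2$group)
})

test_that("the pair census matches manual enumeration on a toy genome", {
  # three genes on a circle: 1 ->, 2 <-, 3 -> gives adjacencies
  # (1,2) convergent, (2,3) divergent, (3,1) tandem
  g <- toy_genome(c(1, -1, 1))
  cen <- census_pairs(g, p_default)
  counts <- cen$counts
  expect_equal(sum(counts$n), 6)  # 2n oriented pairs on an n-gene circle
  get <- function(f, t, o) {
    counts$n[counts$focal_type == f & counts$target_type == t &
               counts$orientation == o]
  }
  # types: 1=A, 2=B, 3=AB
  expect_equal(get("A", "B", "convergent"), 1)
  expect_equal(get("B", "A", "convergent"), 1)
  expect_equal(get("B", "AB", "divergent"), 1)
  expect_equal(get("AB", "B", "divergent"), 1)
  # pair (3 ->, 1 ->): reading 3 then 1 along the circle, focal AB is
  # upstream of target A
  expect_equal(get("AB", "A", "focal_upstream"), 1)
  expect_equal(get("A", "AB", "focal_downstream"), 1)
})

test_that("pair census respects the focal/target symmetry invariant", {
  set.seed(91)
  g <- random_genome(20)
  cen <- census_pairs(g, p_default)
  counts <- cen$counts
  for (f in c("A", "B", "AB")) {
    for (t in c("A", "B", "AB")) {
      up <- counts$n[counts$focal_type == f & counts$target_type == t &
                       counts$orientation == "focal_upstream"]
      down <- counts$n[counts$focal_type == t & counts$target_type == f &
                         counts$orientation == "focal_downstream"]
      expect_equal(up, down)
      conv_ft <- counts$n[counts$focal_type == f & counts$target_type == t &
                            counts$orientation == "convergent"]
      conv_tf <- counts$n[counts$focal_type == t & counts$target_type == f &
                            counts$orientation == "convergent"]
      expect_equal(conv_ft, conv_tf)
    }
  }
  # a convergent pair generates positive supercoiling in both directions
  # (the second circular adjacency of this 2-gene genome lies beyond
  # d_max and contributes nothing)
  gc <- genome(data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
                          length = 1000, orientation = c(1, -1)),
               total_length = 67500)
  cc <- census_pairs(gc, p_default)
  contrib <- cc$contributions
  for (env in c("A", "B")) {
    expect_gt(contrib$positive[contrib$focal_type == "A" &
                                 contrib$target_type == "B" &
                                 contrib$environment == env], 0)
    expect_gt(contrib$positive[contrib$focal_type == "B" &
                                 contrib$target_type == "A" &
                                 contrib$environment == env], 0)
  }
  expect_true(all(contrib$negative == 0))
})

test_that("triplet canonicalization quotients 216 raw classes into 108", {
  types <- c("A", "B", "AB")
  oris <- c(1L, -1L)
  raw <- expand.grid(t1 = types, t2 = types, t3 = types,
                     o1 = oris, o2 = oris, o3 = oris,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(raw), 216)
  labels <- vapply(seq_len(nrow(raw)), function(r) {
    canonical_triplet(unlist(raw[r, 1:3], use.names = FALSE),
                      unlist(raw[r, 4:6], use.names = FALSE))$label
  }, character(1))
  expect_equal(length(unique(labels)), 108)
  # each canonical class covers exactly two raw classes
  expect_true(all(table(labels) == 2))
  expect_equal(length(triplet_classes()), 108)

  # worked symmetry example: (A>, B<, AB<) maps to (AB>, B>, A<)
  can <- canonical_triplet(c("A", "B", "AB"), c(1L, -1L, -1L))
  expect_equal(can$types, c("AB", "B", "A"))
  expect_equal(can$orients, c(1L, 1L, -1L))
  # a triplet already in canonical form is untouched
  can2 <- canonical_triplet(c("AB", "B", "A"), c(1L, 1L, -1L))
  expect_equal(can2$label, can$label)
})

test_that("triplet frequencies cover every window exactly once", {
  set.seed(97)
  g <- random_genome(20)
  tab <- census_triplets(g)
  expect_equal(nrow(tab), 108)
  expect_equal(sum(tab$count), 60)
  expect_equal(sum(tab$frequency), 1)

  # manual check on a three-gene genome: every window canonicalizes to a
  # class present in the table
  gt <- toy_genome(c(1, -1, 1))
  tt <- census_triplets(gt)
  expect_equal(sum(tt$count), 3)
})

test_that("minimal subnetworks reproduce full-genome activation minimally", {
  g1 <- genome(data.frame(id = 1, type = "AB", begin = 0, length = 1000,
                          orientation = 1), total_length = 67500)
  expect_equal(minimal_subnetwork_size(g1, p_default, 1, "A"), 1)

  set.seed(101)
  g <- random_genome(10)
  full <- suppressWarnings(solve_expression(g, p_default, "A"))
  e_half <- activation_threshold(p_default)
  for (gid in g$id[1:6]) {
    k <- minimal_subnetwork_size(g, p_default, gid, "A")
    center <- match(gid, g$id)
    # the returned k reproduces the full-genome state
    if (k < n_genes(g)) {
      sub <- tscevo:::extract_subnetwork(g, center, k)
      st <- suppressWarnings(solve_expression(sub, p_default,
                                              delta_sigma_env = "A",
                                              circular = FALSE))
      expect_equal(st$activated[(k + 1) / 2], full$activated[center])
      # ... and no smaller odd size does
      if (k > 1) {
        sub2 <- tscevo:::extract_subnetwork(g, center, k - 2)
        st2 <- suppressWarnings(solve_expression(sub2, p_default,
                                                 delta_sigma_env = "A",
                                                 circular = FALSE))
        expect_false(st2$activated[(k - 1) / 2] == full$activated[center])
      }
    }
  }
})

test_that("knockout switch sets exclude the knocked gene and detect isolation", {
  # non-interacting genome: all pairwise distances beyond d_max
  gfar <- genome(
    data.frame(id = 1:3, type = c("A", "B", "AB"),
               begin = c(0, 20000, 40000), length = 1000,
               orientation = c(1, -1, 1)),
    total_length = 60000
  )
  sw <- knockout_switches(gfar, p_default, 1)
  expect_equal(nrow(sw$A), 0)
  expect_equal(nrow(sw$B), 0)

  set.seed(103)
  g <- random_genome(10)
  for (gid in g$id[1:5]) {
    sw <- knockout_switches(g, p_default, gid)
    expect_false(gid %in% c(sw$A$gene_id, sw$B$gene_id))
  }
  expect_error(knockout_switches(g, p_default, 999), "not present")
})

test_that("the effective interaction graph reflects knockout switches", {
  gfar <- genome(
    data.frame(id = 1:3, type = c("A", "B", "AB"),
               begin = c(0, 20000, 40000), length = 1000,
               orientation = c(1, -1, 1)),
    total_length = 60000
  )
  graph <- build_effective_graph(gfar, p_default)
  expect_equal(igraph::vcount(graph), 3)
  expect_equal(igraph::ecount(graph), 0)
  st <- graph_stats(graph)
  expect_equal(st$wcc_sizes, c(1, 1, 1))
  expect_equal(sum(st$n_edges), 0)

  set.seed(107)
  g <- random_genome(5)
  graph <- build_effective_graph(g, p_default)
  expect_equal(igraph::vcount(graph), 15)
  # edge g -> h exists iff the knockout of g switches h somewhere
  edges <- igraph::as_data_frame(graph, what = "edges")
  for (gid in g$id) {
    sw <- knockout_switches(g, p_default, gid)
    switched <- sort(unique(c(sw$A$gene_id, sw$B$gene_id)))
    from_g <- sort(as.integer(edges$to[edges$from == as.character(gid)]))
    expect_equal(from_g, switched)
  }
  # handshake: degree sums equal the edge count
  st <- graph_stats(graph)
  types <- factor(igraph::V(graph)$type, c("A", "B", "AB"))
  expect_equal(sum(igraph::degree(graph, mode = "out")), st$n_edges)
  expect_equal(sum(igraph::degree(graph, mode = "in")), st$n_edges)
  # determinism
  graph2 <- build_effective_graph(g, p_default)
  expect_true(igraph::identical_graphs(graph, graph2))
})

test_that("random genome baselines are reproducible and well-formed", {
  set.seed(109)
  a <- random_genome_baseline(p_default, 3, function(g) n_genes(g))
  expect_equal(unlist(a), c(60, 60, 60))
  set.seed(109)
  b <- random_genome_baseline(p_default, 3, function(g) g$begin[5])
  set.seed(109)
  b2 <- random_genome_baseline(p_default, 3, function(g) g$begin[5])
  expect_identical(b, b2)
})

test_that("geometric mean fitness aggregates replicate traces", {
  log1 <- data.frame(generation = 0:2, best_fitness = c(0.1, 0.2, 0.4))
  log2 <- data.frame(generation = 0:2, best_fitness = c(0.4, 0.2, 0.1))
  gm <- geometric_mean_best_fitness(list(log1, log2))
  expect_equal(gm$geom_mean_fitness, c(0.2, 0.2, 0.2))
  # identical replicates reproduce the trace; gm <= arithmetic mean
  gm1 <- geometric_mean_best_fitness(list(log1, log1))
  expect_equal(gm1$geom_mean_fitness, log1$best_fitness)
  set.seed(113)
  logs <- lapply(1:4, function(i) {
    data.frame(generation = 0:5, best_fitness = runif(6))
  })
  gm2 <- geometric_mean_best_fitness(logs)
  am <- rowMeans(sapply(logs, `[[`, "best_fitness"))
  expect_true(all(gm2$geom_mean_fitness <= am + 1e-12))
})
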