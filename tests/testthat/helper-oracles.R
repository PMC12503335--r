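# Independent reference implementations used as oracles. These are kept
# deliberately naive (dense arithmetic, explicit case tables, brute-force
# iteration) and share no code with the package internals they check.

# Closed-form expression chain for a gene feeling only background
# supercoiling: sigma -> opening sigmoid -> exponential expression.
closed_chain <- function(delta_sigma, sigma_basal = -0.066,
                         sigma_half = -0.042, epsilon = 0.005, m = 2.5) {
  sigma <- sigma_basal + delta_sigma
  U <- 1 / (1 + exp((sigma - sigma_half) / epsilon))
  exp(m * (U - 1))
}

# Hand-enumerated sign table of the twin-domain interaction, keyed by
# (side of j relative to i's reading direction, same strand?).
ref_eta_table <- function(side, same_strand) {
  key <- paste(side, same_strand)
  switch(key,
    "upstream TRUE" = 1L,
    "upstream FALSE" = -1L,
    "downstream TRUE" = -1L,
    "downstream FALSE" = 1L,
    stop("bad key")
  )
}

# Reference signed offset computed from explicit arc walks: enumerate the
# two arcs from i's promoter to j's middle and take the shorter.
ref_signed_offset <- function(g, i, j) {
  L <- g$total_length
  p <- if (g$orientation[i] > 0) g$begin[i] else g$begin[i] + g$length[i]
  p <- p %% L
  mid <- (g$begin[j] + g$length[j] / 2) %% L
  # arc walking in increasing coordinates from p to mid
  arc_up_coords <- (mid - p) %% L
  if (g$orientation[i] > 0) {
    down <- arc_up_coords
  } else {
    down <- (L - arc_up_coords) %% L
  }
  up <- L - down
  if (down == up) return(list(distance = down, side = "tie"))
  if (down < up) list(distance = down, side = "downstream")
  else list(distance = up, side = "upstream")
}

# Dense R implementation of one expression update (Eq chain), used for
# residual checks and the brute-force fixed-point oracle.
ref_update <- function(e, M, sigma0, params) {
  sigma <- sigma0 + as.numeric(M %*% e)
  U <- 1 / (1 + exp(pmin(pmax((sigma - params$sigma_half) / params$epsilon,
                              -700), 700)))
  exp(params$m * (U - 1))
}

# Brute-force damped fixed-point solver from an arbitrary start.
ref_fixed_point <- function(e0, M, sigma0, params, w = 0.1,
                            tol = 1e-12, max_iter = 2e5) {
  e <- e0
  for (t in seq_len(max_iter)) {
    enew <- e + w * (ref_update(e, M, sigma0, params) - e)
    if (max(abs(enew - e)) < tol) return(list(e = enew, converged = TRUE))
    e <- enew
  }
  list(e = e, converged = FALSE)
}

# Small three-gene toy genome with controllable orientations.
toy_genome <- function(orientations = c(1, 1, 1), spacing = 1125,
                       gene_length = 1000, sigma_basal = -0.066) {
  genome(
    data.frame(
      id = 1:3, type = c("A", "B", "AB"),
      begin = (0:2) * spacing, length = gene_length,
      orientation = orientations
    ),
    total_length = 3 * spacing, sigma_basal = sigma_basal
  )
}

expect_same_genome <- function(a, b) {
  expect_equal(a$id, b$id)
  expect_equal(a$type, b$type)
  expect_identical(a$begin, b$begin)
  expect_identical(a$length, b$length)
  expect_identical(a$orientation, b$orientation)
  expect_identical(a$total_length, b$total_length)
}
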