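#' Simulation parameters
#'
#' Bundles every constant of the transcription-supercoiling coupling model
#' and of the evolutionary simulation. Defaults are averaged *E. coli*
#' values: gene length 1 kb, initial intergenic distance 125 bp,
#' supercoiling transmission distance 5 kb, basal supercoiling -0.066,
#' torsional drag 0.03, promoter opening threshold -0.042, opening
#' sensitivity 0.005 and inverse effective thermal energy 2.5.
#'
#' @param c Torsional drag coefficient: magnitude of the supercoiling
#'   variation generated at zero distance by a fully expressed gene
#'   (dimensionless supercoiling density).
#' @param d_max Supercoiling transmission distance in bp; beyond it two
#'   genes do not interact.
#' @param sigma_basal Basal (background) supercoiling density of the
#'   chromosome. Negative values denote underwinding.
#' @param sigma_half Supercoiling level at which the promoter opening
#'   sigmoid is at half maximum.
#' @param epsilon Width of the promoter opening sigmoid crossover.
#' @param m Inverse effective thermal energy; expression ranges in
#'   `[exp(-m), 1]`.
#' @param k_selection Selection intensity: fitness is `exp(-k * g)` where
#'   `g` is the squared distance of per-type mean expression to its
#'   targets.
#' @param lam Poisson rate of genomic inversions per reproduction.
#' @param pop_size Number of individuals per population.
#' @param delta_sigma_A,delta_sigma_B Supercoiling shift imposed by
#'   environment A (DNA relaxation, positive) and environment B (increased
#'   negative supercoiling).
#' @param gene_length Gene length in bp.
#' @param intergene Initial intergenic distance in bp.
#' @param n_genes_per_type Number of genes of each of the three types
#'   (A, B, AB) on a freshly generated genome.
#' @param solver_tol Max-norm convergence tolerance of the fixed-point
#'   expression solver.
#' @param solver_max_iter Iteration cap of the fixed-point solver.
#' @param damping Damping factor of the fixed-point update (1 = plain
#'   synchronous substitution).
#'
#' @return An object of class `tsc_params` (a validated named list).
#' @export
#' @examples
#' p <- sim_params()
#' activation_threshold(p)
sim_params <- function(c = 0.03,
                       d_max = 5000,
                       sigma_basal = -0.066,
                       sigma_half = -0.042,
                       epsilon = 0.005,
                       m = 2.5,
                       k_selection = 50,
                       lam = 2,
                       pop_size = 100,
                       delta_sigma_A = 0.01,
                       delta_sigma_B = -0.01,
                       gene_length = 1000,
                       intergene = 125,
                       n_genes_per_type = 20,
                       solver_tol = 1e-10,
                       solver_max_iter = 40000,
                       damping = 1) {
  p <- list(
    c = c, d_max = d_max, sigma_basal = sigma_basal,
    sigma_half = sigma_half, epsilon = epsilon, m = m,
    k_selection = k_selection, lam = lam, pop_size = pop_size,
    delta_sigma_A = delta_sigma_A, delta_sigma_B = delta_sigma_B,
    gene_length = gene_length, intergene = intergene,
    n_genes_per_type = n_genes_per_type,
    solver_tol = solver_tol, solver_max_iter = solver_max_iter,
    damping = damping
  )
  validate_params(p)
  structure(p, class = "tsc_params")
}

validate_params <- function(p) {
  stopifnot(
    is.numeric(p$d_max), p$d_max > 0,
    is.numeric(p$epsilon), p$epsilon > 0,
    is.numeric(p$m), p$m > 0,
    is.numeric(p$pop_size), p$pop_size >= 1,
    is.numeric(p$lam), p$lam >= 0,
    is.numeric(p$k_selection), p$k_selection >= 0,
    is.numeric(p$gene_length), p$gene_length > 0,
    is.numeric(p$intergene), p$intergene >= 0,
    is.numeric(p$n_genes_per_type), p$n_genes_per_type >= 1,
    is.numeric(p$solver_tol), p$solver_tol > 0,
    is.numeric(p$solver_max_iter), p$solver_max_iter >= 1,
    is.numeric(p$damping), p$damping > 0, p$damping <= 1
  )
  invisible(p)
}

#' @export
print.tsc_params <- function(x, ...) {
  cat("Transcription-supercoiling coupling parameters\n")
  cat(sprintf("  genome : gene_length=%g bp, intergene=%g bp, %g genes/type\n",
              x$gene_length, x$intergene, x$n_genes_per_type))
  cat(sprintf("  coupling: c=%g, d_max=%g bp, sigma_basal=%g\n",
              x$c, x$d_max, x$sigma_basal))
  cat(sprintf("  promoter: sigma_half=%g, epsilon=%g, m=%g\n",
              x$sigma_half, x$epsilon, x$m))
  cat(sprintf("  evolution: k=%g, lambda=%g, N=%g, dsA=%+g, dsB=%+g\n",
              x$k_selection, x$lam, x$pop_size,
              x$delta_sigma_A, x$delta_sigma_B))
  invisible(x)
}

#' Environmental supercoiling shifts
#'
#' @param params A [sim_params()] object.
#' @return Named numeric vector `c(A = delta_sigma_A, B = delta_sigma_B)`.
#' @export
environments <- function(params) {
  c(A = params$delta_sigma_A, B = params$delta_sigma_B)
}

# Resolve an environment given either by label ("A"/"B") or as a numeric
# supercoiling shift.
resolve_env <- function(env, params) {
  if (is.character(env)) {
    env <- match.arg(env, c("A", "B"))
    return(environments(params)[[env]])
  }
  stopifnot(is.numeric(env), length(env) == 1)
  env
}
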