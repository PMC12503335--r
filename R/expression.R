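#' Supercoiling interaction matrix of a genome
#'
#' Entry `(i, j)` is the infinitesimal variation of supercoiling at the
#' promoter of gene `i` per unit of expression of gene `j`:
#' `eta * c * max(1 - d(i, j) / d_max, 0)`, where `d(i, j)` is the
#' shortest circular distance from gene `i`'s promoter to gene `j`'s
#' middle, and `eta` follows the twin-domain sign rules (see [eta()]).
#' The diagonal is zero: genes do not interact with themselves.
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @param circular If `FALSE`, genes are treated as a linear arrangement
#'   (no wrap-around interactions); used for contiguous subnetworks.
#' @return An `n x n` numeric matrix.
#' @export
build_interaction_matrix <- function(g, params = sim_params(),
                                     circular = TRUE) {
  cpp_interaction_matrix(g$begin, g$length, g$orientation, g$total_length,
                         params$c, params$d_max, circular)
}

#' Local supercoiling at each promoter
#'
#' Background level plus the transcription-generated contribution of every
#' other gene: `sigma_i = sigma_basal + delta_sigma_env + sum_j M[i, j] * e_j`.
#'
#' @param M Interaction matrix from [build_interaction_matrix()].
#' @param e Expression vector (0 allowed only for knocked-out genes).
#' @param params A [sim_params()] object (supplies `sigma_basal`).
#' @param delta_sigma_env Environmental supercoiling shift.
#' @return Numeric vector of local supercoiling densities.
#' @export
local_supercoiling <- function(M, e, params = sim_params(),
                               delta_sigma_env = 0) {
  as.numeric(params$sigma_basal + delta_sigma_env + M %*% e)
}

#' Promoter opening free energy
#'
#' Sigmoid response of promoter opening to local supercoiling:
#' `U = 1 / (1 + exp((sigma - sigma_half) / epsilon))`, strictly
#' decreasing in `sigma` (negative supercoiling favors opening).
#' Arguments beyond the overflow range saturate exactly to 0 or 1.
#'
#' @param sigma Local supercoiling density (vectorized).
#' @param params A [sim_params()] object.
#' @return Opening values in `[0, 1]`.
#' @export
opening_energy <- function(sigma, params = sim_params()) {
  z <- (sigma - params$sigma_half) / params$epsilon
  out <- numeric(length(z))
  out[z > 700] <- 0
  out[z < -700] <- 1
  mid <- z >= -700 & z <= 700
  out[mid] <- 1 / (1 + exp(z[mid]))
  out
}

#' Expression level from promoter opening
#'
#' `e = exp(m * (U - 1))`, ranging from `exp(-m)` (promoter fully
#' hindered) to 1 (fully open).
#'
#' @param U Opening values in `[0, 1]` (vectorized).
#' @param params A [sim_params()] object.
#' @return Expression levels in `[exp(-m), 1]`.
#' @export
expression_from_opening <- function(U, params = sim_params()) {
  exp(params$m * (U - 1))
}

#' Activation threshold
#'
#' Midpoint between the minimal and maximal expression levels,
#' `(exp(-m) + 1) / 2`. A gene is "activated" when its expression is
#' strictly above this value.
#'
#' @param params A [sim_params()] object.
#' @return The threshold `e_1/2`.
#' @export
activation_threshold <- function(params = sim_params()) {
  (exp(-params$m) + 1) / 2
}

#' Closed-form expression of an isolated gene
#'
#' A gene without interacting neighbors feels only the background
#' supercoiling, so its expression follows directly from the opening
#' sigmoid: useful as the neighbor-less baseline of environment sweeps.
#'
#' @param delta_sigma_env Environmental supercoiling shift (vectorized).
#' @param params A [sim_params()] object.
#' @return Expression levels.
#' @export
isolated_expression <- function(delta_sigma_env, params = sim_params()) {
  expression_from_opening(
    opening_energy(params$sigma_basal + delta_sigma_env, params), params
  )
}

#' Equilibrium gene expression of a genome
#'
#' Computes the fixed point of the transcription-supercoiling system by
#' synchronous substitution: starting from all genes at the activation
#' threshold `e_1/2`, expression and local supercoiling are recomputed
#' from one another until the max-norm change falls below `solver_tol`.
#' Knocked-out genes have their expression pinned to exactly 0 at every
#' step (they generate no supercoiling). The result is deterministic for
#' fixed inputs.
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @param delta_sigma_env Environmental supercoiling shift, or an
#'   environment label `"A"` / `"B"`.
#' @param knockouts Integer vector of gene ids to knock out.
#' @param record_trajectory If `TRUE`, keep the per-iteration expression
#'   matrix (iterations in rows).
#' @param circular Evaluate on the circle (default) or as a linear gene
#'   arrangement.
#' @return An object of class `tsc_expression`: list with `expression`,
#'   `sigma_local`, `opening`, `activated` (logical), `iterations`,
#'   `converged`, `gene_id`, `type`, and optionally `trajectory`.
#'   A warning is raised if the iteration did not converge.
#' @export
#' @examples
#' set.seed(1)
#' g <- random_genome(2)
#' st <- solve_expression(g, sim_params(), delta_sigma_env = "A")
#' st$expression
solve_expression <- function(g, params = sim_params(), delta_sigma_env = 0,
                             knockouts = integer(0),
                             record_trajectory = FALSE, circular = TRUE) {
  ds <- resolve_env(delta_sigma_env, params)
  M <- build_interaction_matrix(g, params, circular = circular)
  knocked <- g$id %in% knockouts
  if (length(knockouts) > 0 && sum(knocked) != length(unique(knockouts))) {
    stop("knockouts must be existing gene ids")
  }
  res <- cpp_fixed_point(
    M, g$sigma_basal + ds, params$sigma_half, params$epsilon, params$m,
    knocked, params$solver_tol, params$solver_max_iter, params$damping,
    record_trajectory
  )
  if (!res$converged) {
    warning(sprintf(
      "fixed-point iteration did not converge within %d iterations",
      params$solver_max_iter
    ))
  }
  structure(
    list(
      expression = res$expression,
      sigma_local = res$sigma_local,
      opening = res$opening,
      activated = res$expression > activation_threshold(params) & !knocked,
      iterations = res$iterations,
      converged = res$converged,
      gene_id = g$id,
      type = g$type,
      knocked = knocked,
      trajectory = res$trajectory
    ),
    class = "tsc_expression"
  )
}

#' @export
print.tsc_expression <- function(x, ...) {
  cat(sprintf(
    "Expression state: %d genes, %d activated, %s in %d iterations\n",
    length(x$expression), sum(x$activated),
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Serialize an expression state to a data frame / CSV
#'
#' @param state A `tsc_expression`.
#' @param g The `tsc_genome` it was computed from.
#' @param path Optional CSV path; when given the table is also written.
#' @param trajectory_path Optional CSV path for the per-iteration
#'   trajectory in long format (iteration, gene_id, expression); requires
#'   a state solved with `record_trajectory = TRUE`.
#' @return Data frame with one row per gene: id, type, orientation,
#'   begin, expression, sigma_local and activation.
#' @export
expression_table <- function(state, g, path = NULL, trajectory_path = NULL) {
  if (!is.null(trajectory_path)) {
    if (is.null(state$trajectory)) {
      stop("state has no recorded trajectory; solve with record_trajectory = TRUE")
    }
    tr <- state$trajectory
    long <- data.frame(
      iteration = rep(seq_len(nrow(tr)) - 1L, times = ncol(tr)),
      gene_id = rep(state$gene_id, each = nrow(tr)),
      expression = as.vector(tr)
    )
    write.csv(long, trajectory_path, row.names = FALSE)
  }
  df <- data.frame(
    gene_id = state$gene_id, type = state$type,
    orientation = ifelse(g$orientation > 0, "+", "-"),
    begin = g$begin,
    expression = state$expression, sigma_local = state$sigma_local,
    activated = state$activated
  )
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
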