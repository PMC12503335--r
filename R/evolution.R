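#' Per-type expression targets in each environment
#'
#' Environment A (DNA relaxation) wants A and AB genes fully expressed
#' (target 1) and B genes at the minimal level `exp(-m)`; environment B
#' is symmetric under swapping A and B.
#'
#' @param params A [sim_params()] object.
#' @return A 3 x 2 matrix, rows `A`, `B`, `AB`, columns `A`, `B`.
#' @export
expression_targets <- function(params = sim_params()) {
  e_min <- exp(-params$m)
  matrix(c(1, e_min, 1, e_min, 1, 1), nrow = 3, byrow = FALSE,
         dimnames = list(c("A", "B", "AB"), c("A", "B")))
}

type_codes <- function(g) {
  match(g$type, c("A", "B", "AB")) - 1L
}

#' Evaluate the fitness of a genome
#'
#' Solves the expression fixed point in both environments, computes the
#' per-type mean expression levels, the gap `g` (sum of squared
#' deviations of the six per-type means from their targets) and the
#' fitness `f = exp(-k * g)`.
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @return A list of class `tsc_fitness`: `fitness`, `gap`,
#'   `mean_expression` (3 x 2 matrix, types x environments),
#'   `activated` (3 x 2 counts) and `converged`. Solver non-convergence
#'   is surfaced as a warning; fitness is still computed from the
#'   returned state.
#' @export
evaluate_genome <- function(g, params = sim_params()) {
  res <- cpp_evaluate_genome(
    g$begin, g$length, g$orientation, type_codes(g), g$total_length,
    g$sigma_basal, params$c, params$d_max, params$sigma_half,
    params$epsilon, params$m, params$delta_sigma_A, params$delta_sigma_B,
    params$k_selection, params$solver_tol, params$solver_max_iter,
    params$damping
  )
  if (!res$converged) {
    warning("expression solver did not converge for at least one environment")
  }
  dimnames(res$mean_expression) <- dimnames(res$activated) <-
    list(c("A", "B", "AB"), c("A", "B"))
  structure(
    list(fitness = res$fitness, gap = res$gap,
         mean_expression = res$mean_expression, activated = res$activated,
         converged = res$converged),
    class = "tsc_fitness"
  )
}

#' @export
print.tsc_fitness <- function(x, ...) {
  cat(sprintf("fitness = %.6g (gap = %.6g)\n", x$fitness, x$gap))
  print(round(x$mean_expression, 4))
  invisible(x)
}

#' Fitness-proportional selection with replacement
#'
#' @param fitness Vector of strictly positive fitness values.
#' @param n Number of reproducers to draw (defaults to the population
#'   size).
#' @return Integer vector of `n` selected indices.
#' @export
select_reproducers <- function(fitness, n = length(fitness)) {
  if (any(fitness <= 0) || !all(is.finite(fitness))) {
    stop("all fitness values must be strictly positive and finite")
  }
  sample.int(length(fitness), n, replace = TRUE, prob = fitness)
}

#' Initialize a population of clones
#'
#' Seeds the population with `pop_size` clones of a single randomly
#' generated genome, as at the start of an evolutionary run.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `tsc_population`: `individuals` (list of
#'   genomes), `generation`, and a per-individual fitness cache.
#' @export
init_population <- function(params = sim_params()) {
  founder <- random_genome(params$n_genes_per_type, params$gene_length,
                           params$intergene, params$sigma_basal)
  structure(
    list(
      individuals = rep(list(founder), params$pop_size),
      cache = vector("list", params$pop_size),
      generation = 0L
    ),
    class = "tsc_population"
  )
}

#' @export
print.tsc_population <- function(x, ...) {
  cat(sprintf("Population of %d individuals at generation %d\n",
              length(x$individuals), x$generation))
  invisible(x)
}

# Evaluate every individual, reusing cached records for unmutated clones.
evaluate_population <- function(pop, params) {
  lapply(seq_along(pop$individuals), function(i) {
    rec <- pop$cache[[i]]
    if (is.null(rec)) evaluate_genome(pop$individuals[[i]], params) else rec
  })
}

# One log row per generation, as a named numeric vector (cheap inside the
# generational loop; run logs convert to a data frame once at the end).
generation_record <- function(generation, recs) {
  fit <- vapply(recs, `[[`, numeric(1), "fitness")
  best <- which.max(fit)
  act <- recs[[best]]$activated
  c(
    generation = generation,
    best_fitness = fit[best],
    best_gap = recs[[best]]$gap,
    mean_fitness = mean(fit),
    act_A_envA = act["A", "A"], act_B_envA = act["B", "A"],
    act_AB_envA = act["AB", "A"],
    act_A_envB = act["A", "B"], act_B_envB = act["B", "B"],
    act_AB_envB = act["AB", "B"]
  )
}

#' Advance a population by one generation
#'
#' Evaluates every individual in both environments, draws reproducers
#' proportionally to fitness with replacement, and creates each offspring
#' by applying Poisson-many random inversions to its parent. Generations
#' are non-overlapping and the population size is constant.
#'
#' @param pop A `tsc_population`.
#' @param params A [sim_params()] object.
#' @return A list with the next `tsc_population` (`population`) and the
#'   one-row log `record` of the evaluated parents (generation number,
#'   best fitness and gap, per-type activated counts of the best
#'   individual in each environment).
#' @export
step_generation <- function(pop, params = sim_params()) {
  step <- step_core(pop, params)
  step$record <- as.data.frame(as.list(step$record))
  step
}

step_core <- function(pop, params) {
  recs <- evaluate_population(pop, params)
  record <- generation_record(pop$generation, recs)
  fit <- vapply(recs, `[[`, numeric(1), "fitness")
  best_parent <- pop$individuals[[which.max(fit)]]
  parents <- select_reproducers(fit)
  offspring <- vector("list", length(parents))
  cache <- vector("list", length(parents))
  for (o in seq_along(parents)) {
    p <- parents[o]
    child <- pop$individuals[[p]]
    res <- cpp_mutate(child$begin, child$length, child$orientation,
                      child$total_length, params$lam)
    if (res$n_inversions == 0) {
      cache[[o]] <- recs[[p]]  # clone: expression state is unchanged
    } else {
      child <- rearranged_genome(child, res)
    }
    offspring[[o]] <- child
  }
  pop$individuals <- offspring
  pop$cache <- cache
  pop$generation <- pop$generation + 1L
  list(population = pop, record = record, best_genome = best_parent)
}

#' Run one evolutionary replicate
#'
#' Seeds the random stream, initializes a clonal population from one
#' random genome and iterates [step_generation()] for `n_generations`,
#' logging the best evaluated individual at every generation. With an
#' `output_dir`, writes `runlog.csv`, a `params.json` echo and periodic
#' best-genome snapshots (`best_gen<t>.json`, written atomically).
#'
#' @param seed Integer seed for the replicate's random stream.
#' @param params A [sim_params()] object.
#' @param n_generations Number of generations to simulate (0 = log the
#'   initial generation only).
#' @param output_dir Optional output directory.
#' @param checkpoint_every Snapshot cadence in generations.
#' @return A list of class `tsc_run`: `runlog` (data frame, one row per
#'   generation), `population` (final), `best_genome` (best individual of
#'   the last evaluated generation), `seed` and `params`.
#' @export
#' @examples
#' p <- sim_params(pop_size = 10, n_genes_per_type = 3)
#' run <- run_replicate(seed = 1, params = p, n_generations = 5)
#' run$runlog$best_fitness
run_replicate <- function(seed, params = sim_params(), n_generations,
                          output_dir = NULL, checkpoint_every = 1000) {
  stopifnot(n_generations >= 0)
  set.seed(seed)
  pop <- init_population(params)
  logs <- vector("list", n_generations + 1)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(params),
                         file.path(output_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (t in seq_len(n_generations)) {
    step <- step_core(pop, params)
    logs[[t]] <- step$record
    pop <- step$population
    if (!is.null(output_dir) && (t %% checkpoint_every == 0)) {
      checkpoint_genome(step$best_genome, output_dir,
                        sprintf("best_gen%d.json", step$record[["generation"]]))
    }
  }
  # final evaluation: log the last generation's parents as well
  recs <- evaluate_population(pop, params)
  logs[[n_generations + 1]] <- generation_record(pop$generation, recs)
  pop$cache <- recs
  best_genome <- pop$individuals[[
    which.max(vapply(recs, `[[`, numeric(1), "fitness"))]]
  runlog <- as.data.frame(do.call(rbind, logs))
  if (!is.null(output_dir)) {
    write.csv(runlog, file.path(output_dir, "runlog.csv"), row.names = FALSE)
    checkpoint_genome(best_genome, output_dir,
                      sprintf("best_gen%d.json", pop$generation))
  }
  structure(
    list(runlog = runlog, population = pop, best_genome = best_genome,
         seed = seed, params = params),
    class = "tsc_run"
  )
}

checkpoint_genome <- function(g, dir, filename) {
  tmp <- file.path(dir, paste0(".", filename, ".tmp"))
  save_genome(g, tmp)
  file.rename(tmp, file.path(dir, filename))
}

#' @export
print.tsc_run <- function(x, ...) {
  last <- x$runlog[nrow(x$runlog), ]
  cat(sprintf(
    "Evolutionary run (seed %d): %d generations, best fitness %.4g (gap %.4g)\n",
    x$seed, last$generation, last$best_fitness, last$best_gap
  ))
  invisible(x)
}
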