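#' Activated gene counts per type and environment
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @return A 3 x 2 matrix (types A, B, AB x environments A, B) of counts
#'   of genes whose equilibrium expression exceeds the activation
#'   threshold.
#' @export
activation_counts <- function(g, params = sim_params()) {
  rec <- evaluate_genome(g, params)
  rec$activated
}

#' Mean expression per gene type across a supercoiling sweep
#'
#' Solves the expression fixed point of a genome over a grid of
#' environmental supercoiling shifts, alongside the neighbor-less
#' closed-form baseline and, optionally, the average expression of
#' freshly drawn random genomes with the same genome parameters.
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @param grid Numeric vector of supercoiling shifts (defaults to -0.02
#'   to +0.02 in steps of 0.001, bracketing the two environments).
#' @param n_random Number of random genomes for the baseline (0 = skip).
#'   Uses the current R random stream.
#' @return A long data frame with columns `delta_sigma_env`, `group`
#'   (`"A"`, `"B"`, `"AB"`, `"isolated"`, `"random"`),
#'   `mean_expression`, and `converged`.
#' @export
environment_sweep <- function(g, params = sim_params(),
                              grid = seq(-0.02, 0.02, by = 0.001),
                              n_random = 0) {
  stopifnot(is.numeric(grid), length(grid) >= 1)
  randoms <- if (n_random > 0) {
    replicate(n_random,
              random_genome(params$n_genes_per_type, params$gene_length,
                            params$intergene, params$sigma_basal),
              simplify = FALSE)
  } else {
    list()
  }
  rows <- lapply(grid, function(ds) {
    st <- suppressWarnings(solve_expression(g, params, delta_sigma_env = ds))
    by_type <- tapply(st$expression, factor(st$type, c("A", "B", "AB")), mean)
    out <- data.frame(
      delta_sigma_env = ds,
      group = c("A", "B", "AB", "isolated"),
      mean_expression = c(as.numeric(by_type),
                          isolated_expression(ds, params)),
      converged = st$converged
    )
    if (length(randoms) > 0) {
      rnd <- vapply(randoms, function(rg) {
        rst <- suppressWarnings(solve_expression(rg, params,
                                                 delta_sigma_env = ds))
        mean(rst$expression)
      }, numeric(1))
      out <- rbind(out, data.frame(
        delta_sigma_env = ds, group = "random",
        mean_expression = mean(rnd), converged = TRUE
      ))
    }
    out
  })
  do.call(rbind, rows)
}

# Relative orientation class of an adjacent (focal, target) pair, reading
# the short arc with the focal gene on the left. `focal_left` says whether
# the focal gene is the left (lower-coordinate) member; if not, the arc is
# reflected, which flips both orientations.
classify_pair <- function(ori_focal, ori_target, focal_left) {
  if (!focal_left) {
    ori_focal <- -ori_focal
    ori_target <- -ori_target
  }
  if (ori_focal > 0 && ori_target < 0) return("convergent")
  if (ori_focal < 0 && ori_target > 0) return("divergent")
  if (ori_focal > 0) return("focal_upstream")
  "focal_downstream"
}

pair_orientation_levels <- c("convergent", "divergent",
                             "focal_upstream", "focal_downstream")

#' Census of oriented pairs of neighboring genes
#'
#' Every adjacency on the circle yields two oriented pairs (each gene once
#' as the focal gene). Pairs are classified by relative orientation
#' (convergent, divergent, focal upstream, focal downstream) and
#' stratified by the types of the focal and target genes. For each pair
#' the supercoiling contribution of the focal gene at the target's
#' promoter (interaction coefficient times the focal gene's equilibrium
#' expression) is accumulated per environment, split into positive and
#' negative totals.
#'
#' @param g A `tsc_genome` with at least 2 genes.
#' @param params A [sim_params()] object.
#' @return A list of class `tsc_pair_census` with `counts` (complete
#'   3 x 3 x 4 grid: focal_type, target_type, orientation, n) and
#'   `contributions` (focal_type, target_type, environment,
#'   positive, negative).
#' @export
census_pairs <- function(g, params = sim_params()) {
  n <- n_genes(g)
  stopifnot(n >= 2)
  M <- build_interaction_matrix(g, params)
  expr <- lapply(environments(params), function(ds) {
    suppressWarnings(solve_expression(g, params, delta_sigma_env = ds))$expression
  })
  types <- c("A", "B", "AB")
  counts <- array(0L, dim = c(3, 3, 4),
                  dimnames = list(types, types, pair_orientation_levels))
  contrib <- array(0, dim = c(3, 3, 2, 2),
                   dimnames = list(types, types, c("A", "B"),
                                   c("positive", "negative")))
  for (left in seq_len(n)) {
    right <- if (left == n) 1L else left + 1L
    for (role in 1:2) {
      focal <- if (role == 1) left else right
      target <- if (role == 1) right else left
      orient <- classify_pair(g$orientation[focal], g$orientation[target],
                              focal_left = (role == 1))
      ft <- g$type[focal]
      tt <- g$type[target]
      counts[ft, tt, orient] <- counts[ft, tt, orient] + 1L
      for (env in c("A", "B")) {
        v <- M[target, focal] * expr[[env]][focal]
        if (v >= 0) {
          contrib[ft, tt, env, "positive"] <-
            contrib[ft, tt, env, "positive"] + v
        } else {
          contrib[ft, tt, env, "negative"] <-
            contrib[ft, tt, env, "negative"] + v
        }
      }
    }
  }
  counts_df <- expand.grid(
    focal_type = types, target_type = types,
    orientation = pair_orientation_levels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  counts_df$n <- mapply(function(f, t, o) counts[f, t, o],
                        counts_df$focal_type, counts_df$target_type,
                        counts_df$orientation)
  contrib_df <- expand.grid(
    focal_type = types, target_type = types, environment = c("A", "B"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  contrib_df$positive <- mapply(
    function(f, t, e) contrib[f, t, e, "positive"],
    contrib_df$focal_type, contrib_df$target_type, contrib_df$environment)
  contrib_df$negative <- mapply(
    function(f, t, e) contrib[f, t, e, "negative"],
    contrib_df$focal_type, contrib_df$target_type, contrib_df$environment)
  structure(list(counts = counts_df, contributions = contrib_df),
            class = "tsc_pair_census")
}

triplet_label <- function(types, orients) {
  paste0(types, ifelse(orients > 0, ">", "<"), collapse = " ")
}

#' Canonicalize a gene triplet class
#'
#' A triplet read in the opposite direction is the same physical
#' arrangement, so classes are quotiented by keeping the representative
#' whose central gene is in forward (leading) orientation: when the
#' central gene is reverse, the tuple is reversed and all orientations
#' flipped.
#'
#' @param types Character vector of 3 gene types.
#' @param orients Integer vector of 3 orientations (`+1` / `-1`).
#' @return A list with canonical `types`, `orients`, and a `label`
#'   string such as `"AB> B> A<"`.
#' @export
canonical_triplet <- function(types, orients) {
  stopifnot(length(types) == 3, length(orients) == 3)
  if (orients[2] < 0) {
    types <- rev(types)
    orients <- -rev(orients)
  }
  list(types = types, orients = orients,
       label = triplet_label(types, orients))
}

#' All canonical triplet classes
#'
#' Enumerates the `3^3 * 2^3 = 216` raw (type, orientation) triplet
#' classes and quotients them by the symmetry of [canonical_triplet()],
#' giving 108 canonical classes.
#'
#' @return Character vector of the 108 canonical class labels.
#' @export
triplet_classes <- function() {
  types <- c("A", "B", "AB")
  oris <- c(1L, -1L)
  grid <- expand.grid(t1 = types, t2 = types, t3 = types,
                      o1 = oris, o2 = oris, o3 = oris,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  labels <- vapply(seq_len(nrow(grid)), function(r) {
    canonical_triplet(unlist(grid[r, 1:3], use.names = FALSE),
                      unlist(grid[r, 4:6], use.names = FALSE))$label
  }, character(1))
  sort(unique(labels))
}

#' Census of consecutive gene triplets
#'
#' Each of the `n` consecutive windows of 3 genes on the circle is mapped
#' to its canonical class; relative frequency is count / n.
#'
#' @param g A `tsc_genome` with at least 3 genes.
#' @return Data frame over all 108 canonical classes with `class`,
#'   `count` and `frequency` (summing to 1).
#' @export
census_triplets <- function(g) {
  n <- n_genes(g)
  stopifnot(n >= 3)
  classes <- triplet_classes()
  counts <- setNames(integer(length(classes)), classes)
  for (i in seq_len(n)) {
    idx <- ((i - 2):i %% n) + 1L  # window centered on gene i
    lab <- canonical_triplet(g$type[idx], g$orientation[idx])$label
    counts[lab] <- counts[lab] + 1L
  }
  data.frame(class = classes, count = as.integer(counts),
             frequency = as.numeric(counts) / n, row.names = NULL)
}

# Extract the k consecutive genes centered on position index `center`
# (begin order), unrolled to a linear arrangement that preserves the
# original circular arc distances between the extracted genes.
extract_subnetwork <- function(g, center, k) {
  n <- n_genes(g)
  h <- (k - 1) / 2
  idx <- ((center - h - 1 + (0:(k - 1))) %% n) + 1L
  L <- g$total_length
  begins <- g$begin[idx]
  if (k > 1) {
    gaps <- diff(begins) %% L
    begins <- cumsum(c(0, gaps))
  } else {
    begins <- 0
  }
  sub <- structure(
    list(
      id = g$id[idx], type = g$type[idx], begin = begins,
      length = g$length[idx], orientation = g$orientation[idx],
      basal_expression = g$basal_expression[idx],
      total_length = max(begins + g$length[idx]) + 1,
      sigma_basal = g$sigma_basal
    ),
    class = "tsc_genome"
  )
  sub
}

#' Minimal contiguous subnetwork size reproducing a gene's activation state
#'
#' For odd sizes `k = 1, 3, 5, ...` the `k` genes centered on the focal
#' gene are extracted with their original arc distances and evaluated as
#' a linear (non-circular) system; the returned `k` is the smallest for
#' which the central gene's activation state matches its state in the
#' complete genome. If no odd `k < n` matches, `n` is returned (the full
#' circular genome trivially matches).
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @param gene_id Id of the focal gene.
#' @param env Environment label `"A"` / `"B"` or a numeric supercoiling
#'   shift.
#' @return Odd integer subnetwork size (or `n`).
#' @export
minimal_subnetwork_size <- function(g, params = sim_params(), gene_id,
                                    env = "A") {
  ds <- resolve_env(env, params)
  center <- match(gene_id, g$id)
  if (is.na(center)) stop("gene_id not present in genome")
  full <- suppressWarnings(solve_expression(g, params, delta_sigma_env = ds))
  target_state <- full$activated[center]
  n <- n_genes(g)
  if (n == 1) return(1L)
  for (k in seq(1, n - 1, by = 2)) {
    sub <- extract_subnetwork(g, center, k)
    st <- suppressWarnings(
      solve_expression(sub, params, delta_sigma_env = ds, circular = FALSE)
    )
    central <- (k + 1) / 2
    if (st$activated[central] == target_state) return(k)
  }
  n
}

#' Genes switched by a single knockout
#'
#' Solves the expression fixed point with and without the knockout in
#' both environments and reports every other gene whose activation state
#' differs: `on_to_off` (the knocked-out gene was needed for activation)
#' or `off_to_on` (it was needed for inhibition).
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @param gene_id Id of the gene to knock out.
#' @return A list with one data frame per environment (`A`, `B`), each
#'   with columns `gene_id` and `direction`.
#' @export
knockout_switches <- function(g, params = sim_params(), gene_id) {
  if (!gene_id %in% g$id) stop("gene_id not present in genome")
  out <- lapply(environments(params), function(ds) {
    full <- suppressWarnings(solve_expression(g, params,
                                              delta_sigma_env = ds))
    ko <- suppressWarnings(solve_expression(g, params, delta_sigma_env = ds,
                                            knockouts = gene_id))
    switched <- which(full$activated != ko$activated & g$id != gene_id)
    data.frame(
      gene_id = g$id[switched],
      direction = ifelse(full$activated[switched], "on_to_off", "off_to_on")
    )
  })
  names(out) <- c("A", "B")
  out
}

#' Knockout-derived effective interaction graph
#'
#' Knocks out every gene in turn and adds a directed edge from the
#' knocked-out gene to every gene whose activation state is switched in
#' at least one environment. Edges are labeled `activation` (switched
#' off a gene that was on), `inhibition` (switched on a gene that was
#' off) or `mixed` when the two environments disagree; at most one edge
#' per ordered gene pair.
#'
#' @param g A `tsc_genome`.
#' @param params A [sim_params()] object.
#' @return A directed [igraph::graph] whose vertices carry the gene
#'   `type` attribute and edges a `label` attribute.
#' @export
build_effective_graph <- function(g, params = sim_params()) {
  edges <- list()
  for (gid in g$id) {
    sw <- knockout_switches(g, params, gid)
    tab <- rbind(
      if (nrow(sw$A)) cbind(sw$A, env = "A"),
      if (nrow(sw$B)) cbind(sw$B, env = "B")
    )
    if (is.null(tab) || nrow(tab) == 0) next
    for (target in unique(tab$gene_id)) {
      dirs <- unique(tab$direction[tab$gene_id == target])
      label <- if (length(dirs) > 1) {
        "mixed"
      } else if (dirs == "on_to_off") {
        "activation"
      } else {
        "inhibition"
      }
      edges[[length(edges) + 1]] <-
        data.frame(from = gid, to = target, label = label)
    }
  }
  edge_df <- if (length(edges)) {
    do.call(rbind, edges)
  } else {
    data.frame(from = integer(0), to = integer(0), label = character(0))
  }
  vertices <- data.frame(name = as.character(g$id), type = g$type)
  igraph::graph_from_data_frame(
    transform(edge_df, from = as.character(from), to = as.character(to)),
    directed = TRUE, vertices = vertices
  )
}

#' Summary statistics of an effective interaction graph
#'
#' @param graph A directed igraph from [build_effective_graph()].
#' @return A list with `wcc_sizes` (weakly connected component sizes,
#'   decreasing), `n_edges`, and mean out-/in-degree by gene type
#'   (out-degree grouped by the knocked-out gene's type, in-degree by the
#'   switched gene's type).
#' @export
graph_stats <- function(graph) {
  comp <- igraph::components(graph, mode = "weak")
  types <- factor(igraph::V(graph)$type, levels = c("A", "B", "AB"))
  outd <- igraph::degree(graph, mode = "out")
  ind <- igraph::degree(graph, mode = "in")
  list(
    wcc_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
    n_edges = igraph::ecount(graph),
    mean_out_degree = tapply(outd, types, mean),
    mean_in_degree = tapply(ind, types, mean)
  )
}

#' Apply an analysis to freshly drawn random genomes
#'
#' Draws `n_genomes` random genomes with the genome parameters of
#' `params` (the same scheme that seeds evolutionary runs) and applies
#' `stat_fun` to each, as a null baseline for evolved-genome statistics.
#' Uses the current R random stream.
#'
#' @param params A [sim_params()] object.
#' @param n_genomes Number of random genomes.
#' @param stat_fun Function of one `tsc_genome`.
#' @return List of `n_genomes` results of `stat_fun`.
#' @export
random_genome_baseline <- function(params = sim_params(), n_genomes = 30,
                                   stat_fun) {
  stopifnot(n_genomes >= 1, is.function(stat_fun))
  replicate(n_genomes, {
    g <- random_genome(params$n_genes_per_type, params$gene_length,
                       params$intergene, params$sigma_basal)
    stat_fun(g)
  }, simplify = FALSE)
}

#' Geometric mean of best fitness across replicate run logs
#'
#' @param runlogs List of run logs (data frames with `generation` and
#'   `best_fitness`), aligned on generations.
#' @return Data frame with `generation`, `geom_mean_fitness`, and the
#'   first/last decile traces `q10` / `q90`.
#' @export
geometric_mean_best_fitness <- function(runlogs) {
  stopifnot(length(runlogs) >= 1)
  gens <- runlogs[[1]]$generation
  fit <- vapply(runlogs, function(log) {
    stopifnot(identical(log$generation, gens))
    log$best_fitness
  }, numeric(length(gens)))
  fit <- matrix(fit, nrow = length(gens))
  if (any(fit <= 0)) stop("fitness values must be strictly positive")
  data.frame(
    generation = gens,
    geom_mean_fitness = exp(rowMeans(log(fit))),
    q10 = apply(fit, 1, quantile, probs = 0.1),
    q90 = apply(fit, 1, quantile, probs = 0.9)
  )
}
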