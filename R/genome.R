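#' Circular genome objects
#'
#' A `tsc_genome` holds an ordered set of non-overlapping, typed, oriented
#' genes on a circle of `total_length` bp, plus the basal supercoiling level
#' of the chromosome. Coordinates are 0-based half-open intervals
#' `[begin, begin + length)` taken modulo `total_length`; orientation is
#' `+1` (forward, increasing coordinates) or `-1` (reverse). Genes carry a
#' stored basal expression level (defaults to 1) which the expression model
#' does not currently use.
#'
#' @param genes A data frame with columns `id`, `type` (one of `"A"`,
#'   `"B"`, `"AB"`), `begin`, `length`, `orientation` (`+1`/`-1` or
#'   `"+"`/`"-"`), and optionally `basal_expression`.
#' @param total_length Total genome length in bp.
#' @param sigma_basal Basal supercoiling density.
#' @return An object of class `tsc_genome`.
#' @export
#' @examples
#' g <- genome(
#'   data.frame(id = 1:2, type = c("A", "B"), begin = c(0, 1125),
#'              length = 1000, orientation = c(1, -1)),
#'   total_length = 2250, sigma_basal = -0.066
#' )
#' n_genes(g)
genome <- function(genes, total_length, sigma_basal = -0.066) {
  stopifnot(is.data.frame(genes))
  if (is.character(genes$orientation)) {
    genes$orientation <- ifelse(genes$orientation == "+", 1L, -1L)
  }
  if (is.null(genes$basal_expression)) genes$basal_expression <- 1
  if (is.null(genes$id)) genes$id <- seq_len(nrow(genes))
  ord <- order(genes$begin)
  g <- structure(
    list(
      id = as.integer(genes$id[ord]),
      type = as.character(genes$type[ord]),
      begin = as.numeric(genes$begin[ord]),
      length = as.numeric(genes$length[ord]),
      orientation = as.integer(genes$orientation[ord]),
      basal_expression = as.numeric(genes$basal_expression[ord]),
      total_length = as.numeric(total_length),
      sigma_basal = as.numeric(sigma_basal)
    ),
    class = "tsc_genome"
  )
  validate_genome(g)
}

#' Validate the invariants of a circular genome
#'
#' Checks positive gene lengths, coordinates within `[0, total_length)`,
#' allowed types and orientations, and pairwise disjointness of the
#' occupied intervals (wrap-aware).
#'
#' @param g A `tsc_genome`.
#' @return `g`, invisibly; errors on any violated invariant.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "tsc_genome"))
  n <- length(g$begin)
  L <- g$total_length
  if (n == 0) stop("genome has no genes")
  if (any(g$length <= 0)) stop("gene lengths must be positive")
  if (sum(g$length) > L) stop("gene lengths exceed total genome length")
  if (any(g$begin < 0 | g$begin >= L)) stop("gene begins must lie in [0, L)")
  if (!all(g$type %in% c("A", "B", "AB"))) stop("gene types must be A, B or AB")
  if (!all(g$orientation %in% c(-1L, 1L))) stop("orientation must be +1 or -1")
  if (is.unsorted(g$begin)) stop("genes must be ordered by begin")
  if (n > 1) {
    # walking the circle in begin order, each gene must end at or before
    # the next gene's begin (circular gap for the last gene)
    nxt <- c(g$begin[-1], g$begin[1] + L)
    if (any(g$begin + g$length > nxt)) stop("gene intervals overlap")
  }
  invisible(g)
}

#' @export
print.tsc_genome <- function(x, ...) {
  cat(sprintf(
    "Circular genome: %d genes, %g bp, sigma_basal = %g\n",
    length(x$begin), x$total_length, x$sigma_basal
  ))
  tab <- table(factor(x$type, levels = c("A", "B", "AB")))
  cat(sprintf("  gene types: A=%d B=%d AB=%d; intergenic total = %g bp\n",
              tab[["A"]], tab[["B"]], tab[["AB"]],
              x$total_length - sum(x$length)))
  invisible(x)
}

#' @export
as.data.frame.tsc_genome <- function(x, ...) {
  data.frame(
    id = x$id, type = x$type, begin = x$begin, length = x$length,
    orientation = x$orientation, basal_expression = x$basal_expression
  )
}

#' Number of genes on a genome
#' @param g A `tsc_genome`.
#' @return Integer gene count.
#' @export
n_genes <- function(g) length(g$begin)

#' Generate a random circular genome
#'
#' Gene types form a uniformly random permutation of the multiset
#' \{A, B, AB\} x `n_per_type`; orientations are fair coin flips; genes are
#' equally spaced with intergenic distance `intergene`, ids assigned
#' clockwise starting at coordinate 0. Uses the current R random stream.
#'
#' @param n_per_type Number of genes of each type.
#' @param gene_length Gene length in bp.
#' @param intergene Intergenic distance in bp.
#' @param sigma_basal Basal supercoiling density.
#' @return A `tsc_genome` with `3 * n_per_type` genes and total length
#'   `3 * n_per_type * (gene_length + intergene)`.
#' @export
#' @examples
#' set.seed(1)
#' g <- random_genome()        # 60 genes, 67,500 bp at defaults
#' g
random_genome <- function(n_per_type = 20, gene_length = 1000,
                          intergene = 125, sigma_basal = -0.066) {
  stopifnot(n_per_type >= 1)
  n <- 3L * as.integer(n_per_type)
  types <- sample(rep(c("A", "B", "AB"), n_per_type))
  ori <- sample(c(1L, -1L), n, replace = TRUE)
  spacing <- gene_length + intergene
  genome(
    data.frame(
      id = seq_len(n), type = types,
      begin = (seq_len(n) - 1) * spacing,
      length = gene_length, orientation = ori
    ),
    total_length = n * spacing,
    sigma_basal = sigma_basal
  )
}

#' Promoter positions of all genes
#'
#' The promoter of a forward gene sits at `begin`; that of a reverse gene
#' at `begin + length` (the half-open right edge), symmetric under
#' reflection.
#'
#' @param g A `tsc_genome`.
#' @return Numeric vector of promoter coordinates in bp (not reduced
#'   modulo the genome length, so a reverse gene `[0, 1000)` reports 1000).
#' @export
promoter_position <- function(g) {
  ifelse(g$orientation > 0, g$begin, g$begin + g$length)
}

#' Gene middles (average polymerase position)
#'
#' @param g A `tsc_genome`.
#' @return Numeric vector `(begin + length / 2) %% total_length`; may be
#'   half-integer.
#' @export
gene_middle <- function(g) {
  (g$begin + g$length / 2) %% g$total_length
}

#' Signed circular offset from one gene's promoter to another gene's middle
#'
#' Measures the shortest circular distance from the promoter of gene `i`
#' to the middle of gene `j`, and on which side of gene `i` (relative to
#' its transcription direction) gene `j` lies.
#'
#' @param g A `tsc_genome`.
#' @param i,j Gene indices in begin order (not ids); `i != j`.
#' @return A list with `distance` (real bp) and `side` (`"upstream"`,
#'   `"downstream"`, or `"tie"` for an exact antipodal tie at `L / 2`).
#' @export
signed_offset <- function(g, i, j) {
  stopifnot(i != j)
  L <- g$total_length
  p <- promoter_position(g)[i] %% L
  mid <- gene_middle(g)[j]
  fwd_arc <- (mid - p) %% L
  down <- if (g$orientation[i] > 0) fwd_arc else (p - mid) %% L
  up <- L - down
  if (down == up) return(list(distance = down, side = "tie"))
  if (down < up) list(distance = down, side = "downstream")
  else list(distance = up, side = "upstream")
}

#' Sign of the supercoiling interaction between two genes
#'
#' Twin-domain sign rules for the effect of the transcription of gene `j`
#' on the local supercoiling at the promoter of gene `i`: an upstream gene
#' on the same strand generates positive supercoiling (+1), an upstream
#' gene on the opposite strand negative supercoiling (-1); downstream the
#' signs are reversed.
#'
#' @param g A `tsc_genome`.
#' @param i Index of the affected gene.
#' @param j Index of the transcribed gene.
#' @return -1, 0 (antipodal tie) or +1.
#' @export
eta <- function(g, i, j) {
  off <- signed_offset(g, i, j)
  if (off$side == "tie") return(0L)
  same <- g$orientation[i] == g$orientation[j]
  if (off$side == "upstream") {
    if (same) 1L else -1L
  } else {
    if (same) -1L else 1L
  }
}

# Intergenic segments of a genome: start coordinate and length of the gap
# following each gene in begin order (wrap-aware; zero-length gaps kept).
intergenic_segments <- function(g) {
  L <- g$total_length
  ends <- g$begin + g$length
  list(start = ends %% L, length = c(g$begin[-1], g$begin[1] + L) - ends)
}

# TRUE for each bp position in x lying inside some gene's occupied interval
position_in_gene <- function(g, x) {
  L <- g$total_length
  vapply(x, function(xx) any(((xx - g$begin) %% L) < g$length), logical(1))
}

#' Sample a genomic inversion
#'
#' Draws both endpoints uniformly over all non-coding (intergenic) bp
#' positions of the genome, so genes can never be broken apart; longer
#' intergenes receive proportionally more breakpoints. Both endpoints may
#' fall in the same intergene (a phenotypically neutral inversion).
#'
#' @param g A `tsc_genome` with at least one intergenic bp.
#' @return A list of class `tsc_inversion` with integer `start_bp` and
#'   `end_bp`.
#' @export
sample_inversion <- function(g) {
  pos <- cpp_sample_inversion(g$begin, g$length, g$total_length)
  structure(list(start_bp = pos[1], end_bp = pos[2]), class = "tsc_inversion")
}

#' Apply a genomic inversion
#'
#' Reverses the segment between the two intergenic endpoints: every gene
#' inside the segment is mirrored within it and its orientation flipped;
#' relative positions and distances between inverted genes are conserved,
#' as are gene counts, gene lengths, total length and total intergenic
#' length. The inverted arc is the one that does not wrap coordinate 0.
#'
#' @param g A `tsc_genome`.
#' @param ev A `tsc_inversion` (or list with `start_bp`, `end_bp`).
#' @return The rearranged `tsc_genome`.
#' @export
#' @examples
#' set.seed(1)
#' g <- random_genome(2)
#' ev <- sample_inversion(g)
#' identical(apply_inversion(apply_inversion(g, ev), ev), g)  # involution
apply_inversion <- function(g, ev) {
  res <- cpp_apply_inversion(g$begin, g$length, g$orientation,
                             g$total_length, ev$start_bp, ev$end_bp)
  rearranged_genome(g, res)
}

# Fold the (begin, length, orientation, perm) output of a C++ genome
# operator back into a tsc_genome, carrying gene identity along.
rearranged_genome <- function(g, res) {
  g$begin <- res$begin
  g$length <- res$length
  g$orientation <- res$orientation
  g$id <- g$id[res$perm]
  g$type <- g$type[res$perm]
  g$basal_expression <- g$basal_expression[res$perm]
  g
}

# Restore begin-sorted storage order after a rearrangement.
reorder_genome <- function(g) {
  ord <- order(g$begin)
  for (f in c("id", "type", "begin", "length", "orientation",
              "basal_expression")) {
    g[[f]] <- g[[f]][ord]
  }
  g
}

#' Mutate a genome by Poisson-many random inversions
#'
#' Draws the number of inversions from a Poisson law of rate `lam` and
#' applies them sequentially; `lam = 0` (or a zero draw) returns the
#' genome unchanged.
#'
#' @param g A `tsc_genome`.
#' @param lam Poisson rate of inversions.
#' @return The mutated `tsc_genome`.
#' @export
mutate <- function(g, lam = 2) {
  stopifnot(lam >= 0)
  res <- cpp_mutate(g$begin, g$length, g$orientation, g$total_length, lam)
  rearranged_genome(g, res)
}

#' Reflect a genome (mirror image)
#'
#' Reverses all coordinates and flips all orientations. The mirrored
#' genome has identical expression dynamics under the distance-and-
#' orientation-only coupling model.
#'
#' @param g A `tsc_genome`.
#' @return The mirrored `tsc_genome`.
#' @export
mirror_genome <- function(g) {
  L <- g$total_length
  g$begin <- (L - (g$begin + g$length)) %% L
  g$orientation <- -g$orientation
  reorder_genome(g)
}

#' Rotate all genome coordinates
#'
#' @param g A `tsc_genome`.
#' @param offset Shift in bp (any real; coordinates are taken modulo the
#'   genome length).
#' @return The rotated `tsc_genome`.
#' @export
rotate_genome <- function(g, offset) {
  g$begin <- (g$begin + offset) %% g$total_length
  reorder_genome(g)
}
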