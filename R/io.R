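GENOME_SCHEMA_VERSION <- 1L

#' Save a genome to JSON
#'
#' Writes the documented genome schema: `{schema_version, total_length,
#' sigma_basal, genes: [{id, type, begin, length, orientation: "+"/"-",
#' basal_expression}]}`. Numbers are written at full precision so the
#' round trip is bit-exact.
#'
#' @param g A `tsc_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_genome <- function(g, path) {
  genes <- as.data.frame(g)
  genes$orientation <- ifelse(genes$orientation > 0, "+", "-")
  jsonlite::write_json(
    list(
      schema_version = GENOME_SCHEMA_VERSION,
      total_length = g$total_length,
      sigma_basal = g$sigma_basal,
      genes = genes
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Load a genome from JSON
#'
#' Reads the schema written by [save_genome()]; the genome's invariants
#' (disjoint intervals, valid lengths, types, orientations) are
#' re-validated on load, so a tampered file fails with an integrity
#' error.
#'
#' @param path Input file path.
#' @return A `tsc_genome`.
#' @export
load_genome <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version)) {
    stop("genome file has no schema_version field")
  }
  if (raw$schema_version != GENOME_SCHEMA_VERSION) {
    stop(sprintf("unsupported genome schema version %s", raw$schema_version))
  }
  genome(raw$genes, total_length = raw$total_length,
         sigma_basal = raw$sigma_basal)
}

#' Export a genome as GFF3
#'
#' One feature line per gene, 1-based inclusive coordinates, strand from
#' the gene orientation; provided for interoperability with genome
#' browsers. (Import is not supported; [load_genome()] is the canonical
#' reader.)
#'
#' @param g A `tsc_genome`.
#' @param path Output file path.
#' @param seqid Sequence name used in the first column.
#' @return `path`, invisibly.
#' @export
genome_to_gff3 <- function(g, path, seqid = "chromosome") {
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", seqid, as.integer(g$total_length)),
    sprintf(
      "%s\ttscevo\tgene\t%d\t%d\t.\t%s\t.\tID=gene%d;gene_type=%s",
      seqid,
      as.integer(g$begin) + 1L,
      as.integer(g$begin + g$length),  # may exceed L for a wrapped gene
      ifelse(g$orientation > 0, "+", "-"),
      g$id, g$type
    )
  )
  writeLines(lines, path)
  invisible(path)
}

config_defaults <- function() {
  c(unclass(sim_params()),
    list(n_generations = 1000, n_replicates = 1, base_seed = 1,
         checkpoint_every = 1000, output_dir = "tscevo_out"))
}

#' Load a run configuration
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed)
#' configuration file; missing keys are filled with the model defaults,
#' unknown keys are rejected, and out-of-range values fail validation.
#' An empty file therefore yields the full default configuration.
#'
#' @param path Config file path (`.json`, `.yaml` or `.yml`).
#' @return A list of class `tsc_config`: all [sim_params()] fields plus
#'   `n_generations`, `n_replicates`, `base_seed`, `checkpoint_every`
#'   and `output_dir`, fully materialized.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nchar(trimws(txt)) == 0) list() else jsonlite::fromJSON(txt)
  }
  if (is.null(user)) user <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  cfg[names(user)] <- user
  params_fields <- names(unclass(sim_params()))
  validate_params(cfg[params_fields])
  stopifnot(cfg$n_generations >= 0, cfg$n_replicates >= 1,
            cfg$checkpoint_every >= 1)
  structure(cfg, class = "tsc_config")
}

#' Extract the simulation parameters from a configuration
#'
#' @param cfg A `tsc_config` from [load_config()].
#' @return The corresponding [sim_params()] object.
#' @export
config_params <- function(cfg) {
  do.call(sim_params, unclass(cfg)[names(unclass(sim_params()))])
}

#' Echo a resolved configuration to JSON
#'
#' The echoed file is fully explicit (all defaults materialized) and can
#' be re-loaded with [load_config()] to reproduce the run without the
#' original config file.
#'
#' @param cfg A `tsc_config`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
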