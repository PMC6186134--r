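# Readers/writers for the on-disk species layout and tabular interchange.
#
# One directory per species:
#   universal.fasta   codon-aware alignment, concatenated universal genes
#   core.fasta        codon-aware alignment, concatenated core genes
#   tree.nwk          strain tree with branch lengths (substitutions/site)
#   families.tsv      strains x families presence/absence (0/1)
#   metadata.txt      "key: value" lines (lifestyle, mutation_rate, ...)
#   hits.tsv          optional universal-protein hit table

#' Species metadata
#'
#' @param lifestyle one of free_living, commensal, obligate_pathogen,
#'   plant_pathogen, obligate_intracellular, unknown.
#' @param min_doubling_time minimal doubling time in hours (optional).
#' @param mutation_rate mutations per site per generation (optional).
#' @param mycoplasma logical; relaxes the universal-ortholog QC threshold.
#' @export
species_metadata <- function(lifestyle = "unknown", min_doubling_time = NA,
                             mutation_rate = NA, mycoplasma = FALSE) {
  if (!lifestyle %in% LIFESTYLES)
    abort_category("validation_error",
                   sprintf("unknown lifestyle '%s'", lifestyle))
  if (!is.na(mutation_rate) && (!is.finite(mutation_rate) || mutation_rate <= 0))
    abort_category("validation_error", "mutation_rate must be finite and > 0")
  if (!is.na(min_doubling_time) && min_doubling_time <= 0)
    abort_category("validation_error", "min_doubling_time must be > 0")
  structure(list(lifestyle = lifestyle,
                 min_doubling_time = as.numeric(min_doubling_time),
                 mutation_rate = as.numeric(mutation_rate),
                 mycoplasma = isTRUE(mycoplasma)),
            class = "species_metadata")
}

write_metadata <- function(meta, path) {
  lines <- c(sprintf("lifestyle: %s", meta$lifestyle),
             sprintf("min_doubling_time: %s",
                     ifelse(is.na(meta$min_doubling_time), "NA",
                            format(meta$min_doubling_time, digits = 12))),
             sprintf("mutation_rate: %s",
                     ifelse(is.na(meta$mutation_rate), "NA",
                            format(meta$mutation_rate, digits = 12))),
             sprintf("mycoplasma: %s", ifelse(meta$mycoplasma, "true", "false")))
  writeLines(lines, path)
  invisible(path)
}

read_metadata <- function(path) {
  if (!file.exists(path))
    abort_category("missing_file_error", sprintf("metadata file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^:=]+)\\s*[:=]\\s*(.*)$", lines))
  vals <- stats::setNames(vapply(kv, function(m) trimws(m[3]), ""),
                          vapply(kv, function(m) trimws(m[2]), ""))
  num <- function(key) {
    v <- vals[key]
    if (is.na(v) || v == "NA") NA_real_ else as.numeric(v)
  }
  species_metadata(
    lifestyle = unname(vals["lifestyle"] %|NA|% "unknown"),
    min_doubling_time = num("min_doubling_time"),
    mutation_rate = num("mutation_rate"),
    mycoplasma = tolower(unname(vals["mycoplasma"] %|NA|% "false")) %in%
      c("true", "1", "yes"))
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Read a simple key-value configuration file
#'
#' Lines of the form \code{key: value} or \code{key = value}; \code{#}
#' comments allowed.  Values are auto-typed (numeric / logical / string).
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort_category("missing_file_error", sprintf("config file not found: %s", path))
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^:=]+)\\s*[:=]\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) < 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    parsed <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(parsed)) parsed
    else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
    else val
  }
  out
}

#' Write and re-read presence/absence matrices
#' @param matrix a \code{gene_family_matrix} (or binary matrix).
#' @param path TSV path.
#' @export
write_presence_tsv <- function(matrix, path) {
  m <- if (inherits(matrix, "gene_family_matrix")) matrix$presence else matrix
  df <- data.frame(strain_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  if (!file.exists(path))
    abort_category("missing_file_error", sprintf("presence matrix not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$strain_id
  gene_family_matrix(m)
}

#' Write and re-read hit tables
#' @param hits a \code{hit_table}.
#' @param path TSV path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path))
    abort_category("missing_file_error", sprintf("hit table not found: %s", path))
  hit_table(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Load one species' dataset from its directory
#'
#' Reads, validates and cross-references the per-species files.  Strain
#' identifiers in the tree and family matrix must match the universal
#' alignment exactly; alignment lengths must be multiples of 3; sequences
#' are normalized to uppercase.
#'
#' @param directory_path species directory (see layout above).
#' @param config optional configuration list (unused hooks for future
#'   overrides of file names).
#' @return object of class \code{species_dataset} with fields species_id,
#'   strain_ids, universal_alignment, core_alignment, strain_tree,
#'   family_matrix, metadata, hits (NULL when absent).
#' @export
load_species_dataset <- function(directory_path, config = list()) {
  need <- function(file, role) {
    p <- file.path(directory_path, file)
    if (!file.exists(p))
      abort_category("missing_file_error",
                     sprintf("%s missing (expected %s)", role, p))
    p
  }
  universal <- read_codon_alignment(need("universal.fasta", "universal alignment"))
  core <- read_codon_alignment(need("core.fasta", "core alignment"))
  tree <- read_newick(need("tree.nwk", "strain tree"))
  fam <- read_presence_tsv(need("families.tsv", "family matrix"))
  meta <- read_metadata(need("metadata.txt", "metadata"))
  hits_path <- file.path(directory_path, "hits.tsv")
  hits <- if (file.exists(hits_path)) read_hit_table(hits_path) else NULL
  strain_ids <- sort(names(universal))
  check_ids <- function(ids, what) {
    extra <- setdiff(ids, strain_ids)
    missing <- setdiff(strain_ids, ids)
    if (length(extra) || length(missing))
      abort_category("validation_error", sprintf(
        "strain-id mismatch in %s: unknown [%s], absent [%s]", what,
        paste(extra, collapse = ", "), paste(missing, collapse = ", ")))
  }
  check_ids(tree$tip.label, "tree")
  check_ids(names(core), "core alignment")
  check_ids(rownames(fam$presence), "family matrix")
  structure(list(species_id = basename(normalizePath(directory_path)),
                 strain_ids = strain_ids,
                 universal_alignment = universal, core_alignment = core,
                 strain_tree = tree, family_matrix = fam, metadata = meta,
                 hits = hits),
            class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("species_dataset '%s': %d strains, universal %d nt, core %d nt, %d families\n",
              x$species_id, length(x$strain_ids),
              aln_length(x$universal_alignment), aln_length(x$core_alignment),
              ncol(x$family_matrix$presence)))
  invisible(x)
}

#' Write a per-species results table
#'
#' Tab-separated, header line, missing values as "NA"; numeric values are
#' written with full precision so a write/read round trip is lossless.
#'
#' @param records data.frame of per-species rows.
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  df <- records
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        if (is.na(v)) "NA" else format(v, digits = 17), "")
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_category("io_error", sprintf("cannot write %s", path))
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path))
    abort_category("missing_file_error", sprintf("results table not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE)
}
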