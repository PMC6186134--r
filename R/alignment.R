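# In-frame codon alignments are stored as a named character vector of
# equal-length uppercase sequences with class "codon_alignment".

#' Construct a codon alignment
#'
#' @param seqs named character vector of aligned nucleotide sequences, one
#'   per strain, equal lengths, length a multiple of 3.
#' @return object of class \code{codon_alignment}.
#' @export
codon_alignment <- function(seqs) {
  if (length(seqs) == 0L)
    return(structure(character(0), class = "codon_alignment"))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    abort_category("validation_error", "sequences must carry unique strain names")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    abort_category("validation_error", "aligned sequences must have equal length")
  if (lens[1] %% 3 != 0L)
    abort_category("frame_error",
                   sprintf("alignment length %d is not a multiple of 3", lens[1]))
  structure(seqs, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences x %d nt (%d codons)\n",
              length(x), nchar(x[1]), nchar(x[1]) %/% 3))
  invisible(x)
}

aln_length <- function(aln) if (length(aln) == 0L) 0L else nchar(aln[[1]])

# strains x sites character matrix
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

# strains x codons character matrix of 3-mers
codon_matrix <- function(aln) {
  n_cod <- aln_length(aln) %/% 3L
  m <- matrix("", length(aln), n_cod, dimnames = list(names(aln), NULL))
  for (i in seq_along(aln)) {
    s <- aln[[i]]
    m[i, ] <- substring(s, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  }
  m
}

#' Read a FASTA alignment as a codon alignment
#' @param path FASTA file.
#' @export
read_codon_alignment <- function(path) {
  if (!file.exists(path))
    abort_category("missing_file_error", sprintf("alignment file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(toupper(as.character(x)), names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(unclass(seqs)), path,
                              width = 80L)
  invisible(path)
}
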