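#' Read a multi-record FASTA file of DNA sequences
#'
#' Residues are uppercased and validated against the A/C/G/T/N alphabet;
#' an illegal residue raises an error naming the offending record and
#' position.
#'
#' @param path FASTA file.
#' @param topology Topology assigned to every record (mitogenomes are
#'   `"circular"` by default).
#' @return List of [circ_seq], preserving record order.
#' @export
read_fasta <- function(path, topology = "circular") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  mapply(function(id, s) circ_seq(id, s, topology),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [circ_seq] (or a single one), or an
#'   [annotated_genome].
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "annotated_genome")) seqs <- seqs$sequence
  if (inherits(seqs, "circ_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
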