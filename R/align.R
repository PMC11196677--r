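# Global pairwise alignment with affine gaps, the substrate of every
# distance computation. The dynamic programming itself is delegated to
# Biostrings::pairwiseAlignment (Gotoh algorithm, C implementation); this
# module pins the scoring semantics: a gap of length k costs
# gap_open + k * gap_extend, and terminal gaps are penalized (true global
# alignment), so a long 3' extension on one gene shows up as a terminal gap
# run rather than being ignored.

#' Alignment scoring parameters
#'
#' @param level `"nt"` or `"aa"`.
#' @param gap_open Non-negative gap opening penalty (default 3, the
#'   penalty used for all reported divergences).
#' @param gap_extend Non-negative per-residue gap extension penalty
#'   (default 3).
#' @param match Nucleotide match score (default +1).
#' @param mismatch Nucleotide mismatch score (default -1).
#' @param aa_matrix Named amino-acid substitution matrix (default
#'   `"BLOSUM62"`).
#' @return An `align_params` list.
#' @export
align_params <- function(level = c("nt", "aa"), gap_open = 3,
                         gap_extend = 3, match = 1, mismatch = -1,
                         aa_matrix = "BLOSUM62") {
  level <- match.arg(level)
  stopifnot(gap_open >= 0, gap_extend >= 0, is.finite(match),
            is.finite(mismatch))
  structure(list(level = level, gap_open = gap_open,
                 gap_extend = gap_extend, match = match,
                 mismatch = mismatch, aa_matrix = aa_matrix),
            class = "align_params")
}

# substitution matrix over A/C/G/T/N: N columns score 0 so ambiguity
# neither rewards nor penalizes; downstream distances drop N columns anyway
nt_matrix <- function(params) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

.matrix_cache <- new.env(parent = emptyenv())

aa_matrix_for <- function(params) {
  key <- params$aa_matrix
  if (is.null(.matrix_cache[[key]])) {
    e <- new.env()
    utils::data(list = key, package = "Biostrings", envir = e)
    .matrix_cache[[key]] <- get(key, envir = e)
  }
  .matrix_cache[[key]]
}

#' Optimal global alignment of two sequences
#'
#' Affine gap model: opening a gap costs `gap_open + gap_extend` for its
#' first residue and `gap_extend` for each further residue. Deterministic
#' for fixed inputs and parameters.
#'
#' @param a,b Sequences (plain strings), both nucleotide or both protein
#'   per `params$level`.
#' @param params An [align_params].
#' @return An `alignment` object: `gapped_a`, `gapped_b` (equal-length
#'   strings with `-` gaps), `params`, `score`.
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  if (params$level == "nt") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "global", substitutionMatrix = nt_matrix(params),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = aa_matrix_for(params),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
  }
  alignment(as.character(Biostrings::alignedPattern(pa)),
            as.character(Biostrings::alignedSubject(pa)),
            params, Biostrings::score(pa))
}

#' Construct an alignment object
#'
#' @param gapped_a,gapped_b Equal-length gapped strings.
#' @param params The [align_params] used.
#' @param score Alignment score.
#' @export
alignment <- function(gapped_a, gapped_b, params, score = NA_real_) {
  stopifnot(nchar(gapped_a) == nchar(gapped_b))
  structure(list(gapped_a = gapped_a, gapped_b = gapped_b,
                 params = params, score = score),
            class = "alignment")
}

#' @export
length.alignment <- function(x) nchar(x$gapped_a)

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d columns, level %s, score %.2f\n",
              length(x), x$params$level, x$score))
  invisible(x)
}

# drop a single trailing stop symbol from a translated CDS
strip_stop <- function(aa) sub("\\*$", "", aa)

#' Align a pair of named features from two genomes
#'
#' Extracts the strand-aware feature sequences, translates them (dropping
#' the terminal stop) when `params$level == "aa"`, and aligns globally.
#'
#' @param genome_a,genome_b Annotated genomes.
#' @param feature_a,feature_b Feature names.
#' @param params An [align_params].
#' @param table Genetic code for translation (default `"5"`).
#' @return An `alignment`.
#' @export
align_feature_pair <- function(genome_a, feature_a, genome_b, feature_b,
                               params = align_params(), table = "5") {
  sa <- feature_sequence(genome_a, feature_a)
  sb <- feature_sequence(genome_b, feature_b)
  if (params$level == "aa") {
    sa <- strip_stop(translate(sa, table))
    sb <- strip_stop(translate(sb, table))
  }
  global_align(sa, sb, params)
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param aln An `alignment`.
#' @param path Output file.
#' @param ids Record names for the two rows.
#' @export
write_alignment_fasta <- function(aln, path, ids = c("a", "b")) {
  writeLines(c(paste0(">", ids[1]), aln$gapped_a,
               paste0(">", ids[2]), aln$gapped_b), path)
  invisible(path)
}
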