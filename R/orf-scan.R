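# Six-frame ORF discovery on circular genomes under the invertebrate
# mitochondrial code.

#' ORF scan configuration
#'
#' Defaults reflect mitochondrial practice: table 5 allows {TTG, ATT, ATC,
#' ATA, ATG, GTG} as initiators, but the default start set is restricted to
#' {ATG, ATA, ATT, GTG} to curb spurious starts; the full set can be passed
#' explicitly. Reported ORF lengths include the stop codon by default.
#'
#' @param min_length_nt Minimum ORF length in nt (>= 3, divisible by 3).
#' @param start_codons Character vector of start codons.
#' @param stop_codons Character vector of stop codons.
#' @param include_stop_in_length Count the terminal stop in the ORF span.
#' @param allow_wrap Report ORFs spanning the origin of circular genomes.
#' @return An `orf_config` list.
#' @export
orf_config <- function(min_length_nt = 300L,
                       start_codons = c("ATG", "ATA", "ATT", "GTG"),
                       stop_codons = c("TAA", "TAG"),
                       include_stop_in_length = TRUE,
                       allow_wrap = TRUE) {
  stopifnot(min_length_nt >= 3L, min_length_nt %% 3L == 0L,
            length(start_codons) > 0L, length(stop_codons) > 0L,
            !any(start_codons %in% stop_codons))
  structure(list(min_length_nt = as.integer(min_length_nt),
                 start_codons = toupper(start_codons),
                 stop_codons = toupper(stop_codons),
                 include_stop_in_length = include_stop_in_length,
                 allow_wrap = allow_wrap),
            class = "orf_config")
}

# Scan one strand string. For circular genomes the string is doubled so
# ORFs can run through the origin; starts are restricted to the first copy.
# Returns rows (start, end) in 0-based strand coordinates, end possibly > L.
scan_strand <- function(s, L, cfg, circular) {
  n <- nchar(s)
  hits <- list()
  for (offset in 0:2) {
    cs <- seq(offset, n - 3L, 3L)           # codon starts, 0-based
    if (length(cs) == 0L) next
    codons <- substring(s, cs + 1L, cs + 3L)
    stop_i <- which(codons %in% cfg$stop_codons)
    start_i <- which(codons %in% cfg$start_codons)
    if (length(stop_i) == 0L || length(start_i) == 0L) next
    prev <- 0L
    for (si in stop_i) {
      cand <- start_i[start_i > prev & start_i < si]
      prev <- si
      if (length(cand) == 0L) next
      a <- cs[cand[1L]]                      # earliest start after last stop
      e <- cs[si] + (if (cfg$include_stop_in_length) 3L else 0L)
      len <- e - a
      if (len < cfg$min_length_nt || len > L) next
      if (circular && a >= L) next           # duplicate of a first-copy ORF
      hits[[length(hits) + 1L]] <- c(a, e)
    }
  }
  if (length(hits) == 0L) return(matrix(integer(), ncol = 2L))
  do.call(rbind, hits)
}

# Map a [start, end) span in minus-strand (revcomp) coordinates back to
# plus-strand intervals, ordered so feature_sequence reads 5'->3'.
minus_intervals <- function(a, e, L) {
  if (e <= L) {
    matrix(c(L - e, L - a), ncol = 2L)
  } else {
    rbind(c(2L * L - e, L), c(0L, L - a))
  }
}

plus_intervals <- function(a, e, L) {
  if (e <= L) matrix(c(a, e), ncol = 2L)
  else rbind(c(a, L), c(0L, e - L))
}

#' Find open reading frames in all six frames
#'
#' Each ORF runs from a start codon to the first in-frame stop; overlapping
#' candidates sharing a stop are reduced to the longest (earliest start).
#' On circular genomes ORFs may span the origin (two-interval features)
#' when `allow_wrap` is set. Results are sorted by length descending and
#' named `ORF1`, `ORF2`, ...
#'
#' @param genome An [annotated_genome] or [circ_seq].
#' @param cfg An [orf_config].
#' @return List of [mt_feature] of kind `"ORF"`.
#' @export
find_orfs <- function(genome, cfg = orf_config()) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  L <- length(seq)
  circular <- seq$topology == "circular" && cfg$allow_wrap
  fwd <- seq$residues
  rev <- revcomp(fwd)
  if (circular) {
    fwd <- paste0(fwd, fwd)
    rev <- paste0(rev, rev)
  }
  res <- list()
  h <- scan_strand(fwd, L, cfg, circular)
  for (i in seq_len(nrow(h)))
    res[[length(res) + 1L]] <- list(strand = "+",
                                    iv = plus_intervals(h[i, 1L], h[i, 2L], L))
  h <- scan_strand(rev, L, cfg, circular)
  for (i in seq_len(nrow(h)))
    res[[length(res) + 1L]] <- list(strand = "-",
                                    iv = minus_intervals(h[i, 1L], h[i, 2L], L))
  if (length(res) == 0L) return(list())
  lens <- vapply(res, function(r) sum(r$iv[, 2L] - r$iv[, 1L]), integer(1))
  # stable sort: length desc, then leftmost coordinate for determinism
  firsts <- vapply(res, function(r) min(r$iv[, 1L]), integer(1))
  ord <- order(-lens, firsts)
  res <- res[ord]
  lapply(seq_along(res), function(i)
    mt_feature(paste0("ORF", i), "ORF", res[[i]]$strand, res[[i]]$iv))
}

# fraction of feature a's positions covered by feature b (circular,
# strand-agnostic)
overlap_fraction <- function(a, b) {
  pa <- feature_positions(a)
  pb <- feature_positions(b)
  length(intersect(pa, pb)) / length(pa)
}

#' Separate unassigned ORFs from annotated genes
#'
#' Retains ORFs whose overlap with every non-ORF annotated feature is below
#' `max_overlap_frac` of the ORF's own length. Overlap is computed on
#' circular genome coordinates and ignores strand, so an ORF antisense to a
#' gene is still considered assigned.
#'
#' @param orfs List of ORF features from [find_orfs].
#' @param genome The [annotated_genome] the ORFs were found on.
#' @param max_overlap_frac Overlap threshold (default 0.5).
#' @return Filtered list of ORF features.
#' @export
unassigned_orfs <- function(orfs, genome, max_overlap_frac = 0.5) {
  annot <- Filter(function(f) f$kind != "ORF", genome$features)
  Filter(function(orf) {
    all(vapply(annot, function(g) overlap_fraction(orf, g), numeric(1)) <
          max_overlap_frac)
  }, orfs)
}

#' Tabulate ORF calls
#'
#' @param orfs List of ORF features.
#' @param genome Genome they belong to (for the id column).
#' @return A tibble with name, strand, start, end, length and wrap flag.
#' @export
orf_table <- function(orfs, genome = NULL) {
  id <- if (is.null(genome)) NA_character_ else genome$sequence$id
  tibble::tibble(
    genome = id,
    name = vapply(orfs, `[[`, "", "name"),
    strand = vapply(orfs, `[[`, "", "strand"),
    start = vapply(orfs, function(f) f$intervals[1L, 1L], integer(1)),
    end = vapply(orfs, function(f) f$intervals[nrow(f$intervals), 2L],
                 integer(1)),
    length = vapply(orfs, feature_length, integer(1)),
    wraps = vapply(orfs, function(f) nrow(f$intervals) > 1L, logical(1))
  )
}
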