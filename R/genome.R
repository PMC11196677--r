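#' @importFrom stats setNames runif sd
#' @importFrom utils head tail data packageVersion write.table
NULL

#' Circular (or linear) DNA sequence
#'
#' A minimal container for a mitogenome-scale DNA sequence. Residues are
#' stored uppercase over the alphabet A/C/G/T/N; all coordinate arithmetic
#' downstream is 0-based half-open, modulo length when `topology` is
#' `"circular"`.
#'
#' @param id Record identifier.
#' @param residues DNA string; lowercase input is folded to uppercase.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `circ_seq`.
#' @export
circ_seq <- function(id, residues, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'")
  bad <- regexpr("[^ACGTN]", residues)
  if (bad > 0L) {
    stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                 substr(residues, bad, bad), id, as.integer(bad)))
  }
  structure(list(id = id, residues = residues, topology = topology),
            class = "circ_seq")
}

#' @export
length.circ_seq <- function(x) nchar(x$residues)

#' Annotated feature on a genome
#'
#' Intervals are 0-based half-open `[start, end)` pairs in genome
#' coordinates, ordered; a feature spanning the origin of a circular genome
#' is represented as two intervals. CDS and ORF features must have total
#' length divisible by 3.
#'
#' @param name Feature label, e.g. `"cox1"`, `"trnF"`, `"ORF1"`.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"ORF"`, `"noncoding"`.
#' @param strand `"+"` or `"-"`.
#' @param intervals Two-column integer matrix (start, end) or a list of
#'   length-2 vectors.
#' @return An object of class `mt_feature`.
#' @export
mt_feature <- function(name, kind, strand, intervals) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "ORF", "noncoding"))
  stopifnot(strand %in% c("+", "-"))
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.integer(intervals), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  if (any(intervals[, 2L] <= intervals[, 1L]))
    stop("feature '", name, "': empty or inverted interval")
  len <- sum(intervals[, 2L] - intervals[, 1L])
  if (kind %in% c("CDS", "ORF") && len %% 3L != 0L)
    stop("feature '", name, "': ", kind, " length ", len,
         " not divisible by 3")
  structure(list(name = name, kind = kind, strand = strand,
                 intervals = intervals),
            class = "mt_feature")
}

#' Total feature length in bp
#' @param f A `mt_feature`.
#' @export
feature_length <- function(f) {
  sum(f$intervals[, 2L] - f$intervals[, 1L])
}

#' Annotated genome: sequence plus typed, stranded features
#'
#' @param sequence A [circ_seq].
#' @param features List of [mt_feature]; names must be unique (the GenBank
#'   reader disambiguates duplicates with numeric suffixes).
#' @param source Provenance string (file path or accession).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(sequence, features = list(), source = "") {
  stopifnot(inherits(sequence, "circ_seq"))
  L <- length(sequence)
  for (f in features) {
    stopifnot(inherits(f, "mt_feature"))
    if (any(f$intervals < 0L) || any(f$intervals > L))
      stop("feature '", f$name, "' outside [0, ", L, ")")
  }
  nms <- vapply(features, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate feature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(features) <- nms
  structure(list(sequence = sequence, features = features, source = source),
            class = "annotated_genome")
}

#' @export
length.annotated_genome <- function(x) length(x$sequence)

#' @export
print.annotated_genome <- function(x, ...) {
  kinds <- table(vapply(x$features, `[[`, "", "kind"))
  cat(sprintf("<annotated_genome> %s: %d bp (%s), %d features (%s)\n",
              x$sequence$id, length(x), x$sequence$topology,
              length(x$features),
              paste(names(kinds), kinds, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param s DNA string over A/C/G/T/N.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the spliced, strand-aware sequence of a feature
#'
#' Intervals are concatenated in stored order, then reverse-complemented if
#' the feature lies on the minus strand, so the result always reads 5' to 3'
#' in the feature's own orientation.
#'
#' @param genome An [annotated_genome].
#' @param feature A [mt_feature] belonging to `genome`, or a feature name.
#' @return DNA string.
#' @export
feature_sequence <- function(genome, feature) {
  if (is.character(feature)) {
    if (!feature %in% names(genome$features))
      stop("unknown feature '", feature, "' in ", genome$sequence$id)
    feature <- genome$features[[feature]]
  }
  res <- genome$sequence$residues
  parts <- apply(feature$intervals, 1L, function(iv) {
    substr(res, iv[1L] + 1L, iv[2L])
  })
  s <- paste(parts, collapse = "")
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement an entire annotated genome
#'
#' Features are remapped: position p maps to L - p, strands flip, interval
#' order within a feature is reversed so extraction still reads 5' to 3'.
#'
#' @param genome An [annotated_genome].
#' @export
reverse_complement <- function(genome) {
  L <- length(genome)
  feats <- lapply(genome$features, function(f) {
    iv <- f$intervals
    iv2 <- cbind(L - iv[, 2L], L - iv[, 1L])
    iv2 <- iv2[rev(seq_len(nrow(iv2))), , drop = FALSE]
    mt_feature(f$name, f$kind, if (f$strand == "+") "-" else "+", iv2)
  })
  annotated_genome(
    circ_seq(genome$sequence$id, revcomp(genome$sequence$residues),
             genome$sequence$topology),
    unname(feats), genome$source)
}

.code_cache <- new.env(parent = emptyenv())

genetic_code <- function(table = "5") {
  key <- as.character(table)
  if (is.null(.code_cache[[key]])) {
    .code_cache[[key]] <- Biostrings::getGeneticCode(key)
  }
  .code_cache[[key]]
}

#' Translate a nucleotide sequence
#'
#' Defaults to NCBI translation table 5 (invertebrate mitochondrial code:
#' ATA=Met, TGA=Trp, AGA/AGG=Ser). Stop codons are rendered `"*"`; codons
#' containing N translate to `"X"`.
#'
#' @param nt DNA string; length must be divisible by 3.
#' @param table NCBI genetic code id (character or integer), default `"5"`.
#' @return Amino-acid string of length `nchar(nt)/3`.
#' @export
translate <- function(nt, table = "5") {
  n <- nchar(nt)
  if (n == 0L || n %% 3L != 0L)
    stop("sequence length ", n, " not divisible by 3")
  code <- genetic_code(table)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Classify every genome position by coding status
#'
#' Returns an integer vector of length `length(genome)` with values 0
#' (noncoding), 1/2/3 (codon position within a CDS or ORF, counted along the
#' feature's own 5'-to-3' orientation), or 4 (structural RNA). Later
#' features overwrite earlier ones at overlaps.
#'
#' @param genome An [annotated_genome].
#' @export
site_classes <- function(genome) {
  cls <- integer(length(genome))
  for (f in genome$features) {
    pos <- feature_positions(f)
    if (f$kind %in% c("CDS", "ORF")) {
      cls[pos + 1L] <- rep_len(1:3, length(pos))
    } else if (f$kind %in% c("tRNA", "rRNA")) {
      cls[pos + 1L] <- 4L
    }
  }
  cls
}

# 0-based genome positions of a feature, in 5'->3' feature order
feature_positions <- function(f) {
  pos <- unlist(apply(f$intervals, 1L, function(iv) seq(iv[1L], iv[2L] - 1L),
                      simplify = FALSE))
  if (f$strand == "-") pos <- rev(pos)
  pos
}
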