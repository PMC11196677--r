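# Divergence statistics: uncorrected p-distance, Tamura 3-parameter
# correction for transition/transversion and GC-content bias, and
# sliding-window divergence along an alignment.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

aln_chars <- function(aln) {
  list(a = strsplit(aln$gapped_a, "", fixed = TRUE)[[1]],
       b = strsplit(aln$gapped_b, "", fixed = TRUE)[[1]])
}

# which alignment columns are comparable: no gap, no ambiguity in either row
comparable_cols <- function(ca, cb, level) {
  amb <- if (level == "nt") c("-", "N") else c("-", "X")
  !(ca %in% amb | cb %in% amb)
}

#' Uncorrected p-distance of a pairwise alignment
#'
#' Columns with a gap or ambiguity (N for nucleotides, X for amino acids)
#' in either row are excluded; `p` is the fraction of differing sites among
#' those compared. For nucleotide alignments the transition fraction `P`
#' (A/G, C/T) and transversion fraction `Q` are also reported, with
#' `p = P + Q` exactly. For a single pair, `"pairwise"` and `"complete"`
#' deletion coincide; the argument exists so multi-pair tables can state
#' their convention.
#'
#' @param aln An `alignment`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A `distance_result`: `p`, `compared_sites`, `P`, `Q`, `theta`,
#'   `h`, `d_t92` (NA until [tamura3p]), `saturated`, `level`.
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  ch <- aln_chars(aln)
  keep <- comparable_cols(ch$a, ch$b, aln$params$level)
  a <- ch$a[keep]
  b <- ch$b[keep]
  n <- length(a)
  res <- structure(list(p = NA_real_, compared_sites = n,
                        P = NA_real_, Q = NA_real_,
                        theta = NA_real_, h = NA_real_,
                        d_t92 = NA_real_, saturated = FALSE,
                        undefined = n == 0L,
                        level = aln$params$level, deletion = deletion),
                   class = "distance_result")
  if (n == 0L) return(res)
  diff <- a != b
  res$p <- sum(diff) / n
  if (aln$params$level == "nt") {
    ts <- diff & ((a %in% PURINES & b %in% PURINES) |
                    (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
    res$P <- sum(ts) / n
    res$Q <- sum(diff & !ts) / n
    pooled <- c(a, b)
    res$theta <- mean(pooled %in% c("G", "C"))
    res$h <- 2 * res$theta * (1 - res$theta)
  }
  res
}

#' Tamura 3-parameter distance
#'
#' Corrects the observed divergence for multiple hits using the
#' transition/transversion split and the GC content of the compared sites:
#' with `h = 2*theta*(1-theta)` where `theta` is the GC fraction pooled
#' over both sequences,
#' `d = -h*log(1 - P/h - Q) - 0.5*(1-h)*log(1 - 2Q)`.
#' When a log argument is non-positive or `h = 0` the distance is
#' undefined and the result carries a saturation flag instead of a value.
#'
#' @param aln A nucleotide `alignment`.
#' @param deletion Site-deletion convention, as in [p_distance].
#' @return A `distance_result` with `d_t92` filled in (or `saturated =
#'   TRUE`).
#' @export
tamura3p <- function(aln, deletion = "pairwise") {
  if (aln$params$level != "nt")
    stop("Tamura 3-parameter distance is defined for nucleotide alignments")
  res <- p_distance(aln, deletion)
  if (res$undefined) return(res)
  res$d_t92 <- t92_closed_form(res$theta, res$P, res$Q)
  if (is.na(res$d_t92)) res$saturated <- TRUE
  res
}

# closed form; returns NA outside the domain
t92_closed_form <- function(theta, P, Q) {
  h <- 2 * theta * (1 - theta)
  arg1 <- 1 - ifelse(h > 0, P / h, Inf) - Q
  arg2 <- 1 - 2 * Q
  if (h <= 0 || arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -h * log(arg1) - 0.5 * (1 - h) * log(arg2)
}

#' Sliding-window divergence along an alignment
#'
#' Windows slide over alignment columns; each window's value is the
#' p-distance with pairwise deletion restricted to that window. A window
#' with zero comparable sites yields `NA`. Centers are reported in
#' alignment (column) coordinates, 0-based.
#'
#' @param aln An `alignment`.
#' @param window Window width in columns (default 100).
#' @param step Step between window starts (default 25).
#' @return A `window_profile`: `centers`, `values`, `n_compared`,
#'   `window`, `step`, `metric`.
#' @export
sliding_divergence <- function(aln, window = 100L, step = 25L) {
  len <- length(aln)
  if (window > len) stop("window (", window, ") exceeds alignment length (",
                         len, ")")
  stopifnot(window >= step, step >= 1L)
  ch <- aln_chars(aln)
  keep <- comparable_cols(ch$a, ch$b, aln$params$level)
  diff <- keep & (ch$a != ch$b)
  ckeep <- cumsum(keep)
  cdiff <- cumsum(diff)
  starts <- seq(0L, len - window, by = step)
  n_comp <- ckeep[starts + window] - c(0L, ckeep)[starts + 1L]
  n_diff <- cdiff[starts + window] - c(0L, cdiff)[starts + 1L]
  vals <- ifelse(n_comp > 0L, n_diff / n_comp, NA_real_)
  window_profile(centers = starts + window / 2, values = vals,
                 window = window, step = step, metric = "p_distance",
                 n_compared = n_comp)
}

#' Construct a window profile
#'
#' @param centers Strictly increasing positions.
#' @param values Metric values (NA allowed).
#' @param window,step Window geometry in bp or columns.
#' @param metric Metric name.
#' @param n_compared Sites contributing per window (optional).
#' @export
window_profile <- function(centers, values, window, step, metric,
                           n_compared = NULL) {
  stopifnot(length(centers) == length(values),
            !is.unsorted(centers, strictly = TRUE),
            window >= step, step >= 1)
  structure(list(centers = centers, values = values,
                 window = as.integer(window), step = as.integer(step),
                 metric = metric, n_compared = n_compared),
            class = "window_profile")
}

#' @export
as.data.frame.window_profile <- function(x, ...) {
  d <- data.frame(center = x$centers, value = x$values)
  if (!is.null(x$n_compared)) d$n_compared <- x$n_compared
  d
}

#' Long-format distance table over a set of feature pairings
#'
#' Aligns every requested pair of features and reports p-distance plus
#' (for nucleotide level) the Tamura 3-parameter distance. Missing
#' features flag the row rather than aborting the table.
#'
#' @param genomes Named list of [annotated_genome].
#' @param pairs Data frame with columns `genome_a`, `feature_a`,
#'   `genome_b`, `feature_b` (see [feature_grid]).
#' @param params An [align_params].
#' @param table Genetic code id for aa-level translation.
#' @return A tibble, one row per pairing.
#' @export
distance_matrix <- function(genomes, pairs, params = align_params(),
                            table = "5") {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- genomes[[pairs$genome_a[i]]]
    gb <- genomes[[pairs$genome_b[i]]]
    base <- tibble::tibble(
      genome_a = pairs$genome_a[i], feature_a = pairs$feature_a[i],
      genome_b = pairs$genome_b[i], feature_b = pairs$feature_b[i],
      level = params$level, p = NA_real_, compared_sites = NA_integer_,
      P = NA_real_, Q = NA_real_, d_t92 = NA_real_,
      saturated = NA, note = "")
    ok_a <- !is.null(ga) && pairs$feature_a[i] %in% names(ga$features)
    ok_b <- !is.null(gb) && pairs$feature_b[i] %in% names(gb$features)
    if (!ok_a || !ok_b) {
      base$note <- "missing feature"
      return(base)
    }
    aln <- align_feature_pair(ga, pairs$feature_a[i], gb, pairs$feature_b[i],
                              params, table)
    d <- if (params$level == "nt") tamura3p(aln) else p_distance(aln)
    base$p <- d$p
    base$compared_sites <- d$compared_sites
    base$P <- d$P
    base$Q <- d$Q
    base$d_t92 <- d$d_t92
    base$saturated <- d$saturated
    base
  })
  do.call(rbind, rows)
}

#' All-vs-all pairing specification for [distance_matrix]
#'
#' @param genome_a,genome_b Names of the two genomes (as keyed in the
#'   genome list).
#' @param features_a,features_b Feature name vectors; the full cross
#'   product is produced.
#' @export
feature_grid <- function(genome_a, features_a, genome_b, features_b) {
  g <- expand.grid(feature_a = features_a, feature_b = features_b,
                   stringsAsFactors = FALSE)
  tibble::tibble(genome_a = genome_a, feature_a = g$feature_a,
                 genome_b = genome_b, feature_b = g$feature_b)
}
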