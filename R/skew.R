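# Compositional skew tracks: AT-skew (A-T)/(A+T), GC-skew (G-C)/(G+C) and
# GC content relative to the genome average, in sliding windows over the
# circular genome, optionally restricted to a site class (noncoding,
# codon position 1/2/3).

#' Sliding-window compositional skew profile
#'
#' Windows start every `step` bp and wrap around the origin of circular
#' genomes, so the whole circle is covered. With a `site_mask`, only
#' positions in the selected classes contribute to the window counts —
#' `"noncoding"` means positions outside every annotated feature
#' (structural-RNA positions belong to neither class), `"codon1"`,
#' `"codon2"`, `"codon3"` are codon positions counted along each CDS/ORF
#' in its own reading direction. Filtered tracks conventionally use a
#' wider window (e.g. 1000 bp); pass it explicitly.
#'
#' @param genome An [annotated_genome].
#' @param metric `"at_skew"`, `"gc_skew"` or `"gc_content_rel"` (signed
#'   difference from the genome-average GC over the same mask).
#' @param window Window width in bp (default 200).
#' @param step Step in bp (default 25).
#' @param site_mask `NULL` (all positions) or a character subset of
#'   `c("noncoding", "codon1", "codon2", "codon3")`.
#' @return A `window_profile`; a window whose denominator is empty yields
#'   `NA`.
#' @export
skew_profile <- function(genome,
                         metric = c("at_skew", "gc_skew", "gc_content_rel"),
                         window = 200L, step = 25L, site_mask = NULL) {
  metric <- match.arg(metric)
  L <- length(genome)
  if (window > L) stop("window exceeds genome length")
  stopifnot(window >= step, step >= 1L)
  res <- strsplit(genome$sequence$residues, "", fixed = TRUE)[[1]]
  use <- rep(TRUE, L)
  if (!is.null(site_mask)) {
    site_mask <- match.arg(site_mask,
                           c("noncoding", "codon1", "codon2", "codon3"),
                           several.ok = TRUE)
    cls <- site_classes(genome)
    wanted <- c(noncoding = 0L, codon1 = 1L, codon2 = 2L,
                codon3 = 3L)[site_mask]
    use <- cls %in% wanted
  }
  circular <- genome$sequence$topology == "circular"
  starts <- if (circular) seq(0L, L - 1L, by = step)
            else seq(0L, L - window, by = step)
  isA <- (res == "A") & use
  isT <- (res == "T") & use
  isG <- (res == "G") & use
  isC <- (res == "C") & use
  # doubled cumulative sums make wrapped windows a single subtraction
  csum <- function(x) cumsum(if (circular) c(x, x) else x)
  cA <- csum(isA); cT <- csum(isT); cG <- csum(isG); cC <- csum(isC)
  wsum <- function(cs) cs[starts + window] - c(0, cs)[starts + 1L]
  A <- wsum(cA); T <- wsum(cT); G <- wsum(cG); C <- wsum(cC)
  vals <- switch(metric,
    at_skew = ifelse(A + T > 0, (A - T) / (A + T), NA_real_),
    gc_skew = ifelse(G + C > 0, (G - C) / (G + C), NA_real_),
    gc_content_rel = {
      tot <- A + T + G + C
      gtot <- sum(isA | isT | isG | isC)
      gGC <- if (gtot > 0) sum(isG | isC) / gtot else NA_real_
      ifelse(tot > 0, (G + C) / tot - gGC, NA_real_)
    })
  window_profile(centers = starts + window / 2, values = vals,
                 window = window, step = step, metric = metric)
}
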