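# Randomized-sequence null for homology detection. At divergences beyond
# ~0.6 an optimal aligner produces substantial spurious identity between
# unrelated sequences; the operational test asks whether an observed
# pairwise distance is distinguishably SMALLER than the distance obtained
# when one sequence's residues are shuffled (composition and length
# preserved) and the pair realigned.

# evaluate expr under a temporary RNG state; caller's stream is untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-stage seed derivation from one top-level seed; stays under 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

shuffle_residues <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(ch[sample.int(length(ch))], collapse = "")
}

#' Randomization test for homology between two sequences
#'
#' The observed statistic is the p-distance of the optimal global
#' alignment. The null is built by shuffling the residues of `b` (or of
#' both sequences, per `scheme`), realigning with identical parameters,
#' and recording the p-distance, `n_reps` times. The empirical left-tail
#' p-value with add-one correction, `(#(null <= observed) + 1)/(n_reps +
#' 1)`, is small when the observed pair is more similar than unrelated
#' sequences of the same composition — the homology signal.
#'
#' @param a,b Sequences at `params$level`.
#' @param params An [align_params] (aa level with BLOSUM62 by default).
#' @param n_reps Number of shuffles (>= 20).
#' @param seed Integer seed; results are deterministic given it.
#' @param scheme `"shuffle_b"` (default) or `"shuffle_both"`.
#' @return A `null_test_result`: `observed_d`, `null_values`,
#'   `null_mean`, `null_sd`, `z = (null_mean - observed_d)/null_sd`,
#'   `p_emp`, `n_reps`, `seed`, `scheme`, `level`.
#' @export
randomization_test <- function(a, b, params = align_params("aa"),
                               n_reps = 100L, seed,
                               scheme = c("shuffle_b", "shuffle_both")) {
  scheme <- match.arg(scheme)
  stopifnot(nzchar(a), nzchar(b), n_reps >= 20L)
  if (missing(seed)) stop("a seed is required for the randomization null")
  observed <- p_distance(global_align(a, b, params))$p
  amb <- if (params$level == "nt") "N" else "X"
  batchable <- scheme == "shuffle_b" &&
    !grepl(amb, a, fixed = TRUE) && !grepl(amb, b, fixed = TRUE)
  null_values <- if (batchable) {
    # one vectorized alignment call for all replicates; without ambiguity
    # symbols, mismatches/(matches+mismatches) equals the pairwise-deletion
    # p-distance exactly
    shuffles <- with_seed(seed, vapply(seq_len(n_reps), function(i)
      shuffle_residues(b), character(1)))
    set <- if (params$level == "nt") Biostrings::DNAStringSet(shuffles)
           else Biostrings::AAStringSet(shuffles)
    submat <- if (params$level == "nt") nt_matrix(params)
              else aa_matrix_for(params)
    ref <- if (params$level == "nt") Biostrings::DNAString(a)
           else Biostrings::AAString(a)
    pa <- Biostrings::pairwiseAlignment(
      set, ref, type = "global", substitutionMatrix = submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    Biostrings::nmismatch(pa) /
      (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))
  } else {
    with_seed(seed, vapply(seq_len(n_reps), function(i) {
      bb <- shuffle_residues(b)
      aa <- if (scheme == "shuffle_both") shuffle_residues(a) else a
      p_distance(global_align(aa, bb, params))$p
    }, numeric(1)))
  }
  null_mean <- mean(null_values)
  null_sd <- stats::sd(null_values)
  z <- if (isTRUE(null_sd > 0)) (null_mean - observed) / null_sd else NA_real_
  structure(list(observed_d = observed, null_values = null_values,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 p_emp = (sum(null_values <= observed) + 1) / (n_reps + 1),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 scheme = scheme, level = params$level),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf(
    "<null_test> observed %.4f vs null %.4f +/- %.4f (z = %.2f, p_emp = %.4g, n = %d)\n",
    x$observed_d, x$null_mean, x$null_sd, x$z, x$p_emp, x$n_reps))
  invisible(x)
}

#' Screen an ORF set against a gene set for homology
#'
#' Runs [randomization_test] over the full ORF-by-gene grid (e.g. three
#' unassigned ORFs against the seven complex I genes of a reference
#' genome) at amino-acid level by default. A pair is called
#' `"homology-supported"` only when its empirical p-value beats `alpha`
#' after Bonferroni correction across the grid — a deliberately
#' conservative rule, since alignment optimization alone shrinks observed
#' distances below the shuffle null. Features that do not translate
#' cleanly (length not a codon multiple, or internal stops) are flagged,
#' not fatal.
#'
#' @param genome_a Genome carrying the ORFs; `orfs` names its features.
#' @param orfs Character vector of feature names in `genome_a`.
#' @param genome_b Genome carrying the reference genes; `genes` names its
#'   features.
#' @param genes Character vector of feature names in `genome_b`.
#' @param params An [align_params].
#' @param n_reps Shuffles per pair.
#' @param seed Top-level seed; per-pair seeds are derived from it.
#' @param alpha Family-wise significance level (default 0.05).
#' @param table Genetic code id.
#' @return A tibble with one row per pair: observed and null summaries,
#'   `p_emp`, `verdict`.
#' @export
homology_screen <- function(genome_a, orfs, genome_b, genes,
                            params = align_params("aa"), n_reps = 100L,
                            seed, alpha = 0.05, table = "5") {
  if (missing(seed)) stop("a seed is required for the randomization null")
  grid <- expand.grid(orf = orfs, gene = genes, stringsAsFactors = FALSE)
  n_tests <- nrow(grid)
  if (n_tests == 0L) {
    return(tibble::tibble(orf = character(), gene = character(),
                          observed_d = numeric(), null_mean = numeric(),
                          null_sd = numeric(), z = numeric(),
                          p_emp = numeric(), verdict = character()))
  }
  rows <- lapply(seq_len(n_tests), function(i) {
    out <- tibble::tibble(orf = grid$orf[i], gene = grid$gene[i],
                          observed_d = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, z = NA_real_,
                          p_emp = NA_real_, verdict = "flagged")
    sa <- try(feature_sequence(genome_a, grid$orf[i]), silent = TRUE)
    sb <- try(feature_sequence(genome_b, grid$gene[i]), silent = TRUE)
    if (inherits(sa, "try-error") || inherits(sb, "try-error")) return(out)
    if (params$level == "aa") {
      sa <- try(strip_stop(translate(sa, table)), silent = TRUE)
      sb <- try(strip_stop(translate(sb, table)), silent = TRUE)
      bad <- function(s) inherits(s, "try-error") || grepl("*", s, fixed = TRUE)
      if (bad(sa) || bad(sb)) return(out)
    }
    r <- randomization_test(sa, sb, params, n_reps, derive_seed(seed, i))
    out$observed_d <- r$observed_d
    out$null_mean <- r$null_mean
    out$null_sd <- r$null_sd
    out$z <- r$z
    out$p_emp <- r$p_emp
    out$verdict <- if (r$p_emp < alpha / n_tests) "homology-supported"
                   else "not-supported"
    out
  })
  do.call(rbind, rows)
}
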