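# End-to-end comparison of an M-type-like genome against an F-type-like
# reference: shared-gene divergence table, ORF-vs-nadh homology screen,
# cox1 sliding-window divergence, gene-order scenario, skew tracks. Every
# number in the report bundle is produced by an exported operation of the
# modules above; this file only orchestrates and writes TSV.

read_genome_input <- function(x, role) {
  if (inherits(x, "annotated_genome")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("cannot read ", role, " input: ", x)
    return(read_genbank(x))
  }
  stop("unusable ", role, " input; give an annotated_genome or a GenBank file")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full two-genome comparison
#'
#' Produces the analysis surfaces of a divergent-mitogenome comparison as
#' machine-readable tables under `out_dir`:
#' \describe{
#'   \item{distances.tsv}{nucleotide p-distance and Tamura-3P for every
#'     shared non-ORF feature pair (pairwise deletion; alignment
#'     parameters echoed in the run log).}
#'   \item{homology_grid.tsv}{amino-acid randomization-null screen of
#'     every unassigned ORF in the M genome against every `nad*` gene of
#'     the F genome, with Bonferroni-corrected verdicts.}
#'   \item{windows.tsv}{sliding-window divergence along the cox1
#'     alignment.}
#'   \item{gene_order_report.txt}{breakpoint distance and minimal
#'     rearrangement scenario between the canonical gene orders.}
#'   \item{skew.tsv}{AT-skew, GC-skew and relative GC tracks for both
#'     genomes.}
#'   \item{run_log.txt}{configuration echo, so every table can be traced
#'     to its parameters.}
#' }
#' Deterministic given inputs and `seed`.
#'
#' @param m M-type genome: [annotated_genome] or GenBank file path.
#' @param f F-type reference genome, same forms.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the randomization nulls.
#' @param nt_params,aa_params Alignment parameters for the distance table
#'   and the homology screen.
#' @param n_reps Shuffles per homology-null pair.
#' @param alpha Family-wise significance level for the screen.
#' @param window,step Sliding-divergence window geometry (columns).
#' @param skew_window,skew_step Skew-track window geometry (bp).
#' @param max_ops Depth bound for the gene-order search.
#' @return Invisibly, a list with all computed tables.
#' @export
run_comparison <- function(m, f, out_dir, seed,
                           nt_params = align_params("nt"),
                           aa_params = align_params("aa"),
                           n_reps = 100L, alpha = 0.05,
                           window = 100L, step = 25L,
                           skew_window = 200L, skew_step = 25L,
                           max_ops = 4L) {
  if (missing(seed)) stop("run_comparison requires a seed")
  m <- read_genome_input(m, "M")
  f <- read_genome_input(f, "F")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- list(M = m, F = f)

  non_orf <- function(g) names(Filter(function(x) x$kind != "ORF",
                                      g$features))
  shared <- intersect(non_orf(m), non_orf(f))
  distances <- if (length(shared)) {
    pairs <- tibble::tibble(genome_a = "M", feature_a = shared,
                            genome_b = "F", feature_b = shared)
    distance_matrix(genomes, pairs, nt_params)
  } else NULL
  if (!is.null(distances)) write_tsv(distances, file.path(out_dir,
                                                          "distances.tsv"))

  orfs <- names(Filter(function(x) x$kind == "ORF", m$features))
  nadh <- grep("^nad", non_orf(f), value = TRUE)
  grid <- homology_screen(m, orfs, f, nadh, aa_params, n_reps,
                          seed = derive_seed(seed, 11L), alpha = alpha)
  write_tsv(grid, file.path(out_dir, "homology_grid.tsv"))

  windows <- NULL
  if ("cox1" %in% shared) {
    aln <- align_feature_pair(m, "cox1", f, "cox1", nt_params)
    if (length(aln) >= window) {
      prof <- sliding_divergence(aln, window, step)
      windows <- cbind(pair = "cox1:M-F", as.data.frame(prof))
      write_tsv(windows, file.path(out_dir, "windows.tsv"))
    }
  }

  order_m <- canonical_order(m)
  order_f <- canonical_order(f)
  scenario <- minimal_scenario(order_f, order_m, max_ops = max_ops)
  bp <- breakpoint_distance(order_f, order_m)
  rep_lines <- c(
    sprintf("breakpoint_distance\t%d", as.integer(bp)),
    sprintf("labels_dropped\t%d", attr(bp, "dropped")),
    sprintf("achieved\t%s", scenario$achieved),
    sprintf("op_count\t%d", scenario$op_count),
    vapply(scenario$ops, function(op) paste("op", op$type,
      paste(unlist(op[-1]), collapse = ","), sep = "\t"), ""))
  writeLines(rep_lines, file.path(out_dir, "gene_order_report.txt"))

  skews <- do.call(rbind, lapply(names(genomes), function(g)
    do.call(rbind, lapply(c("at_skew", "gc_skew", "gc_content_rel"),
      function(metric) {
        prof <- skew_profile(genomes[[g]], metric, skew_window, skew_step)
        cbind(genome = g, metric = metric, as.data.frame(prof))
      }))))
  write_tsv(skews, file.path(out_dir, "skew.tsv"))

  writeLines(c(
    sprintf("mitocomp %s", as.character(utils::packageVersion("mitocomp"))),
    sprintf("seed\t%d", as.integer(seed)),
    sprintf("m\t%s (%d bp)", m$sequence$id, length(m)),
    sprintf("f\t%s (%d bp)", f$sequence$id, length(f)),
    sprintf("nt gap_open/extend\t%g/%g", nt_params$gap_open,
            nt_params$gap_extend),
    sprintf("aa matrix\t%s", aa_params$aa_matrix),
    sprintf("null n_reps/alpha\t%d/%g", n_reps, alpha),
    sprintf("window/step\t%d/%d", window, step),
    sprintf("skew window/step\t%d/%d", skew_window, skew_step)),
    file.path(out_dir, "run_log.txt"))

  invisible(list(distances = distances, homology = grid, windows = windows,
                 scenario = scenario, breakpoints = bp, skews = skews))
}
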