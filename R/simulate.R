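# Truth-tagged synthetic mitogenome simulator. Generates an F-type-like
# reference genome (full gene complement including the seven complex I
# genes) and derives an M-type-like counterpart: retained genes mutated to
# a planted per-gene divergence, all nadh genes deleted, three long
# non-homologous ORFs inserted, a random 3' extension appended to cox1,
# and a small fixed set of gene-order moves applied.
#
# Two constructions make downstream truths sharp rather than statistical:
#   * every intergenic spacer is salted with a 12 bp cassette carrying stop
#     codons in all six reading frames, so no spurious ORF >= 300 bp can
#     live in or across a spacer, and each planted ORF is preceded by the
#     cassette so the ORF scanner recovers its exact coordinates;
#   * exact-planting mutation flips exactly round(p * L) positions, so the
#     measured per-gene p-distance equals the planted value to the digit.

# stops in all six frames: fwd CTA GTT AAT [TAA] / TAG / TAA, rev likewise
STOP_CASSETTE <- "CTAGTTAATTAA"

# four codons (TTA GTT AAT TAT): stop-free in the reading frame, but with a
# stop in each of the five other frames; periodically woven into planted
# ORF bodies so their only open frame is the intended one
ORF_FRAME_SALT <- "TTAGTTAATTAT"

# AT-rich base composition mimicking invertebrate mtDNA
MT_BASE_PROBS <- c(A = 0.35, C = 0.12, G = 0.18, T = 0.35)

F_GENE_LENGTHS <- c(
  cox1 = 1701, cox2 = 690, cox3 = 780, cytb = 1140, atp6 = 711, atp8 = 162,
  nad1 = 927, nad2 = 1053, nad3 = 351, nad4 = 1380, nad4L = 297,
  nad5 = 1716, nad6 = 501, rrnS = 950, rrnL = 1300)

NADH_GENES <- c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")

TRNA_NAMES <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnQ", "trnE",
                "trnG", "trnH", "trnI", "trnK", "trnL1", "trnL2", "trnM",
                "trnF", "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY",
                "trnV")

# F-type layout: trnF sits between trnA and cox1, the [trnW, trnG, rrnS]
# block between trnV and trnM — the two neighbourhoods the derived M-type
# rearranges.
F_LAYOUT <- c("cox1", "trnK", "cox2", "trnD", "atp8", "atp6", "cox3", "trnR",
              "nad4L", "nad4", "trnH", "nad5", "trnS1", "trnS2", "rrnL",
              "trnL1", "trnL2", "nad1", "trnP", "nad6", "cytb", "trnT",
              "nad3", "trnN", "nad2", "trnI", "trnQ", "trnE", "trnC",
              "trnY", "trnV", "trnW", "trnG", "rrnS", "trnM", "trnA",
              "trnF")

MINUS_STRAND_FEATURES <- c("trnQ", "trnC")

#' Simulation configuration
#'
#' Defaults emulate the study conditions of divergent bivalve
#' mitogenome pairs: ~19.5 kb circular genomes, a shared core gene set,
#' per-gene observed divergence 0.45, three planted non-homologous ORFs
#' (~4.0/0.95/0.85 kb), a ~1 kb 3' extension on cox1 bringing it to
#' ~2.7 kb, all seven nadh genes dropped from the M-like copy, and three
#' gene-order moves.
#'
#' @param genome_length_target Target F-genome length in bp; intergenic
#'   spacers absorb the difference from the fixed gene lengths. Use
#'   `spacer_total = 0` for a genome that is exactly the sum of its
#'   features.
#' @param divergence_p Target observed per-gene p-distance in `[0, 1)`.
#' @param mode `"exact_planting"` (flip exactly `round(p*L)` sites;
#'   default) or `"stochastic_jc"` (independent per-site substitution).
#' @param kappa Transition/transversion ratio among planted substitutions.
#' @param n_orfs Number of planted unassigned ORFs (0-3).
#' @param orf_lengths ORF lengths in bp including the stop codon.
#' @param drop_genes Genes removed from the M-like copy.
#' @param cox1_extension Length of the random in-frame 3' extension on
#'   cox1, bp (multiple of 3).
#' @param n_moves Number of gene-order moves (0-3) from the fixed move
#'   plan: relocate the `[trnW, trnG, rrnS]` block, relocate `trnF`,
#'   swap `trnI` with `trnE`.
#' @param spacer_total Total intergenic length; `NULL` derives it from
#'   `genome_length_target`.
#' @param seed Mandatory integer seed; every simulator draw flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length_target = 19500L,
                       divergence_p = 0.45,
                       mode = c("exact_planting", "stochastic_jc"),
                       kappa = 2,
                       n_orfs = 3L,
                       orf_lengths = c(3999L, 951L, 849L),
                       drop_genes = NADH_GENES,
                       cox1_extension = 999L,
                       n_moves = 3L,
                       spacer_total = NULL,
                       seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("sim_config requires a seed")
  stopifnot(divergence_p >= 0, divergence_p < 1, kappa > 0,
            n_orfs >= 0L, n_orfs <= 3L,
            length(orf_lengths) >= n_orfs,
            all(orf_lengths %% 3L == 0L),
            cox1_extension %% 3L == 0L,
            n_moves >= 0L, n_moves <= 3L)
  structure(list(genome_length_target = as.integer(genome_length_target),
                 divergence_p = divergence_p, mode = mode, kappa = kappa,
                 n_orfs = as.integer(n_orfs),
                 orf_lengths = as.integer(orf_lengths),
                 drop_genes = drop_genes,
                 cox1_extension = as.integer(cox1_extension),
                 n_moves = as.integer(n_moves),
                 spacer_total = spacer_total,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n, probs = MT_BASE_PROBS) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# stop-free random codons (reading frame only), AT-rich composition
random_codons <- function(n_codons, stop_codons = c("TAA", "TAG")) {
  out <- character(n_codons)
  i <- 1L
  while (i <= n_codons) {
    cod <- random_dna(3L)
    if (!cod %in% stop_codons) {
      out[i] <- cod
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# ATG + stop-free body + TAA, total length len
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG", random_codons(len / 3L - 2L), "TAA")
}

# planted ORF: ATG + body + TAA where the body interleaves random
# stop-free codons with ORF_FRAME_SALT every ~15 codons, so no off-frame
# stop-free run long enough to register as a spurious unassigned ORF can
# exist inside a planted ORF
random_orf_seq <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 36L)
  body_codons <- len / 3L - 2L
  parts <- character()
  remaining <- body_codons
  while (remaining >= 19L) {
    parts <- c(parts, random_codons(15L), ORF_FRAME_SALT)
    remaining <- remaining - 19L
  }
  if (remaining > 0L) parts <- c(parts, random_codons(remaining))
  paste0("ATG", paste(parts, collapse = ""), "TAA")
}

# spacer with stop cassettes every <= 40 random bp: no >= 300 bp ORF can
# live inside or read through it on either strand
random_spacer <- function(len) {
  parts <- character()
  remaining <- len
  while (remaining >= 52L) {
    chunk <- min(40L, remaining - 12L)
    parts <- c(parts, random_dna(chunk), STOP_CASSETTE)
    remaining <- remaining - chunk - 12L
  }
  if (remaining > 0L) parts <- c(parts, random_dna(remaining))
  paste(parts, collapse = "")
}

fresh_insert_spacer <- function() {
  paste0(random_dna(10L), STOP_CASSETTE, random_dna(8L))
}

segment <- function(name, kind, strand, seq) {
  list(name = name, kind = kind, strand = strand, seq = seq)
}

# concatenate segments into an annotated genome; spacer segments become
# plain sequence, feature segments get coordinates
assemble_genome <- function(segments, id, source = "simulated") {
  seqs <- vapply(segments, `[[`, "", "seq")
  lens <- nchar(seqs)
  starts <- cumsum(c(0L, head(lens, -1L)))
  feats <- list()
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    if (sg$kind == "spacer") next
    sq <- if (sg$strand == "-") revcomp(sg$seq) else sg$seq
    feats[[length(feats) + 1L]] <-
      mt_feature(sg$name, sg$kind, sg$strand,
                 matrix(c(starts[i], starts[i] + lens[i]), ncol = 2L))
    segments[[i]]$seq <- sq
  }
  residues <- paste(vapply(segments, `[[`, "", "seq"), collapse = "")
  annotated_genome(circ_seq(id, residues, "circular"), feats, source)
}

#' Simulate an F-type-like reference mitogenome
#'
#' Builds a circular genome with six protein-coding genes (cox1-cox3,
#' cytb, atp6, atp8), the seven nadh genes, two rRNAs and twenty-two
#' tRNAs in a fixed layout, separated by stop-salted intergenic spacers
#' sized to reach the target length. CDS sequences are random stop-free
#' codons under the invertebrate mitochondrial code; RNA features are
#' random sequence of realistic length (no secondary structure).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config].
#' @return List with `genome` (an [annotated_genome]), `truth` (a
#'   `truth_table`), and `segments` (the internal layout, consumed by
#'   [derive_m_genome]).
#' @export
simulate_f_genome <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    trna_len <- sample(60:75, length(TRNA_NAMES), replace = TRUE)
    names(trna_len) <- TRNA_NAMES
    feat_len <- c(F_GENE_LENGTHS, trna_len)
    total_feat <- sum(feat_len[F_LAYOUT])
    spacer_total <- cfg$spacer_total %||%
      max(0L, cfg$genome_length_target - total_feat)
    n_gaps <- length(F_LAYOUT)
    base <- spacer_total %/% n_gaps
    extra <- spacer_total %% n_gaps
    gap_len <- rep(base, n_gaps) + c(rep(1L, extra), rep(0L, n_gaps - extra))
    segments <- list()
    for (i in seq_along(F_LAYOUT)) {
      nm <- F_LAYOUT[i]
      kind <- if (nm %in% names(F_GENE_LENGTHS)) {
        if (startsWith(nm, "rrn")) "rRNA" else "CDS"
      } else "tRNA"
      sq <- if (kind == "CDS") random_cds(feat_len[[nm]])
            else random_dna(feat_len[[nm]])
      strand <- if (nm %in% MINUS_STRAND_FEATURES) "-" else "+"
      segments[[length(segments) + 1L]] <- segment(nm, kind, strand, sq)
      if (gap_len[i] > 0L)
        segments[[length(segments) + 1L]] <-
          segment(paste0("spacer", i), "spacer", "+",
                  random_spacer(gap_len[i]))
    }
    genome <- assemble_genome(segments, "F_sim")
    truth <- structure(list(
      genes = tibble::tibble(name = names(feat_len[F_LAYOUT]),
                             length = unname(feat_len[F_LAYOUT]),
                             planted_p = 0, realized_p = 0),
      homolog_map = setNames(F_LAYOUT, F_LAYOUT),
      orfs = NULL, moves = list(), dropped = character(),
      seed = cfg$seed), class = "truth_table")
    list(genome = genome, truth = truth, segments = segments)
  })
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# Mutate a feature sequence to observed divergence p. exact_planting flips
# exactly round(p*L) distinct sites; stochastic_jc substitutes each site
# independently with probability p. Substitutions are transitions with
# probability kappa/(kappa+1). In coding sequence a substitution that
# would create an in-frame stop codon is redirected to another base so
# translations stay clean; the site still changes, so planted p is exact.
mutate_seq <- function(seq, p, mode, kappa, coding = FALSE) {
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sites <- if (mode == "exact_planting") {
    k <- round(p * L)
    if (k == 0L) integer() else sort(sample.int(L, k))
  } else {
    which(stats::runif(L) < p)
  }
  for (s in sites) {
    old <- ch[s]
    if (!old %in% names(TRANSITION)) next
    choices <- if (stats::runif(1) < kappa / (kappa + 1))
      c(TRANSITION[[old]], TRANSVERSIONS[[old]])
    else
      c(sample(TRANSVERSIONS[[old]]), TRANSITION[[old]])
    for (new in choices) {
      ch[s] <- new
      if (!coding) break
      cstart <- s - (s - 1L) %% 3L
      codon <- paste(ch[cstart:(cstart + 2L)], collapse = "")
      if (!(codon %in% c("TAA", "TAG") && cstart + 2L < L)) break
      ch[s] <- old
    }
  }
  paste(ch, collapse = "")
}

#' Derive an M-type-like genome from a simulated F-type genome
#'
#' Copies the F layout, then: mutates every retained gene to the target
#' divergence, deletes `drop_genes` (the nadh set by default), appends a
#' random in-frame 3' extension to cox1, applies the configured
#' gene-order moves, and inserts the planted non-homologous ORFs, each
#' wrapped in fresh stop-salted spacers. The returned truth table
#' records realized per-gene divergence, the homology map (planted ORFs
#' map to no gene), planted ORF coordinates, applied moves and dropped
#' genes, and is verified by replay in the test suite.
#'
#' @param f Result of [simulate_f_genome] (or an [annotated_genome] of
#'   the same shape, from which the layout is reconstructed).
#' @param cfg The same [sim_config].
#' @return List with `genome`, `truth`, `segments`.
#' @export
derive_m_genome <- function(f, cfg) {
  segments <- if (is.list(f) && !is.null(f$segments)) f$segments
              else segments_from_genome(f)
  with_seed(derive_seed(cfg$seed, 2L), {
    seg_names <- vapply(segments, `[[`, "", "name")
    planted <- list()
    # 1. mutate retained genes
    for (i in seq_along(segments)) {
      sg <- segments[[i]]
      if (sg$kind == "spacer" || sg$name %in% cfg$drop_genes) next
      L <- nchar(sg$seq)
      mut <- mutate_seq(sg$seq, cfg$divergence_p, cfg$mode, cfg$kappa,
                        coding = sg$kind %in% c("CDS", "ORF"))
      segments[[i]]$seq <- mut
      realized <- sum(strsplit(sg$seq, "")[[1]] != strsplit(mut, "")[[1]]) / L
      planted[[sg$name]] <- c(planted_p = cfg$divergence_p,
                              realized_p = realized, length = L)
    }
    # 2. delete dropped genes
    segments <- segments[!(seg_names %in% cfg$drop_genes)]
    seg_names <- vapply(segments, `[[`, "", "name")
    # 3. cox1 3' extension (replace terminal stop, extend, restop)
    if (cfg$cox1_extension > 0L && "cox1" %in% seg_names) {
      i <- match("cox1", seg_names)
      body <- substr(segments[[i]]$seq, 1L, nchar(segments[[i]]$seq) - 3L)
      segments[[i]]$seq <- paste0(body,
                                  random_codons(cfg$cox1_extension / 3L),
                                  "TAA")
    }
    # 4. gene-order moves (fixed plan, applied to the segment list)
    moves <- list()
    move_block <- function(segments, block, after) {
      nms <- vapply(segments, `[[`, "", "name")
      idx <- match(block, nms)
      blockseg <- segments[idx]
      segments <- segments[-idx]
      at <- match(after, vapply(segments, `[[`, "", "name"))
      append(segments, c(list(segment(paste0("ins_sp_", block[1]), "spacer",
                                      "+", fresh_insert_spacer())),
                         blockseg),
             after = at)
    }
    if (cfg$n_moves >= 1L) {
      segments <- move_block(segments, c("trnW", "trnG", "rrnS"), "trnS2")
      moves[[1]] <- list(op = "relocate_block",
                         block = c("trnW", "trnG", "rrnS"),
                         from = "trnV|trnM", to = "trnS2|rrnL")
    }
    if (cfg$n_moves >= 2L) {
      segments <- move_block(segments, "trnF", "cytb")
      moves[[2]] <- list(op = "relocate_block", block = "trnF",
                         from = "trnA|cox1", to = "cytb|.")
    }
    if (cfg$n_moves >= 3L) {
      nms <- vapply(segments, `[[`, "", "name")
      i <- match("trnI", nms)
      j <- match("trnE", nms)
      tmp <- segments[[i]]
      segments[[i]] <- segments[[j]]
      segments[[j]] <- tmp
      moves[[3]] <- list(op = "swap", block = c("trnI", "trnE"))
    }
    # 5. plant ORFs, each preceded by a cassette so the scanner recovers
    # exact coordinates, wrapped in fresh spacers
    orf_anchor <- c("trnF", "trnS2", "trnG")
    if (cfg$n_moves < 2L) orf_anchor[1] <- "cytb"
    for (k in seq_len(cfg$n_orfs)) {
      nms <- vapply(segments, `[[`, "", "name")
      at <- match(orf_anchor[k], nms)
      orfseq <- random_orf_seq(cfg$orf_lengths[k])
      ins <- list(
        segment(paste0("orf_sp_a", k), "spacer", "+",
                paste0(random_dna(10L), STOP_CASSETTE)),
        segment(paste0("uORF", k), "ORF", "+", orfseq),
        segment(paste0("orf_sp_b", k), "spacer", "+", fresh_insert_spacer()))
      segments <- append(segments, ins, after = at)
    }
    genome <- assemble_genome(segments, "M_sim")
    pl <- do.call(rbind, planted)
    retained <- rownames(pl)
    orf_feats <- Filter(function(f) f$kind == "ORF", genome$features)
    homolog_map <- c(setNames(retained, retained),
                     setNames(rep(NA_character_, length(orf_feats)),
                              vapply(orf_feats, `[[`, "", "name")))
    truth <- structure(list(
      genes = tibble::tibble(name = retained,
                             length = as.integer(unname(pl[, "length"])),
                             planted_p = unname(pl[, "planted_p"]),
                             realized_p = unname(pl[, "realized_p"])),
      homolog_map = homolog_map,
      orfs = orf_table(orf_feats, genome),
      moves = moves,
      dropped = intersect(cfg$drop_genes, F_LAYOUT),
      seed = cfg$seed), class = "truth_table")
    list(genome = genome, truth = truth, segments = segments)
  })
}

# reconstruct a segment list from an assembled genome whose features are
# contiguous and non-overlapping (the simulator's own output shape)
segments_from_genome <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  res <- genome$sequence$residues
  feats <- genome$features[order(vapply(genome$features,
                                        function(f) f$intervals[1L, 1L],
                                        integer(1)))]
  segments <- list()
  pos <- 0L
  for (f in feats) {
    s <- f$intervals[1L, 1L]
    e <- f$intervals[nrow(f$intervals), 2L]
    if (s > pos)
      segments[[length(segments) + 1L]] <-
        segment(paste0("spacer@", pos), "spacer", "+",
                substr(res, pos + 1L, s))
    segments[[length(segments) + 1L]] <-
      segment(f$name, f$kind, f$strand, feature_sequence(genome, f))
    pos <- e
  }
  if (pos < nchar(res))
    segments[[length(segments) + 1L]] <-
      segment("spacer@end", "spacer", "+", substr(res, pos + 1L, nchar(res)))
  segments
}

#' Simulate a matched F/M mitogenome pair
#'
#' Convenience wrapper running [simulate_f_genome] then
#' [derive_m_genome] under one configuration.
#'
#' @param cfg A [sim_config].
#' @return List with `f`, `m` (each `genome` + `truth` + `segments`) and
#'   `cfg`.
#' @export
simulate_pair <- function(cfg) {
  f <- simulate_f_genome(cfg)
  m <- derive_m_genome(f, cfg)
  list(f = f, m = m, cfg = cfg)
}

#' Write a truth table as TSV sidecar files
#'
#' @param truth A `truth_table`.
#' @param dir Output directory; files `truth_genes.tsv`, `truth_orfs.tsv`
#'   and `truth_moves.tsv` are written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(truth$orfs))
    utils::write.table(truth$orfs, file.path(dir, "truth_orfs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  moves <- vapply(truth$moves, function(m)
    paste(m$op, paste(m$block, collapse = ","), sep = ":"), "")
  writeLines(moves, file.path(dir, "truth_moves.tsv"))
  invisible(dir)
}
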