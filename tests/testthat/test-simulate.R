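test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 42)
  p1 <- simulate_pair(cfg)
  p2 <- simulate_pair(cfg)
  expect_identical(p1$f$genome$sequence$residues,
                   p2$f$genome$sequence$residues)
  expect_identical(p1$m$genome$sequence$residues,
                   p2$m$genome$sequence$residues)
  expect_identical(p1$m$truth$genes, p2$m$truth$genes)
  p3 <- simulate_pair(sim_config(seed = 43))
  expect_false(identical(p1$f$genome$sequence$residues,
                         p3$f$genome$sequence$residues))
})

test_that("the F genome hits its length budget with the full gene set", {
  pair <- cached_pair()
  f <- pair$f$genome
  expect_lt(abs(length(f) - 19500) / 19500, 0.1)
  kinds <- vapply(f$features, `[[`, "", "kind")
  expect_equal(sum(kinds == "tRNA"), 22L)
  expect_equal(sum(kinds == "rRNA"), 2L)
  expect_true(all(c("cox1", "cox2", "cox3", "cytb", "atp6", "atp8",
                    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5",
                    "nad6") %in% names(f$features)))
  # all CDS translate cleanly under the invertebrate code
  for (nm in names(f$features)) {
    ft <- f$features[[nm]]
    if (ft$kind != "CDS") next
    aa <- translate(feature_sequence(f, ft))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("zero spacer budget makes the genome exactly the sum of features", {
  cfg <- sim_config(seed = 5, spacer_total = 0)
  f <- simulate_f_genome(cfg)
  expect_equal(length(f$genome),
               sum(vapply(f$genome$features, feature_length, integer(1))))
})

test_that("a null configuration leaves the M genome identical to F", {
  cfg <- sim_config(seed = 6, divergence_p = 0, n_orfs = 0,
                    cox1_extension = 0, n_moves = 0,
                    drop_genes = character())
  pair <- simulate_pair(cfg)
  expect_identical(pair$m$genome$sequence$residues,
                   pair$f$genome$sequence$residues)
})

test_that("the M genome lacks the nadh set and matches the study's anatomy", {
  pair <- cached_pair()
  m <- pair$m$genome
  expect_false(any(grepl("^nad", names(m$features))))
  kinds <- vapply(m$features, `[[`, "", "kind")
  expect_equal(sum(kinds == "ORF"), 3L)
  expect_equal(sum(kinds == "tRNA"), 22L)
  # cox1 was extended in frame
  expect_equal(feature_length(m$features[["cox1"]]), 1701L + 999L)
  aa <- translate(feature_sequence(m, "cox1"))
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
})

test_that("truth replay: exact planting reproduces per-gene p to the digit", {
  pair <- cached_pair()
  truth <- pair$m$truth$genes
  genomes <- list(M = pair$m$genome, F = pair$f$genome)
  for (nm in c("cytb", "atp6", "rrnL", "trnF")) {
    d <- p_distance(align_feature_pair(genomes$M, nm, genomes$F, nm))
    expect_equal(d$p, truth$realized_p[truth$name == nm],
                 tolerance = 1e-12, label = nm)
    expect_equal(truth$realized_p[truth$name == nm],
                 round(0.45 * truth$length[truth$name == nm]) /
                   truth$length[truth$name == nm],
                 label = nm)
  }
  # cox1: positional homology of the shared region is known (the random
  # extension replaced the terminal codon), so replay on fixed columns;
  # the terminal codon itself may differ, hence the 3-site slack
  ma <- substr(feature_sequence(genomes$M, "cox1"), 1, 1698)
  fa <- substr(feature_sequence(genomes$F, "cox1"), 1, 1698)
  d <- p_distance(alignment(ma, fa, align_params("nt")))
  expect_equal(d$compared_sites, 1698L)
  expect_lte(abs(d$p - truth$realized_p[truth$name == "cox1"]), 3 / 1701)
})

test_that("stochastic mode lands within binomial bounds of the target", {
  cfg <- sim_config(seed = 8, mode = "stochastic_jc")
  pair <- simulate_pair(cfg)
  truth <- pair$m$truth$genes
  big <- truth[truth$length >= 600, ]
  bounds <- function(L) qbinom(c(0.005, 0.995), L, 0.45) / L
  for (i in seq_len(nrow(big))) {
    b <- bounds(big$length[i])
    expect_gte(big$realized_p[i], b[1])
    expect_lte(big$realized_p[i], b[2])
  }
})

test_that("planted transition:transversion ratio follows kappa", {
  pair <- cached_pair()
  genomes <- list(M = pair$m$genome, F = pair$f$genome)
  pairs <- tibble::tibble(genome_a = "M", genome_b = "F",
                          feature_a = c("rrnL", "cytb", "atp6"),
                          feature_b = c("rrnL", "cytb", "atp6"))
  tab <- distance_matrix(genomes, pairs)
  ratio <- sum(tab$P * tab$compared_sites) / sum(tab$Q * tab$compared_sites)
  # kappa = 2 by default; coding-sequence stop avoidance nudges it slightly
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("gene-order truth: the planted moves are recovered as a minimal scenario", {
  pair <- cached_pair()
  of <- canonical_order(pair$f$genome)
  om <- canonical_order(pair$m$genome)
  sc <- minimal_scenario(of, om, max_ops = 3)
  expect_true(sc$achieved)
  expect_equal(sc$op_count, length(pair$m$truth$moves))
  # fewer planted moves, fewer ops
  cfg1 <- sim_config(seed = 9, n_moves = 1)
  pr <- simulate_pair(cfg1)
  sc1 <- minimal_scenario(canonical_order(pr$f$genome),
                          canonical_order(pr$m$genome), max_ops = 2)
  expect_true(sc1$achieved)
  expect_equal(sc1$op_count, 1L)
})

test_that("truth sidecars are written as plain text tables", {
  pair <- cached_pair()
  dir <- withr::local_tempdir()
  write_truth(pair$m$truth, dir)
  genes <- read.delim(file.path(dir, "truth_genes.tsv"))
  expect_equal(sort(genes$name), sort(pair$m$truth$genes$name))
  expect_true(file.exists(file.path(dir, "truth_orfs.tsv")))
  moves <- readLines(file.path(dir, "truth_moves.tsv"))
  expect_length(moves, 3L)
})
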