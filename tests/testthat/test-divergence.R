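mk_aln <- function(a, b, level = "nt") {
  alignment(a, b, align_params(level))
}

test_that("p-distance counts differences, transitions and transversions", {
  expect_equal(p_distance(mk_aln("ACGT", "ACGT"))$p, 0)
  d <- p_distance(mk_aln("ACGT", "ACGA"))
  expect_equal(d$p, 0.25)
  expect_equal(d$P, 0)      # T->A is a transversion
  expect_equal(d$Q, 0.25)
  d2 <- p_distance(mk_aln("ACGT", "GCGT"))
  expect_equal(d2$P, 0.25)  # A->G is a transition
})

test_that("pairwise deletion drops gap and ambiguity columns", {
  d <- p_distance(mk_aln("AC-T", "ACGT"))
  expect_equal(d$compared_sites, 3L)
  expect_equal(d$p, 0)
  dn <- p_distance(mk_aln("ANGT", "ACGT"))
  expect_equal(dn$compared_sites, 3L)
  # all columns uncomparable: undefined result, not an exception
  d0 <- p_distance(mk_aln("--N", "AC-"))
  expect_true(d0$undefined)
})

test_that("P + Q = p exactly and p is symmetric", {
  set.seed(71)
  for (i in 1:20) {
    a <- rand_dna(120)
    b <- rand_dna(120)
    d <- p_distance(mk_aln(a, b))
    expect_equal(d$p, d$P + d$Q)
    expect_equal(p_distance(mk_aln(b, a))$p, d$p)
  }
})

test_that("Tamura-3P matches its closed form and flags saturation", {
  # no divergence
  expect_equal(tamura3p(mk_aln("ACGT", "ACGT"))$d_t92, 0)
  # frozen high-precision evaluation of
  # -h log(1 - P/h - Q) - (1-h)/2 log(1 - 2Q) at theta=.5, P=.1, Q=.05
  d <- mitocomp:::t92_closed_form(0.5, 0.1, 0.05)
  expect_equal(d, 0.1701811651403470, tolerance = 1e-9)
  expect_equal(d, 0.17018, tolerance = 1e-4)
  # outside the domain: 1 - P/h - Q < 0
  expect_true(is.na(mitocomp:::t92_closed_form(0.5, 0.5, 0.3)))
  # an alignment engineered to saturate carries the flag
  a <- strrep("AG", 30)
  b <- strrep("GA", 30)
  r <- tamura3p(mk_aln(a, b))
  expect_true(r$saturated || r$d_t92 >= r$p)
})

test_that("Tamura-3P dominates p and converges to it at low divergence", {
  set.seed(81)
  for (i in 1:10) {
    a <- rand_dna(1200)
    b <- mutate_exactly(a, sample(60:400, 1), c("A", "C", "G", "T"))
    r <- tamura3p(mk_aln(a, b))
    if (!r$saturated) expect_gte(r$d_t92, r$p)
  }
  a <- rand_dna(3000)
  b <- mutate_exactly(a, 30, c("A", "C", "G", "T"))  # p = 0.01
  r <- tamura3p(mk_aln(a, b))
  expect_equal(r$p, 0.01)
  expect_lt(abs(r$d_t92 - r$p) / r$p, 0.05)
})

test_that("exact site planting is recovered to the digit", {
  set.seed(91)
  for (pstar in c(0.1, 0.3, 0.5)) {
    a <- rand_dna(9000)
    b <- mutate_exactly(a, round(pstar * 9000), c("A", "C", "G", "T"))
    # positional homology is known (no indels): measure on fixed columns
    d <- p_distance(mk_aln(a, b))
    expect_identical(d$p, pstar)
    expect_equal(d$compared_sites, 9000L)
    # the optimizing aligner agrees at moderate divergence, where the
    # gapless alignment is also the affine-gap optimum
    if (pstar < 0.5) {
      expect_identical(p_distance(global_align(a, b))$p, pstar)
    }
  }
})

test_that("sliding divergence reduces to the global value and respects bounds", {
  set.seed(101)
  a <- rand_dna(600)
  b <- mutate_exactly(a, 120, c("A", "C", "G", "T"))  # p = 0.2
  aln <- global_align(a, b)
  whole <- sliding_divergence(aln, window = length(aln), step = 25)
  expect_length(whole$values, 1L)
  expect_equal(whole$values, p_distance(aln)$p)
  prof <- sliding_divergence(aln, window = 100, step = 25)
  # uniformly planted divergence: every window inside the binomial 99% band
  band <- qbinom(c(0.005, 0.995), 100, 0.2) / 100
  expect_true(all(prof$values >= band[1] & prof$values <= band[2]))
  expect_error(sliding_divergence(aln, window = 1000), "exceeds")
})

test_that("a planted homology breakpoint is localized within one window step", {
  set.seed(111)
  a <- rand_dna(3000)
  # homologous for 1500 bp, unrelated beyond: mimics a gene whose 3' part
  # lost all similarity
  b <- paste0(mutate_exactly(substr(a, 1, 1500), 150, c("A", "C", "G", "T")),
              rand_dna(1500))
  aln <- mk_aln(a, b)  # equal lengths: compare on fixed columns
  prof <- sliding_divergence(aln, 100, 25)
  low <- prof$values < 0.3
  # last fully-homologous window and first fully-random window bracket 1500
  boundary <- prof$centers[max(which(low))]
  expect_lt(abs(boundary - 1500), 100 + 25)
})

test_that("distance_matrix reports grids and flags missing features", {
  pair <- cached_pair()
  genomes <- list(M = pair$m$genome, F = pair$f$genome)
  pairs <- tibble::tibble(genome_a = "M",
                          feature_a = c("cox2", "cox3", "ghost"),
                          genome_b = "F",
                          feature_b = c("cox2", "cox3", "cox1"))
  tab <- distance_matrix(genomes, pairs)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$note[3], "missing feature")
  truth <- pair$m$truth$genes
  for (g in c("cox2", "cox3")) {
    expect_equal(tab$p[tab$feature_a == g],
                 truth$realized_p[truth$name == g])
  }
  # identical genomes: off-diagonal zero everywhere
  id3 <- list(A = pair$f$genome, B = pair$f$genome, C = pair$f$genome)
  pp <- rbind(feature_grid("A", "cox2", "B", "cox2"),
              feature_grid("B", "cox2", "C", "cox2"))
  expect_true(all(distance_matrix(id3, pp)$p == 0))
})
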