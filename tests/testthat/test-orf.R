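test_that("a minimal linear ORF is found with stop included in its length", {
  g <- circ_seq("lin", "ATGAAATAA", topology = "linear")
  orfs <- find_orfs(g, orf_config(min_length_nt = 9L))
  expect_length(orfs, 1L)
  expect_equal(feature_length(orfs[[1]]), 9L)
  expect_equal(unname(orfs[[1]]$intervals[1, ]), c(0L, 9L))
})

test_that("stop codons end ORFs and the longest candidate per stop wins", {
  # two in-frame starts share one stop; the earlier start is reported
  g <- circ_seq("lin", paste0("ATGAAAATGAAATAA", "CTAGTTAATTAA"),
                topology = "linear")
  orfs <- find_orfs(g, orf_config(min_length_nt = 9L))
  spans <- vapply(orfs, function(f) f$intervals[1, 1], integer(1))
  expect_true(0L %in% spans)
  on_plus_f0 <- Filter(function(f) f$strand == "+" &&
                         f$intervals[1, 1] %% 3 == 0, orfs)
  expect_equal(max(vapply(on_plus_f0, feature_length, integer(1))), 15L)
})

test_that("wrap-around ORFs span the origin as two-interval features", {
  # start codon begins 3 bp before the origin, stop ends at position 9
  L <- 36L
  seqn <- paste0("AAAAAATAA", strrep("CTAGTTAATTAA", 2), "ATG")
  stopifnot(nchar(seqn) == L)
  g <- circ_seq("circ", seqn, topology = "circular")
  orfs <- find_orfs(g, orf_config(min_length_nt = 9L))
  wraps <- Filter(function(f) nrow(f$intervals) > 1L, orfs)
  expect_true(length(wraps) >= 1L)
  w <- Filter(function(f) f$strand == "+" && f$intervals[1, 1] == 33L,
              wraps)[[1]]
  expect_equal(unname(w$intervals[1, ]), c(33L, 36L))
  expect_equal(unname(w$intervals[2, ]), c(0L, 9L))
  expect_equal(translate(feature_sequence(annotated_genome(g), w)), "MKK*")
})

test_that("reported ORFs are frame-clean: codon multiple, no internal stop, stop-terminated", {
  for (seed in 1:3) {
    pair <- cached_pair(seed = 100 + seed)
    g <- pair$m$genome
    orfs <- find_orfs(g)
    expect_gt(length(orfs), 0L)
    for (f in orfs) {
      expect_equal(feature_length(f) %% 3L, 0L)
      aa <- translate(feature_sequence(g, f))
      expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)),
                   label = paste("internal stop in", f$name))
      expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    }
  }
})

test_that("reverse-complementing the genome maps the ORF set with strands flipped", {
  g <- cached_pair()$m$genome
  L <- length(g)
  orfs <- find_orfs(g)
  orfs_rc <- find_orfs(reverse_complement(g))
  key <- function(f, flip = FALSE) {
    iv <- f$intervals
    if (flip) {
      iv <- cbind(L - iv[, 2], L - iv[, 1])[rev(seq_len(nrow(iv))), ,
                                            drop = FALSE]
    }
    strand <- if (flip) (if (f$strand == "+") "-" else "+") else f$strand
    paste(strand, paste(t(iv), collapse = ","))
  }
  expect_setequal(vapply(orfs_rc, key, "", flip = TRUE),
                  vapply(orfs, key, ""))
})

test_that("unassigned_orfs applies the overlap threshold on circular coordinates", {
  gene <- paste0("ATG", strrep("GCT", 200), "TAA")  # 606 bp
  orf_seq <- paste0("ATG", strrep("GCA", 120), "TAA")              # 366 bp
  g <- mk_genome(list(
    list(name = "cox1", kind = "CDS", strand = "+", seq = gene),
    list(name = "free", kind = "ORF", strand = "+", seq = orf_seq),
    list(name = "trnX", kind = "tRNA", strand = "+", seq = rand_dna(66))))
  inside <- mt_feature("inside", "ORF", "+",
                       g$features[["cox1"]]$intervals + c(3L, -300L))
  free <- g$features[["free"]]
  # overlapping a tRNA by ~10% of the ORF's length
  tr <- g$features[["trnX"]]$intervals
  brush_start <- tr[1, 1] - 270L
  brush <- mt_feature("brush", "ORF", "+",
                      matrix(c(brush_start, brush_start + 300L), ncol = 2))
  kept <- unassigned_orfs(list(inside, free, brush), g)
  expect_setequal(vapply(kept, `[[`, "", "name"), c("free", "brush"))
})

test_that("simulated genomes yield exactly the planted unassigned ORFs, at exact coordinates", {
  for (seed in c(11, 12, 13)) {
    pair <- cached_pair(seed = seed)
    m <- pair$m$genome
    found <- unassigned_orfs(find_orfs(m), m)
    truth <- pair$m$truth$orfs
    expect_equal(length(found), nrow(truth))
    found_keys <- vapply(found, function(f)
      paste(f$strand, f$intervals[1, 1], feature_length(f)), "")
    truth_keys <- paste(truth$strand, truth$start, truth$length)
    expect_setequal(found_keys, truth_keys)
  }
  # the F-type genome, with its full gene complement, has none
  f <- cached_pair(seed = 11)$f$genome
  expect_length(unassigned_orfs(find_orfs(f), f), 0L)
})

test_that("planted ORFs at the reported inventory scale are recovered", {
  cfg <- sim_config(seed = 401, orf_lengths = c(996L, 921L, 801L))
  pair <- simulate_pair(cfg)
  m <- pair$m$genome
  found <- unassigned_orfs(find_orfs(m), m)
  expect_setequal(vapply(found, feature_length, integer(1)),
                  c(996L, 921L, 801L))
})

test_that("orf_config validates its invariants", {
  expect_error(orf_config(min_length_nt = 10L))
  expect_error(orf_config(start_codons = "TAA"))
})
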