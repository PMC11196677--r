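# Independent oracles and fixture builders shared across the suite. None
# of these reuse package internals: the brute-force aligner, the codon
# table and the rearrangement enumerator are written from scratch so they
# can stand as cross-checks of the implementation.

# --- brute-force affine-gap global aligner (exhaustive enumeration) ------
# Recursion over all monotone alignments with an affine gap automaton:
# entering a gap costs open + ext, continuing costs ext. Exponential; only
# for sequences up to length ~8.
bf_align_score <- function(a, b, match = 1, mismatch = -1,
                           open = 3, ext = 3, submat = NULL) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  subst <- function(x, y) {
    if (!is.null(submat)) submat[x, y]
    else if (x == y) match else mismatch
  }
  rec <- function(i, j, state) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      best <- max(best, subst(av[i + 1], bv[j + 1]) + rec(i + 1, j + 1, "M"))
    }
    if (i < n) {  # gap in b
      cost <- ext + if (state == "GB") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "GB"))
    }
    if (j < m) {  # gap in a
      cost <- ext + if (state == "GA") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "GA"))
    }
    best
  }
  rec(0, 0, "M")
}

# --- NCBI translation table 5, built by hand ------------------------------
HAND_TABLE5 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "S", AGG = "S",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# --- random sequences -----------------------------------------------------
rand_dna <- function(n, probs = c(A = .3, C = .2, G = .2, T = .3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

# substitute exactly k positions of a string to different symbols
mutate_exactly <- function(s, k, alphabet) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  at <- sample.int(length(ch), k)
  for (i in at) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
  paste(ch, collapse = "")
}

# --- tiny annotated-genome fixture ---------------------------------------
# builds a linear-layout circular genome from (name, kind, strand, seq)
# rows separated by fixed spacers, so coordinates are predictable
mk_genome <- function(specs, id = "test", spacer = "CTAGTTAATTAA") {
  seqs <- character()
  feats <- list()
  pos <- 0L
  for (sp in specs) {
    seqs <- c(seqs, spacer)
    pos <- pos + nchar(spacer)
    sq <- sp$seq
    feats[[length(feats) + 1L]] <-
      mt_feature(sp$name, sp$kind, sp$strand,
                 matrix(c(pos, pos + nchar(sq)), ncol = 2))
    seqs <- c(seqs, if (sp$strand == "-") revcomp(sq) else sq)
    pos <- pos + nchar(sq)
  }
  seqs <- c(seqs, spacer)
  annotated_genome(circ_seq(id, paste(seqs, collapse = ""), "circular"),
                   feats, "fixture")
}

# --- independent rearrangement-scenario oracle ---------------------------
# Iterative-deepening exhaustive enumeration over block relocations and
# swaps, with its own op application code. Returns the minimal op count
# reaching `target` (circular rotation equality) within `max_depth`, or
# Inf. Only for small orders.
oracle_apply_reloc <- function(v, from, len, dest) {
  idx <- from:(from + len - 1)
  rest <- v[-idx]
  append(rest, v[idx], after = dest)
}

oracle_ops <- function(n) {
  ops <- list()
  for (from in 1:n) for (len in 1:(n - 1)) {
    if (from + len - 1 > n) break
    for (dest in 0:(n - len))
      if (dest != from - 1)
        ops[[length(ops) + 1]] <- list("r", from, len, dest)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    ops[[length(ops) + 1]] <- list("s", i, j)
  ops
}

oracle_circ_equal <- function(v, w) {
  n <- length(v)
  for (k in seq_len(n)) {
    if (all(v == w[c(k:n, seq_len(k - 1))[seq_len(n)]])) return(TRUE)
  }
  FALSE
}

oracle_min_ops <- function(source, target, max_depth) {
  n <- length(source)
  ops <- oracle_ops(n)
  dfs <- function(v, depth) {
    if (oracle_circ_equal(target, v)) return(0L)
    if (depth == 0L) return(Inf)
    best <- Inf
    for (op in ops) {
      w <- if (op[[1]] == "r")
        oracle_apply_reloc(v, op[[2]], op[[3]], op[[4]])
      else {
        u <- v
        u[c(op[[2]], op[[3]])] <- v[c(op[[3]], op[[2]])]
        u
      }
      r <- dfs(w, depth - 1L)
      if (!is.infinite(r)) best <- min(best, r + 1L)
      if (best == 1L) break
    }
    best
  }
  for (d in 0:max_depth) {
    r <- dfs(source, d)
    if (!is.infinite(r)) return(r)
  }
  Inf
}

# --- cached simulated pairs (simulation is the expensive fixture) --------
.sim_cache <- new.env(parent = emptyenv())
cached_pair <- function(seed = 7, ...) {
  key <- paste(seed, ..., sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_pair(sim_config(seed = seed, ...))
  }
  .sim_cache[[key]]
}
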