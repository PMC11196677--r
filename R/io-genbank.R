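# GenBank flat-file I/O. Hand-written reader covering the subset every
# mitogenome record uses: LOCUS (length + topology), FEATURES with
# join()/complement() locations, ORIGIN. Coordinates are converted from
# GenBank 1-based inclusive to the package's 0-based half-open convention at
# this boundary and nowhere else.

AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
            Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
            Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
            Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

# "tRNA-Phe" (optionally with a "(gaa)" anticodon tag) -> "trnF"
trna_short_name <- function(product) {
  m <- regmatches(product, regexec("tRNA[- ]([A-Za-z]{3})", product))[[1]]
  if (length(m) == 2L && m[2] %in% names(AA3TO1))
    paste0("trn", AA3TO1[[m[2]]])
  else
    NULL
}

# Parse a GenBank location string into (strand, intervals 0-based half-open).
# Supports n, n..m, join(...), order(...), outer complement(...), and the
# all-elements-complemented form join(complement(..), complement(..)).
parse_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  inner_comp <- grepl("^complement\\(", parts)
  if (any(inner_comp)) {
    if (!all(inner_comp) || strand == "-")
      stop("unsupported mixed-strand location: ", loc)
    strand <- "-"
    parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
    parts <- rev(parts)  # restore ascending genome order
  }
  iv <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    c(nums[1L] - 1L, nums[2L])  # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  dimnames(iv) <- list(NULL, c("start", "end"))
  list(strand = strand, intervals = iv)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Captures CDS, tRNA and rRNA features (a CDS labelled `ORF...` in its
#' gene/product/note qualifier becomes kind `"ORF"`). Feature names come
#' from `/gene`, else `/product` (with `tRNA-Xxx` products normalized to
#' `trnX` one-letter names), else `/note`, else a generated label.
#' Duplicate names — e.g. the two serine and leucine tRNAs — are
#' disambiguated with numeric suffixes in parse order. Locations spanning
#' the origin of a circular record yield a single two-interval feature.
#'
#' @param path GenBank flat file.
#' @return An [annotated_genome].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)

  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("no LOCUS line in ", path)
  toks <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("missing ORIGIN in ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  residues <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  sequence <- circ_seq(id, residues, topology)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    # a new feature starts with a key at column 6; qualifiers at column 22
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1])
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      # location may continue over lines until the first /qualifier
      qual_at <- grep("^ {21}/", chunk)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(chunk)
      loc <- paste(trimws(sub("^ {5}\\S+", "", chunk[seq_len(loc_end)])),
                   collapse = "")
      quals <- parse_qualifiers(chunk[seq_len(length(chunk)) > loc_end])
      parsed <- parse_location(loc)
      if (any(parsed$intervals > length(sequence)))
        stop("feature location beyond sequence end in ", path, ": ", loc)
      name <- quals[["gene"]] %||% quals[["product"]] %||% quals[["note"]] %||%
        paste0(key, "_", length(feats) + 1L)
      kind <- key
      if (key == "tRNA") {
        short <- trna_short_name(name)
        if (!is.null(short)) name <- short
      }
      # unassigned ORFs may be labelled in gene, product or note, with or
      # without a prefix (ORF1, uORF2, "orf; unknown function")
      if (key == "CDS" && grepl("orf", name, ignore.case = TRUE)) kind <- "ORF"
      feats[[length(feats) + 1L]] <-
        mt_feature(name, kind, parsed$strand, parsed$intervals)
    }
  }
  # numeric-suffix disambiguation of duplicate names, in parse order
  nms <- vapply(feats, `[[`, "", "name")
  for (dup in unique(nms[duplicated(nms)])) {
    at <- which(nms == dup)
    for (j in seq_along(at)) feats[[at[j]]]$name <- paste0(dup, j)
  }
  annotated_genome(sequence, feats, source = path)
}

parse_qualifiers <- function(lines) {
  lines <- trimws(lines)
  quals <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "/")) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0L) {
        cur <- substr(ln, 2L, eq - 1L)
        quals[[cur]] <- gsub("\"", "", substr(ln, eq + 1L, nchar(ln)))
      } else {
        cur <- substr(ln, 2L, nchar(ln))
        quals[[cur]] <- TRUE
      }
    } else if (!is.null(cur) && is.character(quals[[cur]])) {
      quals[[cur]] <- paste(quals[[cur]], gsub("\"", "", ln))
    }
  }
  quals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_location <- function(f) {
  segs <- apply(f$intervals, 1L, function(iv)
    paste0(iv[1L] + 1L, "..", iv[2L]))
  loc <- if (length(segs) > 1L)
    paste0("join(", paste(segs, collapse = ","), ")") else segs
  if (f$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits the minimal LOCUS/FEATURES/ORIGIN structure that [read_genbank]
#' round-trips: gene and product qualifiers, join/complement locations,
#' 60-column ORIGIN blocks.
#'
#' @param genome An [annotated_genome].
#' @param path Output file.
#' @export
write_genbank <- function(genome, path) {
  L <- length(genome)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s     UNK",
                   genome$sequence$id, L, genome$sequence$topology),
           sprintf("DEFINITION  %s", genome$source),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  for (f in genome$features) {
    key <- switch(f$kind, ORF = "CDS", noncoding = "misc_feature", f$kind)
    out <- c(out,
             sprintf("     %-15s %s", key, format_location(f)),
             sprintf("                     /gene=\"%s\"", f$name))
  }
  out <- c(out, "ORIGIN")
  res <- tolower(genome$sequence$residues)
  starts <- seq(1L, L, 60L)
  for (s in starts) {
    chunk <- substr(res, s, min(s + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write features as GFF3
#'
#' @param genome An [annotated_genome].
#' @param path Output file.
#' @param features Subset of features to write (default all).
#' @export
write_gff3 <- function(genome, path, features = genome$features) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  id <- genome$sequence$id
  for (f in features) {
    type <- switch(f$kind, CDS = "CDS", ORF = "open_reading_frame",
                   tRNA = "tRNA", rRNA = "rRNA", "region")
    for (i in seq_len(nrow(f$intervals))) {
      iv <- f$intervals[i, ]
      writeLines(sprintf("%s\tmitocomp\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                         id, type, iv[1L] + 1L, iv[2L], f$strand,
                         f$name, f$name), con)
    }
  }
  invisible(path)
}
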