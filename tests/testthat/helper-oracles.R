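# Independent brute-force oracles, deliberately coded in the most naive way
# possible (explicit loops, no shared helpers with the package internals).

# median-of-ratios as published for DESeq2: per-gene log pseudo-reference,
# per-sample median of log ratios over genes with no zero count, exponentiated
bf_size_factors <- function(m) {
  ref_rows <- c()
  for (i in seq_len(nrow(m))) if (all(m[i, ] > 0)) ref_rows <- c(ref_rows, i)
  log_pseudo <- numeric(length(ref_rows))
  for (r in seq_along(ref_rows)) {
    tot <- 0
    for (j in seq_len(ncol(m))) tot <- tot + log(m[ref_rows[r], j])
    log_pseudo[r] <- tot / ncol(m)
  }
  s <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    lr <- numeric(length(ref_rows))
    for (r in seq_along(ref_rows)) lr[r] <- log(m[ref_rows[r], j]) - log_pseudo[r]
    s[j] <- exp(median(lr))
  }
  names(s) <- colnames(m)
  s
}

bf_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# every occurrence of pattern (exact ACGT) on both strands, naive comparison
bf_pattern_hits <- function(seq, pattern) {
  w <- nchar(pattern)
  fwd <- c(); rev <- c()
  rc <- bf_revcomp(pattern)
  for (i in seq_len(nchar(seq) - w + 1)) {
    win <- substr(seq, i, i + w - 1)
    if (win == pattern) fwd <- c(fwd, i)
    if (win == rc) rev <- c(rev, i)
  }
  list(fwd = fwd, rev = rev)
}

# naive PWM scan: score every window on both strands with the given
# log-odds matrix, return 1-based starts of windows scoring >= thr
bf_pwm_scan <- function(seq, lo, thr) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(lo)
  score_at <- function(s, i) {
    tot <- 0
    for (j in 1:L) {
      b <- match(substr(s, i + j - 1, i + j - 1), bases)
      if (is.na(b)) return(NA_real_)
      tot <- tot + lo[b, j]
    }
    tot
  }
  out <- data.frame(start = integer(), strand = character())
  rc <- bf_revcomp(seq)
  n <- nchar(seq)
  for (i in seq_len(n - L + 1)) {
    sc <- score_at(seq, i)
    if (!is.na(sc) && sc >= thr - 1e-9)
      out <- rbind(out, data.frame(start = i, strand = "+"))
    sc <- score_at(rc, i)
    if (!is.na(sc) && sc >= thr - 1e-9)
      out <- rbind(out, data.frame(start = n - (i + L - 1) + 1, strand = "-"))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive double loop over ordered window pairs inside free intervals
bf_count_placements <- function(free_start, free_end, site_len, min_sep) {
  starts <- c()
  for (k in seq_along(free_start))
    if (free_end[k] - free_start[k] + 1 >= site_len)
      starts <- c(starts, free_start[k]:(free_end[k] - site_len + 1))
  n <- 0
  for (a in starts) for (b in starts)
    if (b - (a + site_len - 1) - 1 >= min_sep) n <- n + 1
  n
}

# covered length of a union of 1-based inclusive intervals via bitmap
bf_union_length <- function(starts, ends, n) {
  bits <- logical(n)
  for (k in seq_along(starts)) bits[starts[k]:ends[k]] <- TRUE
  sum(bits)
}

# spreadsheet-style recomputation of the transient normalization
bf_normalize_transient <- function(plate) {
  out <- numeric(nrow(plate))
  for (i in seq_len(nrow(plate))) {
    neg <- c()
    for (j in seq_len(nrow(plate)))
      if (plate$leaf[j] == plate$leaf[i] && plate$role[j] == "negative_control")
        neg <- c(neg, plate$YFP[j])
    out[i] <- (plate$YFP[i] - median(neg)) / plate$mTURQ[i]
  }
  out
}

# small toy annotation built by hand: writes FASTA + GFF3, returns paths
write_toy_annotation <- function(dir = tempfile("toy"), with_utrs = TRUE) {
  dir.create(dir, showWarnings = FALSE)
  # deterministic 1 kb sequence
  set.seed(404)
  seqchr <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", seqchr), fa)
  gff <- file.path(dir, "toy.gff3")
  if (with_utrs) {
    lines <- c("##gff-version 3",
      "chrT\ttoy\tgene\t301\t700\t.\t+\t.\tID=TOY1",
      "chrT\ttoy\tmRNA\t301\t700\t.\t+\t.\tID=TOY1.1;Parent=TOY1",
      "chrT\ttoy\tfive_prime_UTR\t301\t350\t.\t+\t.\tParent=TOY1.1",
      "chrT\ttoy\tCDS\t351\t650\t.\t+\t0\tParent=TOY1.1",
      "chrT\ttoy\tthree_prime_UTR\t651\t700\t.\t+\t.\tParent=TOY1.1")
  } else {
    lines <- c("##gff-version 3",
      "chrT\ttoy\tgene\t301\t700\t.\t+\t.\tID=TOY1",
      "chrT\ttoy\tmRNA\t301\t700\t.\t+\t.\tID=TOY1.1;Parent=TOY1",
      "chrT\ttoy\tCDS\t351\t650\t.\t+\t0\tParent=TOY1.1")
  }
  writeLines(lines, gff)
  list(fasta = fa, gff3 = gff, seq = seqchr)
}
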