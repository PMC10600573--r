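DNA <- c("A", "C", "G", "T")

#' Read a MEME minimal-format motif file
#'
#' Parses motifs into position weight matrices of base probabilities.
#' Background letter frequencies are read when present and default to
#' uniform otherwise.
#'
#' @param path MEME minimal-format file.
#' @return List of PWMs; each is a list with `motif_id`, `mat` (4 x L
#'   probability matrix, rows A/C/G/T) and `background` (length-4 vector).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    vals <- as.numeric(toks[seq(2L, length(toks), by = 2L)])
    names(vals) <- toks[seq(1L, length(toks), by = 2L)]
    bg <- vals[DNA]
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("no MOTIF records in ", path)
  lapply(motif_at, function(i) {
    motif_id <- strsplit(trimws(lines[i]), "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", lines[i:length(lines)])[1L] + i - 1L
    if (is.na(hdr)) stop("motif ", motif_id, " lacks a letter-probability matrix")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(rows, function(r) {
      v <- as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
      if (length(v) != 4L || anyNA(v)) stop("malformed matrix row in motif ", motif_id)
      v
    }, numeric(4), USE.NAMES = FALSE))
    if (any(abs(rowSums(mat) - 1) > 1e-6))
      stop("matrix column of motif ", motif_id, " does not sum to 1")
    mat <- t(mat)                      # -> 4 x L
    rownames(mat) <- DNA
    list(motif_id = motif_id, mat = mat, background = unname(bg))
  })
}

#' Write PWMs to a MEME minimal-format file
#'
#' @param pwms List of PWMs as returned by [read_meme()].
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1L]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           paste(sprintf("%s %.6f", DNA, bg), collapse = " "), "")
  for (p in pwms) {
    L <- ncol(p$mat)
    out <- c(out,
             paste("MOTIF", p$motif_id),
             sprintf("letter-probability matrix: alphabet= ACGT w= %d nsites= 20 E= 0", L),
             apply(p$mat, 2L, function(col) paste(sprintf("%.9f", col), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Log-odds scoring matrix for a PWM
#'
#' Entry for base b at position j is
#' `log2( ((p_bj + pc * bg_b) / (1 + pc)) / bg_b )` where `pc` is the
#' pseudocount weight; a uniform PWM under a uniform background scores 0
#' everywhere.
#'
#' @param pwm A PWM (list with `mat`, `background`).
#' @param pseudocount Pseudocount weight, > 0. Default `1e-3`.
#' @return 4 x L numeric matrix of log2 odds, rows A/C/G/T.
#' @export
pwm_logodds <- function(pwm, pseudocount = 1e-3) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  bg <- pwm$background
  p <- (pwm$mat + pseudocount * bg) / (1 + pseudocount)
  log2(p / bg)
}

# discretized background distribution of window scores; returns list with
# integer granularity and tail probabilities P(S >= s)
pwm_score_distribution <- function(lo, background, granularity = 1e-3) {
  q <- round(lo / granularity)              # integer scores per (base, col)
  lo_min <- sum(apply(q, 2L, min)); lo_max <- sum(apply(q, 2L, max))
  pmf <- numeric(lo_max - lo_min + 1L)      # indexed by score - lo_min + 1
  # running support [cur_min, cur_max]
  cur <- 1; cur_min <- 0L
  pmf_cur <- 1
  vec <- 1                                   # pmf over offset cur_min..cur_max
  for (j in seq_len(ncol(q))) {
    s <- q[, j]
    new_min <- cur_min + min(s); new_max <- cur_min + length(vec) - 1L + max(s)
    nv <- numeric(new_max - new_min + 1L)
    for (b in 1:4) {
      off <- cur_min + s[b] - new_min
      idx <- seq_along(vec) + off
      nv[idx] <- nv[idx] + vec * background[b]
    }
    vec <- nv; cur_min <- new_min
  }
  tail <- rev(cumsum(rev(vec)))
  list(granularity = granularity, min_score = cur_min, pmf = vec, tail = tail)
}

#' Exact p-value of a PWM window score under the background model
#'
#' The null distribution of the log-odds score of a random background window
#' is computed by exact dynamic programming over the discretized score
#' distribution (granularity `1e-3` log2 units).
#'
#' @param pwm A PWM.
#' @param score Numeric vector of log2-odds window scores.
#' @param pseudocount Passed to [pwm_logodds()].
#' @return `P(S >= score)` for a background window, per input score.
#' @export
pwm_score_pvalue <- function(pwm, score, pseudocount = 1e-3) {
  lo <- pwm_logodds(pwm, pseudocount)
  d <- pwm_score_distribution(lo, pwm$background)
  idx <- floor(score / d$granularity + 0.5) - d$min_score + 1L
  idx <- pmax(1L, pmin(idx, length(d$tail) + 1L))
  c(d$tail, 0)[idx]
}

#' Score threshold achieving a given p-value
#'
#' Smallest score whose background tail probability is at most `pvalue`,
#' from the exact score distribution (`method = "exact"`) or from an
#' empirical null of scores on i.i.d. background sequence
#' (`method = "empirical"`, seeded).
#'
#' @param pwm A PWM.
#' @param pvalue Target p-value.
#' @param pseudocount Passed to [pwm_logodds()].
#' @param method `"exact"` or `"empirical"`.
#' @param n_null Number of null windows for the empirical method.
#' @param seed Seed for the empirical null.
#' @return Numeric score threshold.
#' @export
pwm_score_threshold <- function(pwm, pvalue = 1e-4, pseudocount = 1e-3,
                                method = c("exact", "empirical"),
                                n_null = 1e5, seed = 1L) {
  method <- match.arg(method)
  lo <- pwm_logodds(pwm, pseudocount)
  if (method == "exact") {
    d <- pwm_score_distribution(lo, pwm$background)
    ok <- which(d$tail <= pvalue)
    if (!length(ok)) return(Inf)      # even the max score is too likely
    (d$min_score + ok[1L] - 1L) * d$granularity
  } else {
    L <- ncol(lo)
    set.seed(seed)
    draws <- matrix(sample.int(4L, n_null * L, replace = TRUE,
                               prob = pwm$background), ncol = L)
    scores <- rowSums(matrix(lo[cbind(as.vector(draws),
                                      rep(seq_len(L), each = n_null))],
                             ncol = L))
    stats::quantile(scores, probs = 1 - pvalue, names = FALSE, type = 1)
  }
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], DNA)   # N and others -> NA
}

scan_one_strand <- function(code, lo) {
  L <- ncol(lo); n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    v <- lo[code[j:(j + n - 1L)], j]
    s <- s + ifelse(is.na(code[j:(j + n - 1L)]), NA_real_, v)
  }
  s
}

#' Scan a promoter sequence with PWMs
#'
#' Scores every window on both strands with the log-odds matrix of each
#' PWM and reports windows at or above the threshold. The threshold may be
#' given directly as a score, or derived from a p-value under the exact
#' background score distribution (default p <= 1e-4). Scores are computed on
#' a 1e-3 log2-unit grid (the same grid as the p-value computation).
#' Windows containing `N` never match.
#'
#' @param seq Promoter sequence (character scalar).
#' @param pwms List of PWMs.
#' @param pvalue Score p-value threshold (ignored when `threshold` given).
#' @param threshold Optional explicit log2-odds score threshold (scalar or
#'   named per motif).
#' @param pseudocount Passed to [pwm_logodds()].
#' @return `data.frame` of hits: `motif_id`, `start`, `end` (1-based
#'   inclusive, promoter-local), `strand`, `score`, `pvalue`.
#' @export
scan_promoter <- function(seq, pwms, pvalue = 1e-4, threshold = NULL,
                          pseudocount = 1e-3) {
  code <- encode_dna(seq)
  n <- length(code)
  comp <- rev(5L - code)               # reverse complement in code space
  hits <- list()
  for (p in pwms) {
    lo <- pwm_logodds(p, pseudocount)
    d <- pwm_score_distribution(lo, p$background)
    lo_q <- round(lo / d$granularity) * d$granularity   # scanning grid
    thr <- if (!is.null(threshold)) {
      if (!is.null(names(threshold))) threshold[[p$motif_id]] else threshold
    } else {
      ok <- which(d$tail <= pvalue)
      if (!length(ok)) Inf else (d$min_score + ok[1L] - 1L) * d$granularity
    }
    L <- ncol(lo)
    for (str in c("+", "-")) {
      cd <- if (str == "+") code else comp
      sc <- scan_one_strand(cd, lo_q)
      at <- which(!is.na(sc) & sc >= thr - 1e-9)
      if (!length(at)) next
      start <- if (str == "+") at else n - (at + L - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = p$motif_id, start = start, end = start + L - 1L,
        strand = str, score = sc[at],
        pvalue = pwm_score_pvalue(p, sc[at], pseudocount),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start, out$motif_id, out$strand), , drop = FALSE]
}

#' Merge motif hits into a non-overlapping interval set
#'
#' @param hits Hit `data.frame` from [scan_promoter()] (needs `start`,
#'   `end`).
#' @return [IRanges::IRanges] of merged, sorted, non-overlapping intervals
#'   covering every hit base.
#' @export
hits_to_intervalset <- function(hits) {
  if (nrow(hits) == 0L) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(hits$start, hits$end))
}
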