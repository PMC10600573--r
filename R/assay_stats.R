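#' Read a long-format plate table
#'
#' Expects columns `leaf`, `injection`, `role`, `state`, `disc`, `read`,
#' `YFP`, `mTURQ` (extra columns pass through). Roles are `test`,
#' `negative_control` or `unrepressed_control`; `state` holds the NOR input
#' state (`"0,0"`, `"0,1"`, `"1,0"`, `"1,1"`) where applicable.
#'
#' @param path CSV file.
#' @return `data.frame`.
#' @export
read_plate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("leaf", "injection", "YFP", "mTURQ")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) stop("plate table lacks columns: ",
                            paste(missing, collapse = ", "))
  df
}

#' Ratio-metric normalization for transient-expression assays
#'
#' For every datapoint, the leaf's negative-control median YFP (an
#' injection carrying only the internal-control fluorophore, capturing
#' autofluorescence plus bleed-through) is subtracted from the YFP reading,
#' and the result is divided by the datapoint's own mTURQ reading:
#' `signal = (YFP - median(neg YFP on same leaf)) / mTURQ`.
#'
#' @param plate Plate `data.frame` with a `role` column containing a
#'   `negative_control` injection on every leaf.
#' @return Input with a `signal` column appended; datapoints with
#'   `mTURQ <= 0` are dropped with a warning.
#' @export
normalize_transient <- function(plate) {
  leaves <- unique(plate$leaf)
  neg_med <- vapply(leaves, function(lf) {
    y <- plate$YFP[plate$leaf == lf & plate$role == "negative_control"]
    if (!length(y)) stop("leaf ", lf, " has no negative_control injection")
    stats::median(y)
  }, numeric(1))
  names(neg_med) <- as.character(leaves)
  bad <- plate$mTURQ <= 0
  if (any(bad)) {
    warning(sum(bad), " datapoint(s) with non-positive mTURQ dropped")
    plate <- plate[!bad, , drop = FALSE]
  }
  plate$signal <- (plate$YFP - neg_med[as.character(plate$leaf)]) / plate$mTURQ
  plate
}

#' Select the replicates closest to the group median
#'
#' Computes each biological replicate's median signal, then retains the `k`
#' replicates whose medians are closest to the median of replicate medians
#' (ties broken by replicate id).
#'
#' @param signal Numeric vector of datapoint signals.
#' @param replicate Parallel vector of replicate (leaf) ids.
#' @param k Number of replicates to retain (default 3).
#' @return Character vector of retained replicate ids; all replicates (with
#'   a warning) when fewer than `k` exist.
#' @export
select_replicates <- function(signal, replicate, k = 3L) {
  med <- tapply(signal, as.character(replicate), stats::median)
  if (length(med) < k) {
    warning("only ", length(med), " replicates; keeping all")
    return(names(med))
  }
  centre <- stats::median(med)
  ord <- order(abs(med - centre), names(med))
  sort(names(med)[ord[seq_len(k)]])
}

# restore user RNG state after internally seeded computations
with_preserved_seed <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  force(expr)
}

#' Dunnett many-to-one comparisons against a control
#'
#' Compares every treatment group mean against the control group with
#' family-wise error control at `alpha`, using the classical Dunnett
#' procedure: pooled-variance t statistics referred to the equicorrelated
#' multivariate-t distribution (correlation
#' `sqrt(n_i n_j / ((n_i+n0)(n_j+n0)))`), with two-sided adjusted p-values
#' computed by [mvtnorm::pmvt()]. With a single treatment group this
#' reduces exactly to the two-sample pooled t test.
#'
#' @param x Numeric response (typically per-replicate median signals).
#' @param group Parallel grouping vector.
#' @param control Label of the control group.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `data.frame` with one row per treatment group: `group`,
#'   `estimate` (difference of means), `t`, `p_adjusted`, `significant`.
#'   Groups with fewer than 2 observations are excluded with a warning.
#' @export
dunnett_vs_control <- function(x, group, control, alpha = 0.05) {
  group <- as.character(group)
  if (!control %in% group) stop("control group '", control, "' not present")
  n_by <- table(group)
  small <- names(n_by)[n_by < 2L]
  if (length(small)) {
    warning("groups with <2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    x <- x[keep]; group <- group[keep]
    if (!control %in% group) stop("control group excluded")
  }
  labs <- setdiff(sort(unique(group)), control)
  if (!length(labs)) stop("need at least one treatment group")
  n0 <- sum(group == control)
  m0 <- mean(x[group == control])
  ni <- vapply(labs, function(g) sum(group == g), numeric(1))
  mi <- vapply(labs, function(g) mean(x[group == g]), numeric(1))
  df <- length(x) - length(labs) - 1L
  s2 <- sum(vapply(c(control, labs), function(g) {
    xs <- x[group == g]; sum((xs - mean(xs))^2)
  }, numeric(1))) / df
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tstat <- (mi - m0) / se
  k <- length(labs)
  padj <- if (k == 1L) {
    2 * stats::pt(-abs(tstat), df)
  } else {
    lam <- sqrt(ni / (ni + n0))
    R <- outer(lam, lam); diag(R) <- 1
    vapply(abs(tstat), function(tt) {
      with_preserved_seed({
        set.seed(20231019L)
        1 - mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k),
                          df = df, corr = R, sigma = NULL,
                          algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1L]
      })
    }, numeric(1))
  }
  data.frame(group = labs, estimate = mi - m0, t = tstat,
             p_adjusted = pmax(0, pmin(1, padj)),
             significant = pmax(0, pmin(1, padj)) < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-leaf NOR-gate normalization
#'
#' The raw signal is `YFP / mTURQ`; every datapoint is then divided by the
#' median signal of the unrepressed `(0,0)` injection on the *same leaf*, so
#' each leaf's unrepressed control is centred on exactly 1 and leaf-level
#' multiplicative effects cancel.
#'
#' @param plate Plate `data.frame` with `state` column; every leaf must
#'   carry an unrepressed injection.
#' @param unrepressed State label of the unrepressed control (default
#'   `"0,0"`).
#' @return Input with `signal` (raw ratio) and `norm_signal` (fold change
#'   from the unrepressed control) columns appended.
#' @export
nor_normalize <- function(plate, unrepressed = "0,0") {
  plate$signal <- plate$YFP / plate$mTURQ
  leaves <- unique(plate$leaf)
  ctrl_med <- vapply(leaves, function(lf) {
    s <- plate$signal[plate$leaf == lf & plate$state == unrepressed]
    if (!length(s)) stop("leaf ", lf, " has no (", unrepressed, ") injection")
    stats::median(s)
  }, numeric(1))
  names(ctrl_med) <- as.character(leaves)
  plate$norm_signal <- plate$signal / ctrl_med[as.character(plate$leaf)]
  plate
}

#' Fold repression between two input states
#'
#' Median normalized signal of the unrepressed state divided by that of the
#' repressed state; values >= 1 indicate repression.
#'
#' @param norm_signal Numeric vector of normalized signals.
#' @param state Parallel state labels.
#' @param unrepressed,repressed State labels (defaults `"0,0"`, `"1,1"`).
#' @return Single numeric fold repression (`NA` with a warning when the
#'   repressed median is not positive).
#' @export
fold_repression <- function(norm_signal, state, unrepressed = "0,0",
                            repressed = "1,1") {
  num <- stats::median(norm_signal[state == unrepressed])
  den <- stats::median(norm_signal[state == repressed])
  if (!length(num) || !length(den) || is.na(num) || is.na(den))
    stop("both states must be present")
  if (den <= 0) {
    warning("non-positive repressed-state median; fold repression undefined")
    return(NA_real_)
  }
  num / den
}

#' One-way ANOVA + Tukey HSD + compact letter display
#'
#' Fits a one-way ANOVA, runs Tukey's honest significant difference test on
#' all pairs at level `alpha`, and summarises the significance pattern as a
#' compact letter display built by the insert-and-absorb algorithm: two
#' groups share a letter if and only if they are not significantly
#' different.
#'
#' @param x Numeric response.
#' @param group Parallel grouping vector (>= 2 groups, >= 2 observations
#'   each).
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with `group`, `n`, `mean`, `letters`, ordered by
#'   decreasing mean; the Tukey p-value matrix is attached as attribute
#'   `"tukey_p"`.
#' @export
anova_tukey_cld <- function(x, group, alpha = 0.05) {
  group <- factor(as.character(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs >= 2 observations")
  labs <- levels(group)
  k <- length(labs)
  means <- tapply(x, group, mean)
  pmat <- matrix(1, k, k, dimnames = list(labs, labs))
  resid_var <- sum(tapply(x, group, function(v) sum((v - mean(v))^2))) /
    (length(x) - k)
  if (resid_var < .Machine$double.eps * max(1, mean(x)^2)) {
    if (diff(range(means)) > sqrt(.Machine$double.eps))
      stop("degenerate within-group variance with differing means")
    # all observations identical: nothing distinguishable
  } else {
    fit <- stats::aov(x ~ group)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
      pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
    }
  }
  letters_by <- cld_insert_absorb(pmat < alpha, means)
  out <- data.frame(group = labs, n = as.integer(table(group)),
                    mean = as.numeric(means),
                    letters = letters_by[labs],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$mean, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tukey_p") <- pmat
  out
}

# insert-and-absorb compact letter display from a logical significance
# matrix (TRUE = significantly different); letters run a, b, ... down the
# group means; returns named letter strings
cld_insert_absorb <- function(sig, means = NULL) {
  labs <- rownames(sig)
  if (is.null(means)) means <- stats::setNames(rep(0, length(labs)), labs)
  cols <- list(labs)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- labs[pairs[r, 1L]]; b <- labs[pairs[r, 2L]]
    nxt <- list()
    for (col in cols) {
      if (a %in% col && b %in% col)
        nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
      else nxt <- c(nxt, list(col))
    }
    # absorb columns contained in another column
    keep <- vapply(seq_along(nxt), function(i) {
      !any(vapply(seq_along(nxt), function(j)
        j != i && all(nxt[[i]] %in% nxt[[j]]) &&
          !(all(nxt[[j]] %in% nxt[[i]]) && j > i),
        logical(1)))
    }, logical(1))
    cols <- nxt[keep]
  }
  # letter columns ordered by their highest-mean member (ties by label)
  top_mean <- vapply(cols, function(col) max(means[col]), numeric(1))
  first_at <- vapply(cols, function(col) min(match(col, labs)), numeric(1))
  cols <- cols[order(-top_mean, first_at)]
  vapply(labs, function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
}
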