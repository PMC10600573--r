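#' Motif-free intervals within the TSS-proximal window
#'
#' Intersects the complement of the predicted-motif intervals with the
#' window of `tss_window` bp immediately upstream of the TSS (promoter-local
#' coordinates, 1-based; the TSS base itself is excluded).
#'
#' @param forbidden [IRanges::IRanges] of predicted motif intervals,
#'   promoter-local (e.g. from [hits_to_intervalset()]).
#' @param tss_offset 1-based position of the TSS within the promoter part
#'   (for a part with upstream extent `u`, this is `u + 1`).
#' @param tss_window Window size upstream of the TSS (default 500).
#' @return `IRanges` of motif-free intervals available for site placement.
#' @export
free_intervals <- function(forbidden, tss_offset, tss_window = 500L) {
  lo <- max(1L, tss_offset - tss_window)
  hi <- tss_offset - 1L
  if (hi < lo) return(IRanges::IRanges())
  window <- IRanges::IRanges(lo, hi)
  IRanges::setdiff(window, IRanges::reduce(forbidden))
}

#' Enumerate placements of two gRNA target-site windows
#'
#' A placement is an ordered pair of `site_length`-bp windows, each wholly
#' contained in a single motif-free interval, with at least `min_separation`
#' bases between the end of the first window and the start of the second
#' (edge-to-edge gap). The minimal feasible span is therefore
#' `2 * site_length + min_separation` (113 bp at the defaults).
#'
#' @param free `IRanges` of motif-free intervals from [free_intervals()].
#' @param site_length Window length in bp (default 23 = 20 bp protospacer +
#'   3 bp PAM).
#' @param min_separation Minimum gap between the windows in bp (default 67).
#' @param mode `"best"` returns the single placement maximizing the smaller
#'   of the two windows' distances to the nearest forbidden/window edge,
#'   ties broken 5'-most; `"first"` the 5'-most placement; `"all"` every
#'   placement; `"count"` just the number of placements.
#' @return For `"count"` an integer; otherwise a `data.frame` with
#'   `start1`, `end1`, `start2`, `end2`, `separation` (0 rows when
#'   infeasible).
#' @export
enumerate_placements <- function(free, site_length = 23L, min_separation = 67L,
                                 mode = c("best", "first", "all", "count")) {
  mode <- match.arg(mode)
  starts <- unlist(lapply(seq_along(free), function(i) {
    s <- IRanges::start(free)[i]; e <- IRanges::end(free)[i]
    if (e - s + 1L < site_length) integer(0) else s:(e - site_length + 1L)
  }))
  starts <- sort(starts)
  empty <- data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      separation = integer())
  min_s2 <- starts + site_length + min_separation
  if (mode == "count") {
    if (!length(starts)) return(0L)
    # pairs (s1, s2) with s2 >= s1 + site_length + min_separation
    n_ge <- length(starts) - findInterval(min_s2 - 0.5, starts)
    return(as.integer(sum(n_ge)))
  }
  if (!length(starts)) return(empty)
  pairs <- do.call(rbind, lapply(seq_along(starts), function(i) {
    s2 <- starts[starts >= min_s2[i]]
    if (!length(s2)) return(NULL)
    cbind(start1 = starts[i], start2 = s2)
  }))
  if (is.null(pairs)) return(empty)
  plans <- data.frame(start1 = pairs[, "start1"],
                      end1 = pairs[, "start1"] + site_length - 1L,
                      start2 = pairs[, "start2"],
                      end2 = pairs[, "start2"] + site_length - 1L)
  plans$separation <- plans$start2 - plans$end1 - 1L
  plans <- plans[order(plans$start1, plans$start2), , drop = FALSE]
  rownames(plans) <- NULL
  if (mode == "all") return(plans)
  if (mode == "first") return(plans[1L, , drop = FALSE])
  # "best": slack = min over both windows of distance to nearest free-interval
  # edge (free-interval edges abut forbidden intervals or the TSS window)
  edge_slack <- function(ws, we) {
    i <- which(IRanges::start(free) <= ws & IRanges::end(free) >= we)
    min(ws - IRanges::start(free)[i], IRanges::end(free)[i] - we)
  }
  slack <- mapply(function(s1, e1, s2, e2)
    min(edge_slack(s1, e1), edge_slack(s2, e2)),
    plans$start1, plans$end1, plans$start2, plans$end2)
  best <- order(-slack, plans$start1, plans$start2)[1L]
  plans[best, , drop = FALSE]
}

#' Check a gRNA target site for genome orthogonality
#'
#' Exact-substring search of the 23-mer over both strands of every
#' chromosome. A site is genome-orthogonal when no exact match exists.
#'
#' @param site Character 23-mer (20 bp protospacer + NGG PAM) or any
#'   unambiguous DNA string.
#' @param genome `DNAStringSet`.
#' @return List with `site`, `found_in_genome` (logical) and `matches`
#'   (`data.frame` of `chrom`, `start`, `end`, `strand`).
#' @export
check_orthogonality <- function(site, genome) {
  if (!grepl("^[ACGT]+$", site))
    stop("ambiguous or non-DNA bases in site: ", site)
  pat <- Biostrings::DNAString(site)
  rc <- Biostrings::reverseComplement(pat)
  rows <- list()
  for (ch in names(genome)) {
    for (sp in list(list("+", pat), list("-", rc))) {
      m <- Biostrings::matchPattern(sp[[2L]], genome[[ch]])
      if (length(m))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = BiocGenerics::start(m),
          end = BiocGenerics::end(m), strand = sp[[1L]],
          stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  list(site = site, found_in_genome = nrow(matches) > 0L, matches = matches)
}

#' Propose genome-orthogonal gRNA target-site sequences
#'
#' Walks a candidate library in order and accepts the first `n_needed`
#' sites that pass [check_orthogonality()]. Without a user library,
#' candidates are seeded random 20-mers with an NGG PAM appended
#' (deterministic given `seed`).
#'
#' @param genome `DNAStringSet` to screen against.
#' @param n_needed Number of sites required.
#' @param library Optional character vector of candidate 23-mers.
#' @param seed Seed for the generated library.
#' @param n_candidates Size of the generated library.
#' @return Character vector of `n_needed` accepted 23-mers, with rejected
#'   candidates as attribute `"rejected"`.
#' @export
propose_site_sequences <- function(genome, n_needed, library = NULL,
                                   seed = 1L, n_candidates = 20L * n_needed) {
  if (is.null(library)) {
    set.seed(seed)
    library <- vapply(seq_len(n_candidates), function(i)
      paste0(paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                   collapse = ""),
             sample(c("A", "C", "G", "T"), 1L), "GG"),
      character(1))
  }
  if (!length(library)) stop("empty candidate library")
  accepted <- character(0)
  rejected <- character(0)
  for (s in library) {
    if (length(accepted) == n_needed) break
    if (check_orthogonality(s, genome)$found_in_genome)
      rejected <- c(rejected, s)
    else accepted <- c(accepted, s)
  }
  if (length(accepted) < n_needed)
    stop("candidate library exhausted after rejecting: ",
         paste(rejected, collapse = ", "))
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Overwrite placement windows with assigned target-site sequences
#'
#' Produces the modified (NOR-gate) promoter: bases inside the two windows
#' are replaced by `sites[1]` and `sites[2]`; every other base and the
#' total length are unchanged.
#'
#' @param promoter Original promoter sequence (character scalar).
#' @param plan One-row placement `data.frame` (`start1`, `end1`, `start2`,
#'   `end2`).
#' @param sites Character vector of two site sequences with lengths
#'   matching the windows.
#' @return Modified promoter sequence.
#' @export
build_modified_promoter <- function(promoter, plan, sites) {
  stopifnot(nrow(plan) == 1L, length(sites) == 2L)
  n <- nchar(promoter)
  if (plan$end2 > n || plan$start1 < 1L) stop("placement window out of range")
  if (nchar(sites[1L]) != plan$end1 - plan$start1 + 1L ||
      nchar(sites[2L]) != plan$end2 - plan$start2 + 1L)
    stop("site length does not match window length")
  out <- promoter
  substr(out, plan$start1, plan$end1) <- sites[1L]
  substr(out, plan$start2, plan$end2) <- sites[2L]
  out
}

#' Design a NOR-gate promoter in one call
#'
#' Chains [free_intervals()], [enumerate_placements()] (best mode),
#' [propose_site_sequences()] and [build_modified_promoter()].
#'
#' @param promoter Promoter part sequence.
#' @param tss_offset 1-based TSS position within the part.
#' @param hits Motif hits `data.frame` for this promoter.
#' @param genome `DNAStringSet` for orthogonality screening.
#' @param site_library Optional candidate 23-mers.
#' @param seed Seed for site generation.
#' @inheritParams enumerate_placements
#' @param tss_window Window size upstream of TSS.
#' @return List with `plan`, `sites`, `modified` — or `NULL` when no
#'   feasible placement exists.
#' @export
design_nor_promoter <- function(promoter, tss_offset, hits, genome,
                                site_library = NULL, seed = 1L,
                                site_length = 23L, min_separation = 67L,
                                tss_window = 500L) {
  free <- free_intervals(hits_to_intervalset(hits), tss_offset, tss_window)
  plan <- enumerate_placements(free, site_length, min_separation, mode = "best")
  if (nrow(plan) == 0L) return(NULL)
  sites <- propose_site_sequences(genome, 2L, library = site_library, seed = seed)
  list(plan = plan, sites = as.character(sites),
       modified = build_modified_promoter(promoter, plan, sites))
}
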