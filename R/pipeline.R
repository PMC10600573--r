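#' Screen configuration with the pipeline's default constants
#'
#' All tunable constants of the screen live here: the lowest-CV retention
#' fraction (0.03), the promoter cap upstream of the TSS (2000 bp), the
#' terminator cap past the TES (250 bp), the TSS-proximal placement window
#' (500 bp), the gRNA site length (23 = 20 + 3 bp PAM), the minimum site
#' separation (67 bp), the MoClo enzymes and the motif score p-value
#' threshold.
#'
#' @param cv_fraction,promoter_cap,terminator_cap,tss_window,site_length,min_separation,motif_pvalue,seed
#'   Override any default.
#' @param enzymes Enzyme `data.frame` (default [moclo_enzymes()]).
#' @return Named list of validated parameters.
#' @export
screen_config <- function(cv_fraction = 0.03, promoter_cap = 2000L,
                          terminator_cap = 250L, tss_window = 500L,
                          site_length = 23L, min_separation = 67L,
                          motif_pvalue = 1e-4, enzymes = moclo_enzymes(),
                          seed = 1L) {
  cfg <- list(cv_fraction = cv_fraction, promoter_cap = promoter_cap,
              terminator_cap = terminator_cap, tss_window = tss_window,
              site_length = site_length, min_separation = min_separation,
              motif_pvalue = motif_pvalue, enzymes = enzymes, seed = seed)
  num <- unlist(cfg[c("promoter_cap", "terminator_cap", "tss_window",
                      "site_length", "min_separation", "motif_pvalue")])
  if (any(num <= 0)) stop("all screen constants must be positive")
  if (!(cv_fraction > 0 && cv_fraction < 1))
    stop("cv_fraction must be in (0, 1)")
  cfg
}

#' Run the full promoter screen
#'
#' Executes the filtering cascade in order: expressed-in-all ->
#' normalization and CV -> lowest-CV retention -> part extraction ->
#' neighbour-overlap filter -> Golden Gate domestication filter -> motif
#' scan -> two-site placement feasibility. Returns the cascade report
#' (survivor counts per stage, monotone non-increasing) and all stage
#' outputs.
#'
#' @param counts Count matrix (genes x samples), e.g. from [read_counts()]
#'   or [sim_counts()]. Gene ids must match the annotation where genes are
#'   carried forward.
#' @param annotation List from [read_annotation()] (or
#'   [sim_genome_annotation()] output passed through
#'   [write_synthetic_genome()] and re-read).
#' @param pwms List of PWMs from [read_meme()] / [sim_motifs()]; may be
#'   empty (`list()`), in which case the motif stage removes nothing.
#' @param config List from [screen_config()].
#' @return Object of class `"screen_result"`: list with `cascade`
#'   (`data.frame` of stages), `stats`, `parts`, `hits`, `placements`
#'   (per-gene placement counts), `survivors` (final gene ids).
#' @export
run_screen <- function(counts, annotation, pwms = list(),
                       config = screen_config()) {
  stage <- function(name, ids_in, ids_out, params = "")
    data.frame(stage = name, n_in = length(ids_in), n_out = length(ids_out),
               parameters = params, stringsAsFactors = FALSE)
  cascade <- list()
  all_ids <- rownames(counts)

  expressed <- filter_expressed_all(counts)
  cascade[[1]] <- stage("expressed_in_all", all_ids, expressed)

  stats <- gene_stats(counts)
  kept <- select_low_cv(stats, config$cv_fraction)
  low_cv <- kept$gene_id
  cascade[[2]] <- stage("lowest_cv", expressed, low_cv,
                        sprintf("fraction=%g, cv_cutoff=%.4g",
                                config$cv_fraction, attr(kept, "cv_cutoff")))

  in_annot <- intersect(low_cv, annotation$genes$gene_id)
  parts <- extract_parts(annotation, config$promoter_cap,
                         config$terminator_cap, gene_ids = in_annot)
  extractable <- setdiff(unique(parts$gene_id),
                         unique(parts$gene_id[parts$zero_length]))
  cascade[[3]] <- stage("part_extraction", in_annot, extractable,
                        sprintf("promoter_cap=%d, terminator_cap=%d",
                                config$promoter_cap, config$terminator_cap))

  # neighbour overlaps are judged against the *full* annotation
  parts_ok <- parts[parts$gene_id %in% extractable, , drop = FALSE]
  no_overlap <- overlap_filter(parts_ok, annotation$genes)
  cascade[[4]] <- stage("overlap_filter", extractable, no_overlap)

  parts_ok <- parts_ok[parts_ok$gene_id %in% no_overlap, , drop = FALSE]
  domesticated <- domestication_filter(parts_ok, config$enzymes)
  cascade[[5]] <- stage("domestication_filter", no_overlap, domesticated,
                        paste(config$enzymes$name, collapse = "+"))

  promoters <- parts_ok[parts_ok$part_kind == "promoter_5utr" &
                          parts_ok$gene_id %in% domesticated, , drop = FALSE]
  hits <- list(); placements <- integer(0)
  feasible <- character(0)
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    h <- if (length(pwms))
      scan_promoter(p$sequence, pwms, pvalue = config$motif_pvalue)
    else scan_promoter(p$sequence, list())
    hits[[p$gene_id]] <- h
    tss_offset <- p$extent + 1L
    free <- free_intervals(hits_to_intervalset(h), tss_offset,
                           config$tss_window)
    n_pl <- enumerate_placements(free, config$site_length,
                                 config$min_separation, mode = "count")
    placements[p$gene_id] <- n_pl
    if (n_pl > 0L) feasible <- c(feasible, p$gene_id)
  }
  cascade[[6]] <- stage("placement_feasibility", domesticated, feasible,
                        sprintf("tss_window=%d, site_length=%d, min_separation=%d",
                                config$tss_window, config$site_length,
                                config$min_separation))

  out <- list(cascade = do.call(rbind, cascade), stats = stats,
              parts = parts, hits = hits, placements = placements,
              survivors = feasible, config = config)
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Promoter screen cascade:\n")
  print(x$cascade, row.names = FALSE)
  cat(length(x$survivors), "candidate gene(s) survive all filters\n")
  invisible(x)
}

#' Left-join optional annotation columns onto the surviving candidates
#'
#' Pass-through annotation (gene descriptions, core-promoter class,
#' circadian flags, stress CV ...) keyed by gene id. Row count and order of
#' the survivors are preserved; duplicate keys in an annotation table are
#' an error.
#'
#' @param survivors Character vector of gene ids, or `screen_result`.
#' @param ... Named `data.frame`s whose first column is the gene id.
#' @return `data.frame` with one row per survivor and the joined columns.
#' @export
annotate_candidates <- function(survivors, ...) {
  if (inherits(survivors, "screen_result")) survivors <- survivors$survivors
  out <- data.frame(gene_id = survivors, stringsAsFactors = FALSE)
  for (tab in list(...)) {
    key <- as.character(tab[[1L]])
    if (anyDuplicated(key))
      stop("duplicate keys in annotation table: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    idx <- match(out$gene_id, key)
    for (cn in colnames(tab)[-1L]) out[[cn]] <- tab[[cn]][idx]
  }
  out
}
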