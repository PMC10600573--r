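#' Parse a genome and annotation into gene models
#'
#' Reads a GFF3 annotation and genome FASTA and builds one gene model per
#' `gene` feature. All coordinates are 1-based inclusive genomic positions.
#' Strand-aware fields follow transcription order: `tss`/`tes` are the
#' transcription start/end sites, `cds_start` is the first base of the start
#' codon and `cds_end` the last base of the stop codon (so for minus-strand
#' genes `cds_start > cds_end` numerically).
#'
#' When a gene has explicit `five_prime_UTR` / `three_prime_UTR` features the
#' TSS/TES are taken from them; otherwise the gene-span ends stand in, with a
#' warning.
#'
#' @param gff3 Path to a GFF3 file with `gene` and `CDS` features (UTR
#'   features used when present).
#' @param genome Path to the matching genome FASTA, or a
#'   [Biostrings::DNAStringSet].
#' @return List with `genes` (a `data.frame` of gene models: `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `tes`, `cds_start`,
#'   `cds_end`), `genome` (a `DNAStringSet`) and `chrom_lengths`.
#' @export
read_annotation <- function(gff3, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", gff3)
  gene_ids <- as.character(genes$ID)
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(genes))), names(genome))
  if (length(bad))
    stop("annotation references chromosomes absent from the genome: ",
         paste(bad, collapse = ", "))

  # map every feature to its owning gene through the Parent chain
  id_of <- as.character(gr$ID)
  parent_of <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  owner <- stats::setNames(rep(NA_character_, length(gr)), seq_along(gr))
  top <- stats::setNames(gene_ids, gene_ids)
  resolve <- function(i) {
    p <- parent_of[i]
    seen <- 0L
    while (!is.na(p) && !(p %in% gene_ids) && seen < 10L) {
      j <- match(p, id_of)
      if (is.na(j)) return(NA_character_)
      p <- parent_of[j]
      seen <- seen + 1L
    }
    p
  }
  feature_gene <- vapply(seq_along(gr), resolve, character(1))

  per_gene <- function(i) {
    gid <- gene_ids[i]
    g <- genes[i]
    strand <- as.character(BiocGenerics::strand(g))
    if (!strand %in% c("+", "-")) stop("gene ", gid, " has no strand")
    mine <- which(feature_gene == gid)
    cds <- gr[mine][as.character(gr$type[mine]) == "CDS"]
    if (length(cds) == 0L) stop("gene ", gid, " has no CDS features")
    utr5 <- gr[mine][as.character(gr$type[mine]) == "five_prime_UTR"]
    utr3 <- gr[mine][as.character(gr$type[mine]) == "three_prime_UTR"]
    gstart <- BiocGenerics::start(g); gend <- BiocGenerics::end(g)
    if (strand == "+") {
      tss <- if (length(utr5)) min(BiocGenerics::start(utr5)) else gstart
      tes <- if (length(utr3)) max(BiocGenerics::end(utr3)) else gend
      cds_start <- min(BiocGenerics::start(cds))
      cds_end <- max(BiocGenerics::end(cds))
    } else {
      tss <- if (length(utr5)) max(BiocGenerics::end(utr5)) else gend
      tes <- if (length(utr3)) min(BiocGenerics::start(utr3)) else gstart
      cds_start <- max(BiocGenerics::end(cds))
      cds_end <- min(BiocGenerics::start(cds))
    }
    data.frame(gene_id = gid,
               chrom = as.character(GenomicRanges::seqnames(g)),
               strand = strand, start = gstart, end = gend,
               tss = tss, tes = tes,
               cds_start = cds_start, cds_end = cds_end,
               has_utr5 = length(utr5) > 0L, has_utr3 = length(utr3) > 0L,
               stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, lapply(seq_along(genes), per_gene))
  no_utr <- models$gene_id[!(models$has_utr5 & models$has_utr3)]
  if (length(no_utr))
    warning("genes without annotated UTRs (gene-span ends used as TSS/TES): ",
            paste(no_utr, collapse = ", "))
  list(genes = models,
       genome = genome,
       chrom_lengths = stats::setNames(BiocGenerics::width(genome), names(genome)))
}

#' Free distance to the nearest annotated neighbour, strand-aware
#'
#' For each gene, counts the bases strictly between the gene's TSS (or TES)
#' and the nearest span boundary of any *other* annotated gene on either
#' strand, looking transcriptionally upstream of the TSS
#' (`upstream_room`) and downstream of the TES (`downstream_room`). A gene
#' whose span overlaps the reference point gives room 0; with no neighbour
#' the chromosome end bounds the room.
#'
#' @param models Gene-model `data.frame` from [read_annotation()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return `data.frame` with `gene_id`, `upstream_room`, `downstream_room`,
#'   and logicals `upstream_is_neighbour`, `downstream_is_neighbour`
#'   (whether a neighbouring gene, rather than the chromosome end, sets the
#'   bound).
#' @export
find_neighbours <- function(models, chrom_lengths) {
  room_before <- function(pos, chrom, self) {
    # free bases in (boundary, pos), scanning toward lower coordinates
    others <- models[models$chrom == chrom & models$gene_id != self, , drop = FALSE]
    lim <- 0L   # chromosome start: base 0 is the virtual boundary
    from_neighbour <- FALSE
    for (k in seq_len(nrow(others))) {
      s <- others$start[k]; e <- others$end[k]
      if (e < pos && e > lim) { lim <- e; from_neighbour <- TRUE }
      if (s < pos && e >= pos) { lim <- pos - 1L; from_neighbour <- TRUE } # overlap
    }
    c(room = pos - lim - 1L, neigh = from_neighbour)
  }
  room_after <- function(pos, chrom, self) {
    others <- models[models$chrom == chrom & models$gene_id != self, , drop = FALSE]
    lim <- chrom_lengths[[chrom]] + 1L
    from_neighbour <- FALSE
    for (k in seq_len(nrow(others))) {
      s <- others$start[k]; e <- others$end[k]
      if (s > pos && s < lim) { lim <- s; from_neighbour <- TRUE }
      if (s <= pos && e > pos) { lim <- pos + 1L; from_neighbour <- TRUE }
    }
    c(room = lim - pos - 1L, neigh = from_neighbour)
  }
  out <- lapply(seq_len(nrow(models)), function(i) {
    g <- models[i, ]
    if (g$strand == "+") {
      up <- room_before(g$tss, g$chrom, g$gene_id)
      dn <- room_after(g$tes, g$chrom, g$gene_id)
    } else {
      up <- room_after(g$tss, g$chrom, g$gene_id)
      dn <- room_before(g$tes, g$chrom, g$gene_id)
    }
    data.frame(gene_id = g$gene_id,
               upstream_room = unname(up["room"]),
               downstream_room = unname(dn["room"]),
               upstream_is_neighbour = unname(up["neigh"]) > 0,
               downstream_is_neighbour = unname(dn["neigh"]) > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

part_sequence <- function(genome, chrom, start, end, strand) {
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract the promoter+5'UTR part of one gene
#'
#' The part runs from `max_upstream` bp upstream of the TSS -- or from the
#' nearest annotated neighbouring gene, whichever is shorter -- down to the
#' base immediately before the start codon, so the extracted sequence is the
#' promoter plus the entire 5'UTR. Minus-strand parts are returned
#' reverse-complemented (5'->3' relative to the gene).
#'
#' @param model One row of the gene-model `data.frame`.
#' @param genome `DNAStringSet` of the genome.
#' @param neighbours Matching row of [find_neighbours()] output.
#' @param max_upstream Upstream cap in bp from the TSS (default 2000).
#' @return One-row `data.frame`: `gene_id`, `part_kind`, `chrom`, `start`,
#'   `end`, `strand`, `sequence`, `upstream_extent`,
#'   `truncated_by_neighbour`, `zero_length`.
#' @export
extract_promoter_part <- function(model, genome, neighbours, max_upstream = 2000L) {
  room <- max(neighbours$upstream_room, 0L)
  extent <- min(max_upstream, room)
  trunc <- neighbours$upstream_is_neighbour && room < max_upstream
  if (model$strand == "+") {
    start <- model$tss - extent
    end <- model$cds_start - 1L
  } else {
    start <- model$cds_start + 1L
    end <- model$tss + extent
  }
  zero <- extent <= 0L || end < start
  seq <- if (zero) "" else
    part_sequence(genome, model$chrom, start, end, model$strand)
  data.frame(gene_id = model$gene_id, part_kind = "promoter_5utr",
             chrom = model$chrom, start = start, end = end,
             strand = model$strand, sequence = seq,
             upstream_extent = extent,
             truncated_by_neighbour = trunc, zero_length = zero,
             stringsAsFactors = FALSE)
}

#' Extract the 3'UTR+terminator part of one gene
#'
#' The part runs from the base immediately after the stop codon to
#' `max_downstream` bp past the TES, or to the nearest annotated
#' neighbouring gene, whichever is shorter.
#'
#' @inheritParams extract_promoter_part
#' @param max_downstream Downstream cap in bp past the TES (default 250).
#' @return One-row `data.frame` as in [extract_promoter_part()], with
#'   `downstream_extent` in place of `upstream_extent`.
#' @export
extract_terminator_part <- function(model, genome, neighbours, max_downstream = 250L) {
  room <- max(neighbours$downstream_room, 0L)
  extent <- min(max_downstream, room)
  trunc <- neighbours$downstream_is_neighbour && room < max_downstream
  if (model$strand == "+") {
    start <- model$cds_end + 1L
    end <- model$tes + extent
  } else {
    start <- model$tes - extent
    end <- model$cds_end - 1L
  }
  zero <- extent <= 0L || end < start
  seq <- if (zero) "" else
    part_sequence(genome, model$chrom, start, end, model$strand)
  data.frame(gene_id = model$gene_id, part_kind = "3utr_terminator",
             chrom = model$chrom, start = start, end = end,
             strand = model$strand, sequence = seq,
             downstream_extent = extent,
             truncated_by_neighbour = trunc, zero_length = zero,
             stringsAsFactors = FALSE)
}

#' Extract promoter and terminator parts for every gene
#'
#' @param annotation List from [read_annotation()].
#' @param max_upstream,max_downstream Caps passed to the per-gene extractors.
#' @param gene_ids Optional subset of genes to emit parts for; neighbour
#'   truncation always considers every annotated gene.
#' @return `data.frame` with two rows per gene (promoter_5utr and
#'   3utr_terminator), columns as in the per-part extractors plus a common
#'   `extent` column.
#' @export
extract_parts <- function(annotation, max_upstream = 2000L,
                          max_downstream = 250L, gene_ids = NULL) {
  nb <- find_neighbours(annotation$genes, annotation$chrom_lengths)
  idx <- if (is.null(gene_ids)) seq_len(nrow(annotation$genes)) else
    which(annotation$genes$gene_id %in% gene_ids)
  rows <- lapply(idx, function(i) {
    m <- annotation$genes[i, ]
    n <- nb[nb$gene_id == m$gene_id, ]
    p <- extract_promoter_part(m, annotation$genome, n, max_upstream)
    t <- extract_terminator_part(m, annotation$genome, n, max_downstream)
    names(p)[names(p) == "upstream_extent"] <- "extent"
    names(t)[names(t) == "downstream_extent"] <- "extent"
    rbind(p, t)
  })
  if (!length(rows))
    return(data.frame(gene_id = character(), part_kind = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      extent = integer(), truncated_by_neighbour = logical(),
                      zero_length = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' MoClo type IIS enzyme definitions
#'
#' Recognition sequences from standard enzyme catalogues: BsaI `GGTCTC`,
#' BbsI `GAAGAC`. Both are non-palindromic, so both strands are scanned.
#'
#' @return `data.frame` with `name`, `site`, `both_strands`.
#' @export
moclo_enzymes <- function() {
  data.frame(name = c("BsaI", "BbsI"),
             site = c("GGTCTC", "GAAGAC"),
             both_strands = TRUE,
             stringsAsFactors = FALSE)
}

#' Scan a sequence for restriction-enzyme recognition sites
#'
#' Finds every occurrence of each enzyme's recognition sequence on the plus
#' strand and (for non-palindromic, both-strand enzymes) of its reverse
#' complement, reported as a minus-strand hit at the matching plus-strand
#' coordinates. IUPAC ambiguity codes in the recognition sequence are
#' honoured; `N` in the scanned sequence never matches.
#'
#' @param seq Character scalar (A/C/G/T/N) or `DNAString`.
#' @param enzymes `data.frame` as from [moclo_enzymes()].
#' @return `data.frame` with `enzyme`, `start`, `end` (1-based inclusive on
#'   `seq`), `strand`.
#' @export
scan_restriction_sites <- function(seq, enzymes = moclo_enzymes()) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  hits <- list()
  for (i in seq_len(nrow(enzymes))) {
    pat <- Biostrings::DNAString(enzymes$site[i])
    strands <- list(c("+", as.character(pat)))
    if (isTRUE(enzymes$both_strands[i]))
      strands <- c(strands,
                   list(c("-", as.character(Biostrings::reverseComplement(pat)))))
    for (sp in strands) {
      m <- Biostrings::matchPattern(sp[2L], seq,
                                    fixed = c(pattern = FALSE, subject = TRUE))
      if (length(m))
        hits[[length(hits) + 1L]] <- data.frame(
          enzyme = enzymes$name[i],
          start = BiocGenerics::start(m), end = BiocGenerics::end(m),
          strand = sp[1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(enzyme = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$start, out$enzyme, out$strand), , drop = FALSE]
}

#' Golden Gate domestication filter
#'
#' A gene survives only if *both* of its parts (promoter+5'UTR and
#' 3'UTR+terminator) contain zero recognition sites for every enzyme in the
#' list, on either strand.
#'
#' @param parts Parts `data.frame` from [extract_parts()].
#' @param enzymes `data.frame` as from [moclo_enzymes()].
#' @return Character vector of surviving gene ids. The per-part hit counts
#'   are attached as attribute `"site_counts"`.
#' @export
domestication_filter <- function(parts, enzymes = moclo_enzymes()) {
  n_hits <- vapply(parts$sequence, function(s) {
    if (!nzchar(s)) return(0L)
    nrow(scan_restriction_sites(s, enzymes))
  }, integer(1), USE.NAMES = FALSE)
  counts <- data.frame(gene_id = parts$gene_id, part_kind = parts$part_kind,
                       n_sites = n_hits, stringsAsFactors = FALSE)
  bad <- unique(parts$gene_id[n_hits > 0L])
  out <- setdiff(unique(parts$gene_id), bad)
  attr(out, "site_counts") <- counts
  out
}

#' Remove genes whose parts overlap neighbouring annotations
#'
#' A gene is removed when either of its part intervals intersects the
#' annotated span of any *other* gene.
#'
#' @param parts Parts `data.frame` from [extract_parts()].
#' @param models Gene-model `data.frame`.
#' @return Character vector of surviving gene ids.
#' @export
overlap_filter <- function(parts, models) {
  ok <- parts[!parts$zero_length, , drop = FALSE]
  pr <- GenomicRanges::GRanges(ok$chrom, IRanges::IRanges(ok$start, ok$end))
  gr <- GenomicRanges::GRanges(models$chrom, IRanges::IRanges(models$start, models$end))
  hits <- GenomicRanges::findOverlaps(pr, gr)
  offending <- ok$gene_id[S4Vectors::queryHits(hits)] !=
    models$gene_id[S4Vectors::subjectHits(hits)]
  bad <- unique(ok$gene_id[S4Vectors::queryHits(hits)[offending]])
  setdiff(unique(parts$gene_id), bad)
}

#' Write parts to multi-FASTA / BED
#'
#' FASTA headers carry `gene_id|part_kind|chrom:start-end|strand`
#' (coordinates 1-based inclusive); the BED export is 0-based half-open.
#'
#' @param parts Parts `data.frame`.
#' @param fasta,bed Output paths (either may be `NULL` to skip).
#' @export
write_parts <- function(parts, fasta = NULL, bed = NULL) {
  keep <- parts[!parts$zero_length, , drop = FALSE]
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(keep$sequence)
    names(seqs) <- sprintf("%s|%s|%s:%d-%d|%s", keep$gene_id, keep$part_kind,
                           keep$chrom, keep$start, keep$end, keep$strand)
    Biostrings::writeXStringSet(seqs, fasta)
  }
  if (!is.null(bed)) {
    bed_df <- data.frame(keep$chrom, keep$start - 1L, keep$end,
                         paste(keep$gene_id, keep$part_kind, sep = "|"),
                         0L, keep$strand)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(parts)
}
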