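test_that("annotation parsing takes TSS from UTRs, gene ends as fallback", {
  toy <- write_toy_annotation()
  ann <- read_annotation(toy$gff3, toy$fasta)
  g <- ann$genes
  expect_identical(g$tss, 301L)        # five_prime_UTR start
  expect_identical(g$cds_start, 351L)
  expect_identical(g$cds_end, 650L)
  expect_identical(g$tes, 700L)

  toy2 <- write_toy_annotation(with_utrs = FALSE)
  expect_warning(ann2 <- read_annotation(toy2$gff3, toy2$fasta),
                 "without annotated UTRs")
  expect_identical(ann2$genes$tss, 301L)   # gene-span 5' end stands in
  expect_identical(ann2$genes$tes, 700L)

  # annotation referencing a missing chromosome errors
  gff_bad <- file.path(withr::local_tempdir(), "bad.gff3")
  writeLines(c("##gff-version 3",
               "chrZ\ttoy\tgene\t1\t10\t.\t+\t.\tID=X",
               "chrZ\ttoy\tCDS\t1\t9\t.\t+\t0\tParent=X"), gff_bad)
  expect_error(read_annotation(gff_bad, toy$fasta), "absent from the genome")
})

test_that("synthetic annotation round-trips through GFF3/FASTA exactly", {
  sim <- sim_genome_annotation(n_genes = 6, seed = 2,
                               intergenic = c(6000, 800, 3000, 100, 5000, 2500, 4000),
                               strand = c("+", "-", "+", "+", "-", "+"))
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "a.gff3")
  write_synthetic_genome(sim, fa, gff)
  ann <- expect_no_warning(read_annotation(gff, fa))
  cols <- c("gene_id", "chrom", "strand", "start", "end",
            "tss", "tes", "cds_start", "cds_end")
  expect_identical(ann$genes[, cols], sim$genes[, cols])
})

test_that("neighbour room is strand-aware and handles overlap/absence", {
  models <- data.frame(
    gene_id = c("up", "g", "dn"),
    chrom = "c1", strand = c("+", "-", "+"),
    start = c(1000L, 5000L, 9301L), end = c(1999L, 6000L, 9800L),
    tss = c(1000L, 6000L, 9301L), tes = c(1999L, 5000L, 9800L),
    cds_start = c(1100L, 5900L, 9400L), cds_end = c(1899L, 5100L, 9700L),
    stringsAsFactors = FALSE)
  nb <- find_neighbours(models, c(c1 = 20000L))
  g <- nb[nb$gene_id == "g", ]
  # minus-strand gene: upstream is genomically rightward; the plus-strand
  # gene starting 300 bp 5' of its TSS (at 9301 = 6000 + 300 + 1) leaves
  # 3300 free bases... here "dn" starts at 9301 -> room = 9301 - 6000 - 1
  expect_equal(g$upstream_room, 3300)
  expect_true(g$upstream_is_neighbour)
  # downstream (genomically leftward): "up" ends at 1999 -> 5000 - 1999 - 1
  expect_equal(g$downstream_room, 3000)

  # no neighbour: bounded by chromosome ends
  solo <- models[2, ]
  nbs <- find_neighbours(solo, c(c1 = 20000L))
  expect_equal(nbs$upstream_room, 20000 - 6000)
  expect_false(nbs$upstream_is_neighbour)
  expect_equal(nbs$downstream_room, 5000 - 1)

  # overlapping genes give zero room
  ov <- models
  ov$start[3] <- 5500L
  nbo <- find_neighbours(ov, c(c1 = 20000L))
  expect_equal(nbo$upstream_room[nbo$gene_id == "g"], 0)
})

test_that("promoter part spans cap-or-neighbour down to the start codon", {
  sim <- sim_genome_annotation(n_genes = 3, seed = 4,
                               intergenic = c(6000, 800, 6000, 6000),
                               strand = "+", utr5_len = 120L)
  dir <- withr::local_tempdir()
  write_synthetic_genome(sim, file.path(dir, "g.fa"), file.path(dir, "a.gff3"))
  ann <- read_annotation(file.path(dir, "a.gff3"), file.path(dir, "g.fa"))
  parts <- extract_parts(ann)
  p1 <- parts[parts$gene_id == "SYN001" & parts$part_kind == "promoter_5utr", ]
  # 6 kb of free room, 120 bp 5'UTR: extent capped at 2,000, total 2,120
  expect_identical(p1$extent, 2000L)
  expect_identical(nchar(p1$sequence), 2120L)
  expect_false(p1$truncated_by_neighbour)
  # neighbour 800 bp upstream binds before the cap
  p2 <- parts[parts$gene_id == "SYN002" & parts$part_kind == "promoter_5utr", ]
  expect_identical(p2$extent, 800L)
  expect_true(p2$truncated_by_neighbour)
  expect_identical(nchar(p2$sequence), 920L)
})

test_that("minus-strand parts are the reverse complement of the slice", {
  sim <- sim_genome_annotation(n_genes = 2, seed = 6, intergenic = 4000,
                               strand = c("-", "+"))
  dir <- withr::local_tempdir()
  write_synthetic_genome(sim, file.path(dir, "g.fa"), file.path(dir, "a.gff3"))
  ann <- read_annotation(file.path(dir, "a.gff3"), file.path(dir, "g.fa"))
  parts <- extract_parts(ann)
  chrseq <- as.character(ann$genome[["chr1"]])
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    slice <- substr(chrseq, p$start, p$end)
    expected <- if (p$strand == "-") bf_revcomp(slice) else slice
    expect_identical(p$sequence, expected)
  }
})

test_that("terminator part spans stop codon to cap-or-neighbour", {
  sim <- sim_genome_annotation(n_genes = 2, seed = 8,
                               intergenic = c(5000, 100, 5000),
                               strand = "+", utr3_len = 200L)
  dir <- withr::local_tempdir()
  write_synthetic_genome(sim, file.path(dir, "g.fa"), file.path(dir, "a.gff3"))
  ann <- read_annotation(file.path(dir, "a.gff3"), file.path(dir, "g.fa"))
  parts <- extract_parts(ann)
  # the 100 bp gap sits between gene 1 and gene 2: gene 1's terminator is
  # truncated by the neighbour, gene 2's reaches the full 250 bp cap
  t1 <- parts[parts$gene_id == "SYN001" & parts$part_kind == "3utr_terminator", ]
  expect_identical(t1$extent, 100L)
  expect_identical(nchar(t1$sequence), 300L)   # 200 bp 3'UTR + 100
  expect_true(t1$truncated_by_neighbour)
  t2 <- parts[parts$gene_id == "SYN002", ]
  t2 <- t2[t2$part_kind == "3utr_terminator", ]
  # 200 bp 3'UTR + 250 bp cap = 450 bp
  expect_identical(t2$extent, 250L)
  expect_identical(nchar(t2$sequence), 450L)
  # caps hold everywhere
  expect_true(all(parts$extent[parts$part_kind == "promoter_5utr"] <= 2000))
  expect_true(all(parts$extent[parts$part_kind == "3utr_terminator"] <= 250))
})

test_that("overlap filter is exact at interval boundaries", {
  models <- data.frame(
    gene_id = c("g1", "g2"), chrom = "c1", strand = "+",
    start = c(1000L, 3000L), end = c(1999L, 3999L),
    tss = c(1000L, 3000L), tes = c(1999L, 3999L),
    cds_start = c(1100L, 3100L), cds_end = c(1899L, 3899L),
    stringsAsFactors = FALSE)
  part <- function(id, s, e)
    data.frame(gene_id = id, part_kind = "promoter_5utr", chrom = "c1",
               start = s, end = e, strand = "+", sequence = "A",
               extent = 1L, truncated_by_neighbour = FALSE,
               zero_length = FALSE, stringsAsFactors = FALSE)
  # g2's part ends 1 bp before g1's span -> kept
  expect_identical(overlap_filter(part("g2", 2000, 2999), models),
                   "g2")
  # overlapping g1 by exactly 1 bp -> removed
  expect_identical(overlap_filter(part("g2", 1999, 2999), models),
                   character(0))
  # brute-force all-pairs intersection on a random instance
  set.seed(31)
  n <- 12
  rmodels <- data.frame(
    gene_id = sprintf("r%02d", 1:n), chrom = "c1", strand = "+",
    start = as.integer(sort(sample(1:5000, n)) * 10), stringsAsFactors = FALSE)
  rmodels$end <- rmodels$start + sample(200:3000, n)
  rmodels[, c("tss", "tes")] <- rmodels[, c("start", "end")]
  rmodels[, c("cds_start", "cds_end")] <- rmodels[, c("start", "end")]
  rparts <- do.call(rbind, lapply(1:n, function(i)
    part(rmodels$gene_id[i],
         rmodels$start[i] - sample(100:2500, 1), rmodels$start[i] - 1L)))
  got <- overlap_filter(rparts, rmodels)
  brute <- c()
  for (i in 1:n) {
    hit <- FALSE
    for (j in 1:n) if (i != j &&
        rparts$start[i] <= rmodels$end[j] && rparts$end[i] >= rmodels$start[j])
      hit <- TRUE
    if (!hit) brute <- c(brute, rparts$gene_id[i])
  }
  expect_identical(sort(got), sort(brute))
})

test_that("restriction scanning finds sites on both strands", {
  enz <- moclo_enzymes()
  h1 <- scan_restriction_sites("AAGGTCTCAA", enz)
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$enzyme, "BsaI")
  expect_identical(h1$start, 3L)       # 1-based
  expect_identical(h1$strand, "+")
  # reverse complement GAGACC = BsaI on the minus strand
  h2 <- scan_restriction_sites("AAGAGACCAA", enz)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$strand, "-")
  expect_identical(h2$start, 3L)
  # brute-force oracle on a random 10 kb sequence (N never matches)
  set.seed(77)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                    prob = c(.24, .24, .24, .24, .04)), collapse = "")
  got <- scan_restriction_sites(s, enz)
  for (e in enz$name) {
    site <- enz$site[enz$name == e]
    bf <- bf_pattern_hits(s, site)
    expect_identical(got$start[got$enzyme == e & got$strand == "+"],
                     as.integer(bf$fwd))
    expect_identical(got$start[got$enzyme == e & got$strand == "-"],
                     as.integer(bf$rev))
  }
})

test_that("domestication filter removes genes with planted sites", {
  plant <- data.frame(gene = c("SYN002", "SYN004"),
                      part = c("terminator", "promoter"),
                      enzyme = c("BbsI", "BsaI"), stringsAsFactors = FALSE)
  sim <- sim_genome_annotation(n_genes = 5, seed = 10, intergenic = 3000,
                               strand = c("+", "-"), plant_sites = plant)
  dir <- withr::local_tempdir()
  write_synthetic_genome(sim, file.path(dir, "g.fa"), file.path(dir, "a.gff3"))
  ann <- read_annotation(file.path(dir, "a.gff3"), file.path(dir, "g.fa"))
  parts <- extract_parts(ann)
  surv <- domestication_filter(parts)
  expect_identical(sort(surv), c("SYN001", "SYN003", "SYN005"))
  counts <- attr(surv, "site_counts")
  expect_identical(sum(counts$n_sites[counts$gene_id == "SYN002"]), 1L)
})

test_that("genome mirror symmetry preserves part sequences", {
  sim <- sim_genome_annotation(n_genes = 4, seed = 12,
                               intergenic = c(2500, 900, 150, 3000, 2500),
                               strand = c("+", "-", "-", "+"))
  L <- Biostrings::width(sim$genome)[1]
  mirror_genome <- Biostrings::reverseComplement(sim$genome)
  names(mirror_genome) <- "chr1"
  flip <- function(x) L - x + 1L
  mg <- sim$genes
  mg$strand <- ifelse(mg$strand == "+", "-", "+")
  for (cc in c("start", "end", "tss", "tes", "cds_start", "cds_end"))
    mg[[cc]] <- flip(sim$genes[[cc]])
  tmp <- mg$start; mg$start <- mg$end; mg$end <- tmp
  ann1 <- list(genes = sim$genes, genome = sim$genome,
               chrom_lengths = c(chr1 = L))
  ann2 <- list(genes = mg, genome = mirror_genome,
               chrom_lengths = c(chr1 = L))
  p1 <- extract_parts(ann1)
  p2 <- extract_parts(ann2)
  key <- function(p) p[order(p$gene_id, p$part_kind), ]
  expect_identical(key(p1)$sequence, key(p2)$sequence)
  expect_identical(key(p1)$extent, key(p2)$extent)
})

test_that("overlap and domestication filters commute", {
  plant <- data.frame(gene = "SYN003", part = "promoter", enzyme = "BsaI",
                      stringsAsFactors = FALSE)
  sim <- sim_genome_annotation(n_genes = 6, seed = 14,
                               intergenic = c(2500, 0, 400, 3000, 50, 2200, 2500),
                               strand = c("+", "-", "+", "+", "-", "+"),
                               plant_sites = plant)
  dir <- withr::local_tempdir()
  write_synthetic_genome(sim, file.path(dir, "g.fa"), file.path(dir, "a.gff3"))
  ann <- read_annotation(file.path(dir, "a.gff3"), file.path(dir, "g.fa"))
  parts <- extract_parts(ann)
  a <- intersect(domestication_filter(parts), overlap_filter(parts, ann$genes))
  pd <- parts[parts$gene_id %in% domestication_filter(parts), ]
  b <- overlap_filter(pd, ann$genes)
  po <- parts[parts$gene_id %in% overlap_filter(parts, ann$genes), ]
  c_ <- domestication_filter(po)
  expect_identical(sort(a), sort(b))
  expect_identical(sort(a), sort(as.character(c_)))
})

test_that("parts export writes valid FASTA and 0-based BED", {
  sim <- sim_genome_annotation(n_genes = 2, seed = 16, intergenic = 3000)
  dir <- withr::local_tempdir()
  write_synthetic_genome(sim, file.path(dir, "g.fa"), file.path(dir, "a.gff3"))
  ann <- read_annotation(file.path(dir, "a.gff3"), file.path(dir, "g.fa"))
  parts <- extract_parts(ann)
  fa <- file.path(dir, "parts.fa"); bed <- file.path(dir, "parts.bed")
  write_parts(parts, fasta = fa, bed = bed)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(length(back), nrow(parts))
  expect_identical(unname(as.character(back)), parts$sequence)
  bed_df <- read.table(bed, sep = "\t")
  expect_identical(bed_df$V2, parts$start - 1L)   # 0-based half-open export
  expect_identical(bed_df$V3, parts$end)
})
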