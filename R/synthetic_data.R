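#' Simulate a negative-binomial count matrix with planted stable genes
#'
#' Counts are drawn as `K_ij ~ NB(mean = mu_i * s_j, dispersion = alpha_i)`.
#' True size factors are drawn log-uniformly and rescaled to geometric mean
#' 1 (the scale on which median-of-ratios factors are identifiable). A
#' planted subset of "stable" genes receives small dispersion; background
#' genes receive much larger gene-wise dispersion, mimicking
#' tissue-dependent expression.
#'
#' @param n_genes Total number of genes (default 1000).
#' @param n_samples Number of samples (default 10).
#' @param n_stable Number of planted stable genes (default 50).
#' @param seed Seed; the generator is a pure function of its arguments.
#' @param size_factor_range Log-uniform range of true size factors
#'   (default `c(0.5, 2)`).
#' @param mean_range Log-uniform range of true gene means (default
#'   `c(50, 2000)`).
#' @param dispersion_range Log-uniform range of background gene
#'   dispersions (default `c(0.1, 2)`, giving typical cross-tissue CVs of
#'   roughly 0.3--1.5 so that, as in real tissue panels, only a small
#'   percentage of background genes approach the stable-gene CV range).
#' @param stable_dispersion Dispersion of planted stable genes (default
#'   0.005, i.e. at most a tenth of the smallest background dispersion).
#' @return Integer count matrix (genes x samples) with attribute `"truth"`:
#'   a list of `size_factors`, `mu`, `dispersion`, `stable_genes`.
#' @export
sim_counts <- function(n_genes = 1000L, n_samples = 10L, n_stable = 50L,
                       seed = 1L, size_factor_range = c(0.5, 2),
                       mean_range = c(50, 2000),
                       dispersion_range = c(0.1, 2),
                       stable_dispersion = 0.005) {
  set.seed(seed)
  s <- exp(stats::runif(n_samples, log(size_factor_range[1L]),
                        log(size_factor_range[2L])))
  s <- s / exp(mean(log(s)))
  mu <- exp(stats::runif(n_genes, log(mean_range[1L]), log(mean_range[2L])))
  alpha <- exp(stats::runif(n_genes, log(dispersion_range[1L]),
                            log(dispersion_range[2L])))
  stable <- sort(sample.int(n_genes, n_stable))
  alpha[stable] <- stable_dispersion
  m <- matrix(0L, n_genes, n_samples,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  for (j in seq_len(n_samples))
    m[, j] <- as.integer(stats::rnbinom(n_genes, mu = mu * s[j],
                                        size = 1 / alpha))
  attr(m, "truth") <- list(size_factors = stats::setNames(s, colnames(m)),
                           mu = mu, dispersion = alpha,
                           stable_genes = rownames(m)[stable])
  m
}

scrub_patterns <- c("GGTCTC", "GAGACC", "GAAGAC", "GTCTTC")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate single bases until no type IIS recognition site remains on either
# strand (patterns cover both orientations of BsaI and BbsI)
scrub_dna <- function(s) {
  repeat {
    hit <- regexpr(paste(scrub_patterns, collapse = "|"), s)
    if (hit < 0L) return(s)
    at <- hit + 2L
    substr(s, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, at, at)), 1L)
  }
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Simulate a toy multi-gene genome with annotation and ground truth
#'
#' Builds one chromosome of alternating intergenic spacers and gene bodies
#' (5'UTR, CDS beginning `ATG` and ending `TAA`, 3'UTR, in transcription
#' order; minus-strand genes are inserted reverse-complemented). Intergenic
#' distances are controllable per gene so neighbour truncation of both the
#' 2 kb promoter cap and 250 bp terminator cap can be exercised. All
#' backbone sequence is kept free of BsaI/BbsI recognition sites; sites and
#' near-consensus motif matches can then be planted at recorded positions.
#'
#' @param n_genes Number of genes.
#' @param seed Seed.
#' @param intergenic Integer vector (recycled) of intergenic gap lengths
#'   *before* each gene; one extra gap closes the chromosome.
#' @param strand Character vector (recycled) of gene strands.
#' @param utr5_len,cds_len,utr3_len Integer vectors (recycled) of feature
#'   lengths; `cds_len` must be a multiple of 3 and >= 6.
#' @param plant_sites Optional `data.frame(gene, part, enzyme)` planting a
#'   recognition site in a gene's `"promoter"` (150 bp upstream of the TSS)
#'   or `"terminator"` (middle of the 3'UTR) part.
#' @param plant_motifs Optional `data.frame(gene, upstream_offset,
#'   consensus)` writing `consensus` so that it *ends* `upstream_offset` bp
#'   upstream of the gene's TSS (plus strand of the gene).
#' @return List: `genome` (`DNAStringSet`), `genes` (truth `data.frame`
#'   with genomic `tss`, `tes`, `cds_start`, `cds_end`, strand-aware),
#'   `planted_sites`, `planted_motifs` (with genomic coordinates appended).
#' @export
sim_genome_annotation <- function(n_genes = 8L, seed = 1L,
                                  intergenic = 3000L, strand = c("+", "-"),
                                  utr5_len = 120L, cds_len = 900L,
                                  utr3_len = 180L,
                                  plant_sites = NULL, plant_motifs = NULL) {
  set.seed(seed)
  intergenic <- rep_len(as.integer(intergenic), n_genes + 1L)
  strand <- rep_len(strand, n_genes)
  utr5_len <- rep_len(as.integer(utr5_len), n_genes)
  cds_len <- rep_len(as.integer(cds_len), n_genes)
  utr3_len <- rep_len(as.integer(utr3_len), n_genes)
  if (any(cds_len %% 3L != 0L | cds_len < 6L))
    stop("cds_len must be a multiple of 3 and >= 6")
  if (any(intergenic < 0L)) stop("infeasible intergenic spacing")

  pieces <- character(0)
  rows <- list()
  pos <- 0L
  for (i in seq_len(n_genes)) {
    pieces <- c(pieces, random_dna(intergenic[i]))
    pos <- pos + intergenic[i]
    body_tx <- paste0(random_dna(utr5_len[i]),
                      "ATG", random_dna(cds_len[i] - 6L), "TAA",
                      random_dna(utr3_len[i]))
    body_len <- nchar(body_tx)
    body <- if (strand[i] == "+") body_tx else revcomp_chr(body_tx)
    pieces <- c(pieces, body)
    start <- pos + 1L; end <- pos + body_len
    pos <- end
    if (strand[i] == "+") {
      tss <- start; tes <- end
      cds_start <- start + utr5_len[i]
      cds_end <- cds_start + cds_len[i] - 1L
    } else {
      tss <- end; tes <- start
      cds_start <- end - utr5_len[i]
      cds_end <- cds_start - cds_len[i] + 1L
    }
    rows[[i]] <- data.frame(gene_id = sprintf("SYN%03d", i), chrom = "chr1",
                            strand = strand[i], start = start, end = end,
                            tss = tss, tes = tes,
                            cds_start = cds_start, cds_end = cds_end,
                            utr5_len = utr5_len[i], utr3_len = utr3_len[i],
                            stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, random_dna(intergenic[n_genes + 1L]))
  seqchr <- scrub_dna(paste(pieces, collapse = ""))
  genes <- do.call(rbind, rows)

  write_at <- function(seqchr, g, genomic_start, fragment_tx) {
    # fragment given 5'->3' on the gene's strand; genomic_start is the
    # lower genomic coordinate of the written window
    frag <- if (g$strand == "+") fragment_tx else revcomp_chr(fragment_tx)
    substr(seqchr, genomic_start, genomic_start + nchar(frag) - 1L) <- frag
    seqchr
  }

  if (!is.null(plant_sites) && nrow(plant_sites)) {
    enz <- moclo_enzymes()
    plant_sites$start <- NA_integer_
    for (r in seq_len(nrow(plant_sites))) {
      g <- genes[genes$gene_id == plant_sites$gene[r], ]
      site <- enz$site[enz$name == plant_sites$enzyme[r]]
      if (plant_sites$part[r] == "promoter") {
        up <- 150L  # site ends 150 bp upstream of the TSS
        gs <- if (g$strand == "+") g$tss - up - nchar(site) + 1L else g$tss + up
      } else {
        mid <- g$utr3_len %/% 2L  # middle of the 3'UTR
        gs <- if (g$strand == "+") g$tes - g$utr3_len + mid else
          g$tes + g$utr3_len - mid - nchar(site) + 1L
      }
      seqchr <- write_at(seqchr, g, gs, site)
      plant_sites$start[r] <- gs
    }
  }
  if (!is.null(plant_motifs) && nrow(plant_motifs)) {
    plant_motifs$start <- NA_integer_
    for (r in seq_len(nrow(plant_motifs))) {
      g <- genes[genes$gene_id == plant_motifs$gene[r], ]
      cons <- plant_motifs$consensus[r]
      off <- plant_motifs$upstream_offset[r]
      gs <- if (g$strand == "+") g$tss - off - nchar(cons) + 1L else
        g$tss + off
      seqchr <- write_at(seqchr, g, gs, cons)
      plant_motifs$start[r] <- gs
    }
  }

  genome <- Biostrings::DNAStringSet(seqchr)
  names(genome) <- "chr1"
  list(genome = genome, genes = genes,
       planted_sites = plant_sites, planted_motifs = plant_motifs)
}

#' Write a simulated genome to FASTA + GFF3
#'
#' Emits gene, mRNA, five_prime_UTR, CDS and three_prime_UTR features
#' (1-based inclusive, as GFF3 requires) so the files round-trip through
#' [read_annotation()].
#'
#' @param sim List from [sim_genome_annotation()].
#' @param fasta,gff3 Output paths.
#' @export
write_synthetic_genome <- function(sim, fasta, gff3) {
  Biostrings::writeXStringSet(sim$genome, fasta)
  g <- sim$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    mrna <- paste0(r$gene_id, ".1")
    if (r$strand == "+") {
      u5 <- c(r$tss, r$cds_start - 1L)
      cds <- c(r$cds_start, r$cds_end)
      u3 <- c(r$cds_end + 1L, r$tes)
    } else {
      u5 <- c(r$cds_start + 1L, r$tss)
      cds <- c(r$cds_end, r$cds_start)
      u3 <- c(r$tes, r$cds_end - 1L)
    }
    feat <- function(type, s, e, attrs, phase = ".")
      sprintf("%s\tpromoterforge\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              r$chrom, type, s, e, r$strand, phase, attrs)
    lines <- c(lines,
      feat("gene", r$start, r$end, paste0("ID=", r$gene_id)),
      feat("mRNA", r$start, r$end, paste0("ID=", mrna, ";Parent=", r$gene_id)),
      feat("five_prime_UTR", u5[1L], u5[2L], paste0("Parent=", mrna)),
      feat("CDS", cds[1L], cds[2L], paste0("Parent=", mrna), phase = "0"),
      feat("three_prime_UTR", u3[1L], u3[2L], paste0("Parent=", mrna)))
  }
  writeLines(lines, gff3)
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' Simulate a motif library with near-deterministic PWMs
#'
#' Each motif's probability matrix puts weight `1 - 3 * eps` on a random
#' consensus base per column, so the consensus scores near the matrix
#' maximum and random background sequence essentially never reaches the
#' default threshold.
#'
#' @param n_motifs Number of motifs.
#' @param width Motif width (bp).
#' @param seed Seed.
#' @param eps Off-consensus per-base probability (default 0.001).
#' @return List of PWMs (as in [read_meme()]); consensus strings attached
#'   as attribute `"consensus"`.
#' @export
sim_motifs <- function(n_motifs = 3L, width = 10L, seed = 1L, eps = 0.001) {
  set.seed(seed)
  pwms <- vector("list", n_motifs)
  consensus <- character(n_motifs)
  for (k in seq_len(n_motifs)) {
    idx <- sample.int(4L, width, replace = TRUE)
    mat <- matrix(eps, 4L, width, dimnames = list(c("A", "C", "G", "T"), NULL))
    mat[cbind(idx, seq_len(width))] <- 1 - 3 * eps
    consensus[k] <- paste(c("A", "C", "G", "T")[idx], collapse = "")
    pwms[[k]] <- list(motif_id = sprintf("MOTIF%02d", k), mat = mat,
                      background = rep(0.25, 4L))
  }
  attr(pwms, "consensus") <- consensus
  pwms
}

#' Simulate a plate-reader fluorescence table
#'
#' Emulates the agroinfiltration reading scheme: per leaf, one injection
#' per construct plus controls, 2 discs x 12 reads = 24 datapoints per
#' injection per leaf. Signals follow
#' `YFP = leaf_gain * effect * lognormal_noise + autofluorescence` and
#' `mTURQ = leaf_gain * control_level * lognormal_noise`, so both the
#' per-leaf control subtraction and the ratio-metric division are
#' exercised.
#'
#' @param effects Named numeric vector of true YFP expression effects, one
#'   per injection. Names become `injection` labels. For NOR-gate tables
#'   use state names `"0,0"`, `"0,1"`, `"1,0"`, `"1,1"` and set
#'   `states = TRUE`; the effect of a state relative to `"0,0"` is its true
#'   repression ratio.
#' @param n_leaves Number of biological replicates (default 3).
#' @param states Logical: treat injections as NOR input states (adds a
#'   `state` column and roles) instead of transient constructs.
#' @param negative_control Logical: add a YFP-free `negative_control`
#'   injection to every leaf (transient design; default `!states`).
#' @param leaf_gain_sd Log-SD of the per-leaf multiplicative gain.
#' @param noise_sd Log-SD of per-datapoint noise.
#' @param autofluorescence Additive YFP background (default 50).
#' @param control_level True mTURQ expression level (default 1000).
#' @param discs,reads Discs per injection and reads per disc (2 x 12).
#' @param seed Seed.
#' @return Plate `data.frame` (`leaf`, `injection`, `role`, `state`,
#'   `disc`, `read`, `YFP`, `mTURQ`) with attribute `"truth"`.
#' @export
sim_plate_table <- function(effects, n_leaves = 3L, states = FALSE,
                            negative_control = !states,
                            leaf_gain_sd = 0.3, noise_sd = 0.15,
                            autofluorescence = 50, control_level = 1000,
                            seed = 1L, discs = 2L, reads = 12L) {
  set.seed(seed)
  gain <- exp(stats::rnorm(n_leaves, 0, leaf_gain_sd))
  inj <- names(effects)
  if (negative_control) {
    effects <- c(effects, negative_control = 0)
    inj <- names(effects)
  }
  rows <- list()
  for (lf in seq_len(n_leaves)) {
    for (j in seq_along(effects)) {
      n <- discs * reads
      noise_y <- exp(stats::rnorm(n, 0, noise_sd))
      noise_t <- exp(stats::rnorm(n, 0, noise_sd))
      yfp <- gain[lf] * effects[j] * control_level * noise_y + autofluorescence
      mturq <- gain[lf] * control_level * noise_t
      role <- if (inj[j] == "negative_control") "negative_control"
        else if (states && inj[j] == "0,0") "unrepressed_control" else "test"
      rows[[length(rows) + 1L]] <- data.frame(
        leaf = sprintf("leaf%02d", lf), injection = inj[j], role = role,
        state = if (states) inj[j] else NA_character_,
        disc = rep(seq_len(discs), each = reads),
        read = rep(seq_len(reads), times = discs),
        YFP = yfp, mTURQ = mturq, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(effects = effects, leaf_gain = gain,
                             autofluorescence = autofluorescence,
                             control_level = control_level)
  out
}
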