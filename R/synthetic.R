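# Synthetic-data generator. Emulates the statistical structure of the
# erythroid study inputs: two replicate expression contrasts (a GATA1
# gain-of-function induction and a GATA2 enhancer-knockout), GATA1/GATA2
# ChIP peak sets, ATAC accessibility, cCRE intervals, and intronic enhancer
# sequences with planted WGATAR/E-box motifs, plus decoy genes with no
# signal. All outputs are pure functions of (config, seed).

# Internal: derive a deterministic per-stage seed below 2^31 from the global
# seed, so stages can be rerun independently with identical results.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Configuration for the synthetic dataset
#'
#' Defaults reproduce the study-conditions scenario: 60 genes of which 40
#' are SLC-labeled; 27 SLC genes co-regulated (all GATA2-activated, mixed
#' GATA1 direction), 6 GATA1-only and 4 GATA2-only regulated SLC genes;
#' among the 27, 21 are GATA2-occupied, 17 of those also GATA1-occupied, 24
#' accessible, and 8 of the 17 carry a planted accessible intronic enhancer
#' with WGATAR and E-box motifs; 3 regulated non-SLC genes exercise the
#' family filter and the rest are decoys. Expression uses 3 replicates per
#' condition with homoscedastic log2 noise.
#'
#' @param n_chromosomes Number of chromosomes (default 3).
#' @param chrom_length Chromosome length in bp (default 1e6).
#' @param n_genes Total genes (default 60).
#' @param fraction_slc Fraction of genes labeled SLC (default 40/60).
#' @param n_shared Co-regulated SLC genes (default 27).
#' @param n_g1_only,n_g2_only Factor-specific regulated SLC genes (6, 4).
#' @param n_nonslc_regulated Regulated genes outside the SLC family (3).
#' @param n_gata2_occupied GATA2-occupied genes among the shared cohort (21).
#' @param n_gata1_occupied Of those, also GATA1-occupied (17).
#' @param n_accessible Accessible genes among the shared cohort (24).
#' @param n_planted_enhancers Planted intronic enhancers, hosted by the
#'   first genes of the GATA1/GATA2-occupied set (default 8).
#' @param planted_lfc_gata1,planted_lfc_gata2 Optional named numeric vectors
#'   (gene id -> log2 fold change of condition b vs a) overriding the
#'   automatic effect tables; genes absent from a table have no effect.
#' @param replicates Replicates per condition (default 3).
#' @param noise_sd Replicate noise SD on the log2 scale (default 0.5).
#' @param peak_width Length-2 integer range of peak/enhancer widths in bp
#'   (default c(150, 400)).
#' @param n_wgatar_per_enhancer,n_ebox_per_enhancer Motif copies planted per
#'   enhancer (2 and 1).
#' @param motif_free_background Scrub WGATAR/E-box occurrences from the
#'   background sequence before planting motifs (default FALSE).
#' @param n_registry_extra Registry-only family members not present in the
#'   genome, emulating the full transporter ensemble (default 33).
#' @param n_phenotype SLC genes flagged with a reported phenotype (default 6).
#' @param n_decoy_peaks Intergenic decoy peaks per assay per chromosome (4).
#' @param exon_count_range,exon_length_range,intron_length_range,
#'   intergenic_gap_range Structural ranges (bp) for gene layout.
#' @param seed Integer seed (default 1).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 3,
                             chrom_length = 1000000,
                             n_genes = 60,
                             fraction_slc = 40 / 60,
                             n_shared = 27,
                             n_g1_only = 6,
                             n_g2_only = 4,
                             n_nonslc_regulated = 3,
                             n_gata2_occupied = 21,
                             n_gata1_occupied = 17,
                             n_accessible = 24,
                             n_planted_enhancers = 8,
                             planted_lfc_gata1 = NULL,
                             planted_lfc_gata2 = NULL,
                             replicates = 3,
                             noise_sd = 0.5,
                             peak_width = c(150, 400),
                             n_wgatar_per_enhancer = 2,
                             n_ebox_per_enhancer = 1,
                             motif_free_background = FALSE,
                             n_registry_extra = 33,
                             n_phenotype = 6,
                             n_decoy_peaks = 4,
                             exon_count_range = c(2, 6),
                             exon_length_range = c(150, 300),
                             intron_length_range = c(400, 1200),
                             intergenic_gap_range = c(21000, 26000),
                             seed = 1) {
  cfg <- list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    n_genes = n_genes, fraction_slc = fraction_slc,
    n_shared = n_shared, n_g1_only = n_g1_only, n_g2_only = n_g2_only,
    n_nonslc_regulated = n_nonslc_regulated,
    n_gata2_occupied = n_gata2_occupied,
    n_gata1_occupied = n_gata1_occupied,
    n_accessible = n_accessible,
    n_planted_enhancers = n_planted_enhancers,
    planted_lfc_gata1 = planted_lfc_gata1,
    planted_lfc_gata2 = planted_lfc_gata2,
    replicates = replicates, noise_sd = noise_sd,
    peak_width = peak_width,
    n_wgatar_per_enhancer = n_wgatar_per_enhancer,
    n_ebox_per_enhancer = n_ebox_per_enhancer,
    motif_free_background = motif_free_background,
    n_registry_extra = n_registry_extra,
    n_phenotype = n_phenotype,
    n_decoy_peaks = n_decoy_peaks,
    exon_count_range = exon_count_range,
    exon_length_range = exon_length_range,
    intron_length_range = intron_length_range,
    intergenic_gap_range = intergenic_gap_range,
    # analytic expected WGATAR occurrences per kb (both strands) under the
    # uniform base composition: 2 * (2/4) * (1/4)^4 * (2/4) per position
    motif_density_background = 2 * (2 / 4) * (1 / 4)^4 * (2 / 4) * 1000,
    seed = seed
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  pos <- c("n_chromosomes", "chrom_length", "n_genes", "replicates")
  for (f in pos) if (cfg[[f]] < 1) stop(f, " must be positive")
  if (cfg$fraction_slc <= 0 || cfg$fraction_slc > 1)
    stop("fraction_slc must be in (0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$peak_width[1] < 10 || cfg$peak_width[2] < cfg$peak_width[1])
    stop("peak_width must be an increasing positive range")
  n_slc <- round(cfg$fraction_slc * cfg$n_genes)
  if (cfg$n_shared + cfg$n_g1_only + cfg$n_g2_only > n_slc)
    stop("regulated SLC counts exceed the number of SLC genes")
  if (cfg$n_gata2_occupied > cfg$n_shared ||
      cfg$n_gata1_occupied > cfg$n_gata2_occupied ||
      cfg$n_planted_enhancers > cfg$n_gata1_occupied ||
      cfg$n_accessible > cfg$n_shared ||
      cfg$n_planted_enhancers > cfg$n_accessible)
    stop("occupancy/accessibility counts must nest: enhancers <= GATA1 <= ",
         "GATA2-occupied <= shared, enhancers <= accessible <= shared")
  invisible(cfg)
}

# Internal: random DNA of length n as a character vector of bases.
random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Internal: remove every WGATAR/E-box occurrence from a base vector by
# resampling hit windows until no occurrence remains.
scrub_motifs <- function(bases, motifs) {
  seq_str <- paste(bases, collapse = "")
  for (iter in 1:50) {
    hits <- do.call(rbind, lapply(motifs, function(m) scan_motif(seq_str, m)))
    if (is.null(hits) || nrow(hits) == 0) return(strsplit(seq_str, "")[[1]])
    for (r in seq_len(nrow(hits))) {
      w <- hits$end[r] - hits$start[r]
      substr(seq_str, hits$start[r] + 1, hits$end[r]) <-
        paste(random_bases(w), collapse = "")
    }
  }
  stop("failed to scrub background motifs after 50 passes")
}

# Internal: one concrete instance of a planted motif.
wgatar_instance <- function() paste0(sample(c("A", "T"), 1), "GATA",
                                     sample(c("A", "G"), 1))
ebox_instance <- function() paste0("CA", paste(random_bases(2), collapse = ""),
                                   "TG")

#' Generate the synthetic genome, gene models and ground truth
#'
#' Lays out genes with 2-8 exons on uniform-composition chromosomes, labels
#' the SLC family, assigns planted expression effects per contrast, chooses
#' occupancy/accessibility flags, and embeds enhancer sequences (carrying
#' the configured WGATAR and E-box copies by substitution, never spanning
#' enhancer edges) wholly inside introns of their host genes. Deterministic
#' given the config seed.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `sequences` (named character vector,
#'   chromosome -> DNA string), `genes` (a `gene_models`), `truth` (list
#'   with data.frames `genes` and `enhancers`) and `registry`
#'   (a `transporter_registry` covering the SLC genes plus registry-only
#'   ensemble members).
#' @export
generate_genome <- function(config) {
  validate_synthetic_config(config)
  set.seed(stage_seed(config$seed, "genome"))
  n <- config$n_genes
  gene_id <- sprintf("g%03d", seq_len(n))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))

  # --- gene structure and placement ------------------------------------
  exon_list <- vector("list", n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_of <- chroms[(seq_len(n) - 1) %% config$n_chromosomes + 1]
  cursor <- stats::setNames(rep(3000, length(chroms)), chroms)
  tail_reserve <- 60000
  tx_start <- tx_end <- numeric(n)
  for (i in seq_len(n)) {
    ne <- sample(config$exon_count_range[1]:config$exon_count_range[2], 1)
    elen <- sample(config$exon_length_range[1]:config$exon_length_range[2],
                   ne, replace = TRUE)
    ilen <- if (ne > 1)
      sample(config$intron_length_range[1]:config$intron_length_range[2],
             ne - 1, replace = TRUE) else integer(0)
    s <- cursor[chrom_of[i]]
    starts <- s + cumsum(c(0, utils::head(elen, -1) + ilen))
    exon_list[[i]] <- data.frame(gene_id = gene_id[i], start = starts,
                                 end = starts + elen,
                                 stringsAsFactors = FALSE)
    tx_start[i] <- s
    tx_end[i] <- starts[ne] + elen[ne]
    gap <- sample(config$intergenic_gap_range[1]:
                    config$intergenic_gap_range[2], 1)
    cursor[chrom_of[i]] <- tx_end[i] + gap
    if (cursor[chrom_of[i]] + tail_reserve > config$chrom_length)
      stop("genome too small to place ", n, " genes without overlap; ",
           "increase chrom_length or n_chromosomes")
  }

  # --- family labels and registry --------------------------------------
  n_slc <- round(config$fraction_slc * n)
  slc_genes <- sort(sample(gene_id, n_slc))
  family <- ifelse(gene_id %in% slc_genes, "SLC", NA_character_)
  genes_df <- data.frame(gene_id = gene_id, chrom = chrom_of,
                         strand = strand, tx_start = tx_start,
                         tx_end = tx_end, family = family,
                         stringsAsFactors = FALSE)
  gm <- gene_models(genes_df, do.call(rbind, exon_list))

  registry_ids <- c(slc_genes,
                    if (config$n_registry_extra > 0)
                      sprintf("slcx%02d", seq_len(config$n_registry_extra)))
  registry <- transporter_registry(data.frame(
    gene_id = registry_ids,
    family = paste0("Slc", sample(1:52, length(registry_ids),
                                  replace = TRUE)),
    substrate_class = sample(SUBSTRATE_CLASSES, length(registry_ids),
                             replace = TRUE,
                             prob = c(0.25, 0.20, 0.15, 0.10, 0.30)),
    localization = sample(LOCALIZATIONS, length(registry_ids),
                          replace = TRUE),
    phenotype = FALSE,
    stringsAsFactors = FALSE
  ))
  pheno <- sample(slc_genes, min(config$n_phenotype, length(slc_genes)))
  registry$phenotype <- registry$gene_id %in% pheno

  # --- planted expression effects --------------------------------------
  shared <- slc_genes[seq_len(config$n_shared)]
  g1_only <- slc_genes[config$n_shared + seq_len(config$n_g1_only)]
  g2_only <- slc_genes[config$n_shared + config$n_g1_only +
                         seq_len(config$n_g2_only)]
  nonslc <- setdiff(gene_id, slc_genes)
  nonslc_reg <- nonslc[seq_len(min(config$n_nonslc_regulated,
                                   length(nonslc)))]
  occupied2 <- shared[seq_len(config$n_gata2_occupied)]
  occupied1 <- occupied2[seq_len(config$n_gata1_occupied)]
  hosts <- occupied1[seq_len(config$n_planted_enhancers)]
  accessible <- shared[seq_len(config$n_accessible)]

  lfc1 <- config$planted_lfc_gata1
  lfc2 <- config$planted_lfc_gata2
  if (is.null(lfc1) || is.null(lfc2)) {
    mag <- function(g) ifelse(g %in% hosts, stats::runif(length(g), 2.5, 3.5),
                              stats::runif(length(g), 1.2, 2.2))
    auto1 <- auto2 <- stats::setNames(rep(0, n), gene_id)
    # shared cohort: GATA2-activated (down in the enhancer-knockout
    # condition b), mixed GATA1 direction (b = GATA1-induced condition)
    auto2[shared] <- -mag(shared)
    auto1[shared] <- mag(shared) * sample(c(-1, 1), length(shared),
                                          replace = TRUE)
    auto1[g1_only] <- mag(g1_only) * sample(c(-1, 1), length(g1_only),
                                            replace = TRUE)
    auto2[g2_only] <- mag(g2_only) * sample(c(-1, 1), length(g2_only),
                                            replace = TRUE)
    auto1[nonslc_reg] <- mag(nonslc_reg)
    auto2[nonslc_reg] <- -mag(nonslc_reg)
    if (is.null(lfc1)) lfc1 <- auto1[auto1 != 0]
    if (is.null(lfc2)) lfc2 <- auto2[auto2 != 0]
  }
  full1 <- stats::setNames(rep(0, n), gene_id)
  full2 <- stats::setNames(rep(0, n), gene_id)
  full1[names(lfc1)] <- lfc1
  full2[names(lfc2)] <- lfc2

  dir1 <- ifelse(full1 > 0, "up", ifelse(full1 < 0, "down", "none"))
  dir2 <- ifelse(full2 < 0, "up", ifelse(full2 > 0, "down", "none"))

  truth_genes <- data.frame(
    gene_id = gene_id,
    is_slc = gene_id %in% slc_genes,
    lfc_gata1 = unname(full1),
    lfc_gata2 = unname(full2),
    dir_gata1 = unname(dir1),
    dir_gata2 = unname(dir2),
    gata1_occupied = gene_id %in% occupied1,
    gata2_occupied = gene_id %in% occupied2,
    accessible = gene_id %in% accessible,
    has_enhancer = gene_id %in% hosts,
    stringsAsFactors = FALSE
  )

  # --- chromosome sequences ---------------------------------------------
  base_list <- lapply(chroms, function(ch) random_bases(config$chrom_length))
  names(base_list) <- chroms
  if (config$motif_free_background)
    base_list <- lapply(base_list, scrub_motifs,
                        motifs = list(motif_wgatar(), motif_ebox()))

  # --- planted enhancers -------------------------------------------------
  intr <- introns(gm)
  enh <- vector("list", length(hosts))
  for (h in seq_along(hosts)) {
    g <- hosts[h]
    width <- sample(config$peak_width[1]:config$peak_width[2], 1)
    gi <- intr[intr$gene_id == g & (intr$end - intr$start) >= width, ,
               drop = FALSE]
    if (nrow(gi) == 0)
      stop("no intron wide enough for an enhancer in gene ", g)
    j <- sample(nrow(gi), 1)
    off <- sample(0:(gi$end[j] - gi$start[j] - width), 1)
    e_start <- gi$start[j] + off
    ch <- gi$chrom[j]
    # plant motifs by substitution at non-overlapping offsets inside the
    # enhancer, never spanning its edges
    inst <- c(replicate(config$n_wgatar_per_enhancer, wgatar_instance()),
              replicate(config$n_ebox_per_enhancer, ebox_instance()))
    taken <- integer(0)
    for (m in inst) {
      repeat {
        o <- sample(0:(width - nchar(m)), 1)
        if (!any(abs(o - taken) < 6)) break
      }
      taken <- c(taken, o)
      base_list[[ch]][(e_start + o + 1):(e_start + o + nchar(m))] <-
        strsplit(m, "")[[1]]
    }
    enh[[h]] <- data.frame(
      gene_id = g, chrom = ch, intron_index = gi$intron_index[j],
      start = e_start, end = e_start + width,
      n_wgatar_planted = config$n_wgatar_per_enhancer,
      n_ebox_planted = config$n_ebox_per_enhancer,
      accessible = TRUE, ccre = TRUE,
      stringsAsFactors = FALSE
    )
  }
  truth_enh <- if (length(enh)) do.call(rbind, enh) else
    data.frame(gene_id = character(), chrom = character(),
               intron_index = integer(), start = numeric(), end = numeric(),
               n_wgatar_planted = integer(), n_ebox_planted = integer(),
               accessible = logical(), ccre = logical(),
               stringsAsFactors = FALSE)

  sequences <- vapply(base_list, paste, "", collapse = "")
  list(sequences = sequences, genes = gm,
       truth = list(genes = truth_genes, enhancers = truth_enh),
       registry = registry)
}

#' Generate replicate expression contrasts with planted effects
#'
#' Baseline TPM is drawn log-normally (log2 mean 5, sd 1.5; genes with a
#' planted effect are floored at 4 TPM so they are well expressed), the
#' condition-b mean is the baseline times `2^lfc`, and each replicate
#' multiplies its condition mean by `2^N(0, noise_sd)`. The GATA1 contrast
#' has groups `untreated`/`estradiol` (b = estradiol, the GATA1-active
#' condition); the GATA2 contrast has groups `wt`/`mut` (b = mut, the
#' enhancer-knockout condition lacking GATA2).
#'
#' @param genes A `gene_models` or character vector of gene ids.
#' @param truth The `truth` element of [generate_genome()] output (its
#'   `genes` table supplies `lfc_gata1` and `lfc_gata2`).
#' @param config A `synthetic_config`.
#' @return A list with `expr_matrix` elements `gata1` and `gata2` and the
#'   condition maps `groups_gata1`, `groups_gata2`.
#' @export
generate_expression <- function(genes, truth, config) {
  if (config$replicates < 1) stop("replicate count must be >= 1")
  ids <- if (inherits(genes, "gene_models")) genes$genes$gene_id else genes
  tg <- truth$genes
  if (!all(ids %in% tg$gene_id))
    stop("truth does not cover all genes")
  tg <- tg[match(ids, tg$gene_id), ]
  set.seed(stage_seed(config$seed, "expression"))
  nrep <- config$replicates
  one_contrast <- function(lfc, label_a, label_b) {
    baseline <- 2^stats::rnorm(length(ids), mean = 5, sd = 1.5)
    baseline[lfc != 0] <- pmax(baseline[lfc != 0], 4)
    mean_b <- baseline * 2^lfc
    noise <- function(m) m * 2^stats::rnorm(length(m), sd = config$noise_sd)
    vals_a <- matrix(noise(rep(baseline, nrep)), ncol = nrep)
    vals_b <- matrix(noise(rep(mean_b, nrep)), ncol = nrep)
    m <- cbind(vals_a, vals_b)
    rownames(m) <- ids
    colnames(m) <- c(paste0(label_a, "_", seq_len(nrep)),
                     paste0(label_b, "_", seq_len(nrep)))
    groups <- stats::setNames(rep(c(label_a, label_b), each = nrep),
                              colnames(m))
    expression_matrix(m, groups)
  }
  e1 <- one_contrast(tg$lfc_gata1, "untreated", "estradiol")
  e2 <- one_contrast(tg$lfc_gata2, "wt", "mut")
  list(gata1 = e1, gata2 = e2,
       groups_gata1 = e1$groups, groups_gata2 = e2$groups)
}

#' Generate ChIP, ATAC and cCRE peak sets from the ground truth
#'
#' Every planted enhancer is covered by a GATA2 peak (and, per its flags, by
#' GATA1, ATAC and cCRE intervals). GATA2-occupied genes without a planted
#' enhancer receive an intronic GATA2 peak (shared with GATA1 when
#' GATA1-occupied) that does not overlap ATAC; accessible genes without an
#' enhancer receive a promoter ATAC peak. Decoy peaks are placed in
#' intergenic space beyond the assignment window of any gene.
#'
#' @param genes A `gene_models`.
#' @param truth The `truth` element of [generate_genome()] output.
#' @param config A `synthetic_config`.
#' @return A list of `genomic_intervals`: `gata1`, `gata2`, `atac`, `ccre`.
#' @export
generate_peaks <- function(genes, truth, config) {
  set.seed(stage_seed(config$seed, "peaks"))
  gm <- genes
  tg <- truth$genes
  te <- truth$enhancers
  intr <- introns(gm)
  g <- gm$genes
  width_range <- config$peak_width[1]:config$peak_width[2]
  rows <- list(gata1 = list(), gata2 = list(), atac = list(), ccre = list())
  add <- function(assay, chrom, start, end, name) {
    rows[[assay]][[length(rows[[assay]]) + 1]] <<- data.frame(
      chrom = chrom, start = start, end = end, name = name,
      stringsAsFactors = FALSE)
  }

  # enhancer hosts: all assays per truth flags, covering the enhancer
  for (r in seq_len(nrow(te))) {
    nm <- te$gene_id[r]
    add("gata2", te$chrom[r], te$start[r], te$end[r], paste0("g2_", nm))
    if (tg$gata1_occupied[tg$gene_id == nm])
      add("gata1", te$chrom[r], te$start[r], te$end[r], paste0("g1_", nm))
    if (te$accessible[r])
      add("atac", te$chrom[r], te$start[r], te$end[r], paste0("at_", nm))
    if (te$ccre[r])
      add("ccre", te$chrom[r], te$start[r], te$end[r], paste0("cc_", nm))
  }

  # occupied genes without an enhancer: intronic GATA2 (+GATA1) peak
  occ_no_enh <- tg$gene_id[tg$gata2_occupied & !tg$has_enhancer]
  for (nm in occ_no_enh) {
    w <- sample(width_range, 1)
    gi <- intr[intr$gene_id == nm & (intr$end - intr$start) >= w, ,
               drop = FALSE]
    if (nrow(gi) == 0) stop("no intron wide enough for a peak in gene ", nm)
    j <- sample(nrow(gi), 1)
    off <- sample(0:(gi$end[j] - gi$start[j] - w), 1)
    s <- gi$start[j] + off
    add("gata2", gi$chrom[j], s, s + w, paste0("g2_", nm))
    if (tg$gata1_occupied[tg$gene_id == nm])
      add("gata1", gi$chrom[j], s, s + w, paste0("g1_", nm))
  }

  # accessible genes without an enhancer: promoter ATAC peak at the TSS
  acc_no_enh <- tg$gene_id[tg$accessible & !tg$has_enhancer]
  for (nm in acc_no_enh) {
    gi <- g[g$gene_id == nm, ]
    w <- sample(width_range, 1)
    tss <- if (gi$strand == "-") gi$tx_end else gi$tx_start
    s <- max(0, tss - w %/% 2)
    add("atac", gi$chrom, s, s + w, paste0("at_", nm))
  }

  # intergenic decoy peaks, beyond the assignment window of any gene
  for (ch in unique(g$chrom)) {
    tail_start <- max(g$tx_end[g$chrom == ch]) + 11000
    for (assay in names(rows)) {
      for (d in seq_len(config$n_decoy_peaks)) {
        w <- sample(width_range, 1)
        s <- tail_start + (d - 1) * 1200 +
          switch(assay, gata1 = 0, gata2 = 300, atac = 600, ccre = 900)
        if (s + w > config$chrom_length)
          stop("no intergenic room for decoy peaks on ", ch)
        add(assay, ch, s, s + w, paste0("decoy_", assay, "_", ch, "_", d))
      }
    }
  }

  lapply(rows, function(rr) {
    df <- do.call(rbind, rr)
    if (is.null(df)) return(empty_intervals())
    genomic_intervals(df$chrom, df$start, df$end, name = df$name)
  })
}

#' Write a full synthetic dataset to disk
#'
#' Writes the genome FASTA, gene models (GFF3), the four peak BED files, the
#' two expression TSVs with a sample sheet, the transporter registry and the
#' ground-truth tables.
#'
#' @param config A `synthetic_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome(config)
  expr <- generate_expression(sim$genes, sim$truth, config)
  peaks <- generate_peaks(sim$genes, sim$truth, config)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    gata1_peaks = file.path(dir, "gata1_peaks.bed"),
    gata2_peaks = file.path(dir, "gata2_peaks.bed"),
    atac_peaks = file.path(dir, "atac_peaks.bed"),
    ccres = file.path(dir, "ccres.bed"),
    expr_gata1 = file.path(dir, "expr_gata1.tsv"),
    expr_gata2 = file.path(dir, "expr_gata2.tsv"),
    samples = file.path(dir, "samples.tsv"),
    registry = file.path(dir, "registry.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_enhancers = file.path(dir, "truth_enhancers.tsv")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences),
                              paths["genome"])
  write_gff3(sim$genes, paths["genes"])
  write_bed(peaks$gata1, paths["gata1_peaks"])
  write_bed(peaks$gata2, paths["gata2_peaks"])
  write_bed(peaks$atac, paths["atac_peaks"])
  write_bed(peaks$ccre, paths["ccres"])
  write_expression_table(expr$gata1, paths["expr_gata1"])
  write_expression_table(expr$gata2, paths["expr_gata2"])
  samples <- rbind(
    data.frame(sample = names(expr$groups_gata1), contrast = "gata1",
               group = unname(expr$groups_gata1)),
    data.frame(sample = names(expr$groups_gata2), contrast = "gata2",
               group = unname(expr$groups_gata2))
  )
  utils::write.table(samples, paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_transporter_registry(sim$registry, paths["registry"])
  utils::write.table(sim$truth$genes, paths["truth_genes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$enhancers, paths["truth_enhancers"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Ground truth with no planted effects
#'
#' Convenience constructor for null simulations (e.g. type-I error checks).
#'
#' @param gene_ids Character vector of gene ids.
#' @return A `truth` list whose `genes` table has all-zero effects.
#' @export
null_truth <- function(gene_ids) {
  list(genes = data.frame(
    gene_id = gene_ids, is_slc = FALSE,
    lfc_gata1 = 0, lfc_gata2 = 0,
    dir_gata1 = "none", dir_gata2 = "none",
    gata1_occupied = FALSE, gata2_occupied = FALSE,
    accessible = FALSE, has_enhancer = FALSE,
    stringsAsFactors = FALSE
  ), enhancers = data.frame())
}
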