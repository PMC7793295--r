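# Synthetic-data generator: determinism, planted structure, expression and
# peak contracts.

test_that("generation is deterministic given config and seed", {
  cfg <- small_config(seed = 9)
  s1 <- generate_genome(cfg)
  s2 <- generate_genome(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  e1 <- generate_expression(s1$genes, s1$truth, cfg)
  e2 <- generate_expression(s2$genes, s2$truth, cfg)
  expect_identical(e1$gata1$values, e2$gata1$values)
  p1 <- generate_peaks(s1$genes, s1$truth, cfg)
  p2 <- generate_peaks(s2$genes, s2$truth, cfg)
  expect_identical(p1, p2)
  # and the written dataset is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(cfg, d1)
  write_synthetic_dataset(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("genome structure matches the configuration", {
  cfg <- small_config(seed = 4)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$genes$genes), cfg$n_genes)
  exon_counts <- table(sim$genes$exons$gene_id)
  expect_true(all(exon_counts >= cfg$exon_count_range[1] &
                    exon_counts <= cfg$exon_count_range[2]))
  expect_equal(sum(sim$truth$genes$is_slc), round(cfg$fraction_slc *
                                                    cfg$n_genes))
  # occupancy flags nest: enhancers within GATA1 within GATA2 within shared
  tg <- sim$truth$genes
  expect_true(all(!tg$has_enhancer | tg$gata1_occupied))
  expect_true(all(!tg$gata1_occupied | tg$gata2_occupied))
  expect_equal(sum(tg$gata2_occupied), cfg$n_gata2_occupied)
  # an impossible layout errors
  expect_error(generate_genome(small_config(chrom_length = 30000)),
               "too small")
})

test_that("planted enhancers sit in introns of their host and carry WGATAR", {
  sim <- generate_genome(small_config(seed = 12))
  te <- sim$truth$enhancers
  expect_equal(nrow(te), 3)
  intr <- introns(sim$genes)
  for (i in seq_len(nrow(te))) {
    host <- intr[intr$gene_id == te$gene_id[i] &
                   intr$intron_index == te$intron_index[i], ]
    expect_equal(nrow(host), 1)
    expect_true(host$start <= te$start[i] && te$end[i] <= host$end)
    footprint <- substr(sim$sequences[[te$chrom[i]]], te$start[i] + 1,
                        te$end[i])
    expect_gte(nrow(naive_scan(footprint, "WGATAR")), 1)
    expect_gte(nrow(naive_scan(footprint, "CANNTG")), 1)
  }
})

test_that("motif-free background scrubbing removes all background hits", {
  cfg <- small_config(seed = 3, motif_free_background = TRUE)
  sim <- generate_genome(cfg)
  te <- sim$truth$enhancers
  for (ch in names(sim$sequences)) {
    hits <- scan_motif(sim$sequences[[ch]], motif_wgatar())
    # every remaining hit lies inside a planted enhancer
    enh <- te[te$chrom == ch, ]
    inside <- vapply(seq_len(nrow(hits)), function(i)
      any(enh$start <= hits$start[i] & hits$end[i] <= enh$end), TRUE)
    expect_true(all(inside))
  }
})

test_that("noiseless expression reproduces planted fold changes exactly", {
  cfg <- small_config(seed = 2, noise_sd = 0)
  sim <- generate_genome(cfg)
  expr <- generate_expression(sim$genes, sim$truth, cfg)
  fc <- compute_fold_changes(expr$gata1, "untreated", "estradiol",
                             pseudocount = 0)
  tg <- sim$truth$genes[match(fc$gene_id, sim$truth$genes$gene_id), ]
  expect_equal(fc$log2fc, tg$lfc_gata1, tolerance = 1e-12)
  # genes with no planted effect have fold change exactly 1
  expect_true(all(fc$mean_b[tg$lfc_gata1 == 0] ==
                    fc$mean_a[tg$lfc_gata1 == 0]))
})

test_that("mean estimated effect is unbiased under replicate noise", {
  # simulation oracle: average the estimated log2 fold change of one planted
  # gene over 200 seeds at noise_sd = 0.5, n = 3
  planted <- c(gene1 = 2)
  est <- vapply(1:200, function(s) {
    cfg <- synthetic_config(
      n_chromosomes = 1, chrom_length = 200000, n_genes = 3,
      fraction_slc = 1, n_shared = 1, n_g1_only = 0, n_g2_only = 0,
      n_nonslc_regulated = 0, n_gata2_occupied = 1, n_gata1_occupied = 1,
      n_accessible = 1, n_planted_enhancers = 1,
      planted_lfc_gata1 = c(g001 = 2), planted_lfc_gata2 = c(g001 = -2),
      noise_sd = 0.5, seed = s)
    expr <- generate_expression(c("g001", "g002", "g003"),
                                null_truth_with(c(g001 = 2)), cfg)
    fc <- compute_fold_changes(expr$gata1, "untreated", "estradiol",
                               pseudocount = 0)
    fc$log2fc[fc$gene_id == "g001"]
  }, 0)
  expect_lt(abs(mean(est) - 2), 0.1)
})

test_that("peak sets respect the planted truth and width bounds", {
  cfg <- small_config(seed = 6)
  sim <- generate_genome(cfg)
  peaks <- generate_peaks(sim$genes, sim$truth, cfg)
  te <- sim$truth$enhancers
  # every planted, accessible enhancer overlaps >= 1 ATAC peak
  acc <- te[te$accessible, , drop = FALSE]
  for (i in seq_len(nrow(acc))) {
    ov <- peaks$atac$chrom == acc$chrom[i] &
      peaks$atac$start < acc$end[i] & acc$start[i] < peaks$atac$end
    expect_true(any(ov))
  }
  # decoy genes have zero overlapping GATA peaks
  tg <- sim$truth$genes
  g <- sim$genes$genes
  decoys <- g[g$gene_id %in% tg$gene_id[!tg$gata2_occupied], ]
  for (assay in c("gata1", "gata2")) {
    pk <- peaks[[assay]]
    for (i in seq_len(nrow(decoys))) {
      ov <- pk$chrom == decoys$chrom[i] & pk$start < decoys$tx_end[i] &
        decoys$tx_start[i] < pk$end
      expect_false(any(ov))
    }
  }
  # widths within the configured range
  for (assay in names(peaks)) {
    w <- peaks[[assay]]$end - peaks[[assay]]$start
    expect_true(all(w >= cfg$peak_width[1] & w <= cfg$peak_width[2]))
  }
})
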