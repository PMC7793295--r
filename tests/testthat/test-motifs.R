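# IUPAC motif scanning, matched-background sampling, and the permutation
# enrichment test.

test_that("scan_motif handles both strands, N, and palindromes", {
  wg <- motif_wgatar()
  # W -> T, R -> A on the forward strand
  h <- scan_motif("TGATAA", wg)
  expect_equal(h$start, 0)
  expect_equal(h$strand, "+")
  # reverse complement TGATAA reported in forward coordinates, strand "-"
  h <- scan_motif("TTATCA", wg)
  expect_equal(h$start, 0)
  expect_equal(h$strand, "-")
  # N in the sequence never matches a non-N pattern symbol
  expect_equal(nrow(scan_motif("NGATAA", wg)), 0)
  expect_equal(nrow(scan_motif("TGATNA", wg)), 0)
  # palindromic E-box matches once per interval
  h <- scan_motif("CAGCTG", motif_ebox())
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_error(motif_model("bad", "WGAXAR"), "invalid IUPAC")
  expect_error(motif_model("short", "ACG"), "length")
})

test_that("scanning matches the naive sliding-window oracle", {
  set.seed(51)
  for (motif in list(motif_wgatar(), motif_ebox())) {
    for (i in 1:60) {
      s <- random_dna(200)
      got <- scan_motif(s, motif)
      want <- naive_scan(s, motif$pattern)
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("group statistic counts sequences with hits", {
  wg <- motif_wgatar()
  all_hit <- c("TGATAA", "CCAGATAGCC", "TTATCT")
  expect_equal(group_statistic(all_hit, wg), 3)
  none <- c("CCCCCC", "GGGGGG")
  expect_equal(group_statistic(none, wg), 0)
  mixed <- c(all_hit, none)
  oracle <- sum(vapply(mixed, function(s) nrow(scan_motif(s, wg)) > 0, TRUE))
  expect_equal(group_statistic(mixed, wg), oracle)
  expect_equal(group_statistic(c("TGATAATGATAA", "CCCC"), wg,
                               statistic = "count"), 2)
  expect_error(group_statistic(character(), wg), "empty")
  # strand symmetry: reverse complementing every sequence changes nothing
  rc <- vapply(mixed, revcomp_seq, "")
  expect_equal(group_statistic(rc, wg), group_statistic(mixed, wg))
})

test_that("matched background sampling honors its contract", {
  sim <- generate_genome(small_config(seed = 13))
  observed <- data.frame(chrom = c("chr1", "chr2", "chr1"),
                         length = c(200, 350, 150))
  set.seed(1)
  bg <- sample_matched_background(observed, sim$genes, sim$sequences)
  expect_equal(nchar(bg), observed$length)
  coords <- attr(bg, "coords")
  expect_equal(coords$chrom, observed$chrom)
  # every sampled interval lies inside an intron
  intr <- introns(sim$genes)
  for (i in seq_len(nrow(coords))) {
    inside <- intr$chrom == coords$chrom[i] &
      intr$start <= coords$start[i] & coords$end[i] <= intr$end
    expect_true(any(inside))
    # and the returned string is the genome substring at those coordinates
    expect_equal(bg[i], substr(sim$sequences[[coords$chrom[i]]],
                               coords$start[i] + 1, coords$end[i]),
                 ignore_attr = TRUE)
  }
  expect_error(
    sample_matched_background(
      data.frame(chrom = "chr1", length = 1e6), sim$genes, sim$sequences),
    "no intron")
})

test_that("degenerate permutation tests hit their analytic values", {
  sim <- generate_genome(small_config(seed = 14))
  te <- sim$truth$enhancers
  obs <- data.frame(chrom = te$chrom, start = te$start, end = te$end)
  # a pattern that matches everywhere saturates observed and null statistics
  res <- permutation_test(obs, sim$genes, sim$sequences,
                          motif_model("any", "NNNN"), n_iter = 50, seed = 2)
  expect_equal(res$observed_statistic, nrow(obs))
  expect_equal(res$p_empirical, 1)
  # motif-free observed group: statistic 0 is the floor, p = 1
  gm <- toy_gene_models()
  seqs <- c(chr1 = paste(rep("C", 2000), collapse = ""))
  obs0 <- data.frame(chrom = "chr1", start = 400, end = 600)
  res0 <- permutation_test(obs0, gm, seqs, motif_wgatar(), n_iter = 50,
                           seed = 3)
  expect_equal(res0$observed_statistic, 0)
  expect_equal(res0$p_empirical, 1)
  expect_error(permutation_test(obs0, gm, seqs, motif_wgatar(), n_iter = 0),
               "n_iter")
  expect_error(permutation_test(obs0[0, ], gm, seqs, motif_wgatar()),
               "empty")
})

test_that("motifs planted only in the observed group give the floor p-value", {
  # scrubbed background; null support excludes the enhancer-carrying hosts,
  # so every null group statistic is exactly 0 while the observed is > 0:
  # k = 0, hence p_corrected = 1/(n_iter+1) and p_empirical = 0
  cfg <- small_config(seed = 15, motif_free_background = TRUE)
  sim <- generate_genome(cfg)
  te <- sim$truth$enhancers
  keep <- !sim$genes$genes$gene_id %in% te$gene_id
  bg_gm <- gene_models(sim$genes$genes[keep, ],
                       sim$genes$exons[sim$genes$exons$gene_id %in%
                                         sim$genes$genes$gene_id[keep], ])
  obs <- data.frame(chrom = te$chrom, start = te$start, end = te$end)
  for (n_iter in c(37, 200)) {
    res <- permutation_test(obs, bg_gm, sim$sequences, motif_wgatar(),
                            n_iter = n_iter, seed = 4)
    expect_equal(res$observed_statistic, nrow(te))
    expect_equal(res$p_empirical, 0)
    expect_equal(res$p_corrected, 1 / (n_iter + 1))
  }
})

test_that("the fast index path agrees with direct rescanning", {
  sim <- generate_genome(small_config(seed = 16))
  te <- sim$truth$enhancers
  obs <- data.frame(chrom = te$chrom, start = te$start, end = te$end)
  for (stat in c("presence", "count")) {
    r1 <- permutation_test(obs, sim$genes, sim$sequences, motif_wgatar(),
                           n_iter = 60, seed = 5, statistic = stat,
                           method = "index")
    r2 <- permutation_test(obs, sim$genes, sim$sequences, motif_wgatar(),
                           n_iter = 60, seed = 5, statistic = stat,
                           method = "scan")
    expect_equal(r1$observed_statistic, r2$observed_statistic)
    expect_equal(r1$null_counts, r2$null_counts)
    expect_equal(r1$p_empirical, r2$p_empirical)
  }
})

test_that("identical seeds reproduce the null histogram exactly", {
  sim <- generate_genome(small_config(seed = 17))
  te <- sim$truth$enhancers
  obs <- data.frame(chrom = te$chrom, start = te$start, end = te$end)
  r1 <- permutation_test(obs, sim$genes, sim$sequences, motif_ebox(),
                         n_iter = 150, seed = 11)
  r2 <- permutation_test(obs, sim$genes, sim$sequences, motif_ebox(),
                         n_iter = 150, seed = 11)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_identical(r1$p_empirical, r2$p_empirical)
})

test_that("planting extra motif copies never increases the p-value", {
  # observed windows live in intergenic space, so editing them leaves the
  # intronic null support untouched; with a fixed seed the null draws are
  # identical and the observed statistic can only grow
  gm <- toy_gene_models()
  base <- rep("C", 5000)
  seqs0 <- c(chr1 = paste(base, collapse = ""))
  obs <- data.frame(chrom = "chr1", start = c(3000, 3500), end = c(3200, 3700))
  p_prev <- 1.01
  edited <- base
  offsets <- c(3050, 3550, 3100)
  for (step in 0:3) {
    if (step > 0)
      edited[(offsets[step] + 1):(offsets[step] + 6)] <-
        strsplit("TGATAA", "")[[1]]
    seqs <- c(chr1 = paste(edited, collapse = ""))
    res <- permutation_test(obs, gm, seqs, motif_wgatar(), n_iter = 80,
                            seed = 6)
    expect_lte(res$p_empirical, p_prev)
    p_prev <- res$p_empirical
  }
})
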