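# Peak-to-gene assignment, context classification, enhancer calling and
# occupancy summaries.

test_that("assignment context follows the overlap midpoint", {
  gm <- toy_gene_models()
  peaks <- genomic_intervals(
    "chr1",
    start = c(150, 50, 250, 1450, 1750, 5000),
    end   = c(160, 60, 260, 1460, 1760, 5100),
    name = c("intronA", "exonA", "exonA2", "intronB1", "promB_up", "far"))
  asn <- assign_peaks_to_genes(peaks, gm, window = 1000)
  a <- asn[asn$gene_id == "geneA", ]
  expect_equal(a$context[a$peak_name == "intronA"], "intronic")
  expect_equal(a$intron_index[a$peak_name == "intronA"], 1)
  expect_equal(a$context[a$peak_name == "exonA"], "exonic")
  expect_equal(a$context[a$peak_name == "exonA2"], "exonic")
  # geneB is "-" strand: [1400,1600) is its intron 1
  b <- asn[asn$gene_id == "geneB", ]
  expect_equal(b$intron_index[b$peak_name == "intronB1"], 1)
  # upstream of the "-" gene TSS (beyond tx_end) is promoter context
  expect_equal(b$context[b$peak_name == "promB_up"], "promoter")
  # a peak beyond the window is not assigned at all
  expect_false("far" %in% asn$peak_name)
  expect_error(assign_peaks_to_genes(peaks, gm, window = -1), ">= 0")
})

test_that("assignments equal the all-pairs brute-force oracle", {
  set.seed(41)
  sim <- generate_genome(small_config(seed = 41))
  gm <- sim$genes
  chroms <- names(sim$sequences)
  n <- 300
  start <- sample(0:290000, n)
  peaks <- genomic_intervals(sample(chroms, n, replace = TRUE), start,
                             start + sample(100:3000, n, replace = TRUE),
                             name = paste0("p", seq_len(n)))
  asn <- assign_peaks_to_genes(peaks, gm, window = 10000)
  oracle <- brute_force_assign(peaks, gm, window = 10000)
  got <- asn[order(match(asn$peak_name, peaks$name), asn$gene_id),
             c("gene_id", "context", "intron_index")]
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$gene_id, oracle$gene_id)
  expect_equal(got$context, oracle$context)
  expect_equal(got$intron_index, oracle$intron_index)
})

enhancer_fixture <- function(with_atac = TRUE, motif = "TGATAA") {
  gm <- toy_gene_models()
  # chromosome of A's with the motif planted inside geneA's intron [100,200)
  seq_chars <- rep("C", 2000)
  seq_chars[151:156] <- strsplit(motif, "")[[1]]
  sequences <- c(chr1 = paste(seq_chars, collapse = ""))
  gata2 <- genomic_intervals("chr1", 120, 190, name = "g2pk")
  atac <- if (with_atac) genomic_intervals("chr1", 130, 180, name = "at") else
    genomic_intervals("chr1", 1900, 1950, name = "at")
  ccre <- genomic_intervals("chr1", 140, 170, name = "cc")
  gata1 <- genomic_intervals("chr1", 125, 185, name = "g1pk")
  asn <- assign_peaks_to_genes(gata2, gm, window = 1000, assay = "GATA2")
  list(gm = gm, sequences = sequences, asn = asn, atac = atac, ccre = ccre,
       gata1 = gata1)
}

test_that("the enhancer emission rule requires accessibility and WGATAR", {
  fx <- enhancer_fixture(with_atac = TRUE)
  cand <- call_intronic_enhancers(fx$asn, fx$gm, fx$sequences, fx$atac,
                                  fx$ccre, fx$gata1)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$gene_id, "geneA")
  expect_equal(cand$intron_index, 1)
  expect_equal(cand$n_wgatar, 1)
  expect_true(cand$predicted_enhancer)
  expect_true(cand$gata1_occupied && cand$accessible && cand$ccre_overlap)

  # same peak without ATAC overlap: candidate kept, not emitted
  fx2 <- enhancer_fixture(with_atac = FALSE)
  cand2 <- call_intronic_enhancers(fx2$asn, fx2$gm, fx2$sequences, fx2$atac,
                                   fx2$ccre, fx2$gata1)
  expect_equal(nrow(cand2), 1)
  expect_false(cand2$accessible)
  expect_false(cand2$predicted_enhancer)

  # no WGATAR in the footprint: not emitted even when accessible
  fx3 <- enhancer_fixture(motif = "CCCCCC")
  cand3 <- call_intronic_enhancers(fx3$asn, fx3$gm, fx3$sequences, fx3$atac,
                                   fx3$ccre, fx3$gata1)
  expect_equal(cand3$n_wgatar, 0)
  expect_false(cand3$predicted_enhancer)

  expect_error(
    call_intronic_enhancers(
      transform(fx$asn, chrom = "chrZ"), fx$gm,
      fx$sequences, fx$atac, fx$ccre, fx$gata1),
    "missing from genome")
})

test_that("candidates are clipped to introns; multi-intron peaks split", {
  gm <- toy_gene_models()
  sequences <- c(chr1 = paste(rep("C", 2000), collapse = ""))
  # geneB exons [1000,1100),[1300,1400),[1600,1700): a peak [1050,1650)
  # spans both introns and yields one footprint per intron
  gata2 <- genomic_intervals("chr1", 1050, 1650, name = "wide")
  asn <- assign_peaks_to_genes(gata2, gm, window = 1000, assay = "GATA2")
  none <- genomic_intervals("chr1", 1900, 1950)
  cand <- call_intronic_enhancers(asn, gm, sequences, none, none, none)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$start, c(1100, 1400))
  expect_equal(cand$end, c(1300, 1600))
  intr <- introns(gm, "geneB")
  for (i in seq_len(nrow(cand))) {
    host <- intr[intr$intron_index == cand$intron_index[i], ]
    expect_true(host$start <= cand$start[i] && cand$end[i] <= host$end)
    expect_lte(cand$end[i] - cand$start[i], 1650 - 1050)
  }
})

test_that("adding ATAC peaks never removes predicted enhancers", {
  fx <- enhancer_fixture(with_atac = TRUE)
  more_atac <- rbind(fx$atac,
                     genomic_intervals("chr1", 1200, 1500, name = "at2"))
  class(more_atac) <- class(fx$atac)
  base <- call_intronic_enhancers(fx$asn, fx$gm, fx$sequences, fx$atac,
                                  fx$ccre, fx$gata1)
  more <- call_intronic_enhancers(fx$asn, fx$gm, fx$sequences, more_atac,
                                  fx$ccre, fx$gata1)
  none <- call_intronic_enhancers(fx$asn, fx$gm, fx$sequences,
                                  genomic_intervals("chr1", 1900, 1950),
                                  fx$ccre, fx$gata1)
  pred <- function(x) x$gene_id[x$predicted_enhancer]
  expect_true(all(pred(base) %in% pred(more)))
  expect_true(all(pred(none) %in% pred(base)))
})

test_that("occupancy summary matches brute-force recomputation", {
  sim <- generate_genome(small_config(seed = 8))
  cfg <- small_config(seed = 8)
  peaks <- generate_peaks(sim$genes, sim$truth, cfg)
  gm <- sim$genes
  asn <- rbind(
    assign_peaks_to_genes(peaks$gata1, gm, assay = "GATA1"),
    assign_peaks_to_genes(peaks$gata2, gm, assay = "GATA2"),
    assign_peaks_to_genes(peaks$atac, gm, assay = "ATAC"),
    assign_peaks_to_genes(peaks$ccre, gm, assay = "cCRE"))
  occ <- occupancy_summary(gm$genes$gene_id, asn)
  # brute force from raw peak overlaps with the 10 kb window
  g <- gm$genes
  for (assay in c("GATA1", "GATA2", "ATAC", "cCRE")) {
    pk <- peaks[[tolower(sub("cCRE", "ccre", assay))]]
    oracle <- vapply(seq_len(nrow(g)), function(i) {
      any(pk$chrom == g$chrom[i] & pk$start < g$tx_end[i] + 10000 &
            pmax(0, g$tx_start[i] - 10000) < pk$end)
    }, TRUE)
    expect_equal(occ[[assay]], oracle, label = assay)
  }
  marg <- attr(occ, "marginals")
  expect_equal(unname(marg),
               unname(vapply(c("GATA1", "GATA2", "ATAC", "cCRE"),
                             function(a) sum(occ[[a]]), 0)))
  # a gene with no assignments has an all-false row
  lonely <- occupancy_summary("ghost", asn)
  expect_false(any(unlist(lonely[, -1])))
})
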