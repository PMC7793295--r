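# Independent oracles and small fixture builders shared across the suite.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

revcomp_pattern <- function(pattern) {
  paste(rev(IUPAC_COMP[strsplit(pattern, "")[[1]]]), collapse = "")
}

revcomp_seq <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Naive position-by-position sliding-window scan, both strands, reverse
# hits in forward coordinates, palindromic duplicates collapsed to "+".
naive_scan <- function(sequence, pattern) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  match_at <- function(pat_chars, pos) {
    for (k in seq_along(pat_chars)) {
      if (!seq_chars[pos + k - 1] %in% IUPAC_SETS[[pat_chars[k]]])
        return(FALSE)
    }
    TRUE
  }
  w <- nchar(pattern)
  n <- length(seq_chars)
  hits <- data.frame(start = numeric(), end = numeric(),
                     strand = character())
  if (n >= w) {
    fwd_chars <- strsplit(pattern, "")[[1]]
    rev_chars <- strsplit(revcomp_pattern(pattern), "")[[1]]
    for (pos in 1:(n - w + 1)) {
      f <- match_at(fwd_chars, pos)
      r <- match_at(rev_chars, pos)
      if (f)
        hits <- rbind(hits, data.frame(start = pos - 1, end = pos - 1 + w,
                                       strand = "+"))
      if (r && !f)
        hits <- rbind(hits, data.frame(start = pos - 1, end = pos - 1 + w,
                                       strand = "-"))
      if (r && f && revcomp_pattern(pattern) != pattern)
        hits <- rbind(hits, data.frame(start = pos - 1, end = pos - 1 + w,
                                       strand = "-"))
    }
  }
  # keep only "+" for identical intervals (palindromic dedup)
  key <- paste(hits$start, hits$end)
  dup <- duplicated(key) & hits$strand == "-"
  hits <- hits[!dup, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All-pairs quadratic oracle for peak-to-gene assignment.
brute_force_assign <- function(peaks, gm, window) {
  genes <- gm$genes
  intr <- introns(gm)
  rows <- list()
  for (p in seq_len(nrow(peaks))) {
    for (gi in seq_len(nrow(genes))) {
      ws <- max(0, genes$tx_start[gi] - window)
      we <- genes$tx_end[gi] + window
      if (peaks$chrom[p] != genes$chrom[gi]) next
      ov_s <- max(peaks$start[p], ws)
      ov_e <- min(peaks$end[p], we)
      if (ov_e - ov_s < 1) next
      mid <- (ov_s + ov_e - 1) %/% 2
      g <- genes$gene_id[gi]
      it <- intr[intr$gene_id == g & intr$start <= mid & mid < intr$end, ]
      ex <- gm$exons[gm$exons$gene_id == g, ]
      in_exon <- any(ex$start <= mid & mid < ex$end)
      upstream <- if (genes$strand[gi] == "-")
        genes$tx_end[gi] <= mid && mid < genes$tx_end[gi] + window
      else genes$tx_start[gi] - window <= mid && mid < genes$tx_start[gi]
      context <- if (nrow(it) > 0) "intronic" else if (in_exon) "exonic"
        else if (upstream) "promoter" else "flanking"
      rows[[length(rows) + 1]] <- data.frame(
        peak = p, gene_id = g, context = context,
        intron_index = if (nrow(it) > 0) it$intron_index[1] else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peak = integer(), gene_id = character(),
                      context = character(), intron_index = integer())
  out[order(out$peak, out$gene_id), , drop = FALSE]
}

chi2_closed_form <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# A two-gene toy model: gene A ("+", exons [0,100) and [200,300)) and gene B
# ("-", exons [1000,1100), [1300,1400), [1600,1700)).
toy_gene_models <- function() {
  gene_models(
    genes = data.frame(
      gene_id = c("geneA", "geneB"), chrom = "chr1",
      strand = c("+", "-"), tx_start = c(0, 1000), tx_end = c(300, 1700),
      family = c("SLC", NA), stringsAsFactors = FALSE),
    exons = data.frame(
      gene_id = c("geneA", "geneA", "geneB", "geneB", "geneB"),
      start = c(0, 200, 1000, 1300, 1600),
      end = c(100, 300, 1100, 1400, 1700),
      stringsAsFactors = FALSE)
  )
}

# Scaled-down synthetic scenario for fast unit tests (any default can be
# overridden through ...).
small_config <- function(seed = 5, ...) {
  args <- list(
    n_chromosomes = 2, chrom_length = 330000, n_genes = 14,
    fraction_slc = 10 / 14, n_shared = 6, n_g1_only = 2, n_g2_only = 1,
    n_nonslc_regulated = 1, n_gata2_occupied = 5, n_gata1_occupied = 4,
    n_accessible = 5, n_planted_enhancers = 3, n_registry_extra = 10,
    n_phenotype = 2, seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

# Truth object with the given named planted GATA1 effects over three genes.
null_truth_with <- function(lfc1, ids = c("g001", "g002", "g003")) {
  tr <- null_truth(ids)
  tr$genes$lfc_gata1[match(names(lfc1), ids)] <- lfc1
  tr$genes$dir_gata1 <- ifelse(tr$genes$lfc_gata1 > 0, "up",
                               ifelse(tr$genes$lfc_gata1 < 0, "down",
                                      "none"))
  tr
}

# Random regulation_calls over a gene universe.
random_calls <- function(universe, n, factor_name) {
  ids <- sample(universe, n)
  regulation_calls(ids, factor_name,
                   sample(c("activated", "repressed"), n, replace = TRUE),
                   fold_change = stats::runif(n, 1.5, 50))
}
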