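# Peak-to-gene assignment, genomic-context classification, gene-level
# occupancy summaries, and predicted intronic enhancer calling: a GATA2
# ChIP peak footprint clipped to an intron, overlapping accessible
# chromatin, containing at least one WGATAR motif.

#' Assign peaks to genes and classify their genomic context
#'
#' A peak is assigned to a gene iff it overlaps the gene's transcript
#' extended by `window` bp on each side by at least 1 bp. Context is decided
#' by the midpoint of the overlap: `intronic` (with the strand-aware intron
#' index) if the midpoint falls in an intron, else `exonic` if in an exon,
#' else `promoter` if within `window` bp upstream of the TSS (strand-aware),
#' else `flanking`. Ties therefore resolve toward `intronic`. A peak may be
#' assigned to several genes, one record each.
#'
#' @param peaks A `genomic_intervals` data frame.
#' @param gm A `gene_models` object.
#' @param window Assignment window in bp (default 10000), >= 0.
#' @param assay Optional assay label stored on each record.
#' @return A data.frame with columns `peak_name`, `chrom`, `peak_start`,
#'   `peak_end`, `gene_id`, `context`, `intron_index` (NA unless intronic),
#'   `assay`.
#' @export
assign_peaks_to_genes <- function(peaks, gm, window = 10000, assay = NA) {
  if (window < 0) stop("window must be >= 0")
  genes <- gm$genes
  gwin <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tx_start - window),
                     end = genes$tx_end + window,
                     strand = ".",
                     stringsAsFactors = FALSE)
  op <- overlap_pairs(peaks, gwin)
  n <- nrow(op)
  if (n == 0) return(empty_assignments())
  intr <- introns(gm)
  ex <- gm$exons
  out <- vector("list", n)
  for (r in seq_len(n)) {
    p <- op$query[r]; gi <- op$subject[r]
    ov_start <- max(peaks$start[p], gwin$start[gi])
    ov_end <- min(peaks$end[p], gwin$end[gi])
    mid <- (ov_start + ov_end - 1) %/% 2
    g <- genes$gene_id[gi]
    context <- "flanking"
    intron_index <- NA_integer_
    gi_intr <- intr[intr$gene_id == g, , drop = FALSE]
    hit <- which(gi_intr$start <= mid & mid < gi_intr$end)
    if (length(hit)) {
      context <- "intronic"
      intron_index <- gi_intr$intron_index[hit[1]]
    } else {
      gi_ex <- ex[ex$gene_id == g, , drop = FALSE]
      if (any(gi_ex$start <= mid & mid < gi_ex$end)) {
        context <- "exonic"
      } else {
        upstream <- if (genes$strand[gi] == "-") {
          genes$tx_end[gi] <= mid & mid < genes$tx_end[gi] + window
        } else {
          genes$tx_start[gi] - window <= mid & mid < genes$tx_start[gi]
        }
        if (upstream) context <- "promoter"
      }
    }
    out[[r]] <- data.frame(
      peak_name = peaks$name[p], chrom = peaks$chrom[p],
      peak_start = peaks$start[p], peak_end = peaks$end[p],
      gene_id = g, context = context, intron_index = intron_index,
      assay = assay, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_assignments <- function() {
  data.frame(peak_name = character(), chrom = character(),
             peak_start = numeric(), peak_end = numeric(),
             gene_id = character(), context = character(),
             intron_index = integer(), assay = character(),
             stringsAsFactors = FALSE)
}

#' Call predicted intronic enhancers
#'
#' For every GATA2 peak assigned to a gene, each non-empty intersection of
#' the peak with an intron of that gene becomes a candidate (a peak spanning
#' two introns yields one candidate per intron footprint). Candidates are
#' annotated with >= 1 bp overlap flags against GATA1 peaks, ATAC peaks and
#' cCREs, and with WGATAR and E-box hits from scanning the footprint
#' sequence on both strands. A candidate is emitted as a predicted intronic
#' enhancer iff it is GATA2-occupied (by construction), accessible, and
#' carries at least one WGATAR hit; GATA1 occupancy and cCRE overlap are
#' annotations only.
#'
#' @param gata2_assignments Assignments of GATA2 peaks from
#'   [assign_peaks_to_genes()].
#' @param gm A `gene_models` object.
#' @param sequences Named character vector, chromosome -> DNA string.
#' @param atac_peaks,ccres,gata1_peaks `genomic_intervals` frames.
#' @return A data.frame with columns `gene_id`, `intron_index`, `chrom`,
#'   `start`, `end`, `gata1_occupied`, `gata2_occupied`, `accessible`,
#'   `ccre_overlap`, `n_wgatar`, `n_ebox`, `predicted_enhancer`.
#' @export
call_intronic_enhancers <- function(gata2_assignments, gm, sequences,
                                    atac_peaks, ccres, gata1_peaks) {
  asn <- unique(gata2_assignments[, c("chrom", "peak_start", "peak_end",
                                      "gene_id")])
  missing <- setdiff(unique(asn$chrom), names(sequences))
  if (length(missing))
    stop("peak chromosome missing from genome sequences: ",
         paste(missing, collapse = ", "))
  intr <- introns(gm)
  rows <- vector("list", 0)
  for (r in seq_len(nrow(asn))) {
    gi_intr <- intr[intr$gene_id == asn$gene_id[r], , drop = FALSE]
    if (nrow(gi_intr) == 0) next
    s <- pmax(asn$peak_start[r], gi_intr$start)
    e <- pmin(asn$peak_end[r], gi_intr$end)
    keep <- which(e > s)
    for (k in keep) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = asn$gene_id[r], intron_index = gi_intr$intron_index[k],
        chrom = asn$chrom[r], start = s[k], end = e[k],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty_enhancers())
  cand <- unique(do.call(rbind, rows))
  rownames(cand) <- NULL
  wg <- motif_wgatar()
  eb <- motif_ebox()
  footprint <- vapply(seq_len(nrow(cand)), function(i)
    substr(sequences[[cand$chrom[i]]], cand$start[i] + 1, cand$end[i]), "")
  cand$gata1_occupied <- overlaps_any(cand, gata1_peaks)
  cand$gata2_occupied <- TRUE
  cand$accessible <- overlaps_any(cand, atac_peaks)
  cand$ccre_overlap <- overlaps_any(cand, ccres)
  cand$n_wgatar <- vapply(footprint, function(s) nrow(scan_motif(s, wg)), 0L,
                          USE.NAMES = FALSE)
  cand$n_ebox <- vapply(footprint, function(s) nrow(scan_motif(s, eb)), 0L,
                        USE.NAMES = FALSE)
  cand$predicted_enhancer <- cand$gata2_occupied & cand$accessible &
    cand$n_wgatar >= 1
  cand <- cand[order(cand$chrom, cand$start, cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("gene_id", "intron_index", "chrom", "start", "end",
           "gata1_occupied", "gata2_occupied", "accessible", "ccre_overlap",
           "n_wgatar", "n_ebox", "predicted_enhancer")]
}

empty_enhancers <- function() {
  data.frame(gene_id = character(), intron_index = integer(),
             chrom = character(), start = numeric(), end = numeric(),
             gata1_occupied = logical(), gata2_occupied = logical(),
             accessible = logical(), ccre_overlap = logical(),
             n_wgatar = integer(), n_ebox = integer(),
             predicted_enhancer = logical(), stringsAsFactors = FALSE)
}

#' Gene-level occupancy summary across assays
#'
#' @param genes Character vector of gene ids (rows of the summary).
#' @param assignments A data.frame of peak assignments carrying an `assay`
#'   column (rbind of per-assay [assign_peaks_to_genes()] outputs).
#' @param assays Assay columns to report (default GATA1, GATA2, ATAC, cCRE).
#' @return A data.frame, one row per gene, one logical column per assay,
#'   with marginal counts in attribute `"marginals"`.
#' @export
occupancy_summary <- function(genes, assignments,
                              assays = c("GATA1", "GATA2", "ATAC", "cCRE")) {
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (a in assays) {
    hit <- unique(assignments$gene_id[assignments$assay %in% a])
    out[[a]] <- out$gene_id %in% hit
  }
  attr(out, "marginals") <- vapply(assays, function(a) sum(out[[a]]), 0)
  out
}
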