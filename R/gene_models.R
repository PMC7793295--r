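# Gene models: one transcript per gene, exons as disjoint 0-based half-open
# intervals, introns derived as the gaps between consecutive exons. Intron
# index 1 is the first intron in transcription order (strand-aware; unknown
# strand "." is ordered like "+").

#' Construct gene models
#'
#' @param genes A data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` (0-based half-open) and optionally `family`
#'   (registry label such as `"SLC"`; `NA` when unlabeled).
#' @param exons A data.frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open), one row per exon.
#' @return An object of class `gene_models`: a list with elements `genes`
#'   and `exons` (exons sorted by gene then coordinate).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tx_start", "tx_end")
                %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (!"family" %in% names(genes)) genes$family <- NA_character_
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene models")
  if (any(genes$tx_end <= genes$tx_start))
    stop("tx_end must be > tx_start")
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exon with unknown gene_id")
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  # per-gene validation: exons disjoint and contained in [tx_start, tx_end)
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    gi <- genes[genes$gene_id == g, ]
    if (any(e$end <= e$start)) stop("exon end <= start in gene ", g)
    if (e$start[1] < gi$tx_start || e$end[nrow(e)] > gi$tx_end)
      stop("exons outside transcript bounds in gene ", g)
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in gene ", g)
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Derive introns from gene models
#'
#' Introns are the gaps between consecutive exons. `intron_index` counts in
#' transcription order: for `-` strand genes the most 3'-in-coordinates gap
#' is intron 1.
#'
#' @param gm A `gene_models` object.
#' @param gene_ids Optional subset of genes.
#' @return A data.frame with columns `gene_id`, `intron_index`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
introns <- function(gm, gene_ids = NULL) {
  genes <- gm$genes
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids, ]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    e <- gm$exons[gm$exons$gene_id == g, , drop = FALSE]
    if (nrow(e) < 2) { out[[i]] <- NULL; next }
    s <- e$end[-nrow(e)]
    t <- e$start[-1]
    keep <- t > s   # zero-length gaps are not introns
    s <- s[keep]; t <- t[keep]
    if (length(s) == 0) { out[[i]] <- NULL; next }
    k <- length(s)
    idx <- if (genes$strand[i] == "-") rev(seq_len(k)) else seq_len(k)
    out[[i]] <- data.frame(gene_id = g, intron_index = idx,
                           chrom = genes$chrom[i], start = s, end = t,
                           strand = genes$strand[i],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), intron_index = integer(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input must carry `gene` features (with `ID`) and `exon` features
#' (with `Parent`); its 1-based closed coordinates are converted to 0-based
#' half-open on read. BED12 blocks become exons.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (dialect == "gff3") read_gene_models_gff3(path) else
    read_gene_models_bed12(path)
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  gdf <- df[df$type == "gene", , drop = FALSE]
  edf <- df[df$type == "exon", , drop = FALSE]
  if (nrow(gdf) == 0) stop("no gene features in GFF3: ", path)
  strand <- as.character(gdf$strand)
  strand[strand == "*"] <- "."
  genes <- data.frame(
    gene_id = as.character(gdf$ID),
    chrom = as.character(gdf$seqnames),
    strand = strand,
    tx_start = gdf$start - 1,
    tx_end = as.numeric(gdf$end),
    family = if ("family" %in% names(gdf)) as.character(gdf$family)
             else NA_character_,
    stringsAsFactors = FALSE
  )
  parent <- vapply(edf$Parent, function(p) as.character(p)[1], "")
  exons <- data.frame(
    gene_id = parent,
    start = edf$start - 1,
    end = as.numeric(edf$end),
    stringsAsFactors = FALSE
  )
  gene_models(genes, exons)
}

read_gene_models_bed12 <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 12) stop("BED12 requires 12 columns: ", path)
  genes <- data.frame(
    gene_id = x[[4]], chrom = x[[1]], strand = x[[6]],
    tx_start = as.numeric(x[[2]]), tx_end = as.numeric(x[[3]]),
    family = NA_character_, stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    sizes <- as.numeric(strsplit(sub(",$", "", x[i, 11]), ",")[[1]])
    offs <- as.numeric(strsplit(sub(",$", "", x[i, 12]), ",")[[1]])
    if (length(sizes) != x[i, 10] || length(offs) != x[i, 10])
      stop("BED12 block count mismatch for ", x[i, 4])
    data.frame(gene_id = x[i, 4],
               start = x[i, 2] + offs,
               end = x[i, 2] + offs + sizes,
               stringsAsFactors = FALSE)
  }))
  gene_models(genes, exons)
}

#' Write gene models to GFF3
#'
#' Coordinates are converted to GFF3's 1-based closed convention on write,
#' so a write/read round trip is the identity.
#'
#' @param gm A `gene_models` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(gm, path) {
  g <- gm$genes
  e <- gm$exons
  gstr <- ifelse(g$strand == ".", "*", g$strand)
  gr_genes <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$tx_start + 1, g$tx_end), gstr,
    type = "gene", ID = g$gene_id,
    family = g$family
  )
  gi <- match(e$gene_id, g$gene_id)
  gr_exons <- GenomicRanges::GRanges(
    g$chrom[gi],
    IRanges::IRanges(e$start + 1, e$end), gstr[gi],
    type = "exon",
    ID = paste0(e$gene_id, ".e", stats::ave(e$start, e$gene_id,
                                            FUN = seq_along)),
    family = NA_character_
  )
  S4Vectors::mcols(gr_genes)$Parent <- IRanges::CharacterList(
    rep(list(character()), length(gr_genes)))
  S4Vectors::mcols(gr_exons)$Parent <- IRanges::CharacterList(
    as.list(e$gene_id))
  all <- c(gr_genes, gr_exons)
  all <- all[order(as.character(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all),
                   S4Vectors::mcols(all)$type != "gene")]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
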