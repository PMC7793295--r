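# Venn partitioning of regulated-gene calls into factor-specific and
# co-regulated cohorts, four-way direction groups over the shared cohort,
# and substrate-class enrichment against the full transporter registry.

SUBSTRATE_CLASSES <- c("amino acid", "metal", "nucleoside/nucleotide",
                       "vitamin", "other")
LOCALIZATIONS <- c("plasma membrane", "mitochondria", "ER/Golgi",
                   "lysosome", "unknown")

#' Read a transporter-family registry (TSV)
#'
#' Expected columns: `gene_id`, `family` (e.g. `Slc29`), `substrate_class`
#' (one of `amino acid`, `metal`, `nucleoside/nucleotide`, `vitamin`,
#' `other`), `localization` (one of `plasma membrane`, `mitochondria`,
#' `ER/Golgi`, `lysosome`, `unknown`) and optionally `phenotype` (logical:
#' reported hematopoietic-relevant phenotype).
#'
#' @param path Input TSV with header.
#' @return A data.frame of class `transporter_registry`.
#' @export
read_transporter_registry <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  transporter_registry(x)
}

#' Construct/validate a transporter registry
#'
#' @param x Data.frame with the columns documented in
#'   [read_transporter_registry()].
#' @return A validated `transporter_registry` data.frame.
#' @export
transporter_registry <- function(x) {
  need <- c("gene_id", "family", "substrate_class", "localization")
  if (!all(need %in% names(x)))
    stop("registry requires columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id in registry")
  bad <- !x$substrate_class %in% SUBSTRATE_CLASSES
  if (any(bad))
    stop("unknown substrate class: ",
         paste(unique(x$substrate_class[bad]), collapse = ", "))
  bad <- !x$localization %in% LOCALIZATIONS
  if (any(bad))
    stop("unknown localization: ",
         paste(unique(x$localization[bad]), collapse = ", "))
  if (!"phenotype" %in% names(x)) x$phenotype <- FALSE
  x$phenotype <- as.logical(x$phenotype)
  class(x) <- c("transporter_registry", "data.frame")
  x
}

#' Write a transporter registry (TSV)
#' @param registry A `transporter_registry`.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_transporter_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Internal: check one call per gene per factor.
check_unique_calls <- function(calls) {
  if (nrow(calls) == 0) return(invisible(calls))
  dup <- duplicated(calls$gene_id)
  if (any(dup)) {
    g <- calls$gene_id[dup][1]
    d <- unique(calls$direction[calls$gene_id == g])
    if (length(d) > 1)
      stop("conflicting calls for gene ", g, " (", calls$factor[1], ")")
    stop("duplicate call for gene ", g, " (", calls$factor[1], ")")
  }
  invisible(calls)
}

#' Partition two factors' regulation calls into Venn cohorts
#'
#' Produces the three pairwise-disjoint Venn sets (genes regulated by the
#' first factor only, the second only, or both) and, over the shared set,
#' the four direction groups keyed `"up/up"`, `"up/down"`, `"down/up"`,
#' `"down/down"` with the GATA2 direction first (`up` = activated).
#'
#' @param calls_g1 `regulation_calls` for GATA1 (or the first factor).
#' @param calls_g2 `regulation_calls` for GATA2 (or the second factor).
#' @return An object of class `cohort_partition`: list with `g1_only`,
#'   `g2_only`, `shared` (sorted character vectors) and `direction_groups`
#'   (named list of four sorted character vectors, GATA2 direction first).
#' @export
partition_cohorts <- function(calls_g1, calls_g2) {
  check_unique_calls(calls_g1)
  check_unique_calls(calls_g2)
  s1 <- unique(calls_g1$gene_id)
  s2 <- unique(calls_g2$gene_id)
  shared <- sort(intersect(s1, s2))
  dir1 <- stats::setNames(calls_g1$direction, calls_g1$gene_id)
  dir2 <- stats::setNames(calls_g2$direction, calls_g2$gene_id)
  updown <- function(d) ifelse(d == "activated", "up", "down")
  keys <- paste(updown(dir2[shared]), updown(dir1[shared]), sep = "/")
  groups <- lapply(c("up/up", "up/down", "down/up", "down/down"),
                   function(k) sort(shared[keys == k]))
  names(groups) <- c("up/up", "up/down", "down/up", "down/down")
  structure(list(
    g1_only = sort(setdiff(s1, s2)),
    g2_only = sort(setdiff(s2, s1)),
    shared = shared,
    direction_groups = groups
  ), class = "cohort_partition")
}

#' @export
print.cohort_partition <- function(x, ...) {
  cat("cohort_partition:", length(x$g1_only), "factor-1 only,",
      length(x$g2_only), "factor-2 only,", length(x$shared), "shared\n")
  cat(" direction groups (GATA2/GATA1):",
      paste(names(x$direction_groups), lengths(x$direction_groups),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Direction group of a co-regulated gene
#'
#' @param gene Gene id present in both call sets.
#' @param calls_g1,calls_g2 `regulation_calls` for the two factors.
#' @return The group key `"<GATA2 dir>/<GATA1 dir>"`, with `up` = activated.
#' @export
direction_group_of <- function(gene, calls_g1, calls_g2) {
  d1 <- calls_g1$direction[calls_g1$gene_id == gene]
  d2 <- calls_g2$direction[calls_g2$gene_id == gene]
  if (length(d1) == 0 || length(d2) == 0)
    stop("gene ", gene, " is not in both cohorts")
  updown <- function(d) ifelse(d == "activated", "up", "down")
  paste(updown(d2[1]), updown(d1[1]), sep = "/")
}

#' Substrate-class enrichment of a cohort against the registry ensemble
#'
#' Builds the 2x2 table (in/out of cohort) x (in/out of class) over the full
#' registry and applies Pearson's chi-square test (1 df, no continuity
#' correction). The chi-square statistic is always reported; when any
#' expected cell count is below 5 the p-value comes from Fisher's exact test
#' instead, flagged in `method`.
#'
#' @param cohort Non-empty character vector of gene ids, a subset of the
#'   registry.
#' @param class_label One of the substrate-class vocabulary.
#' @param registry A `transporter_registry`.
#' @return A one-row data.frame: `class`, `count_in_cohort`,
#'   `count_in_ensemble`, `cohort_size`, `ensemble_size`, `statistic`
#'   (chi-square), `p_value`, `method` (`"chisq"` or `"fisher"`).
#' @export
substrate_enrichment <- function(cohort, class_label, registry) {
  if (length(cohort) == 0) stop("empty cohort")
  if (!class_label %in% SUBSTRATE_CLASSES)
    stop("unknown substrate class: ", class_label)
  missing <- setdiff(cohort, registry$gene_id)
  if (length(missing))
    stop("cohort genes absent from registry: ",
         paste(utils::head(missing, 3), collapse = ", "))
  in_class <- registry$gene_id[registry$substrate_class == class_label]
  if (length(in_class) == 0)
    stop("no registry members in class: ", class_label)
  n <- nrow(registry)
  a <- length(intersect(cohort, in_class))            # cohort & class
  b <- length(cohort) - a                             # cohort & !class
  c_ <- length(in_class) - a                          # !cohort & class
  d <- n - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat <- unname(ct$statistic)
  if (any(expected < 5)) {
    # small expected counts: keep the statistic, guard the p-value
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- ct$p.value
    method <- "chisq"
  }
  data.frame(class = class_label,
             count_in_cohort = a,
             count_in_ensemble = length(in_class),
             cohort_size = length(cohort),
             ensemble_size = n,
             statistic = stat,
             p_value = p,
             method = method,
             stringsAsFactors = FALSE)
}
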