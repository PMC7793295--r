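# Per-gene fold changes with Welch t-tests on log2(TPM + pseudocount) and
# Benjamini-Hochberg FDR, followed by the >= 1.5-fold regulated-gene call.

#' Compute per-gene fold changes between two conditions
#'
#' `log2fc = log2((mean_b + pc) / (mean_a + pc))`. Significance is a
#' two-sided unpaired t-test on `log2(value + pc)`: Student's test by
#' default (exact at the small replicate numbers typical here, and matching
#' the generator's homoscedastic noise), Welch's with `var_equal = FALSE`.
#' When both groups have zero variance the p-value is 1 if the means agree
#' and 0 otherwise, and a group with fewer than two replicates yields p = 1
#' with `tested = FALSE`. Benjamini-Hochberg FDR is computed across all
#' retained genes. Genes expressed in neither condition (both means below
#' the pseudocount) are dropped before FDR correction when
#' `drop_unexpressed = TRUE`.
#'
#' @param expr An `expr_matrix`.
#' @param group_a,group_b Condition labels present in `expr$groups`; fold
#'   changes are b vs a.
#' @param pseudocount Pseudocount in TPM units (default 0.5; may be 0, in
#'   which case zero-expression genes give non-finite log2fc).
#' @param var_equal Use the pooled-variance Student test (default TRUE);
#'   FALSE gives Welch's test.
#' @param drop_unexpressed Drop genes with both means below the pseudocount
#'   before testing (default TRUE; ignored when `pseudocount` is 0).
#' @return A data.frame with columns `gene_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `p_value`, `fdr`, `tested`.
#' @export
compute_fold_changes <- function(expr, group_a, group_b, pseudocount = 0.5,
                                 var_equal = TRUE,
                                 drop_unexpressed = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"), pseudocount >= 0)
  a <- expr$values[, group_columns(expr, group_a), drop = FALSE]
  b <- expr$values[, group_columns(expr, group_b), drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  pc <- pseudocount
  keep <- rep(TRUE, nrow(a))
  if (drop_unexpressed && pc > 0) keep <- mean_a >= pc | mean_b >= pc
  la <- log2(a + pc)
  lb <- log2(b + pc)
  can_test <- ncol(a) >= 2 && ncol(b) >= 2
  pvec <- vapply(seq_len(nrow(a)), function(i) {
    if (!keep[i]) return(NA_real_)
    if (!can_test) return(1)
    va <- la[i, ]; vb <- lb[i, ]
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      return(if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0)
    }
    stats::t.test(vb, va, var.equal = var_equal)$p.value
  }, 0)
  out <- data.frame(
    gene_id = rownames(expr$values),
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = log2((mean_b + pc) / (mean_a + pc)),
    p_value = pvec,
    tested = can_test,
    stringsAsFactors = FALSE
  )
  out <- out[keep, , drop = FALSE]
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("gene_id", "mean_a", "mean_b", "log2fc", "p_value", "fdr",
          "tested")]
}

#' Call regulated genes at a fold-change and FDR threshold
#'
#' A gene is called iff its fold-change magnitude `max(FC, 1/FC)` is at
#' least `fold_threshold` (inclusive) and `fdr <= fdr_threshold`, optionally
#' restricted to a gene family. Direction is expressed as the factor's
#' action: with `active_condition = "b"` (a gain-of-function contrast such
#' as GATA1 induction), genes up in b are "activated"; with
#' `active_condition = "a"` (a loss-of-function contrast such as a GATA2
#' enhancer knockout where condition b lacks the factor), genes down in b
#' are "activated".
#'
#' @param records Output of [compute_fold_changes()].
#' @param factor_name `"GATA1"` or `"GATA2"` (free label, carried through).
#' @param fold_threshold Fold-change magnitude threshold, >= 1 (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param active_condition `"b"` or `"a"`: the condition in which the factor
#'   is active (default `"b"`).
#' @param family_filter Optional registry label; with `families`, restricts
#'   calls to genes of that family.
#' @param families Named character vector gene_id -> family label.
#' @return A data.frame of class `regulation_calls` with columns `gene_id`,
#'   `factor`, `direction` (`"activated"`/`"repressed"`), `fold_change`
#'   (magnitude, >= threshold), `log2fc`, `fdr`.
#' @export
call_regulated_genes <- function(records, factor_name,
                                 fold_threshold = 1.5, fdr_threshold = 0.05,
                                 active_condition = c("b", "a"),
                                 family_filter = NULL, families = NULL) {
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  active_condition <- match.arg(active_condition)
  r <- records
  # inclusive threshold, compared on the log2 scale with a small tolerance
  pass_fc <- abs(r$log2fc) >= log2(fold_threshold) - 1e-12
  pass_fdr <- !is.na(r$fdr) & r$fdr <= fdr_threshold
  keep <- pass_fc & pass_fdr
  if (!is.null(family_filter)) {
    if (is.null(families))
      stop("family_filter requires a gene -> family map")
    keep <- keep & !is.na(families[r$gene_id]) &
      families[r$gene_id] == family_filter
  }
  r <- r[keep, , drop = FALSE]
  effect <- if (active_condition == "b") r$log2fc else -r$log2fc
  out <- data.frame(
    gene_id = r$gene_id,
    factor = rep(factor_name, nrow(r)),
    direction = ifelse(effect > 0, "activated", "repressed"),
    fold_change = 2^abs(r$log2fc),
    log2fc = r$log2fc,
    fdr = r$fdr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Construct a set of regulation calls directly
#'
#' Useful for working with published cohort listings where only gene sets
#' and directions are known (fold changes and FDRs default to placeholder
#' values that pass the standard thresholds).
#'
#' @param gene_id Character vector of gene ids.
#' @param factor_name Factor label, e.g. `"GATA1"`.
#' @param direction `"activated"` or `"repressed"`, recycled.
#' @param fold_change Fold-change magnitudes (>= 1), recycled.
#' @param fdr FDR values, recycled.
#' @return A `regulation_calls` data.frame.
#' @export
regulation_calls <- function(gene_id, factor_name, direction,
                             fold_change = 2, fdr = 0.01) {
  n <- length(gene_id)
  out <- data.frame(
    gene_id = gene_id,
    factor = rep_len(factor_name, n),
    direction = rep_len(direction, n),
    fold_change = rep_len(fold_change, n),
    log2fc = log2(rep_len(fold_change, n)),
    fdr = rep_len(fdr, n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("regulation_calls", "data.frame")
  out
}
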