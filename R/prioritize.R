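# Ranking of regulated genes by fold-change magnitude and a transparent
# linear evidence score over occupancy / accessibility / enhancer /
# phenotype flags.

#' Top-k genes of one direction by fold-change magnitude
#'
#' Ties in magnitude are broken alphabetically by gene id, so the output is
#' a prefix of one deterministic total order (extending `k` never reorders).
#'
#' @param calls A `regulation_calls` data.frame.
#' @param direction `"activated"` or `"repressed"`.
#' @param k Number of genes to return (>= 1; `k > n` returns all).
#' @return Character vector of gene ids, strongest first.
#' @export
rank_top_k <- function(calls, direction, k) {
  if (k < 1) stop("k must be >= 1")
  r <- calls[calls$direction == direction, , drop = FALSE]
  r <- r[order(-r$fold_change, r$gene_id), , drop = FALSE]
  utils::head(r$gene_id, k)
}

#' Default evidence weights for the priority score
#'
#' @return Named numeric vector: `fc` (weight on log2 fold-change magnitude),
#'   one unit weight per evidence flag, and weight 2 for a reported
#'   phenotype.
#' @export
default_priority_weights <- function() {
  c(fc = 1, gata1_occupied = 1, gata2_occupied = 1, accessible = 1,
    ccre = 1, has_intronic_enhancer = 1, phenotype = 2)
}

#' Linear priority score
#'
#' `score = w_fc * log2(fold_change) + sum(w_flag * flag)` with nonnegative
#' weights, so setting any flag can never decrease the score.
#'
#' @param fold_change Fold-change magnitude (>= 1).
#' @param flags Named logical vector over the flag names in
#'   [default_priority_weights()] (missing flags count as FALSE).
#' @param weights Nonnegative named weights (default
#'   [default_priority_weights()]).
#' @return Numeric score >= 0.
#' @export
priority_score <- function(fold_change, flags = c(),
                           weights = default_priority_weights()) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  flag_names <- setdiff(names(weights), "fc")
  fl <- stats::setNames(rep(FALSE, length(flag_names)), flag_names)
  fl[intersect(names(flags), flag_names)] <-
    as.logical(flags[intersect(names(flags), flag_names)])
  unname(weights["fc"] * log2(fold_change) +
           sum(weights[flag_names] * fl))
}

#' Rank co-regulated candidate genes with full evidence columns
#'
#' Restricted to the co-regulated (shared) cohort. Each gene's fold-change
#' magnitude is the larger of its two factors' magnitudes; evidence flags
#' come from the occupancy summary, the predicted-enhancer set and the
#' registry phenotype column. Ordering: score (descending), then fold-change
#' magnitude (descending), then gene id.
#'
#' @param partition A `cohort_partition`.
#' @param occupancy Output of [occupancy_summary()].
#' @param enhancers Output of [call_intronic_enhancers()].
#' @param registry A `transporter_registry`.
#' @param calls_g1,calls_g2 The two factors' `regulation_calls`.
#' @param k Number of candidates to return (default 10).
#' @param weights Score weights (default [default_priority_weights()]).
#' @return A data.frame with columns `rank`, `gene_id`, `fold_change`,
#'   `direction_group`, the evidence flags and `score`; empty (with a
#'   warning) if the shared cohort is empty.
#' @export
select_candidates <- function(partition, occupancy, enhancers, registry,
                              calls_g1, calls_g2, k = 10,
                              weights = default_priority_weights()) {
  genes <- partition$shared
  if (length(genes) == 0) {
    warning("shared cohort is empty; no candidates")
    return(data.frame(rank = integer(), gene_id = character(),
                      fold_change = numeric(), direction_group = character(),
                      gata1_occupied = logical(), gata2_occupied = logical(),
                      accessible = logical(), ccre = logical(),
                      has_intronic_enhancer = logical(),
                      phenotype = logical(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  fc1 <- stats::setNames(calls_g1$fold_change, calls_g1$gene_id)
  fc2 <- stats::setNames(calls_g2$fold_change, calls_g2$gene_id)
  occ <- occupancy[match(genes, occupancy$gene_id), , drop = FALSE]
  enh_genes <- unique(enhancers$gene_id[enhancers$predicted_enhancer])
  pheno <- stats::setNames(registry$phenotype, registry$gene_id)
  out <- data.frame(
    gene_id = genes,
    fold_change = pmax(fc1[genes], fc2[genes]),
    direction_group = vapply(genes, direction_group_of, "",
                             calls_g1 = calls_g1, calls_g2 = calls_g2),
    gata1_occupied = isTRUE_vec(occ$GATA1),
    gata2_occupied = isTRUE_vec(occ$GATA2),
    accessible = isTRUE_vec(occ$ATAC),
    ccre = isTRUE_vec(occ$cCRE),
    has_intronic_enhancer = genes %in% enh_genes,
    phenotype = isTRUE_vec(pheno[genes]),
    stringsAsFactors = FALSE
  )
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    priority_score(out$fold_change[i],
                   c(gata1_occupied = out$gata1_occupied[i],
                     gata2_occupied = out$gata2_occupied[i],
                     accessible = out$accessible[i],
                     ccre = out$ccre[i],
                     has_intronic_enhancer = out$has_intronic_enhancer[i],
                     phenotype = out$phenotype[i]),
                   weights)
  }, 0)
  out <- out[order(-out$score, -out$fold_change, out$gene_id), ,
             drop = FALSE]
  out <- utils::head(out, k)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
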