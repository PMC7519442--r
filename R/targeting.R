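#' Content-normalize the processed group's AUC
#'
#' The crude and salt-processed extracts are dosed at the same volume, but
#' the in-vitro content of a compound generally differs between them. To
#' make tissue AUCs comparable, the salt-processed group's AUC is divided
#' by the content ratio:
#' \deqn{AUC_{salt}' = AUC_{salt} / (content_{salt} / content_{crude})}
#' so any remaining difference reflects disposition, not dose.
#'
#' @param auc_salt_raw Salt-processed group AUC(s), ng.min/mL.
#' @param content_salt,content_crude Compound content per g of extract in
#'   each preparation (same units; both > 0).
#' @return Normalized AUC(s), ng.min/mL.
#' @examples
#' normalize_salt_auc(1000, content_salt = 2, content_crude = 1)  # 500
#' @export
normalize_salt_auc <- function(auc_salt_raw, content_salt, content_crude) {
  if (any(!is.finite(content_crude)) || any(content_crude <= 0))
    stop("content_crude must be > 0", call. = FALSE)
  if (any(!is.finite(content_salt)) || any(content_salt <= 0))
    stop("content_salt must be > 0", call. = FALSE)
  auc_salt_raw / (content_salt / content_crude)
}

#' Relative targeting efficiency per tissue
#'
#' For each group, every tissue's AUC is expressed as its fraction of the
#' group's summed multi-tissue AUC (heart + liver + spleen + lung + kidney
#' + gonads + uterus; an organ absent in one sex simply contributes its own
#' AUC where it exists and zero elsewhere). The relative targeting
#' efficiency compares the fractions:
#' \deqn{RTE = \frac{frac_{salt}}{frac_{crude}} - 1}
#' RTE > 0 means the processing step increased the tissue's share of total
#' exposure; the statistic is scale-free (invariant to multiplying either
#' group's AUCs by a constant), so the content normalization of
#' [normalize_salt_auc()] must be applied to the salt AUCs *before* calling
#' this when extract contents differ.
#'
#' @param auc_salt Named numeric: tissue -> content-normalized
#'   salt-processed AUC (ng.min/mL).
#' @param auc_crude Named numeric: tissue -> crude-group AUC, same tissue
#'   set.
#' @param compound Identifier carried on the result.
#' @return A `data.frame` of class `rte_result` with one row per tissue:
#'   `compound`, `tissue`, `auc_crude`, `auc_salt_normalized`, `frac_crude`,
#'   `frac_salt`, `rte`, `targeted` (`rte > 0`). A tissue with
#'   `frac_crude = 0` but `frac_salt > 0` gets `rte = Inf`.
#' @examples
#' compute_rte(auc_salt = c(kidney = 300, liver = 100),
#'             auc_crude = c(kidney = 150, liver = 150))
#' @export
compute_rte <- function(auc_salt, auc_crude, compound = NA_character_) {
  tissues <- names(auc_salt)
  if (is.null(tissues) || is.null(names(auc_crude)))
    stop("AUC vectors must be named by tissue", call. = FALSE)
  if (!setequal(tissues, names(auc_crude)))
    stop("the two groups cover different tissue sets", call. = FALSE)
  auc_crude <- auc_crude[tissues]
  if (any(auc_salt < 0) || any(auc_crude < 0))
    stop("negative AUC", call. = FALSE)
  sum_salt <- sum(auc_salt)
  sum_crude <- sum(auc_crude)
  if (sum_salt == 0 || sum_crude == 0)
    stop("summed AUC is zero in a group; RTE undefined", call. = FALSE)
  frac_salt <- auc_salt / sum_salt
  frac_crude <- auc_crude / sum_crude
  rte <- ifelse(frac_crude == 0,
                ifelse(frac_salt > 0, Inf, 0),
                frac_salt / frac_crude - 1)
  out <- data.frame(compound = compound, tissue = tissues,
                    auc_crude = as.numeric(auc_crude),
                    auc_salt_normalized = as.numeric(auc_salt),
                    frac_crude = as.numeric(frac_crude),
                    frac_salt = as.numeric(frac_salt),
                    rte = as.numeric(rte),
                    targeted = as.numeric(rte) > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rte_result", "data.frame")
  out
}

#' RTE for every compound in an AUC table
#'
#' Applies [normalize_salt_auc()] per compound (when contents are given)
#' and [compute_rte()] per compound over all tissues present in both
#' groups.
#'
#' @param tab AUC table from [auc_table()] containing both groups.
#' @param contents Optional `data.frame` with columns `compound`,
#'   `content_crude`, `content_salt`; compounds absent from it are used
#'   unnormalized (ratio 1).
#' @param groups Length-2 character: `c(salt_label, crude_label)`.
#' @return Row-bound `rte_result` across compounds.
#' @export
rte_table <- function(tab, contents = NULL,
                      groups = c("salt_processed", "crude")) {
  rows <- list()
  for (cp in unique(tab$compound)) {
    sub <- tab[tab$compound == cp, ]
    salt <- sub[sub$group == groups[1], ]
    crude <- sub[sub$group == groups[2], ]
    tis <- intersect(salt$tissue, crude$tissue)
    if (length(tis) == 0L) next
    a_salt <- stats::setNames(salt$auc[match(tis, salt$tissue)], tis)
    a_crude <- stats::setNames(crude$auc[match(tis, crude$tissue)], tis)
    if (!is.null(contents)) {
      i <- match(cp, contents$compound)
      if (!is.na(i))
        a_salt <- normalize_salt_auc(a_salt, contents$content_salt[i],
                                     contents$content_crude[i])
    }
    rows[[cp]] <- compute_rte(a_salt, a_crude, compound = cp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rte_result", "data.frame")
  out
}

#' Ranked targeting classification
#'
#' Tissues whose RTE exceeds `threshold` (default 0: any increase in the
#' tissue's share of total exposure counts as targeting), ranked by
#' decreasing RTE within each compound.
#'
#' @param results An `rte_result` (possibly multi-compound).
#' @param threshold RTE classification threshold.
#' @return `data.frame` with `compound`, `tissue`, `rte`, `rank`, sorted by
#'   compound then rank; zero rows when nothing exceeds the threshold.
#' @export
classify_targets <- function(results, threshold = 0) {
  hits <- results[results$rte > threshold, c("compound", "tissue", "rte"),
                  drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(compound = character(0), tissue = character(0),
                      rte = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  hits <- hits[order(hits$compound, -hits$rte), , drop = FALSE]
  hits$rank <- stats::ave(hits$rte, hits$compound,
                          FUN = function(v) seq_along(v))
  rownames(hits) <- NULL
  hits
}
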