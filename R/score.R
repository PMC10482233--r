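#' Correlation-weighted pseudotime score for an external cohort
#'
#' Projects each patient onto the trajectory with the score
#' `score_j = sum_i rho_i * x_ij` over the selected signature genes, where
#' `rho_i` is the Spearman correlation of gene `i` with pseudotime in the
#' spatial dataset and `x_ij` the patient's expression on the cohort's own
#' scale (no renormalization by the number of genes used). Genes are
#' matched by case-insensitive symbol; signature genes absent from the
#' cohort are dropped with a warning and listed in the result; duplicate
#' cohort symbols are collapsed by their mean. Patients are then split
#' into `low`/`intermediate`/`high` tertiles of the score via
#' [tertile_groups()].
#'
#' @param cohort A [cohort_dataset()] (or gene-by-patient matrix).
#' @param signature A [bonferroni_select()] result (selected genes are
#'   used), or any data frame with `gene` and `rho` columns.
#' @param zscore If `TRUE`, each matched gene is standardized across
#'   patients before scoring (off by default: the score is defined on the
#'   cohort's provided scale, and tertiles are scale-robust within a
#'   cohort).
#' @return A `scored_cohort` tibble with `patient_id`, `score`, `group`,
#'   plus attributes `n_genes_used` and `genes_missing`.
#' @export
#' @examples
#' sig <- tibble::tibble(gene = c("g1", "g2", "g3"), rho = c(0.9, -0.8, 0.7))
#' x <- matrix(c(2, 1, 3), nrow = 3, dimnames = list(sig$gene, "pt1"))
#' pseudotime_score(x, sig)$score # 0.9*2 - 0.8*1 + 0.7*3 = 3.1
pseudotime_score <- function(cohort, signature, zscore = FALSE) {
  x <- as_expr_matrix(cohort)
  sig <- as_tibble(signature)
  if (!all(c("gene", "rho") %in% names(sig))) {
    abort("`signature` needs `gene` and `rho` columns.")
  }
  if ("selected" %in% names(sig)) sig <- sig[isTRUE_vec(sig$selected), ]
  if (nrow(sig) == 0) abort("Signature has no selected genes.")

  sym <- toupper(rownames(x))
  if (anyDuplicated(sym)) {
    warn("Duplicate gene symbols in the cohort; collapsing by mean.")
    x <- rowsum(x, group = sym)
    x <- x / as.vector(table(sym)[rownames(x)])
  } else {
    rownames(x) <- sym
  }

  hit <- match(toupper(sig$gene), rownames(x))
  genes_missing <- sig$gene[is.na(hit)]
  if (all(is.na(hit))) abort("No signature gene matches the cohort matrix.")
  if (length(genes_missing)) {
    warn(paste0(length(genes_missing), " signature gene(s) missing from the",
                " cohort and dropped (e.g. ",
                paste(head(genes_missing, 3), collapse = ", "), ")."))
  }
  used <- sig[!is.na(hit), , drop = FALSE]
  xm <- x[hit[!is.na(hit)], , drop = FALSE]
  if (zscore) {
    mu <- rowMeans(xm)
    sdv <- apply(xm, 1, sd)
    sdv[sdv == 0] <- 1
    xm <- (xm - mu) / sdv
  }
  score <- drop(crossprod(xm, used$rho))
  if (!all(is.finite(score))) abort("Non-finite scores computed.")

  grp <- if (length(score) >= 3) {
    tertile_groups(unname(score), ids = colnames(x))
  } else {
    # tertiles are undefined below 3 patients; scores are still valid
    factor(rep(NA_character_, length(score)),
           levels = c("low", "intermediate", "high"))
  }
  out <- tibble(
    patient_id = colnames(x),
    score = unname(score),
    group = grp
  )
  structure(out, class = c("scored_cohort", class(out)),
            n_genes_used = nrow(used),
            genes_missing = genes_missing)
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat("<scored_cohort> ", nrow(x), " patients scored with ",
      attr(x, "n_genes_used"), " signature genes (",
      length(attr(x, "genes_missing")), " missing)\n", sep = "")
  NextMethod()
}

#' Tertile trichotomization of pseudotime scores
#'
#' Ranks scores ascending (ties broken deterministically by patient id)
#' and cuts the cohort into three contiguous rank blocks: the lowest
#' third becomes `low`, then `intermediate`, then `high`. When `n` is not
#' divisible by 3 the extra patients go to the earlier groups, so sizes
#' are `ceiling`-balanced (n = 10 gives 4/3/3) and never differ by more
#' than 1. Labels are invariant under any common strictly increasing
#' transform of the scores.
#'
#' @param scores Numeric vector.
#' @param ids Optional ids used for stable tie-breaking (defaults to the
#'   original order).
#' @return Factor with ordered levels `low`, `intermediate`, `high`.
#' @export
tertile_groups <- function(scores, ids = NULL) {
  n <- length(scores)
  if (n < 3) abort("Need at least 3 patients to form tertiles.")
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(scores, as.character(ids))
  sizes <- rep(n %/% 3, 3)
  rem <- n %% 3
  if (rem >= 1) sizes[1] <- sizes[1] + 1
  if (rem == 2) sizes[2] <- sizes[2] + 1
  lab <- rep(c("low", "intermediate", "high"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = c("low", "intermediate", "high"))
}
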