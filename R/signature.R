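#' Correlate every gene with the pseudotime
#'
#' Computes, per gene, the Spearman rank correlation between expression
#' across samples and the fitted pseudotime, with a two-sided p-value.
#' Ranks use the average-rank convention for ties. P-values follow the
#' standard `stats::cor.test()` Spearman path: the Edgeworth series
#' approximation (AS 89) when there are no ties, and the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` df otherwise — the
#' Edgeworth tail is markedly more accurate at the small sample sizes of
#' ROI panels, which matters because Bonferroni gating probes the extreme
#' tail. Being rank statistics, results are invariant under strictly
#' monotone transforms of either variable. Constant genes get `rho = 0`,
#' `p = 1`.
#'
#' @param normexpr Gene-by-sample matrix (normalized or log scale; ranks
#'   make the choice immaterial) or a [spatial_dataset()].
#' @param z Pseudotime vector aligned with the columns; >= 4 samples
#'   required for the p-value to carry information.
#' @param perm Optional number of seeded Monte-Carlo permutations; when
#'   given, an extra `p_perm` column holds the permutation p-value
#'   `(1 + #{|rho*| >= |rho|}) / (perm + 1)`.
#' @param seed Seed for the permutation draw.
#' @return Tibble with `gene`, `rho`, `p_raw` (and optionally `p_perm`).
#' @export
#' @examples
#' sim <- simulate_spatial(n_genes = 60, seed = 3)
#' y <- q3_normalize(sim$data)
#' correlate_genes(y, sim$true_pseudotime)
correlate_genes <- function(normexpr, z, perm = NULL, seed = 1) {
  x <- as_expr_matrix(normexpr)
  n <- ncol(x)
  if (n < 4) abort("Need at least 4 samples for correlation p-values.")
  if (length(z) != n) abort("`z` must align with the columns of the matrix.")

  constant <- apply(x, 1, function(r) all(r == r[1]))
  rho <- rep(0, nrow(x))
  p <- rep(1, nrow(x))
  idx <- which(!constant)
  for (i in idx) {
    ct <- suppressWarnings(
      cor.test(x[i, ], z, method = "spearman", exact = TRUE)
    )
    rho[i] <- unname(ct$estimate)
    p[i] <- min(1, ct$p.value)
  }
  out <- tibble(gene = rownames(x), rho = rho, p_raw = p)

  if (!is.null(perm)) {
    set.seed(as.integer(seed))
    rz <- rank(z)
    rx <- t(apply(x, 1, rank))
    obs <- abs(suppressWarnings(drop(cor(t(rx), rz))))
    obs[constant] <- 0
    hits <- rep(0, nrow(x))
    for (b in seq_len(perm)) {
      rp <- sample(rz)
      rb <- abs(suppressWarnings(drop(cor(t(rx), rp))))
      rb[constant] <- 0
      hits <- hits + (rb >= obs - 1e-12)
    }
    out$p_perm <- (1 + hits) / (perm + 1)
    out$p_perm[constant] <- 1
  }
  out
}

#' Bonferroni-gated pseudotime signature
#'
#' Applies the Bonferroni correction over all tested genes
#' (`p_adj = min(1, m * p_raw)`, `m` = full panel size, no variance
#' prefilter) and keeps genes with `p_adj` strictly below `alpha`,
#' controlling the family-wise error rate at `alpha`. Selected genes are
#' partitioned by the sign of their correlation into `positive` and
#' `negative` directions.
#'
#' @param corr_tbl Output of [correlate_genes()] (columns `gene`, `rho`,
#'   `p_raw`).
#' @param alpha Family-wise error level in (0, 1); default 0.05.
#' @return A `pseudotime_signature` tibble with columns `gene`, `rho`,
#'   `p_raw`, `p_adj`, `selected`, `direction`, carrying attributes
#'   `alpha` and `m` (number of tests).
#' @export
bonferroni_select <- function(corr_tbl, alpha = 0.05) {
  corr_tbl <- as_tibble(corr_tbl)
  if (!all(c("gene", "rho", "p_raw") %in% names(corr_tbl))) {
    abort("`corr_tbl` needs gene, rho, p_raw columns.")
  }
  m <- nrow(corr_tbl)
  if (m < 1) abort("No genes tested.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  out <- corr_tbl
  out$p_adj <- pmin(1, m * out$p_raw)
  out$selected <- out$p_adj < alpha
  out$direction <- ifelse(out$selected,
                          ifelse(out$rho > 0, "positive", "negative"),
                          NA_character_)
  structure(out, class = c("pseudotime_signature", class(out)),
            alpha = alpha, m = m)
}

#' @export
print.pseudotime_signature <- function(x, ...) {
  n_sel <- sum(x$selected)
  cat("<pseudotime_signature> ", n_sel, "/", attr(x, "m"),
      " genes selected at FWER ", attr(x, "alpha"),
      " (", sum(isTRUE_vec(x$direction == "positive")), " positive, ",
      sum(isTRUE_vec(x$direction == "negative")), " negative)\n", sep = "")
  NextMethod()
}

#' Display-ready ordering of the signature heatmap
#'
#' Extracts the selected signature genes, groups rows by direction
#' (positive block first, each block ordered by decreasing |rho|), orders
#' columns by ascending pseudotime, and z-scores each row for display.
#'
#' @param normexpr Gene-by-sample matrix or [spatial_dataset()].
#' @param signature A [bonferroni_select()] result with >= 1 selected gene.
#' @param z Pseudotime vector aligned with the columns.
#' @return Numeric matrix (signature genes x samples, row mean 0 / sd 1)
#'   with attribute `direction` giving each row's block.
#' @export
signature_heatmap_order <- function(normexpr, signature, z) {
  x <- as_expr_matrix(normexpr)
  if (length(z) != ncol(x)) abort("`z` must align with the columns.")
  sel <- signature[isTRUE_vec(signature$selected), , drop = FALSE]
  if (nrow(sel) == 0) abort("Signature has no selected genes.")
  sel <- sel[order(sel$direction != "positive", -abs(sel$rho)), ]
  missing <- setdiff(sel$gene, rownames(x))
  if (length(missing)) {
    abort(paste0("Signature gene(s) absent from the matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- x[sel$gene, order(z), drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  sdv[sdv == 0] <- 1
  m <- (m - mu) / sdv
  attr(m, "direction") <- sel$direction
  m
}
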