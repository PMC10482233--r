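#' Q3 (upper-quartile) normalization of ROI counts
#'
#' Scales every ROI column by its own 75th percentile of signal, then
#' multiplies all columns by the geometric mean of the per-ROI 75th
#' percentiles so values keep a count-like magnitude. Percentiles use the
#' standard linear-interpolation convention (type 7). After normalization
#' all columns share the same 75th percentile.
#'
#' @param data A [spatial_dataset()] holding raw counts
#'   (`normalized = FALSE`).
#' @return The dataset with normalized `counts` and `normalized = TRUE`.
#' @export
#' @examples
#' sim <- simulate_spatial(n_genes = 50, seed = 1)
#' norm <- q3_normalize(sim$data)
#' apply(norm$counts, 2, quantile, 0.75) # all equal
q3_normalize <- function(data) {
  if (!inherits(data, "spatial_dataset")) {
    abort("`data` must be a spatial_dataset.")
  }
  if (data$normalized) abort("`data` is already Q3-normalized.")
  q3 <- apply(data$counts, 2, quantile, probs = 0.75, names = FALSE, type = 7)
  if (any(q3 <= 0)) {
    bad <- colnames(data$counts)[q3 <= 0]
    abort(paste0("ROI(s) with zero 75th percentile: ",
                 paste(bad, collapse = ", ")))
  }
  scale_factor <- exp(mean(log(q3)))
  out <- sweep(data$counts, 2, q3, "/") * scale_factor
  spatial_dataset(out, zone = data$samples$zone, normalized = TRUE)
}

#' Log-transform a normalized expression matrix
#'
#' Elementwise `log2(x + pseudocount)`, the variance-stabilizing transform
#' used before latent-trajectory modelling.
#'
#' @param data A normalized [spatial_dataset()] or a non-negative matrix.
#' @param pseudocount Positive offset added before taking logs.
#' @return A numeric matrix of log2 expression values.
#' @export
log_transform <- function(data, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  if (inherits(data, "spatial_dataset") && !data$normalized) {
    abort("Normalize the dataset (q3_normalize) before log-transforming.")
  }
  x <- as_expr_matrix(data)
  if (any(x < 0)) abort("Negative entries cannot be log-transformed.")
  log2(x + pseudocount)
}
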