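#' Fit a latent pseudotime by variational Bayesian factor analysis
#'
#' Models the centered log-expression of gene `g` in sample `j` as
#' `y_gj = mu_g + c_g * z_j + eps_gj`, `eps_gj ~ N(0, 1/tau_g)`, with
#' standard-normal priors on `mu_g`, `c_g` and the latent pseudotime `z_j`,
#' and `Gamma(2, 2)` priors on the gene precisions `tau_g`. The posterior
#' is approximated by mean-field coordinate-ascent variational inference
#' (CAVI); the evidence lower bound (ELBO) is computed after every sweep
#' and is non-decreasing up to floating-point tolerance. This is the
#' covariate-free reduction of the PhenoPath-style model for bulk
#' expression: with no covariates the interaction loadings vanish and the
#' model is classical Bayesian one-factor analysis.
#'
#' `z` is initialized from the first principal component of the samples
#' (sign fixed so the loading of the highest-variance gene is positive),
#' making the fit deterministic. `z` is identified only up to sign and
#' monotone scale; use [orient_pseudotime()] to anchor the direction
#' DZ to Peri, and downstream analyses use ranks of `z`.
#'
#' @param logexpr Numeric gene-by-sample matrix of log expression (e.g.
#'   from [log_transform()]), or a normalized [spatial_dataset()] which is
#'   log2(x+1)-transformed internally. Needs >= 3 samples and >= 2 genes
#'   with nonzero variance.
#' @param max_iter Maximum number of CAVI sweeps.
#' @param tol Convergence tolerance on the absolute ELBO change.
#' @param seed Integer seed (kept for interface stability; the
#'   initialization is deterministic).
#'
#' @return An object of class `pseudotime_fit` with elements `z` (named
#'   posterior-mean pseudotime), `z_sd`, `lambda` (per-gene loadings),
#'   `mu` (per-gene intercepts on the centered scale), `tau` (per-gene
#'   posterior-mean precision), `elbo_trace`, `converged`, `oriented`,
#'   and `zones` (filled by [orient_pseudotime()]).
#' @seealso [tidy.pseudotime_fit()], [glance.pseudotime_fit()],
#'   [pca_trajectory()]
#' @export
#' @examples
#' sim <- simulate_spatial(n_genes = 120, effect_size = 2, seed = 7)
#' y <- log_transform(q3_normalize(sim$data))
#' fit <- fit_pseudotime(y)
#' cor(fit$z, sim$true_pseudotime, method = "spearman")
fit_pseudotime <- function(logexpr, max_iter = 500, tol = 1e-6, seed = 1) {
  if (inherits(logexpr, "spatial_dataset")) {
    zones <- logexpr$samples$zone
    logexpr <- log_transform(logexpr)
  } else {
    zones <- NULL
    logexpr <- as.matrix(logexpr)
  }
  if (!all(is.finite(logexpr))) abort("`logexpr` contains non-finite values.")
  N <- ncol(logexpr)
  G <- nrow(logexpr)
  if (N < 3) abort("Need at least 3 samples.")
  rv <- apply(logexpr, 1, var)
  if (sum(rv > 0) < 2) abort("no expression variance")

  Y <- logexpr - rowMeans(logexpr)     # center genes
  a0 <- 2; b0 <- 2                     # Gamma prior on precisions

  # deterministic PC1 initialization, sign anchored on the most variable gene
  pc <- prcomp(t(Y), center = FALSE)
  z0 <- pc$x[, 1]
  anchor <- which.max(rv)
  if (pc$rotation[anchor, 1] < 0) z0 <- -z0
  sdz <- sd(z0)
  m_z <- if (sdz > 0) (z0 - mean(z0)) / sdz else rep(0, N)
  s_z <- 1e-3

  m_mu <- rep(0, G); s_mu <- 1
  m_c <- drop(Y %*% m_z) / N; s_c <- rep(1, G)
  a_tau <- rep(a0 + N / 2, G)
  b_tau <- b0 + 0.5 * rowSums((Y - outer(m_c, m_z))^2)

  elbo_trace <- numeric(0)
  converged <- FALSE
  ln2pi <- log(2 * pi)

  for (it in seq_len(max_iter)) {
    Et <- a_tau / b_tau
    Ez2 <- m_z^2 + s_z

    # loadings c_g
    prec_c <- 1 + Et * sum(Ez2)
    m_c <- Et * drop((Y - m_mu) %*% m_z) / prec_c
    s_c <- 1 / prec_c

    # intercepts mu_g (data are centered, so these stay near 0)
    prec_mu <- 1 + N * Et
    m_mu <- Et * rowSums(Y - outer(m_c, m_z)) / prec_mu
    s_mu <- 1 / prec_mu

    # precisions tau_g
    Ec2 <- m_c^2 + s_c
    resid <- Y - m_mu - outer(m_c, m_z)
    ss <- rowSums(resid^2) + N * s_mu + Ec2 * sum(Ez2) - m_c^2 * sum(m_z^2)
    a_tau <- rep(a0 + N / 2, G)
    b_tau <- b0 + 0.5 * ss

    # pseudotime z_j
    Et <- a_tau / b_tau
    Ec2 <- m_c^2 + s_c
    prec_z <- 1 + sum(Et * Ec2)
    m_z <- drop(crossprod(Y - m_mu, Et * m_c)) / prec_z
    s_z <- 1 / prec_z

    # ELBO with the current variational parameters
    Ez2 <- m_z^2 + s_z
    Elogt <- digamma(a_tau) - log(b_tau)
    resid <- Y - m_mu - outer(m_c, m_z)
    ss <- rowSums(resid^2) + N * s_mu + Ec2 * sum(Ez2) - m_c^2 * sum(m_z^2)
    ll <- sum(N / 2 * (Elogt - ln2pi) - 0.5 * Et * ss)
    pri <- -0.5 * sum(ln2pi + m_mu^2 + s_mu) -
      0.5 * sum(ln2pi + m_c^2 + s_c) -
      0.5 * sum(ln2pi + Ez2) +
      sum(a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elogt - b0 * Et)
    ent <- 0.5 * sum(log(2 * pi * exp(1) * s_mu)) +
      0.5 * sum(log(2 * pi * exp(1) * s_c)) +
      0.5 * N * log(2 * pi * exp(1) * s_z) +
      sum(a_tau - log(b_tau) + lgamma(a_tau) + (1 - a_tau) * digamma(a_tau))
    elbo <- ll + pri + ent
    elbo_trace <- c(elbo_trace, elbo)
    if (it > 1 && abs(elbo - elbo_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      z = setNames(m_z, colnames(logexpr)),
      z_sd = setNames(rep(sqrt(s_z), N), colnames(logexpr)),
      lambda = setNames(m_c, rownames(logexpr)),
      mu = setNames(m_mu, rownames(logexpr)),
      tau = setNames(a_tau / b_tau, rownames(logexpr)),
      elbo_trace = elbo_trace,
      converged = converged,
      oriented = FALSE,
      zones = zones
    ),
    class = "pseudotime_fit"
  )
}

#' Orient a pseudotime fit from dark zone toward peri-follicular areas
#'
#' The latent pseudotime is identified only up to sign; this anchors its
#' direction so DZ microregions sit at the start and peri-follicular
#' regions at the end of the trajectory (mean z over DZ < mean z over
#' Peri). Idempotent.
#'
#' @param fit A [fit_pseudotime()] result.
#' @param zones Character vector of zone labels aligned with `fit$z`;
#'   defaults to the zones carried by the fit when it was built from a
#'   [spatial_dataset()]. Must contain at least one `DZ` and one `Peri`.
#' @return The fit with `oriented = TRUE` and possibly sign-flipped `z`
#'   and loadings.
#' @export
orient_pseudotime <- function(fit, zones = fit$zones) {
  stopifnot(inherits(fit, "pseudotime_fit"))
  if (is.null(zones)) abort("Zone labels are required to orient the fit.")
  if (length(zones) != length(fit$z)) {
    abort("`zones` must align with the fitted samples.")
  }
  if (!any(zones == "DZ") || !any(zones == "Peri")) {
    abort("Orientation needs at least one DZ and one Peri sample.")
  }
  if (mean(fit$z[zones == "DZ"]) > mean(fit$z[zones == "Peri"])) {
    fit$z <- -fit$z
    fit$lambda <- -fit$lambda
  }
  fit$oriented <- TRUE
  fit$zones <- zones
  fit
}

#' @export
print.pseudotime_fit <- function(x, ...) {
  cat("<pseudotime_fit> ", length(x$z), " samples, ", length(x$lambda),
      " genes; ", length(x$elbo_trace), " CAVI iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n",
      "final ELBO: ", format(x$elbo_trace[length(x$elbo_trace)]),
      if (x$oriented) "; oriented DZ -> Peri" else "; unoriented", "\n",
      sep = "")
  invisible(x)
}

#' Tidy a pseudotime fit into a per-sample tibble
#'
#' @param x A `pseudotime_fit`.
#' @param ... Unused.
#' @return Tibble with `roi_id`, `zone` (if known), `z`, `z_sd`.
#' @export
tidy.pseudotime_fit <- function(x, ...) {
  out <- tibble(roi_id = names(x$z), z = unname(x$z), z_sd = unname(x$z_sd))
  if (!is.null(x$zones)) out <- tibble::add_column(out, zone = x$zones, .after = 1)
  out
}

#' One-row fit summary
#'
#' @param x A `pseudotime_fit`.
#' @param ... Unused.
#' @return Tibble with sizes, iteration count, final ELBO, convergence and
#'   orientation flags.
#' @export
glance.pseudotime_fit <- function(x, ...) {
  tibble(
    n_samples = length(x$z),
    n_genes = length(x$lambda),
    n_iter = length(x$elbo_trace),
    elbo = x$elbo_trace[length(x$elbo_trace)],
    converged = x$converged,
    oriented = x$oriented
  )
}

#' Two-dimensional PCA view of the trajectory
#'
#' Projects the samples onto the two leading principal components of the
#' centered (not scaled) log-expression matrix and joins the fitted
#' pseudotime, reproducing the standard trajectory-over-PCA display.
#'
#' @param logexpr Gene-by-sample matrix (>= 3 samples) or normalized
#'   [spatial_dataset()].
#' @param z Pseudotime vector aligned with the samples (e.g. `fit$z`).
#' @return Tibble with `roi_id`, `PC1`, `PC2`, `z`. When the matrix has
#'   rank < 2 the second component is reported as zeros with a warning.
#' @export
pca_trajectory <- function(logexpr, z) {
  if (inherits(logexpr, "spatial_dataset")) logexpr <- log_transform(logexpr)
  logexpr <- as.matrix(logexpr)
  if (ncol(logexpr) < 3) abort("Need at least 3 samples.")
  if (length(z) != ncol(logexpr)) abort("`z` must align with the samples.")
  pc <- prcomp(t(logexpr), center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  if (ncol(pc$x) < 2 || pc$sdev[2] < 1e-12) {
    warn("Expression matrix has rank < 2; PC2 set to 0.")
    pc2 <- rep(0, ncol(logexpr))
  } else {
    pc2 <- pc$x[, 2]
  }
  tibble(
    roi_id = colnames(logexpr),
    PC1 = unname(pc1),
    PC2 = unname(pc2),
    z = unname(z)
  )
}
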