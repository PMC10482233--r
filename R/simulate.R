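#' Simulate a spatial ROI dataset with a planted expression trajectory
#'
#' Generates negative-binomial probe counts for microregions of the three
#' lymphoid-tissue zones, with a latent per-ROI progression `t` drawn from
#' ordered, mildly overlapping zone intervals (DZ lowest, Peri highest) so
#' that zone identity constrains but does not fully determine the ordering.
#' A chosen fraction of genes increases log-linearly along `t`, a fraction
#' decreases, and the rest are trend-free; a log-normal per-ROI depth factor
#' emulates sequencing-depth variation.
#'
#' The gene-`g` mean in ROI `j` is `exp(a_g + b_g * (t_j - 1/2)) * d_j` with
#' slope `b_g` equal to `+effect_size`, `-effect_size` or `0`, baseline
#' `exp(a_g)` log-normal around ~50 counts, and depth factor `d_j`.
#'
#' @param n_per_zone ROIs per zone (the profiled tissue uses 5); must be
#'   at least 2 so downstream correlations are defined.
#' @param n_genes Total number of genes on the panel (default mirrors the
#'   1824-gene cancer transcriptome panel).
#' @param frac_pos,frac_neg Fractions of genes with increasing / decreasing
#'   trends; `frac_pos + frac_neg` must not exceed 1.
#' @param effect_size Non-negative slope of the log-mean trend across the
#'   whole trajectory (dimensionless; 0 gives a global null).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param depth_lognorm_sd Standard deviation of the per-ROI log-normal
#'   depth factor; `0` disables depth variation.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#'
#' @return A list of class `spatial_sim` with elements `data` (a
#'   [spatial_dataset()]), `true_pseudotime` (named vector `t`), and
#'   `true_slope` (named vector `b_g`).
#' @export
#' @examples
#' sim <- simulate_spatial(n_per_zone = 5, n_genes = 100, seed = 1)
#' sim$data
simulate_spatial <- function(n_per_zone = 5,
                             n_genes = 1824,
                             frac_pos = 0.04,
                             frac_neg = 0.06,
                             effect_size = 2,
                             dispersion = 0.1,
                             depth_lognorm_sd = 0.2,
                             seed = 1) {
  if (n_per_zone < 2) abort("`n_per_zone` must be >= 2.")
  if (n_genes < 1) abort("`n_genes` must be positive.")
  if (frac_pos < 0 || frac_neg < 0 || frac_pos + frac_neg > 1) {
    abort("`frac_pos` and `frac_neg` must be in [0,1] with sum <= 1.")
  }
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (depth_lognorm_sd < 0) abort("`depth_lognorm_sd` must be >= 0.")

  set.seed(as.integer(seed))
  zones <- rep(c("DZ", "LZ", "Peri"), each = n_per_zone)
  # overlapping zone windows: a continuum, not three point masses
  lo <- c(DZ = 0.0, LZ = 0.3, Peri = 0.6)[zones]
  hi <- c(DZ = 0.4, LZ = 0.7, Peri = 1.0)[zones]
  t_true <- runif(length(zones), lo, hi)
  roi_id <- paste0(zones, "_", sequence(rep(n_per_zone, 3)))
  names(t_true) <- roi_id

  n_pos <- floor(frac_pos * n_genes)
  n_neg <- floor(frac_neg * n_genes)
  slope <- c(rep(effect_size, n_pos), rep(-effect_size, n_neg),
             rep(0, n_genes - n_pos - n_neg))
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  names(slope) <- gene_id

  base_log_mean <- log(rlnorm(n_genes, meanlog = log(50), sdlog = 1))
  depth <- exp(rnorm(length(zones), 0, depth_lognorm_sd))

  mu <- exp(outer(base_log_mean, rep(1, length(zones))) +
              outer(slope, t_true - 0.5)) *
    rep(depth, each = n_genes)
  counts <- if (dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = n_genes)
  } else {
    matrix(rpois(length(mu), lambda = mu), nrow = n_genes)
  }
  dimnames(counts) <- list(gene_id, roi_id)

  structure(
    list(
      data = spatial_dataset(counts, zone = zones),
      true_pseudotime = t_true,
      true_slope = slope
    ),
    class = "spatial_sim"
  )
}

#' Simulate a lymphoma-like cohort with planted signature structure
#'
#' Draws a latent per-patient progression `u ~ Uniform(0, 1)` and lets it
#' drive (i) the expression of the supplied signature genes in the
#' direction of each gene's correlation weight, (ii) cell-of-origin label
#' odds, (iii) optionally genetic-subtype odds, and (iv) exponential
#' survival with hazards depending on the tercile of `u`. Non-signature
#' filler genes are pure noise. The planted `u`-terciles (named `low`,
#' `intermediate`, `high`) are returned as ground truth.
#'
#' Signature gene `i` has expression
#' `x_ij = base_i + 4 * rho_i * (u_j - 1/2) + N(0, 1)` on a log-intensity
#' scale, so genes move along `u` proportionally to (and in the sign of)
#' their weight. The enriched COO class has its odds multiplied by
#' `enrichment_odds` for patients in the high `u`-tercile (that is the
#' parameter's definition: the odds ratio enriching the class in the high
#' tercile); an optional subtype is enriched the same way in the low
#' tercile.
#' Overall-survival hazard is `log(2)/60` per month for the high tercile
#' (median 60 months) scaled by `hazard_ratio_low_vs_high` for the low and
#' its square root for the intermediate tercile; progression-free survival
#' uses 1.5x those hazards. Censoring is independent exponential with
#' per-patient rate chosen so the expected censored fraction equals
#' `censoring_rate` exactly.
#'
#' @param signature A signature table as produced by [bonferroni_select()]
#'   (only the selected genes are planted), or any data frame with `gene`
#'   and `rho` columns, in which case all rows are used.
#' @param n_patients Number of patients.
#' @param n_genes Total genes in the cohort matrix; defaults to twice the
#'   signature size and must not be smaller than the signature size.
#' @param enrichment_odds Odds multiplier (top vs bottom of `u`) for the
#'   enriched COO class; `1` plants no association.
#' @param enriched_class COO class tilted toward the high tercile
#'   (the peri-follicular apex enriches `Unclassified` cases).
#' @param subtype_enrichment_odds Odds multiplier tilting
#'   `enriched_subtype` toward the *low* tercile; `1` (default) plants no
#'   subtype association and leaves subtype sampling neutral.
#' @param enriched_subtype Genetic subtype tilted toward the low tercile.
#' @param hazard_ratio_low_vs_high Overall-survival hazard ratio of the
#'   low-`u` versus the high-`u` tercile (> 1 means low fares worse).
#' @param censoring_rate Expected fraction of censored patients, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#'
#' @return A list of class `cohort_sim` with `data` (a
#'   [cohort_dataset()]), `true_u` (named vector) and `true_group`
#'   (named factor `low`/`intermediate`/`high` by `u`-tercile).
#' @export
simulate_cohort <- function(signature,
                            n_patients = 600,
                            n_genes = NULL,
                            enrichment_odds = 8,
                            enriched_class = "Unclassified",
                            subtype_enrichment_odds = 1,
                            enriched_subtype = "EZB",
                            hazard_ratio_low_vs_high = 2,
                            censoring_rate = 0.2,
                            seed = 1) {
  sig <- as_tibble(signature)
  if (!all(c("gene", "rho") %in% names(sig))) {
    abort("`signature` needs `gene` and `rho` columns.")
  }
  if ("selected" %in% names(sig)) sig <- sig[isTRUE_vec(sig$selected), ]
  if (nrow(sig) == 0) abort("`signature` has no (selected) genes.")
  if (n_patients < 3) abort("`n_patients` must be >= 3.")
  if (enrichment_odds <= 0 || subtype_enrichment_odds <= 0) {
    abort("Enrichment odds must be > 0.")
  }
  if (hazard_ratio_low_vs_high <= 0) abort("`hazard_ratio_low_vs_high` must be > 0.")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("`censoring_rate` must be in [0, 1).")
  }
  n_sig <- nrow(sig)
  if (is.null(n_genes)) n_genes <- 2L * n_sig
  if (n_genes < n_sig) {
    abort("`n_genes` is smaller than the signature size.")
  }

  set.seed(as.integer(seed))
  u <- runif(n_patients)
  pid <- sprintf("P%04d", seq_len(n_patients))
  names(u) <- pid
  true_group <- tertile_groups(u, ids = pid)
  names(true_group) <- pid

  gene_id <- c(sig$gene, sprintf("FILLER%04d", seq_len(n_genes - n_sig)))
  base <- rnorm(n_genes, mean = 8, sd = 1)
  slope <- c(4 * sig$rho, rep(0, n_genes - n_sig))
  expr <- outer(base, rep(1, n_patients)) + outer(slope, u - 0.5) +
    matrix(rnorm(n_genes * n_patients), nrow = n_genes)
  dimnames(expr) <- list(gene_id, pid)

  # COO: baseline class mix; the enriched class's odds are multiplied by
  # `enrichment_odds` for patients in the high u-tercile (the parameter's
  # definition), and by 1 elsewhere
  base_p <- c(GCB = 0.5, ABC = 0.35, Unclassified = 0.15)
  if (!enriched_class %in% names(base_p)) {
    abort("`enriched_class` must be one of GCB, ABC, Unclassified.")
  }
  odds <- matrix(rep(base_p / (1 - base_p), each = n_patients),
                 nrow = n_patients, dimnames = list(pid, names(base_p)))
  odds[true_group == "high", enriched_class] <-
    odds[true_group == "high", enriched_class] * enrichment_odds
  coo <- unname(apply(odds, 1, function(o) {
    sample(names(base_p), 1, prob = o / sum(o))
  }))

  # genetic subtype: optional planted enrichment in the *low* tercile
  sub_p <- c(BN2 = 0.12, EZB = 0.18, MCD = 0.15, ST2 = 0.08, A53 = 0.06,
             Other.ABC = 0.15, Other.GCB = 0.15, Other.Unclassified = 0.11)
  if (!enriched_subtype %in% names(sub_p)) {
    abort("Unknown `enriched_subtype`.")
  }
  sodds <- matrix(rep(sub_p, each = n_patients), nrow = n_patients,
                  dimnames = list(pid, names(sub_p)))
  sodds[true_group == "low", enriched_subtype] <-
    sodds[true_group == "low", enriched_subtype] * subtype_enrichment_odds
  subtype <- unname(apply(sodds, 1, function(o) {
    sample(names(sub_p), 1, prob = o / sum(o))
  }))

  ipi <- sample(c("low", "medium", "high"), n_patients, replace = TRUE,
                prob = c(0.35, 0.4, 0.25))

  hr_step <- c(low = hazard_ratio_low_vs_high,
               intermediate = sqrt(hazard_ratio_low_vs_high),
               high = 1)[as.character(true_group)]
  h_os <- log(2) / 60 * hr_step
  surv <- function(h) {
    t_ev <- rexp(n_patients, rate = h)
    if (censoring_rate > 0) {
      t_cn <- rexp(n_patients, rate = h * censoring_rate / (1 - censoring_rate))
      list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
    } else {
      list(time = t_ev, event = rep(1L, n_patients))
    }
  }
  os <- surv(h_os)
  pfs <- surv(1.5 * h_os)

  patients <- tibble(
    patient_id = pid,
    coo = coo,
    subtype = subtype,
    os_time = os$time, os_event = os$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    ipi = ipi
  )

  structure(
    list(
      data = cohort_dataset(expr, patients),
      true_u = u,
      true_group = true_group
    ),
    class = "cohort_sim"
  )
}

# logical subset helper tolerant of NA
isTRUE_vec <- function(x) !is.na(x) & x
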