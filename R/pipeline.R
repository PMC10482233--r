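#' Run the full spatial-pseudotime pipeline
#'
#' Chains every stage end to end: Q3 normalization of the spatial ROI
#' counts, latent-pseudotime fitting and DZ-to-Peri orientation, PCA
#' trajectory export, Bonferroni-gated signature derivation, then for each
#' configured cohort the correlation-weighted scoring with tertile
#' grouping, COO association (Jaccard + Fisher), genetic-subtype
#' composition when available, and survival analysis (Kaplan-Meier,
#' log-rank, proportional-hazards check, multivariate Cox) when the
#' endpoint columns are present. All artifacts are written under
#' `out_dir` and listed, with MD5 content hashes, in `manifest.json`;
#' identical inputs, configuration and seed reproduce identical hashes.
#'
#' @param config Either a YAML file path or a list with elements:
#'   \describe{
#'     \item{spatial}{list with `matrix` and `metadata` TSV paths (layout
#'       of [write_sim_bundle()]).}
#'     \item{cohorts}{named list; each element a list with `matrix` and
#'       `metadata` paths, optionally `geo` (series-matrix file instead of
#'       `matrix`) and `annotation` (probe-to-symbol TSV).}
#'     \item{out_dir}{output directory.}
#'     \item{alpha}{FWER level for the signature gate (default 0.05).}
#'     \item{seed}{root seed (default 1).}
#'     \item{zscore}{standardize cohort genes before scoring (default
#'       FALSE).}
#'     \item{endpoint}{`"os"` or `"pfs"` (default `"os"`).}
#'   }
#' @return Invisibly, a tibble manifest (`artifact`, `path`, `md5`); also
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1
  zscore <- isTRUE(config$zscore)
  endpoint <- config$endpoint %||% "os"
  if (!endpoint %in% c("os", "pfs")) abort("`endpoint` must be os or pfs.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  out_dir <- config$out_dir
  if (is.null(out_dir)) abort("`out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline failed at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }
  emit <- function(name, path) {
    artifacts[[name]] <<- path
    inform(paste0("[", name, "] -> ", basename(path)))
  }

  # --- spatial stages -------------------------------------------------
  spatial <- stage("read_spatial", {
    counts <- read_expression_tsv(config$spatial$matrix)
    meta <- read_metadata_tsv(config$spatial$metadata)
    spatial_dataset(counts[, meta$roi_id, drop = FALSE], zone = meta$zone)
  })
  inform(paste0("[read_spatial] ", nrow(spatial$counts), " genes x ",
                ncol(spatial$counts), " ROIs"))
  norm <- stage("normalize", q3_normalize(spatial))
  f_norm <- file.path(out_dir, "normalized_matrix.tsv")
  write_expression_tsv(norm$counts, f_norm); emit("normalized_matrix", f_norm)

  fit <- stage("pseudotime", {
    orient_pseudotime(fit_pseudotime(norm, seed = seed))
  })
  f_pt <- file.path(out_dir, "pseudotime.tsv")
  readr::write_tsv(tidy(fit), f_pt); emit("pseudotime", f_pt)

  traj <- stage("trajectory", pca_trajectory(norm, fit$z))
  f_traj <- file.path(out_dir, "trajectory.tsv")
  readr::write_tsv(traj, f_traj); emit("trajectory", f_traj)

  signature <- stage("signature", {
    bonferroni_select(correlate_genes(norm, fit$z), alpha = alpha)
  })
  f_sig <- file.path(out_dir, "signature.tsv")
  write_signature_tsv(signature, f_sig); emit("signature", f_sig)
  inform(paste0("[signature] ", sum(signature$selected), "/",
                nrow(signature), " genes selected at FWER ", alpha))
  if (any(signature$selected)) {
    hm <- signature_heatmap_order(norm, signature, fit$z)
    f_hm <- file.path(out_dir, "signature_heatmap.tsv")
    write_expression_tsv(hm, f_hm); emit("signature_heatmap", f_hm)
  }

  # --- per-cohort stages ----------------------------------------------
  for (cname in names(config$cohorts)) {
    cc <- config$cohorts[[cname]]
    cohort <- stage(paste0("read_cohort:", cname), {
      expr <- if (!is.null(cc$geo)) {
        read_geo_series_matrix(cc$geo, annotation = cc$annotation)
      } else {
        read_expression_tsv(cc$matrix)
      }
      meta <- read_metadata_tsv(cc$metadata)
      cohort_dataset(expr[, meta$patient_id, drop = FALSE], meta)
    })
    inform(paste0("[read_cohort:", cname, "] ", nrow(cohort$expr),
                  " genes x ", ncol(cohort$expr), " patients"))
    scored <- stage(paste0("score:", cname), {
      pseudotime_score(cohort, signature, zscore = zscore)
    })
    f_sc <- file.path(out_dir, paste0(cname, "_scored.tsv"))
    readr::write_tsv(as_tibble(scored), f_sc)
    emit(paste0(cname, "_scored"), f_sc)

    report <- list(cohort = cname,
                   n_patients = nrow(scored),
                   n_genes_used = attr(scored, "n_genes_used"),
                   genes_missing = attr(scored, "genes_missing"))

    meta <- cohort$patients
    if ("coo" %in% names(meta) && any(!is.na(meta$coo))) {
      coo <- setNames(meta$coo, meta$patient_id)
      grp <- setNames(as.character(scored$group), scored$patient_id)
      jac <- jaccard_matrix(coo, grp)
      tab <- table(coo = meta$coo,
                   group = scored$group[match(meta$patient_id,
                                              scored$patient_id)])
      fp <- fisher_association(unclass(tab), seed = seed)
      report$coo <- list(jaccard = jac, fisher_p = fp$p_value,
                         fisher_method = fp$method)
    }
    if ("subtype" %in% names(meta) && any(!is.na(meta$subtype))) {
      sp <- subtype_proportions(scored,
                                setNames(meta$subtype, meta$patient_id),
                                seed = seed)
      report$subtype <- list(proportions = sp$proportions,
                             fisher_p = sp$fisher_p, method = sp$method)
    }
    tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
    if (all(c(tcol, ecol) %in% names(meta)) && any(!is.na(meta[[tcol]]))) {
      sdat <- dplyr::inner_join(as_tibble(scored), meta, by = "patient_id")
      sdat$time <- sdat[[tcol]]; sdat$event <- sdat[[ecol]]
      km <- km_fit(sdat, time, event, group)
      lr <- logrank_test(sdat, time, event, group)
      has_coo <- "coo" %in% names(sdat) && any(!is.na(sdat$coo))
      has_ipi <- "ipi" %in% names(sdat) && any(!is.na(sdat$ipi))
      cox <- if (has_coo && has_ipi) {
        cox_multivariate(sdat, time, event, group, coo, ipi)
      } else if (has_coo) {
        cox_multivariate(sdat, time, event, group, coo)
      } else if (has_ipi) {
        cox_multivariate(sdat, time, event, group, ipi = ipi)
      } else {
        cox_multivariate(sdat, time, event, group)
      }
      f_km <- file.path(out_dir, paste0(cname, "_km.tsv"))
      readr::write_tsv(as_tibble(km), f_km)
      emit(paste0(cname, "_km"), f_km)
      report$survival <- list(endpoint = endpoint,
                              logrank = as.list(lr),
                              ph_check = ph_check(cox),
                              cox = tidy(cox))
    }
    f_rep <- file.path(out_dir, paste0(cname, "_report.json"))
    jsonlite::write_json(report, f_rep, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
    emit(paste0(cname, "_report"), f_rep)
  }

  manifest <- tibble(
    artifact = names(artifacts),
    path = unname(artifacts),
    md5 = unname(tools::md5sum(unname(artifacts)))
  )
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  inform(paste0("[manifest] ", nrow(manifest), " artifacts"))
  invisible(manifest)
}
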