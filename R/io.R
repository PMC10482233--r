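#' Read and write gene-by-sample expression TSV files
#'
#' The interchange layout is a tab-separated file whose first column
#' (named `gene`) holds gene symbols and whose remaining header fields are
#' sample ids.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @return `read_expression_tsv()` returns the matrix;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- tibble(gene = rownames(mat))
  df <- dplyr::bind_cols(df, as_tibble(as.data.frame(mat)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Read and write sample metadata TSV files
#'
#' One row per sample; the first column is the sample id (`roi_id` for
#' spatial data, `patient_id` for cohorts), followed by annotation columns
#' (`zone`, or `coo`/`subtype`/`os_time`/`os_event`/`pfs_time`/
#' `pfs_event`/`ipi`).
#'
#' @param meta Data frame of metadata.
#' @param path File path.
#' @return `read_metadata_tsv()` returns a tibble.
#' @export
write_metadata_tsv <- function(meta, path) {
  readr::write_tsv(as_tibble(meta), path)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Signature TSV interchange
#'
#' Writes/reads the signature table (`gene`, `rho`, `p_raw`, `p_adj`,
#' `selected`, `direction`) consumed by [pseudotime_score()]; the
#' round-trip preserves all values.
#'
#' @param signature A [bonferroni_select()] result.
#' @param path File path.
#' @return `read_signature_tsv()` returns a `pseudotime_signature`
#'   tibble.
#' @export
write_signature_tsv <- function(signature, path) {
  df <- as_tibble(signature)
  attr(df, "alpha") <- NULL
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          gene = "c", direction = "c",
                          selected = "l", .default = "d"
                        ))
  structure(df, class = c("pseudotime_signature", class(df)),
            m = nrow(df), alpha = NA_real_)
}

#' Write a simulated dataset bundle to disk
#'
#' Writes the expression TSV, the metadata TSV and a JSON sidecar holding
#' the simulation ground truth, the on-disk layout every pipeline stage
#' reads back.
#'
#' @param sim A [simulate_spatial()] or [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the files written.
#' @export
write_sim_bundle <- function(sim, dir, prefix = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fm <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  fmd <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  ft <- file.path(dir, paste0(prefix, "_truth.json"))
  if (inherits(sim, "spatial_sim")) {
    write_expression_tsv(sim$data$counts, fm)
    write_metadata_tsv(sim$data$samples, fmd)
    truth <- list(true_pseudotime = as.list(sim$true_pseudotime),
                  true_slope = as.list(sim$true_slope))
  } else if (inherits(sim, "cohort_sim")) {
    write_expression_tsv(sim$data$expr, fm)
    write_metadata_tsv(sim$data$patients, fmd)
    truth <- list(true_u = as.list(sim$true_u),
                  true_group = as.list(as.character(sim$true_group)))
  } else {
    abort("`sim` must be a spatial_sim or cohort_sim.")
  }
  jsonlite::write_json(truth, ft, auto_unbox = TRUE, digits = NA)
  c(matrix = fm, metadata = fmd, truth = ft)
}

#' Read a GEO series-matrix text file
#'
#' Parses the expression block of a series-matrix file: `!`-prefixed
#' metadata lines are skipped, and the tab-separated block between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers is
#' read with its `ID_REF` probe column as rownames. Quoted fields may
#' contain tabs. An optional probe-to-symbol annotation collapses probes
#' mapping to the same symbol by their mean.
#'
#' @param path Series-matrix file.
#' @param annotation Optional probe annotation: a data frame (or TSV path)
#'   whose first two columns are probe id and gene symbol. Probes without
#'   a symbol are dropped.
#' @return Numeric matrix, probes (or symbols) by samples.
#' @export
read_geo_series_matrix <- function(path, annotation = NULL) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1) {
    abort("Series-matrix table markers not found.")
  }
  block <- lines[(beg + 1):(end - 1)]
  df <- utils::read.delim(text = paste(block, collapse = "\n"),
                          sep = "\t", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "ID_REF") {
    abort("Series-matrix block lacks the ID_REF column.")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$ID_REF)

  if (!is.null(annotation)) {
    if (is.character(annotation) && length(annotation) == 1) {
      annotation <- read_metadata_tsv(annotation)
    }
    annotation <- as.data.frame(annotation)
    probe <- as.character(annotation[[1]])
    symbol <- as.character(annotation[[2]])
    sym <- symbol[match(rownames(m), probe)]
    keep <- !is.na(sym) & sym != ""
    m <- m[keep, , drop = FALSE]
    sym <- sym[keep]
    m <- rowsum(m, group = sym)
    m <- m / as.vector(table(sym)[rownames(m)])
  }
  m
}
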