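#' Spatial ROI expression dataset
#'
#' Bundles a gene-by-ROI expression matrix with per-ROI annotation for
#' spatially profiled microregions. Zones follow the germinal-center
#' anatomy: dark zone (`DZ`), light zone (`LZ`) and peri-/inter-follicular
#' area (`Peri`).
#'
#' @param counts Numeric matrix, genes in rows (unique rownames = gene
#'   symbols), ROIs in columns (unique colnames = ROI ids). All values must
#'   be finite and non-negative.
#' @param zone Character vector of zone labels, one per ROI, each one of
#'   `"DZ"`, `"LZ"`, `"Peri"`.
#' @param normalized Logical flag; `TRUE` once the matrix has been
#'   Q3-normalized (see [q3_normalize()]).
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `counts` (matrix), `samples` (tibble with `roi_id`, `zone`) and
#'   `normalized`.
#' @export
#' @examples
#' m <- matrix(rpois(40, 20), nrow = 8,
#'             dimnames = list(paste0("g", 1:8), paste0("roi", 1:5)))
#' spatial_dataset(m, zone = c("DZ", "DZ", "LZ", "LZ", "Peri"))
spatial_dataset <- function(counts, zone, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    abort("`counts` must have unique gene symbols as rownames.")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    abort("`counts` must have unique ROI ids as colnames.")
  }
  if (!all(is.finite(counts)) || any(counts < 0)) {
    abort("`counts` must be finite and non-negative.")
  }
  zone <- as.character(zone)
  if (length(zone) != ncol(counts)) {
    abort("`zone` must supply one label per ROI column.")
  }
  bad <- setdiff(unique(zone), c("DZ", "LZ", "Peri"))
  if (length(bad)) {
    abort(paste0("Unknown zone label(s): ", paste(bad, collapse = ", "),
                 " (expected DZ, LZ, Peri)."))
  }
  structure(
    list(
      counts = counts,
      samples = tibble(roi_id = colnames(counts), zone = zone),
      normalized = isTRUE(normalized)
    ),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("<spatial_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " ROIs (", if (x$normalized) "Q3-normalized" else "raw counts", ")\n",
      sep = "")
  print(table(zone = x$samples$zone))
  invisible(x)
}

#' Lymphoma cohort expression dataset
#'
#' Bundles a gene-by-patient expression matrix (kept on whatever scale the
#' source cohort provides) with per-patient clinical annotation:
#' cell-of-origin class (`GCB`, `ABC`, `Unclassified`), optional genetic
#' subtype (`BN2`, `EZB`, `MCD`, `ST2`, `A53`, `Other.*`), optional
#' overall/progression-free survival and optional IPI risk class.
#'
#' @param expr Numeric matrix, genes in rows, patients in columns; unique
#'   dimnames required.
#' @param patients Data frame with one row per patient. Must contain
#'   `patient_id` matching `colnames(expr)`; recognised optional columns are
#'   `coo`, `subtype`, `os_time`, `os_event`, `pfs_time`, `pfs_event`,
#'   `ipi`. Missing annotation stays `NA`.
#'
#' @return An object of class `cohort_dataset`: list with `expr` (matrix)
#'   and `patients` (tibble).
#' @export
cohort_dataset <- function(expr, patients) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` needs gene rownames and patient colnames.")
  }
  if (anyDuplicated(colnames(expr))) abort("Duplicate patient ids in `expr`.")
  patients <- as_tibble(patients)
  if (!"patient_id" %in% names(patients)) {
    abort("`patients` must contain a `patient_id` column.")
  }
  if (anyDuplicated(patients$patient_id)) abort("Duplicate patient ids.")
  if (!setequal(patients$patient_id, colnames(expr))) {
    abort("`patients$patient_id` must match the columns of `expr`.")
  }
  patients <- patients[match(colnames(expr), patients$patient_id), ]
  for (col in c("os_time", "pfs_time")) {
    if (col %in% names(patients)) {
      v <- patients[[col]]
      if (any(v < 0, na.rm = TRUE)) abort(paste0("`", col, "` has negative times."))
    }
  }
  for (col in c("os_event", "pfs_event")) {
    if (col %in% names(patients)) {
      v <- patients[[col]]
      if (!all(v %in% c(0, 1, NA))) abort(paste0("`", col, "` must be 0/1."))
    }
  }
  structure(list(expr = expr, patients = patients), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$expr), " genes x ", ncol(x$expr),
      " patients\n", sep = "")
  if ("coo" %in% names(x$patients)) print(table(coo = x$patients$coo, useNA = "ifany"))
  invisible(x)
}

# internal: extract an expression matrix from the containers or a plain matrix
as_expr_matrix <- function(x) {
  if (inherits(x, "spatial_dataset")) return(x$counts)
  if (inherits(x, "cohort_dataset")) return(x$expr)
  as.matrix(x)
}
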