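#' Jaccard similarity between two patient partitions
#'
#' For every class `a` of the first labelling and group `b` of the second,
#' computes `|A intersect B| / |A union B|` over the patient sets, the
#' set-pair index used to compare cell-of-origin classes with pseudotime
#' groups.
#'
#' @param labels_a,labels_b Label vectors over the same patients. When
#'   both are named, patients are matched by name (an error is raised if
#'   the universes differ); otherwise they are matched by position and
#'   must have equal length.
#' @return Long tibble with `class`, `group`, `jaccard`.
#' @export
#' @examples
#' jaccard_matrix(c(p1 = "x", p2 = "x", p3 = "y"),
#'                c(p1 = "u", p2 = "v", p3 = "v"))
jaccard_matrix <- function(labels_a, labels_b) {
  na <- names(labels_a); nb <- names(labels_b)
  if (!is.null(na) && !is.null(nb)) {
    if (!setequal(na, nb)) {
      abort("The two labellings cover different patient universes.")
    }
    labels_b <- labels_b[match(na, nb)]
  } else if (length(labels_a) != length(labels_b)) {
    abort("Unnamed labellings must have equal length.")
  }
  ids <- na %||% seq_along(labels_a)
  keep <- !is.na(labels_a) & !is.na(labels_b)
  labels_a <- as.character(labels_a)[keep]
  labels_b <- as.character(labels_b)[keep]
  ids <- ids[keep]
  cls <- unique(labels_a); grp <- unique(labels_b)
  grid <- tidyr::expand_grid(class = cls, group = grp)
  grid$jaccard <- purrr::map2_dbl(grid$class, grid$group, function(a, b) {
    A <- ids[labels_a == a]; B <- ids[labels_b == b]
    length(intersect(A, B)) / length(union(A, B))
  })
  grid
}

#' Fisher exact test of a contingency table
#'
#' Association test between two categorical labellings. For 2x2 tables
#' the two-sided p-value is computed directly by hypergeometric
#' enumeration under the probability-mass criterion (sum of the
#' probabilities of all tables no more likely than the observed one). For
#' larger tables with total count <= 200 the exact conditional
#' (Freeman-Halton) test is attempted via the network algorithm; when that
#' is infeasible, or for larger totals, a seeded Monte-Carlo test with
#' fixed margins is used.
#'
#' @param x Matrix or table of non-negative integer counts.
#' @param mc_reps Number of Monte-Carlo tables when simulation is used.
#' @param seed Seed for the Monte-Carlo draw.
#' @return List of class `fisher_association` with `p_value`, `method`
#'   (`"exact_2x2"`, `"exact_network"` or `"monte_carlo"`), and `table`.
#' @export
#' @examples
#' fisher_association(matrix(c(3, 1, 1, 3), 2))$p_value # 34/70
fisher_association <- function(x, mc_reps = 1e5, seed = 1) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x)) || !all(is.finite(x))) {
    abort("Counts must be non-negative integers.")
  }
  n <- sum(x)
  if (n < 1) abort("Empty table.")
  storage.mode(x) <- "integer"

  if (all(dim(x) == c(2, 2))) {
    # probability-mass two-sided criterion, with the conventional relative
    # tolerance so ties in probability count as "as extreme"
    m <- sum(x[1, ]); k <- sum(x[, 1])
    lo <- max(0, k - sum(x[2, ])); hi <- min(m, k)
    supp <- lo:hi
    pr <- dhyper(supp, m, n - m, k)
    p_obs <- dhyper(x[1, 1], m, n - m, k)
    p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
    return(structure(list(p_value = p, method = "exact_2x2", table = x),
                     class = "fisher_association"))
  }

  if (n <= 200) {
    exact <- tryCatch(
      stats::fisher.test(x, workspace = 2e7)$p.value,
      error = function(e) NULL
    )
    if (!is.null(exact)) {
      return(structure(list(p_value = exact, method = "exact_network",
                            table = x),
                       class = "fisher_association"))
    }
  }
  set.seed(as.integer(seed))
  p <- stats::fisher.test(x, simulate.p.value = TRUE, B = mc_reps)$p.value
  structure(list(p_value = p, method = "monte_carlo", table = x),
            class = "fisher_association")
}

#' @export
print.fisher_association <- function(x, ...) {
  cat("Fisher exact test (", x$method, "): p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Pseudotime-category composition of genetic subtypes
#'
#' For every genetic subtype, the fraction of its patients falling in each
#' pseudotime category (rows sum to 1), together with a Fisher exact test
#' of the subtype-by-category table. Patients without a subtype label are
#' excluded pairwise and their count reported.
#'
#' @param scored A [pseudotime_score()] result (or data frame with
#'   `patient_id` and `group`).
#' @param subtype Subtype labels, either named by patient id or aligned
#'   positionally with `scored`; `NA` marks unlabelled patients.
#' @param mc_reps,seed Passed to [fisher_association()].
#' @return List of class `association_report` with `proportions` (tibble,
#'   one row per subtype), `table` (counts), `fisher_p`, `method` and
#'   `n_excluded`.
#' @export
subtype_proportions <- function(scored, subtype, mc_reps = 1e5, seed = 1) {
  scored <- as_tibble(scored)
  if (!all(c("patient_id", "group") %in% names(scored))) {
    abort("`scored` needs patient_id and group columns.")
  }
  if (!is.null(names(subtype))) {
    subtype <- subtype[match(scored$patient_id, names(subtype))]
  } else if (length(subtype) != nrow(scored)) {
    abort("`subtype` must be named or aligned with `scored`.")
  }
  keep <- !is.na(subtype) & !is.na(scored$group)
  if (!any(keep)) abort("No patient carries both a subtype and a group.")
  tab <- table(subtype = as.character(subtype[keep]),
               group = factor(scored$group[keep],
                              levels = c("low", "intermediate", "high")))
  fp <- fisher_association(unclass(tab), mc_reps = mc_reps, seed = seed)
  props <- as_tibble(prop.table(tab, 1))
  props <- tidyr::pivot_wider(props, names_from = "group", values_from = "n")
  structure(
    list(
      proportions = props,
      table = tab,
      fisher_p = fp$p_value,
      method = fp$method,
      n_excluded = sum(!keep)
    ),
    class = "association_report"
  )
}

#' @export
print.association_report <- function(x, ...) {
  cat("<association_report> Fisher p = ", format(x$fisher_p, digits = 4),
      " (", x$method, "); ", x$n_excluded, " unlabelled patients excluded\n",
      sep = "")
  print(x$proportions)
  invisible(x)
}
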