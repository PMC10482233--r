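# Shared fixtures built in code: a reference hand signature and small
# deterministic datasets used across test files.

make_signature <- function(n_pos = 25, n_neg = 35) {
  tibble::tibble(
    gene = sprintf("SG%03d", seq_len(n_pos + n_neg)),
    rho = c(seq(0.5, 0.95, length.out = n_pos),
            seq(-0.95, -0.5, length.out = n_neg))
  )
}

# tiny spatial dataset with known counts
toy_spatial <- function(counts, zones = NULL) {
  if (is.null(zones)) {
    zones <- rep(c("DZ", "LZ", "Peri"), length.out = ncol(counts))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("roi", seq_len(ncol(counts)))
  }
  spatial_dataset(counts, zone = zones)
}

# exact two-sided Fisher p for a 2x2 table by direct enumeration over the
# hypergeometric support, written only with lchoose (independent of dhyper
# and of the package's implementation)
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- sapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  })
  p <- exp(logp)
  obs <- p[a - lo + 1]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# all permutations of a vector (used for exact Spearman enumeration at n=8)
all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}
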