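test_that("perfect monotone genes reach rho = +/-1", {
  z <- c(0.3, 0.9, 0.1, 0.5, 0.7)
  # up follows z's ranks, down the reversed ranks
  x <- rbind(up = rank(z), down = max(rank(z)) + 1 - rank(z))
  colnames(x) <- paste0("s", 1:5)
  ct <- correlate_genes(x, z)
  expect_equal(ct$rho[ct$gene == "up"], 1)
  expect_equal(ct$rho[ct$gene == "down"], -1)
})

test_that("rho and p match exact permutation enumeration at n = 8", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  z <- 1:8
  m <- matrix(x, nrow = 1, dimnames = list("gx", paste0("s", 1:8)))
  ct <- correlate_genes(m, z)

  # oracle: Spearman rho from average ranks, by hand
  rx <- rank(x); rz <- rank(z)
  rho_hand <- sum((rx - mean(rx)) * (rz - mean(rz))) /
    sqrt(sum((rx - mean(rx))^2) * sum((rz - mean(rz))^2))
  expect_equal(ct$rho, rho_hand, tolerance = 1e-12)

  # oracle: exact two-sided p over all 8! permutations of z
  P <- all_perms(1:8)
  rxc <- rx - mean(rx)
  num <- P %*% rxc                       # permutation covariances (x const)
  den <- sqrt(sum(rxc^2) * sum((rz - mean(rz))^2))
  rho_all <- as.vector(num) / den
  p_exact <- mean(abs(rho_all) >= abs(rho_hand) - 1e-12)
  expect_lt(abs(ct$p_raw - p_exact), 0.02)

  # the seeded Monte-Carlo permutation option agrees with the enumeration
  ctp <- correlate_genes(m, z, perm = 4000, seed = 1)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(ctp$p_perm - p_exact), 3 * se + 1 / 4001)
})

test_that("constant genes get rho 0 and p 1; short series are rejected", {
  m <- rbind(flat = rep(2, 5), var = c(1, 4, 2, 5, 3))
  colnames(m) <- paste0("s", 1:5)
  ct <- correlate_genes(m, z = 1:5)
  expect_equal(ct$rho[1], 0)
  expect_equal(ct$p_raw[1], 1)
  expect_error(correlate_genes(m[, 1:3], z = 1:3), "4 samples")
})

test_that("correlation output is invariant under monotone transforms of z", {
  sim <- simulate_spatial(n_genes = 50, seed = 13)
  norm <- q3_normalize(sim$data)
  z <- sim$true_pseudotime
  a <- correlate_genes(norm, z)
  b <- correlate_genes(norm, exp(3 * z) - 1)
  expect_equal(a, b)
})

test_that("Bonferroni gate follows min(1, m*p) with strict alpha cut", {
  t1 <- tibble::tibble(gene = "g", rho = 0.9, p_raw = 0.04)
  s1 <- bonferroni_select(t1, alpha = 0.05)
  expect_equal(s1$p_adj, 0.04)
  expect_true(s1$selected)

  t2 <- tibble::tibble(gene = sprintf("g%d", 1:1000), rho = 0.5,
                       p_raw = c(1e-4, runif(999, 0.2, 1)))
  s2 <- bonferroni_select(t2)
  expect_equal(s2$p_adj[1], 0.1)
  expect_false(s2$selected[1])

  expect_error(bonferroni_select(t1, alpha = 0), "alpha")
  expect_error(bonferroni_select(t1, alpha = 1), "alpha")
})

test_that("selected directions match the planted trend signs", {
  sim <- simulate_spatial(n_genes = 200, frac_pos = 0.15, frac_neg = 0.15,
                          effect_size = 2, seed = 17)
  norm <- q3_normalize(sim$data)
  fit <- orient_pseudotime(fit_pseudotime(norm))
  sig <- bonferroni_select(correlate_genes(norm, fit$z))
  sel <- sig[sig$selected, ]
  expect_gt(nrow(sel), 10)
  planted <- sign(sim$true_slope[sel$gene])
  expect_true(all(ifelse(sel$direction == "positive", 1, -1) == planted))
})

test_that("selection controls the family-wise error rate on calibrated nulls", {
  # independent planted ordering: valid p-values, so Bonferroni must hold
  hits <- sapply(1:200, function(s) {
    sim <- simulate_spatial(n_genes = 200, effect_size = 0, seed = 40000 + s)
    norm <- q3_normalize(sim$data)
    any(bonferroni_select(correlate_genes(norm, sim$true_pseudotime))$selected)
  })
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("heatmap ordering groups directions and z-scores rows", {
  sim <- simulate_spatial(n_genes = 150, frac_pos = 0.2, frac_neg = 0.2,
                          effect_size = 2, seed = 19)
  norm <- q3_normalize(sim$data)
  fit <- orient_pseudotime(fit_pseudotime(norm))
  sig <- bonferroni_select(correlate_genes(norm, fit$z))
  hm <- signature_heatmap_order(norm, sig, fit$z)

  expect_setequal(colnames(hm), colnames(norm$counts))
  expect_identical(colnames(hm), colnames(norm$counts)[order(fit$z)])
  expect_equal(unname(rowMeans(hm)), rep(0, nrow(hm)), tolerance = 1e-12)
  expect_equal(unname(apply(hm, 1, sd)), rep(1, nrow(hm)), tolerance = 1e-12)
  dirs <- attr(hm, "direction")
  expect_true(all(diff(match(dirs, c("positive", "negative"))) >= 0))
  # positive rows rise along the displayed column order
  pos <- hm[dirs == "positive", , drop = FALSE]
  trend <- apply(pos, 1, function(r) cor(r, seq_along(r)))
  expect_true(all(trend > 0))
})

test_that("empty signatures are rejected by the heatmap view", {
  sim <- simulate_spatial(n_genes = 30, effect_size = 0, seed = 23)
  norm <- q3_normalize(sim$data)
  sig <- bonferroni_select(correlate_genes(norm, sim$true_pseudotime))
  if (!any(sig$selected)) {
    expect_error(signature_heatmap_order(norm, sig, sim$true_pseudotime),
                 "no selected genes")
  } else {
    succeed()
  }
})
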