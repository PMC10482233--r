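test_that("Jaccard index matches set arithmetic", {
  a <- c(p1 = "x", p2 = "x", p3 = "x", p4 = "y")
  b <- c(p1 = "u", p2 = "v", p3 = "v", p4 = "v")
  J <- jaccard_matrix(a, b)
  # A(x) = {p1,p2,p3}, B(v) = {p2,p3,p4}: 2/4
  expect_equal(J$jaccard[J$class == "x" & J$group == "v"], 0.5)
  expect_equal(J$jaccard[J$class == "x" & J$group == "u"], 1 / 3)

  # identical partitions: matching classes have index 1
  self <- jaccard_matrix(a, a)
  expect_equal(self$jaccard[self$class == self$group], c(1, 1))
  expect_true(all(J$jaccard >= 0 & J$jaccard <= 1))
})

test_that("Jaccard is symmetric and matches a brute-force oracle", {
  set.seed(10)
  ids <- sprintf("p%03d", 1:300)
  a <- setNames(sample(c("c1", "c2", "c3"), 300, replace = TRUE), ids)
  b <- setNames(sample(c("g1", "g2", "g3"), 300, replace = TRUE), ids)
  J <- jaccard_matrix(a, b)
  Jt <- jaccard_matrix(b, a)
  for (k in seq_len(nrow(J))) {
    # oracle: naive set loop
    A <- ids[a == J$class[k]]
    B <- ids[b == J$group[k]]
    inter <- sum(A %in% B)
    expect_equal(J$jaccard[k], inter / (length(A) + length(B) - inter))
    # symmetry
    expect_equal(
      J$jaccard[k],
      Jt$jaccard[Jt$class == J$group[k] & Jt$group == J$class[k]]
    )
  }
  expect_error(jaccard_matrix(a, setNames(b, rev(sprintf("q%03d", 1:300)))),
               "universes")
})

test_that("2x2 Fisher p-values come from hypergeometric enumeration", {
  f <- fisher_association(matrix(c(3, 1, 1, 3), 2))
  expect_equal(f$p_value, 34 / 70, tolerance = 1e-12)
  expect_identical(f$method, "exact_2x2")
  expect_equal(fisher_association(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  # dual route: agreement with stats::fisher.test on random tables
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_association(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_association(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("r x c tables use the exact network test when affordable", {
  tab <- diag(20, 3)
  f <- fisher_association(tab)
  expect_identical(f$method, "exact_network")
  expect_lt(f$p_value, 1e-6)
})

test_that("Monte-Carlo Fisher p stays within 3 simulation SEs of exact", {
  tab <- matrix(c(60, 45, 30, 40, 55, 70), nrow = 2, byrow = TRUE)
  # total 300 forces the seeded Monte-Carlo route
  f <- fisher_association(tab, mc_reps = 20000, seed = 5)
  expect_identical(f$method, "monte_carlo")
  exact <- stats::fisher.test(tab, workspace = 2e7)$p.value
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(f$p_value - exact), 3 * se + 1e-4)
  # determinism under the seed
  expect_equal(f$p_value,
               fisher_association(tab, mc_reps = 20000, seed = 5)$p_value)
})

test_that("subtype proportion rows sum to one with the Fisher p attached", {
  sig <- make_signature()
  cs <- simulate_cohort(sig, n_patients = 600, subtype_enrichment_odds = 8,
                        seed = 900)
  sc <- pseudotime_score(cs$data, sig)
  rep <- subtype_proportions(
    sc, setNames(cs$data$patients$subtype, cs$data$patients$patient_id),
    mc_reps = 5000, seed = 1
  )
  sums <- rowSums(rep$proportions[, c("low", "intermediate", "high")])
  expect_equal(unname(sums), rep(1, nrow(rep$proportions)))
  expect_lt(rep$fisher_p, 0.01)
  # the tilted subtype concentrates in the low tercile
  ezb <- rep$proportions[rep$proportions$subtype == "EZB", ]
  expect_identical(names(which.max(unlist(ezb[, -1]))), "low")
})

test_that("planted low-tercile subtype enrichment is detected consistently", {
  sig <- make_signature()
  modal <- sapply(1:20, function(s) {
    cs <- simulate_cohort(sig, n_patients = 600, subtype_enrichment_odds = 8,
                          seed = 900 + s)
    sc <- pseudotime_score(cs$data, sig)
    rep <- subtype_proportions(
      sc, setNames(cs$data$patients$subtype, cs$data$patients$patient_id),
      mc_reps = 2000, seed = s
    )
    ezb <- rep$proportions[rep$proportions$subtype == "EZB", ]
    names(which.max(unlist(ezb[, -1])))
  })
  expect_gte(mean(modal == "low"), 0.95)
})

test_that("patients without subtype labels are excluded pairwise", {
  scored <- tibble::tibble(
    patient_id = sprintf("p%d", 1:9),
    group = factor(rep(c("low", "intermediate", "high"), 3),
                   levels = c("low", "intermediate", "high"))
  )
  subtype <- c(rep("EZB", 4), rep("BN2", 3), NA, NA)
  rep <- subtype_proportions(scored, subtype, mc_reps = 1000, seed = 1)
  expect_equal(rep$n_excluded, 2)
  expect_equal(sum(rep$table), 7)
  expect_error(subtype_proportions(scored, rep(NA, 9)), "No patient")
})
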