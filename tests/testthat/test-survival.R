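test_that("Kaplan-Meier product-limit arithmetic matches hand computation", {
  d <- data.frame(t = c(1, 2, 3), e = c(1, 1, 0))
  km <- km_fit(d, t, e)
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 1 / 3))

  # all censored: flat survival at 1
  d2 <- data.frame(t = c(2, 4, 6), e = c(0, 0, 0))
  expect_true(all(km_fit(d2, t, e)$estimate == 1))

  expect_error(km_fit(data.frame(t = c(-1, 2), e = c(1, 1)), t, e),
               "Negative")
})

test_that("tied events are processed before censorings (6-subject oracle)", {
  # risk-set table by hand:
  # t=2: 6 at risk, 1 event -> 5/6; censor leaves afterwards
  # t=3: 4 at risk, 1 event -> 5/6 * 3/4 = 5/8
  # t=4: 3 at risk, 1 event -> 5/8 * 2/3 = 5/12; censor at same time leaves
  # t=5: 1 at risk, 1 event -> 0
  d <- data.frame(t = c(2, 2, 3, 4, 4, 5), e = c(1, 0, 1, 1, 0, 1))
  km <- km_fit(d, t, e)
  expect_equal(km$time, c(2, 3, 4, 5))
  expect_equal(km$n_risk, c(6, 4, 3, 1))
  expect_equal(km$estimate, c(5 / 6, 5 / 8, 5 / 12, 0))
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(8)
  t <- rexp(40)
  d <- data.frame(t = t, e = 1)
  km <- km_fit(d, t, e)
  emp <- sapply(km$time, function(x) mean(t > x))
  expect_equal(km$estimate, emp)
})

test_that("log-rank is null on duplicated groups and matches a hand O-E table", {
  d <- data.frame(t = rep(c(1, 3, 4, 7, 9), 2), e = rep(c(1, 0, 1, 1, 1), 2),
                  g = rep(c("a", "b"), each = 5))
  lr <- logrank_test(d, t, e, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 2 - 1)

  # 12-subject, 3-group oracle: sum over event times of observed minus
  # expected events per group, with the pooled hypergeometric variance
  d3 <- data.frame(
    t = c(1, 2, 3, 4, 5, 6, 2, 3, 5, 7, 8, 9),
    e = c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 1, 0),
    g = rep(c("a", "b", "c"), each = 4)
  )
  ev_times <- sort(unique(d3$t[d3$e == 1]))
  grp <- sort(unique(d3$g))
  OE <- matrix(0, length(grp), 2, dimnames = list(grp, c("O", "E")))
  V <- matrix(0, length(grp), length(grp), dimnames = list(grp, grp))
  for (tt in ev_times) {
    at_risk <- d3$t >= tt
    n <- sum(at_risk)
    dtot <- sum(d3$t == tt & d3$e == 1)
    for (gg in grp) {
      ng <- sum(at_risk & d3$g == gg)
      OE[gg, "O"] <- OE[gg, "O"] + sum(d3$t == tt & d3$e == 1 & d3$g == gg)
      OE[gg, "E"] <- OE[gg, "E"] + dtot * ng / n
    }
    for (g1 in grp) for (g2 in grp) {
      n1 <- sum(at_risk & d3$g == g1); n2 <- sum(at_risk & d3$g == g2)
      V[g1, g2] <- V[g1, g2] +
        if (n > 1) {
          dtot * (n - dtot) / (n - 1) *
            (ifelse(g1 == g2, n1 / n, 0) - n1 * n2 / n^2)
        } else 0
    }
  }
  u <- (OE[, "O"] - OE[, "E"])[1:2]
  chi2_oracle <- drop(t(u) %*% solve(V[1:2, 1:2]) %*% u)
  lr3 <- logrank_test(d3, t, e, g)
  expect_equal(lr3$statistic, chi2_oracle, tolerance = 1e-8)
  expect_equal(lr3$df, 2)
})

test_that("two-group log-rank equals the squared standardized O-E statistic", {
  set.seed(9)
  d <- data.frame(t = rexp(60, rep(c(1, 2), each = 30)),
                  e = rbinom(60, 1, 0.8),
                  g = rep(c("a", "b"), each = 30))
  sd_fit <- survival::survdiff(survival::Surv(t, e) ~ g, data = d)
  z2 <- (sd_fit$obs[1] - sd_fit$exp[1])^2 / sd_fit$var[1, 1]
  expect_equal(logrank_test(d, t, e, g)$statistic, z2, tolerance = 1e-10)
})

test_that("log-rank has near-certain power at HR = 3 with 200 per arm", {
  p <- sapply(1:50, function(s) {
    set.seed(s)
    d <- data.frame(t = c(rexp(200, 1), rexp(200, 3)),
                    e = 1, g = rep(c("a", "b"), each = 200))
    logrank_test(d, t, e, g)$p_value
  })
  expect_gte(mean(p < 0.001), 0.98)
  expect_error(logrank_test(data.frame(t = 1:3, e = 1, g = "a"), t, e, g),
               "2 groups")
})

test_that("Cox recovery is unbiased and uses the stated reference levels", {
  lhr <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 2000
    g <- rep(c("low", "high"), each = n / 2)
    t <- rexp(n, rate = 0.05 * ifelse(g == "low", 2, 1))
    cn <- rexp(n, rate = 0.0125)
    d <- data.frame(time = pmin(t, cn), event = as.integer(t <= cn),
                    group = g)
    fit <- cox_multivariate(d, time, event, group)
    td <- tidy(fit)
    expect_identical(td$term, "grouphigh")  # "low" is the reference
    -td$estimate[td$term == "grouphigh"]    # log HR low vs high
  })
  expect_lt(abs(mean(lhr) - log(2)), 0.05)
})

test_that("a null covariate's HR interval covers 1 at the nominal rate", {
  covered <- sapply(1:40, function(s) {
    set.seed(100 + s)
    n <- 300
    d <- data.frame(time = rexp(n, 0.1), event = 1,
                    group = sample(c("low", "high"), n, TRUE))
    td <- tidy(cox_multivariate(d, time, event, group))
    td$conf_low[1] <= 1 && td$conf_high[1] >= 1
  })
  expect_gte(mean(covered), 0.85)
})

test_that("an independent noise covariate barely moves the group effect", {
  sig <- make_signature()
  cs <- simulate_cohort(sig, n_patients = 800, hazard_ratio_low_vs_high = 2,
                        seed = 55)
  d <- cs$data$patients
  d$group <- cs$true_group
  base <- tidy(cox_multivariate(d, os_time, os_event, group))
  with_noise <- tidy(cox_multivariate(d, os_time, os_event, group, ipi = ipi))
  b0 <- base$estimate[base$term == "grouphigh"]
  b1 <- with_noise$estimate[with_noise$term == "grouphigh"]
  expect_lt(abs(b1 - b0) / abs(b0), 0.1)
})

test_that("multivariate fit dummy-codes COO and IPI against GCB / low", {
  sig <- make_signature()
  cs <- simulate_cohort(sig, n_patients = 500, seed = 66)
  d <- cs$data$patients
  d$group <- cs$true_group
  fit <- cox_multivariate(d, os_time, os_event, group, coo, ipi)
  td <- tidy(fit)
  expect_true(all(c("groupintermediate", "grouphigh", "cooABC",
                    "cooUnclassified", "ipimedium", "ipihigh") %in% td$term))
  expect_false(any(c("grouplow", "cooGCB", "ipilow") %in% td$term))
  expect_true(all(td$conf_low <= td$hr & td$hr <= td$conf_high))
  gl <- glance(fit)
  expect_equal(gl$n, 500)
  expect_error(
    cox_multivariate(data.frame(time = 1:5, event = 0,
                                group = rep(c("low", "high"), c(3, 2))),
                     time, event, group),
    "No events"
  )
})

test_that("the PH check is calibrated under proportional hazards", {
  p <- sapply(1:200, function(s) {
    set.seed(s)
    n <- 150
    g <- rep(c("a", "b"), each = n / 2)
    t <- rexp(n, rate = 0.1 * ifelse(g == "b", 2, 1))
    cn <- rexp(n, 0.02)
    d <- data.frame(time = pmin(t, cn), event = as.integer(t <= cn),
                    group = g)
    tb <- ph_check(cox_multivariate(d, time, event, group))
    tb$p_value[tb$term == "GLOBAL"]
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("crossing hazards are flagged by the PH check", {
  hits <- sapply(1:30, function(s) {
    set.seed(s)
    n <- 400
    g <- rep(c(0, 1), each = n / 2)
    h1 <- 0.2
    t0 <- log(2) / h1
    t <- sapply(seq_len(n), function(i) {
      if (g[i] == 0) return(rexp(1, h1))
      t1 <- rexp(1, 2 * h1)
      if (t1 < t0) t1 else t0 + rexp(1, h1 / 2)
    })
    d <- data.frame(time = t, event = 1,
                    group = ifelse(g == 1, "b", "a"))
    tb <- ph_check(cox_multivariate(d, time, event, group))
    tb$p_value[tb$term == "GLOBAL"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
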