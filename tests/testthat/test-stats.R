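test_that("normality gate: parametric for normal draws, nonparametric for skewed or tiny groups", {
  set.seed(101)
  # normal data: parametric path in most seeded draws
  hits <- 0L
  for (r in 1:40) {
    d <- tibble::tibble(group = rep(c("a", "b"), each = 30),
                        value = rnorm(60))
    if (assess_normality(d)$parametric) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.85)

  # heavy lognormal: nonparametric path nearly always
  miss <- 0L
  for (r in 1:40) {
    d <- tibble::tibble(group = rep(c("a", "b"), each = 30),
                        value = exp(rnorm(60, sd = 1.5)))
    if (!assess_normality(d)$parametric) miss <- miss + 1L
  }
  expect_gte(miss / 40, 0.9)

  # n = 2 group: warning and nonparametric
  d2 <- tibble::tibble(group = c("a", "a", "b", "b", "b"),
                       value = c(1, 2, 1, 2, 3))
  expect_warning(res <- assess_normality(d2), "n < 3")
  expect_false(res$parametric)
})

test_that("two-group comparisons: symmetric null, separation, exact Mann-Whitney enumeration", {
  # identical samples: t statistic 0, one-tailed p exactly 0.5
  a <- c(1.2, 2.1, 2.9, 3.4, 4.7)
  d <- tibble::tibble(group = rep(c("a", "b"), each = 5), value = c(a, a))
  res <- compare_two(d, alternative = "greater", parametric = TRUE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.5)

  # well-separated samples in the hypothesized direction
  d2 <- tibble::tibble(group = rep(c("a", "b"), each = 8),
                       value = c(rnorm(8, 0, 0.1), rnorm(8, 5, 0.1)))
  res2 <- compare_two(d2, alternative = "less", parametric = TRUE)
  expect_lt(res2$p_value, 1e-3)

  # Mann-Whitney {1,2,3} vs {4,5,6}: U = 0, exact one-tailed p = 1/20
  d3 <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                       value = c(1, 2, 3, 4, 5, 6))
  res3 <- compare_two(d3, alternative = "less", parametric = FALSE)
  expect_equal(unname(res3$statistic), 0)
  expect_equal(res3$p_value, 1 / choose(6, 3))

  # the tail is a required input
  expect_error(compare_two(d3, parametric = FALSE), "required")

  # tidy/glance carry stars; p exactly 0.05 is "ns" under the strict < rule
  expect_equal(glance(res3)$stars, "ns")
  expect_equal(glance(res2)$stars, "****")
})

test_that("Kruskal-Wallis H matches the hand-evaluated rank formula; Dunn p_adj >= raw", {
  d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
                      value = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  res <- compare_multi(d, control = "a", parametric = FALSE)
  # independent evaluation of H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  r <- rank(d$value)
  rbar <- tapply(r, d$group, mean)
  H <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  expect_equal(unname(res$statistic), H)
  expect_equal(unname(res$statistic), 7.2)
  cmp <- res$comparisons
  expect_true(all(cmp$p_adj >= cmp$p_raw - 1e-15))
  expect_true(all(cmp$p_adj <= 1))
  expect_equal(nrow(cmp), 2L)

  # ANOVA + Dunnett: flags only the shifted group
  set.seed(7)
  d2 <- tibble::tibble(
    group = rep(c("control", "t1", "t2"), each = 20),
    value = c(rnorm(20), rnorm(20), rnorm(20, mean = 3))
  )
  res2 <- compare_multi(d2, control = "control", parametric = TRUE)
  cmp2 <- res2$comparisons
  p_t1 <- cmp2$p_adj[grepl("t1", cmp2$comparison)]
  p_t2 <- cmp2$p_adj[grepl("t2", cmp2$comparison)]
  expect_gt(p_t1, 0.05)
  expect_lt(p_t2, 1e-4)
  expect_true(all(cmp2$p_adj >= cmp2$p_raw - 1e-12))

  expect_error(compare_multi(d2, control = "zzz"), "control")
})

test_that("Dunnett flags the one shifted group and controls the family error", {
  set.seed(31)
  hits <- 0L
  for (r in 1:100) {
    d <- tibble::tibble(
      group = rep(c("control", "t1", "t2"), each = 20),
      value = c(rnorm(20), rnorm(20), rnorm(20, mean = 3)))
    cmp <- compare_multi(d, control = "control",
                         parametric = TRUE)$comparisons
    sig <- cmp$p_adj < 0.05
    flagged_only_t2 <- sig[grepl("t2", cmp$comparison)] &&
      !sig[grepl("t1", cmp$comparison)]
    if (flagged_only_t2) hits <- hits + 1L
  }
  expect_gte(hits / 100, 0.95)

  # under the null, Dunn + Bonferroni keeps the family error at or below ~5%
  set.seed(32)
  fam <- 0L
  for (r in 1:400) {
    d <- tibble::tibble(group = rep(c("control", "t1", "t2"), each = 12),
                        value = rnorm(36))
    cmp <- compare_multi(d, control = "control",
                         parametric = FALSE)$comparisons
    if (any(cmp$p_adj < 0.05)) fam <- fam + 1L
  }
  expect_lte(fam / 400, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("Kaplan-Meier matches hand product-limit and empirical survival", {
  # 3 deaths at t = 2, 4, 6: S = 2/3, 1/3, 0
  tab <- tibble::tibble(time_days = c(2, 4, 6), event = c(1, 1, 1),
                        group = "a")
  km <- km_estimate(tab)
  td <- tidy(km)
  expect_equal(td$estimate, c(2 / 3, 1 / 3, 0))

  # all censored: S identically 1
  tabc <- tibble::tibble(time_days = c(2, 4, 6), event = c(0, 0, 0),
                         group = "a")
  tdc <- tidy(km_estimate(tabc))
  expect_true(all(tdc$estimate == 1))

  # without censoring the curve equals the empirical survival function
  set.seed(5)
  tt <- sort(2 * ceiling(rexp(60, 0.08) / 2))
  tabe <- tibble::tibble(time_days = tt, event = 1, group = "a")
  tde <- tidy(km_estimate(tabe))
  for (k in seq_len(nrow(tde))) {
    expect_equal(tde$estimate[k], mean(tt > tde$time[k]))
  }
  # non-increasing, S(0) = 1 implied by first risk set
  expect_true(all(diff(tde$estimate) <= 1e-12))
})

test_that("log-rank: zero on duplicated groups, hand-tallied toy table, relabel invariance", {
  # duplicated groups: statistic 0, p = 1
  base <- tibble::tibble(time_days = c(2, 4, 6, 8), event = 1)
  dup <- dplyr::bind_rows(dplyr::mutate(base, group = "a"),
                          dplyr::mutate(base, group = "b"))
  res <- logrank(dup, "a", "b")
  expect_equal(unname(res$statistic), 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # toy table: A deaths at 2 and 4, B deaths at 6 and 8
  toy <- tibble::tibble(time_days = c(2, 4, 6, 8), event = 1,
                        group = c("A", "A", "B", "B"))
  res2 <- logrank(toy, "A", "B")
  # hand tally of observed and expected events per distinct death time
  at_risk <- function(t, g) sum(toy$time_days >= t & toy$group == g)
  O <- 0; E <- 0; V <- 0
  for (t in c(2, 4, 6, 8)) {
    nA <- at_risk(t, "A"); nB <- at_risk(t, "B"); n <- nA + nB
    dtot <- sum(toy$time_days == t)
    dA <- sum(toy$time_days == t & toy$group == "A")
    O <- O + dA
    E <- E + dtot * nA / n
    if (n > 1) V <- V + dtot * (nA / n) * (nB / n) * (n - dtot) / (n - 1)
  }
  chisq_hand <- (O - E)^2 / V
  expect_equal(unname(res2$statistic), chisq_hand, tolerance = 1e-12)

  # invariance to relabeling the two groups
  res3 <- logrank(toy, "B", "A")
  expect_equal(res3$statistic, res2$statistic, tolerance = 1e-12)

  # zero-event group warns but stays defined
  ze <- tibble::tibble(time_days = c(2, 4, 2, 4), event = c(1, 1, 0, 0),
                       group = c("A", "A", "B", "B"))
  expect_warning(res4 <- logrank(ze, "A", "B"), "zero observed deaths")
  expect_true(is.finite(res4$statistic))
})

test_that("relative expression: closed forms and noisy recovery inside the CI", {
  # identical Ct in both groups -> fold 1
  flat <- generate_ct_table(c(g1 = 1), replicates = 4, noise_sd = 0, seed = 2)
  r1 <- relative_expression(flat, "g1", "rp49", "control")
  expect_equal(r1$fold_change, 1)

  # ddCt exactly -1 -> fold 2
  two <- generate_ct_table(c(g1 = 2), replicates = 4, noise_sd = 0, seed = 2)
  r2 <- relative_expression(two, "g1", "rp49", "control")
  expect_equal(r2$fold_change, 2)

  # planted fold 2 with Ct noise: the 95% CI covers the truth at roughly its
  # nominal rate over repeated fixtures, and recovery stays within 3 SE
  se_ddct <- 0.2 * sqrt(2) * sqrt(2 / 6)
  covered <- 0L
  for (s in 1:50) {
    noisy <- generate_ct_table(c(g1 = 2), replicates = 6, noise_sd = 0.2,
                               seed = s)
    r3 <- relative_expression(noisy, "g1", "rp49", "control")
    if (r3$conf_low <= 2 && 2 <= r3$conf_high) covered <- covered + 1L
    expect_lt(abs(r3$delta_delta_ct + 1), 5 * se_ddct)
  }
  expect_gte(covered / 50, 0.85)

  noisy <- generate_ct_table(c(g1 = 2), replicates = 6, noise_sd = 0.2,
                             seed = 1)
  expect_error(relative_expression(noisy, "g1", "nope", "control"),
               "reference gene")
  expect_error(relative_expression(noisy, "nope", "rp49", "control"),
               "target gene")
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
               c("ns", "*", "**", "***", "****"))
})
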