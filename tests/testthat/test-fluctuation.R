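test_that("Lea-Coulson pmf recursion matches its closed-form anchors", {
  # m = 0 is the point mass at zero
  p0 <- ld_pmf(0, 5)
  expect_equal(p0$prob, c(1, 0, 0, 0, 0, 0))

  # Poisson zero class and the first recursion step
  for (m in c(0.3, 1, 4.7)) {
    p <- ld_pmf(m, 10)
    expect_equal(p$prob[1], exp(-m))
    expect_equal(p$prob[2], m * exp(-m) / 2)
    expect_true(all(p$prob >= 0))
  }

  # normalization: support + tail = 1 to 1e-12 at a generous cap
  for (m in c(0.5, 2, 10, 50)) {
    p <- ld_pmf(m, 10000)
    expect_lt(abs(sum(p$prob) + p$tail_mass - 1), 1e-12)
  }
  expect_error(ld_pmf(-1, 10))
})

test_that("ML fit reproduces closed-form and boundary cases", {
  # all-zero counts: likelihood exp(-n m), maximum at the boundary
  f0 <- fit_mutation_rate(counts = c(0, 0, 0, 0), Nt = 1e8)
  expect_equal(f0$m_hat, 0)
  expect_equal(f0$mu_hat, 0)
  expect_equal(f0$ci_low, 0)
  expect_gt(f0$ci_high, 0)

  # counts [0,0,0,1]: loglik log(m/2) - 4m, root at m = 1/4
  f1 <- fit_mutation_rate(counts = c(0, 0, 0, 1), Nt = 1e8)
  expect_equal(f1$m_hat, 0.25, tolerance = 1e-6)
  expect_equal(f1$mu_hat, f1$m_hat / 1e8)
  expect_lt(f1$ci_low, 0.25)
  expect_gt(f1$ci_high, 0.25)

  # scale consistency: Nt rescaling leaves m_hat, divides mu_hat
  ex <- sim_fluctuation(2e-9, 1e9, 30, seed = 33)
  fa <- fit_mutation_rate(fluctuation_experiment(ex$counts, 1e9), ci = FALSE)
  fb <- fit_mutation_rate(fluctuation_experiment(ex$counts, 5e9), ci = FALSE)
  expect_equal(fa$m_hat, fb$m_hat)
  expect_equal(fa$mu_hat, 5 * fb$mu_hat)
})

test_that("per-cell rate conversion is exact division", {
  expect_equal(per_cell_rate(0.25, 1e8), 2.5e-9)
  expect_equal(per_cell_rate(0, 1e9), 0)
  expect_equal(per_cell_rate(3, 2e9), per_cell_rate(3, 1e9) / 2)
  expect_error(per_cell_rate(1, 0))
})

test_that("fit methods behave like a standard model object", {
  ex <- sim_fluctuation(1e-9, 1e9, 40, seed = 44)
  fit <- fit_mutation_rate(ex)
  expect_s3_class(fit, "ldfit")
  expect_named(coef(fit), c("m", "mu"))
  expect_equal(unname(coef(fit)["mu"]), fit$m_hat / 1e9)
  ci <- confint(fit, "mu")
  expect_lt(ci[1], fit$mu_hat)
  expect_gt(ci[2], fit$mu_hat)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "fluctuation_experiment")
  expect_output(print(fit), "per-cell rate")
})

test_that("profile intervals cover the truth at roughly nominal rate", {
  m_true <- 2
  hits <- vapply(1:60, function(i) {
    ex <- sim_fluctuation(m_true / 1e9, 1e9, 84, seed = 500 + i)
    f <- fit_mutation_rate(ex)
    f$ci_low <= m_true && m_true <= f$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("estimator recovers the mutation parameter with small bias", {
  for (m_true in c(0.5, 2)) {
    mhat <- vapply(1:80, function(i) {
      ex <- sim_fluctuation(m_true / 1e9, 1e9, 84, seed = 700 + i)
      fit_mutation_rate(ex, ci = FALSE)$m_hat
    }, numeric(1))
    expect_lt(abs(mean(mhat) / m_true - 1), 0.05)
  }
})

test_that("jackpot counts are pooled into the tail, not dropped", {
  counts <- c(rep(0, 40), rep(2, 10), 3e4)  # one count above the cap
  fit <- fit_mutation_rate(counts = counts, Nt = 1e9, ci = FALSE)
  expect_gt(fit$m_hat, 0)
  # removing the jackpot lowers the estimate: the tail carries information
  fit2 <- fit_mutation_rate(counts = counts[1:50], Nt = 1e9, ci = FALSE)
  expect_gt(fit$m_hat, fit2$m_hat)
})

test_that("two-sample LRT is null on identical data and detects separation", {
  ex <- sim_fluctuation(1e-9, 1e9, 50, seed = 55)
  t0 <- lrt_mutation_rate(ex, ex)
  expect_lt(t0$statistic, 1e-6)
  expect_gt(t0$p_value, 0.999)

  exA <- sim_fluctuation(5e-10, 1e9, 84, seed = 56)
  exB <- sim_fluctuation(5e-9, 1e9, 84, seed = 57)
  t1 <- lrt_mutation_rate(exA, exB)
  expect_lt(t1$p_value, 0.05)
  expect_gt(t1$statistic, qchisq(0.95, 1))

  # differing Nt under a common rate is respected by the null model
  exC <- sim_fluctuation(1e-9, 1e9, 60, seed = 58)
  exD <- sim_fluctuation(1e-9, 5e9, 60, seed = 59)
  t2 <- lrt_mutation_rate(exC, exD)
  expect_gt(t2$p_value, 0.001)
})

test_that("rate_table composes fits and pairwise tests", {
  exps <- list(
    wt = sim_fluctuation(5e-10, 1e9, 30, seed = 60),
    mut = sim_fluctuation(5e-9, 1e9, 30, seed = 61),
    dup = sim_fluctuation(5e-10, 1e9, 30, seed = 60))
  tab <- rate_table(exps, ci = FALSE)
  expect_equal(tab$estimates$strain, c("wt", "mut", "dup"))
  expect_equal(nrow(tab$tests), 3)
  dup_row <- tab$tests[tab$tests$strain_a == "wt" &
                         tab$tests$strain_b == "dup", ]
  expect_gt(dup_row$p_value, 0.999)  # identical seeds, identical data
  expect_equal(tab$estimates$mu_hat[1], tab$estimates$mu_hat[3])
})
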