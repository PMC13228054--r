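#' Lea-Coulson probability mass function
#'
#' Probability of observing `n` resistant mutants in one culture under the
#' Lea-Coulson formulation of the Luria-Delbruck distribution (constant
#' mutant fitness, full plating): a compound Poisson with `m` expected
#' mutation events per culture and clone-size law `P(J = j) = 1/(j(j+1))`.
#' Computed by the exact recursion
#' `p_0 = exp(-m)`, `p_n = (m/n) * sum_{j=1..n} p_{n-j} / (j+1)`.
#'
#' @param m Expected number of mutation events per culture, `>= 0`.
#' @param n_max Largest count evaluated.
#' @return An object of class `"ld_pmf"`: list with `m`, `prob` (numeric
#'   vector of `p_0 .. p_n_max`), `tail_mass` (`1 - sum(prob)`).
#' @examples
#' p <- ld_pmf(1, 5)
#' p$prob[1]  # exp(-1)
#' p$prob[2]  # exp(-1)/2
#' @export
ld_pmf <- function(m, n_max) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 0,
            n_max >= 0, n_max == floor(n_max))
  prob <- ld_pmf_cpp(m, as.integer(n_max))
  structure(list(m = m, prob = prob,
                 tail_mass = max(0, 1 - sum(prob))),
            class = "ld_pmf")
}

#' @export
print.ld_pmf <- function(x, ...) {
  cat(sprintf("Lea-Coulson pmf: m = %g, support 0..%d, tail mass %.3g\n",
              x$m, length(x$prob) - 1L, x$tail_mass))
  invisible(x)
}

# Log-likelihood of capped counts under the Lea-Coulson pmf.
# Counts above `cap` are pooled into a tail category of probability
# 1 - sum_{0..cap} p_n (jackpot robustness without winsorizing).
.ld_loglik <- function(m, tab, cap) {
  # tab: list(counts = sorted unique capped counts, freq, n_tail, n_max)
  if (m == 0) {
    if (any(tab$counts > 0) || tab$n_tail > 0) return(-Inf)
    return(0)
  }
  n_max <- if (tab$n_tail > 0) as.integer(cap) else tab$n_max
  p <- ld_pmf_cpp(m, n_max)
  ll <- sum(tab$freq * log(p[tab$counts + 1L]))
  if (tab$n_tail > 0)
    ll <- ll + tab$n_tail * log(max(1 - sum(p), 1e-300))
  ll
}

.ld_tabulate <- function(counts, cap) {
  over <- counts > cap
  kept <- counts[!over]
  u <- sort(unique(kept))
  list(counts = as.integer(u),
       freq = as.integer(tabulate(match(kept, u), length(u))),
       n_tail = sum(over),
       n_max = if (length(u)) max(u) else 0L)
}

# Crude starting value for m: zero-class estimator when zeros exist,
# otherwise a fixed-point pass on the Lea-Coulson median relation
# r/m - log(m) ~ 1.24.
.ld_start <- function(counts) {
  z <- mean(counts == 0)
  if (z > 0 && z < 1) return(-log(z))
  r <- max(1, median(counts))
  m <- max(r, 1)
  for (i in 1:20) m <- r / (1.24 + max(log(m), 0))
  max(m, 1e-3)
}

#' Fit the mutation parameter of a fluctuation experiment
#'
#' Maximum-likelihood estimation of the expected number of mutation events
#' per culture, `m`, under the Lea-Coulson model (see [ld_pmf()]), from the
#' distribution of resistant-colony counts across parallel cultures. The
#' per-cell mutation rate is the fitted parameter divided by the mean final
#' population size, `mu = m / Nt`. Counts above `cap` are pooled into a
#' single tail category so that jackpot cultures contribute through the tail
#' mass rather than an enormous pmf support. The 95% interval is obtained by
#' profile likelihood (chi-square(1) drop of `qchisq(level, 1)/2`).
#'
#' @param experiment A [fluctuation_experiment()] (or an object coercible by
#'   the `counts`/`Nt` method below).
#' @param counts Alternative interface: numeric vector of per-culture mutant
#'   counts.
#' @param Nt Final population size (per-strain mean), cells.
#' @param cap Pooling cap for jackpot counts (default `1e4`).
#' @param ci Compute the profile-likelihood interval (default `TRUE`; skip
#'   for speed in large simulation studies).
#' @param level Confidence level of the interval.
#' @return An object of class `"ldfit"` with components `m_hat`, `mu_hat`,
#'   `ci_low`, `ci_high` (on `m`), `loglik`, `Nt`, `n_cultures`, `counts`,
#'   `cap`, `level`. Methods: `print`, `summary`, `coef`, `confint`,
#'   `logLik`, `simulate`.
#' @examples
#' fit <- fit_mutation_rate(counts = c(0, 0, 0, 1), Nt = 1e8)
#' coef(fit)  # m = 0.25, mu = 2.5e-9
#' @export
fit_mutation_rate <- function(experiment = NULL, counts = NULL, Nt = NULL,
                              cap = 1e4, ci = TRUE, level = 0.95) {
  if (is.null(experiment)) {
    experiment <- fluctuation_experiment(counts, Nt)
  } else if (!inherits(experiment, "fluctuation_experiment")) {
    stop("experiment must be a fluctuation_experiment (or pass counts/Nt)")
  }
  counts <- experiment$counts
  Nt <- experiment$Nt
  n <- length(counts)
  if (n < 2) stop("need at least 2 cultures")
  tab <- .ld_tabulate(counts, cap)
  drop <- qchisq(level, df = 1) / 2
  if (all(counts == 0)) {
    # likelihood exp(-n m), maximized at the boundary m = 0
    ci_high <- if (ci) drop / n else NA_real_
    return(.ldfit(0, 0, if (ci) 0 else NA_real_, ci_high, 0,
                  experiment, cap, level))
  }
  nll <- function(logm) -.ld_loglik(exp(logm), tab, cap)
  m0 <- .ld_start(counts)
  lo <- log(m0) - 8; hi <- log(m0) + 8
  for (i in 1:6) {
    opt <- optimize(nll, c(lo, hi), tol = 1e-10)
    at_edge <- min(opt$minimum - lo, hi - opt$minimum) < 0.01
    if (!at_edge) break
    lo <- lo - 6; hi <- hi + 6
  }
  m_hat <- exp(opt$minimum)
  ll_max <- -opt$objective
  ci_low <- ci_high <- NA_real_
  if (ci) {
    g <- function(logm) (-nll(logm)) - (ll_max - drop)
    # lower bound
    lo_b <- opt$minimum
    step <- 1
    repeat {
      if (g(lo_b - step) < 0) break
      lo_b <- lo_b - step
      if (lo_b < opt$minimum - 60) break
    }
    ci_low <- if (lo_b < opt$minimum - 60) 0 else
      exp(uniroot(g, c(lo_b - step, opt$minimum), tol = 1e-8)$root)
    hi_b <- opt$minimum
    repeat {
      if (g(hi_b + step) < 0) break
      hi_b <- hi_b + step
      if (hi_b > opt$minimum + 60) stop("profile CI upper bound diverged")
    }
    ci_high <- exp(uniroot(g, c(opt$minimum, hi_b + step), tol = 1e-8)$root)
  }
  .ldfit(m_hat, m_hat / Nt, ci_low, ci_high, ll_max, experiment, cap, level)
}

.ldfit <- function(m_hat, mu_hat, ci_low, ci_high, loglik, experiment,
                   cap, level) {
  structure(list(m_hat = m_hat, mu_hat = mu_hat,
                 ci_low = ci_low, ci_high = ci_high, loglik = loglik,
                 Nt = experiment$Nt, n_cultures = experiment$n_cultures,
                 counts = experiment$counts, cap = cap, level = level),
            class = "ldfit")
}

#' Convert a mutation parameter to a per-cell rate
#'
#' @param m_hat Mutation parameter (expected mutation events per culture).
#' @param Nt Final population size, cells, `> 0`.
#' @return Per-cell mutation rate `m_hat / Nt`.
#' @export
per_cell_rate <- function(m_hat, Nt) {
  stopifnot(Nt > 0, m_hat >= 0)
  m_hat / Nt
}

#' @export
print.ldfit <- function(x, ...) {
  cat("Lea-Coulson ML fit (", x$n_cultures, " cultures, Nt = ",
      format(x$Nt, scientific = TRUE), ")\n", sep = "")
  cat(sprintf("  m = %.4g", x$m_hat))
  if (!is.na(x$ci_low))
    cat(sprintf("  [%.4g, %.4g] (%d%% profile)", x$ci_low, x$ci_high,
                round(100 * x$level)))
  cat("\n")
  cat(sprintf("  per-cell rate mu = %.4g\n", x$mu_hat))
  invisible(x)
}

#' @export
summary.ldfit <- function(object, ...) {
  out <- c(m = object$m_hat, mu = object$mu_hat,
           ci_low_m = object$ci_low, ci_high_m = object$ci_high,
           ci_low_mu = object$ci_low / object$Nt,
           ci_high_mu = object$ci_high / object$Nt,
           loglik = object$loglik, n_cultures = object$n_cultures,
           Nt = object$Nt)
  class(out) <- "summary.ldfit"
  out
}

#' @export
print.summary.ldfit <- function(x, ...) {
  y <- unclass(x)
  print(signif(y, 5))
  invisible(x)
}

#' @export
coef.ldfit <- function(object, ...) {
  c(m = object$m_hat, mu = object$mu_hat)
}

#' @export
confint.ldfit <- function(object, parm = "m", level = NULL, ...) {
  if (!is.null(level) && level != object$level)
    stop("interval was profiled at level ", object$level,
         "; refit to change it")
  parm <- match.arg(parm, c("m", "mu"))
  ci <- c(object$ci_low, object$ci_high)
  if (parm == "mu") ci <- ci / object$Nt
  matrix(ci, 1, 2, dimnames = list(parm, c("low", "high")))
}

#' @export
logLik.ldfit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n_cultures,
            class = "logLik")
}

#' @export
simulate.ldfit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i)
    sim_fluctuation(object$mu_hat, object$Nt, object$n_cultures)))
}

#' Two-sample likelihood-ratio test of mutation rates
#'
#' Tests whether two fluctuation experiments share a common per-cell
#' mutation rate. Under the null a single rate `mu` drives both strains with
#' `m_A = mu * Nt_A` and `m_B = mu * Nt_B`; under the alternative each
#' strain has its own rate. The statistic is `-2 (loglik_null - loglik_alt)`
#' compared to a chi-square with 1 degree of freedom.
#'
#' @param a,b [fluctuation_experiment()] objects (or `"ldfit"` objects, whose
#'   stored counts are reused).
#' @param cap Jackpot pooling cap, as in [fit_mutation_rate()].
#' @return An object of class `"ld_lrt"`: `statistic`, `df`, `p_value`,
#'   plus the two alternative fits (`fit_a`, `fit_b`) and the common rate
#'   `mu_null`.
#' @export
lrt_mutation_rate <- function(a, b, cap = 1e4) {
  as_exp <- function(x)
    if (inherits(x, "ldfit")) fluctuation_experiment(x$counts, x$Nt)
    else if (inherits(x, "fluctuation_experiment")) x
    else stop("inputs must be fluctuation experiments or ldfit objects")
  a <- as_exp(a); b <- as_exp(b)
  fa <- fit_mutation_rate(a, cap = cap, ci = FALSE)
  fb <- fit_mutation_rate(b, cap = cap, ci = FALSE)
  ll_alt <- fa$loglik + fb$loglik
  ta <- .ld_tabulate(a$counts, cap)
  tb <- .ld_tabulate(b$counts, cap)
  nll_null <- function(logmu) {
    mu <- exp(logmu)
    -(.ld_loglik(mu * a$Nt, ta, cap) + .ld_loglik(mu * b$Nt, tb, cap))
  }
  if (all(a$counts == 0) && all(b$counts == 0)) {
    ll_null <- 0
    mu_null <- 0
  } else {
    mu0 <- max((fa$m_hat + fb$m_hat) / (a$Nt + b$Nt), 1e-300)
    lo <- log(mu0) - 8; hi <- log(mu0) + 8
    for (i in 1:6) {
      opt <- optimize(nll_null, c(lo, hi), tol = 1e-10)
      if (min(opt$minimum - lo, hi - opt$minimum) >= 0.01) break
      lo <- lo - 6; hi <- hi + 6
    }
    ll_null <- -opt$objective
    mu_null <- exp(opt$minimum)
  }
  stat <- max(-2 * (ll_null - ll_alt), 0)
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 mu_null = mu_null, fit_a = fa, fit_b = fb),
            class = "ld_lrt")
}

#' @export
print.ld_lrt <- function(x, ...) {
  cat("Two-sample likelihood-ratio test (Lea-Coulson)\n")
  cat(sprintf("  mu_A = %.4g, mu_B = %.4g, common mu = %.4g\n",
              x$fit_a$mu_hat, x$fit_b$mu_hat, x$mu_null))
  cat(sprintf("  X2 = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-strain mutation-rate table with pairwise tests
#'
#' Fits every strain's fluctuation experiment by ML and runs the two-sample
#' likelihood-ratio test for the requested strain pairs (all pairs by
#' default). Raw p-values are reported without multiplicity correction.
#'
#' @param experiments Named list of [fluctuation_experiment()] objects.
#' @param comparisons List of 2-element character vectors naming strain
#'   pairs; `NULL` = all pairs.
#' @param cap Jackpot pooling cap.
#' @param ci Compute profile intervals for each strain fit.
#' @return An object of class `"rate_table"`: list with `estimates` (data
#'   frame: strain, m_hat, mu_hat, ci bounds, loglik, n_cultures, Nt) and
#'   `tests` (data frame: strain_a, strain_b, statistic, p_value).
#' @export
rate_table <- function(experiments, comparisons = NULL, cap = 1e4,
                       ci = TRUE) {
  stopifnot(is.list(experiments), length(experiments) >= 1,
            !is.null(names(experiments)))
  fits <- lapply(experiments, fit_mutation_rate, cap = cap, ci = ci)
  est <- do.call(rbind, lapply(names(fits), function(s) {
    f <- fits[[s]]
    data.frame(strain = s, m_hat = f$m_hat, mu_hat = f$mu_hat,
               ci_low_mu = f$ci_low / f$Nt, ci_high_mu = f$ci_high / f$Nt,
               loglik = f$loglik, n_cultures = f$n_cultures, Nt = f$Nt,
               stringsAsFactors = FALSE)
  }))
  if (is.null(comparisons) && length(experiments) >= 2) {
    nm <- names(experiments)
    comparisons <- list()
    for (i in seq_along(nm)[-length(nm)])
      for (j in (i + 1):length(nm))
        comparisons[[length(comparisons) + 1L]] <- c(nm[i], nm[j])
  }
  tests <- NULL
  if (length(comparisons)) {
    tests <- do.call(rbind, lapply(comparisons, function(pr) {
      stopifnot(length(pr) == 2, all(pr %in% names(experiments)))
      t <- lrt_mutation_rate(experiments[[pr[1]]], experiments[[pr[2]]],
                             cap = cap)
      data.frame(strain_a = pr[1], strain_b = pr[2],
                 statistic = t$statistic, p_value = t$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(estimates = est, tests = tests), class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Mutation-rate estimates:\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  if (!is.null(x$tests)) {
    cat("\nPairwise likelihood-ratio tests (raw p-values):\n")
    print(x$tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
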