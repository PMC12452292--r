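# Gamma-Poisson shrinker: observed pair counts a_ij ~ Poisson(lambda E_ij)
# with a two-component gamma mixture prior on the rate multiplier lambda.
# The marginal of a is then a two-component negative-binomial mixture,
# maximized over the 5 hyperparameters; the posterior is a conjugate
# mixture of gammas, whose geometric mean is the EBGM.

#' Drug-event pair counts with independence expectations
#'
#' Builds the all-pairs table the mixture prior is fitted on: for every
#' (drug name, PT) pair observed in the data, the number of reports
#' containing both, and the expectation `E = N_drug * N_event / N` from the
#' report-level margins.
#'
#' @param raw a deduplicated `faers_raw`
#' @return data.table with columns `drug`, `event`, `a`, `E`
#' @export
pair_counts <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  dd <- unique(raw$drug[, .(PRIMARYID, drug = tolower(DRUGNAME))])
  re <- unique(raw$reac[, .(PRIMARYID, event = PT)])
  n_total <- nrow(raw$demo)
  n_drug <- dd[, .(n_d = .N), by = drug]
  n_event <- re[, .(n_e = .N), by = event]
  pairs <- merge(dd, re, by = "PRIMARYID", allow.cartesian = TRUE)[
    , .(a = .N), by = .(drug, event)]
  pairs <- merge(pairs, n_drug, by = "drug")
  pairs <- merge(pairs, n_event, by = "event")
  pairs[, E := n_d * n_e / n_total]
  pairs[, .(drug, event, a, E)]
}

neg_mix_loglik <- function(par, a, E) {
  a1 <- par[1]; b1 <- par[2]; a2 <- par[3]; b2 <- par[4]; p <- par[5]
  l1 <- dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  -sum(logsumexp2(log(p) + l1, log1p(-p) + l2))
}

#' Fit the two-gamma mixture prior by maximum marginal likelihood
#'
#' @param a integer vector of observed pair counts
#' @param E positive vector of independence expectations (same length)
#' @param start starting hyperparameters
#'   `(alpha1, beta1, alpha2, beta2, pi_mix)`
#' @param lower,upper box constraints on the gamma hyperparameters
#' @param tol convergence tolerance passed to the L-BFGS-B optimizer
#' @return an `mgps_prior` with the fitted hyperparameters, final
#'   log-likelihood and convergence status; non-convergence is an error
#'   carrying the optimizer message
#' @export
fit_mgps_prior <- function(a, E,
                           start = c(alpha1 = 0.2, beta1 = 0.1,
                                     alpha2 = 2, beta2 = 4, pi_mix = 1 / 3),
                           lower = 1e-6, upper = 1e6, tol = 1e-8) {
  if (is.data.frame(a)) { E <- a$E; a <- a$a }
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 100)
    warnf("only %d drug-event pairs: hyperparameter estimates will be unstable (>= 100 recommended)", length(a))
  # optimize on the log / logit scale: the likelihood is far better
  # conditioned there and the box constraints map to simple bounds
  tstart <- c(log(start[1:4]), stats::qlogis(start[5]))
  neg_ll_t <- function(tp)
    neg_mix_loglik(c(exp(tp[1:4]), stats::plogis(tp[5])), a, E)
  fit <- optim(tstart, neg_ll_t, method = "L-BFGS-B",
               lower = c(rep(log(lower), 4), -13.8),
               upper = c(rep(log(upper), 4), 13.8),
               control = list(maxit = 500L,
                              factr = tol / .Machine$double.eps))
  if (fit$convergence != 0)
    stopf("MGPS hyperparameter optimization did not converge (code %d: %s); counts=%s",
          fit$convergence, fit$message %||% "",
          paste(fit$counts, collapse = "/"))
  par <- c(exp(fit$par[1:4]), stats::plogis(fit$par[5]))
  structure(list(alpha1 = unname(par[1]), beta1 = unname(par[2]),
                 alpha2 = unname(par[3]), beta2 = unname(par[4]),
                 pi_mix = unname(par[5]),
                 loglik = -fit$value, n_pairs = length(a),
                 convergence = fit$convergence),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("two-gamma mixture prior on the reporting-rate multiplier\n")
  cat(sprintf("  component 1: Gamma(%.4g, rate %.4g)  mean %.3f  weight %.3f\n",
              x$alpha1, x$beta1, x$alpha1 / x$beta1, x$pi_mix))
  cat(sprintf("  component 2: Gamma(%.4g, rate %.4g)  mean %.3f  weight %.3f\n",
              x$alpha2, x$beta2, x$alpha2 / x$beta2, 1 - x$pi_mix))
  cat(sprintf("  log marginal likelihood %.3f over %d pairs\n",
              x$loglik, x$n_pairs))
  invisible(x)
}

# posterior mixture weights and component parameters for one (a, E) cell
posterior_mixture <- function(a, E, prior) {
  l1 <- log(prior$pi_mix) +
    dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E),
            log = TRUE)
  l2 <- log1p(-prior$pi_mix) +
    dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E),
            log = TRUE)
  denom <- logsumexp2(l1, l2)
  list(q1 = exp(l1 - denom), q2 = exp(l2 - denom),
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + E,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + E)
}

#' Empirical Bayes geometric mean and its 5th posterior percentile
#'
#' The posterior over the rate multiplier is a two-component gamma mixture
#' `Gamma(alpha_k + a, beta_k + E)`; `EBGM = 2^E[log2 lambda | data]` has a
#' closed form via the digamma function, and `EBGM05` is found by bisection
#' on the posterior mixture CDF to `|CDF - 0.05| < 1e-8`.
#'
#' @param table a [contingency_table()], or any list with fields `a` and
#'   `expected`
#' @param prior a fitted [fit_mgps_prior()]
#' @return list with `ebgm`, `ebgm05`
#' @export
ebgm <- function(table, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  a <- table$a; E <- table$expected
  pm <- posterior_mixture(a, E, prior)
  elog <- pm$q1 * (digamma(pm$shape1) - log(pm$rate1)) +
          pm$q2 * (digamma(pm$shape2) - log(pm$rate2))
  cdf <- function(x) pm$q1 * pgamma(x, pm$shape1, rate = pm$rate1) +
                     pm$q2 * pgamma(x, pm$shape2, rate = pm$rate2)
  lo <- 1e-8
  hi <- a / max(E, 1e-12) * 10 + 10
  while (cdf(hi) < 0.05) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- cdf(mid)
    # tolerance in both CDF and abscissa so the quantile itself is tight
    if (abs(f - 0.05) < 1e-8 && (hi - lo) < 1e-9 * (1 + mid)) break
    if (f < 0.05) lo <- mid else hi <- mid
  }
  list(ebgm = exp(elog), ebgm05 = mid)
}
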