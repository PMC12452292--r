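# Two-sample summary-data MR estimators on a harmonized instrument set.
# All report the causal estimate on the log scale with OR = exp(beta) and
# normal-theory CIs (t-theory for MR-Egger).

mr_result <- function(method, n_snp, b, se, p, extra = list()) {
  structure(c(list(method = method, n_snp = n_snp,
                   beta_hat = b, se_hat = se,
                   or_hat = exp(b),
                   ci_low = exp(b - 1.96 * se),
                   ci_high = exp(b + 1.96 * se),
                   pval = p), extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): OR %s, p = %.3g\n", x$method, x$n_snp,
              fmt_ci(x$or_hat, x$ci_low, x$ci_high), x$pval))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %.4f (se %.4f, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

check_instruments <- function(x, min_snps) {
  stopifnot(is.data.frame(x),
            all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(x)))
  if (nrow(x) < min_snps)
    stopf("at least %d SNPs required, got %d", min_snps, nrow(x))
  invisible(x)
}

#' Inverse-variance-weighted estimate
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights `1/se_y^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`. The standard error uses
#' multiplicative random-effects scaling `max(1, sqrt(Q/(L-1)))`, never
#' deflating; Cochran's Q and its df are reported.
#'
#' @param instruments an [harmonize_gwas()] `instrument_set` (or any data
#'   frame with `beta_x`, `se_x`, `beta_y`, `se_y`); at least 2 SNPs
#' @return an `mr_result` with heterogeneity fields `Q`, `Q_df`
#' @export
mr_ivw <- function(instruments) {
  check_instruments(instruments, 2L)
  w <- 1 / instruments$se_y^2
  bx <- instruments$beta_x; by <- instruments$beta_y
  b <- sum(w * bx * by) / sum(w * bx^2)
  L <- nrow(instruments)
  Q <- sum(w * (by - b * bx)^2)
  scale <- max(1, sqrt(Q / (L - 1)))
  se <- scale / sqrt(sum(w * bx^2))
  mr_result("IVW", L, b, se, 2 * pnorm(-abs(b / se)),
            extra = list(Q = Q, Q_df = L - 1))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects *with* intercept
#' (weights `1/se_y^2`); the slope estimates the causal effect under the
#' InSIDE assumption and the intercept the average directional pleiotropy.
#' Standard errors use the multiplicative random-effects scale floored at
#' 1; p-values come from the t distribution with `L - 2` df. Requires the
#' instrument orientation convention (all `beta_x > 0`).
#'
#' @inheritParams mr_ivw
#' @return an `mr_result` with `intercept`, `intercept_se`, `intercept_p`
#' @export
mr_egger <- function(instruments) {
  check_instruments(instruments, 3L)
  w <- 1 / instruments$se_y^2
  fit <- lm(beta_y ~ beta_x, data = instruments, weights = w)
  L <- nrow(instruments)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  b <- unname(coef(fit)["beta_x"])
  se <- unname(sm$coefficients["beta_x", "Std. Error"] / sm$sigma * scale)
  i0 <- unname(coef(fit)["(Intercept)"])
  i0_se <- unname(sm$coefficients["(Intercept)", "Std. Error"] / sm$sigma * scale)
  mr_result("MR-Egger", L, b, se, 2 * pt(-abs(b / se), df = L - 2),
            extra = list(intercept = i0, intercept_se = i0_se,
                         intercept_p = 2 * pt(-abs(i0 / i0_se), df = L - 2)))
}

# cumulative-weight interpolated weighted median of per-SNP ratios
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(theta[1])
  k <- max(which(s < 0.5))
  if (k == length(theta)) return(theta[length(theta)])
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_se <- function(instruments, point_fun, n_boot, seed, robust = FALSE) {
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(nrow(instruments), instruments$beta_x, instruments$se_x)
    by <- rnorm(nrow(instruments), instruments$beta_y, instruments$se_y)
    point_fun(bx, by)
  }, numeric(1))
  if (robust) mad(est) else sd(est)
}

#' Weighted median estimate
#'
#' Per-SNP ratio estimates `theta_j = beta_y / beta_x` with weights
#' `beta_x^2 / se_y^2`; the estimate is the weighted median via the
#' standard cumulative-weight interpolation at 50%, consistent when at
#' least half the weight comes from valid instruments. The standard error
#' is a seeded parametric bootstrap (betas resampled from their normal
#' sampling distributions).
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed integer seed for the bootstrap
#' @return an `mr_result`
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  check_instruments(instruments, 3L)
  zero <- instruments$beta_x == 0
  if (any(zero)) {
    warnf("dropping %d SNP(s) with zero exposure beta (ratio undefined)", sum(zero))
    instruments <- instruments[!zero, ]
    check_instruments(instruments, 3L)
  }
  w <- instruments$beta_x^2 / instruments$se_y^2
  b <- weighted_median_point(instruments$beta_y / instruments$beta_x, w)
  se <- boot_se(instruments, function(bx, by)
    weighted_median_point(by / bx, bx^2 / instruments$se_y^2),
    n_boot, seed)
  mr_result("Weighted median", nrow(instruments), b, se,
            2 * pnorm(-abs(b / se)))
}

# weighted kernel-density mode of the ratio estimates; bandwidth is
# phi x the modified Silverman rule 0.9 min(sd, mad) n^(-1/5)
kde_mode <- function(theta, w, phi) {
  if (length(unique(theta)) == 1L) return(theta[1])
  h <- phi * 0.9 * min(sd(theta), mad(theta)) * length(theta)^(-1 / 5)
  if (h <= 0) return(weighted_median_point(theta, w))
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512L)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - theta) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Simple and weighted mode estimates
#'
#' Kernel-density modes of the per-SNP ratio estimates: unweighted
#' (simple mode) and inverse-variance weighted (weighted mode), with
#' bandwidth `phi` times the modified Silverman rule. Consistent when the
#' largest homogeneous cluster of instruments is valid. Standard errors by
#' seeded parametric bootstrap (scaled-MAD of the bootstrap modes, robust
#' to the multimodal bootstrap distributions modes produce).
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_phi bandwidth multiplier (default 1)
#' @return list with elements `simple` and `weighted`, each an `mr_result`
#' @export
mr_mode <- function(instruments, bandwidth_phi = 1, n_boot = 1000L,
                    seed = 1L) {
  check_instruments(instruments, 3L)
  theta <- instruments$beta_y / instruments$beta_x
  w_iv <- instruments$beta_x^2 / instruments$se_y^2
  w1 <- rep(1, length(theta))
  b_s <- kde_mode(theta, w1, bandwidth_phi)
  b_w <- kde_mode(theta, w_iv, bandwidth_phi)
  se_s <- boot_se(instruments, function(bx, by)
    kde_mode(by / bx, w1, bandwidth_phi), n_boot, seed, robust = TRUE)
  se_w <- boot_se(instruments, function(bx, by)
    kde_mode(by / bx, bx^2 / instruments$se_y^2, bandwidth_phi),
    n_boot, seed + 1L, robust = TRUE)
  list(simple = mr_result("Simple mode", nrow(instruments), b_s, se_s,
                          2 * pnorm(-abs(b_s / se_s))),
       weighted = mr_result("Weighted mode", nrow(instruments), b_w, se_w,
                            2 * pnorm(-abs(b_w / se_w))))
}

#' Run the full five-estimator battery
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_phi mode bandwidth multiplier
#' @return an `mr_battery`: list of `mr_result`s named `ivw`, `egger`,
#'   `weighted_median`, `simple_mode`, `weighted_mode`
#' @export
mr_all <- function(instruments, n_boot = 1000L, seed = 1L,
                   bandwidth_phi = 1) {
  modes <- mr_mode(instruments, bandwidth_phi, n_boot, seed + 2L)
  structure(list(ivw = mr_ivw(instruments),
                 egger = mr_egger(instruments),
                 weighted_median = mr_weighted_median(instruments, n_boot, seed),
                 simple_mode = modes$simple,
                 weighted_mode = modes$weighted),
            class = "mr_battery")
}

#' Tidy an estimator battery into a report table
#'
#' @param x an `mr_battery`
#' @param exposure,outcome labels for the report columns
#' @param ... unused
#' @return data.frame with columns Exposure, Outcome, Method, SNPs,
#'   `OR (95% CI)` and p, formatted at two decimals (half-up)
#' @export
as.data.frame.mr_battery <- function(x, exposure = "exposure",
                                     outcome = "outcome", ...) {
  rows <- lapply(x, function(r)
    data.frame(Exposure = exposure, Outcome = outcome, Method = r$method,
               SNPs = r$n_snp,
               `OR (95% CI)` = fmt_ci(r$or_hat, r$ci_low, r$ci_high),
               p = ifelse(r$pval < 0.001, "<0.001", fmt_num(r$pval, 3)),
               check.names = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positive-control validation run
#'
#' Runs the full battery against a control outcome with an established
#' effect direction and checks that the IVW estimate reproduces it. A
#' wrong direction (or a non-significant IVW when significance is
#' required) raises a `positive_control_error` condition, the signal for
#' a pipeline to abort; a `direction = "none"` control only warns that no
#' check was applied.
#'
#' @param instruments harmonized instruments against the control outcome
#' @param direction expected IVW direction: `"protective"` (OR < 1),
#'   `"harmful"` (OR > 1), or `"none"`
#' @param alpha significance level the IVW p-value must reach (set `NULL`
#'   to check direction only)
#' @inheritParams mr_all
#' @return list with `battery` (the `mr_battery`) and `passed`
#' @export
positive_control <- function(instruments,
                             direction = c("protective", "harmful", "none"),
                             alpha = 0.05, n_boot = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  battery <- mr_all(instruments, n_boot = n_boot, seed = seed)
  ivw <- battery$ivw
  if (direction == "none") {
    warnf("positive control configured with no expected direction; validation not asserted")
    return(list(battery = battery, passed = NA))
  }
  ok_dir <- if (direction == "protective") ivw$beta_hat < 0 else ivw$beta_hat > 0
  ok_sig <- is.null(alpha) || ivw$pval < alpha
  if (!ok_dir || !ok_sig) {
    cond <- structure(
      class = c("positive_control_error", "error", "condition"),
      list(message = sprintf(
        "positive control failed: IVW OR %.3f (p = %.3g), expected %s%s",
        ivw$or_hat, ivw$pval, direction,
        if (is.null(alpha)) "" else sprintf(" at alpha = %g", alpha)),
        call = sys.call()))
    stop(cond)
  }
  list(battery = battery, passed = TRUE)
}
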