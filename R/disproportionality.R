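# The four disproportionality statistics on a 2x2 drug-event table:
#   a = target drug & target event     b = target drug & other events
#   c = other drugs & target event     d = other drugs & other events
# with expected count E = (a+b)(a+c)/n under independence.

#' Construct a 2x2 disproportionality contingency table
#'
#' @param a,b,c,d nonnegative cell counts: (target drug, target event),
#'   (target drug, other events), (other drugs, target event), (other
#'   drugs, other events)
#' @param label cohort descriptor carried into results
#' @return a `contingency_table` with fields `a`, `b`, `c`, `d`, `n` and
#'   the independence expectation `expected`
#' @export
contingency_table <- function(a, b, c, d, label = "") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stopf("cells must be nonnegative counts")
  # double precision: margin products overflow 32-bit integers easily
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (n <= 0) stopf("empty table: n must be positive")
  structure(list(a = a, b = b, c = c, d = d, n = n,
                 expected = (a + b) * (a + c) / n, label = label),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table%s\n", if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  cat(sprintf("n = %s, E[a] = %.3f\n", format(x$n, big.mark = ","), x$expected))
  invisible(x)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a d)/(b c)` with
#' `CI = exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' A zero cell makes the Woolf interval undefined; by default this is an
#' error naming the cell, or with `haldane = TRUE` 0.5 is added to every
#' cell (flagged in the result).
#'
#' @param table a [contingency_table()]
#' @param haldane apply the Haldane-Anscombe +0.5 correction to all cells
#' @return list with `ror`, `ror_low`, `ror_high`, `corrected`
#' @export
ror_ci <- function(table, haldane = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(a = table$a, b = table$b, c = table$c, d = table$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!haldane)
      stopf("zero cell '%s': ROR interval undefined (set haldane = TRUE to apply the +0.5 correction)",
            names(cells)[which(cells == 0)[1]])
    cells <- cells + 0.5
    corrected <- TRUE
  }
  ror <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se_log <- sqrt(sum(1 / cells))
  list(ror = unname(ror),
       ror_low = unname(exp(log(ror) - 1.96 * se_log)),
       ror_high = unname(exp(log(ror) + 1.96 * se_log)),
       corrected = corrected)
}

#' Proportional reporting ratio and chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`. The chi-square is the Pearson statistic
#' with the Yates continuity correction, each cell's `|O - E| - 0.5`
#' clipped at zero before squaring; `correct = FALSE` gives the plain
#' Pearson statistic. `c = 0` yields an infinite PRR, flagged rather than
#' failing.
#'
#' @param table a [contingency_table()]
#' @param correct apply the Yates continuity correction (default `TRUE`)
#' @return list with `prr`, `chi2`, `prr_infinite`
#' @export
prr_chi2 <- function(table, correct = TRUE) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d; n <- table$n
  if (a + b <= 0 || c + d <= 0)
    stopf("PRR undefined: an entire drug arm is empty")
  prr <- (a / (a + b)) / (c / (c + d))
  obs <- c(a, b, c, d)
  expc <- c((a + b) * (a + c), (a + b) * (b + d),
            (c + d) * (a + c), (c + d) * (b + d)) / n
  dev <- abs(obs - expc)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expc)
  list(prr = prr, chi2 = chi2, prr_infinite = !is.finite(prr))
}

#' Information component with gamma credibility bound
#'
#' The observed-vs-expected shrinkage form of the Bayesian confidence
#' propagation information component:
#' `IC = log2((a + 0.5)/(E + 0.5))` with `E = (a+b)(a+c)/n`, and `IC025`
#' the base-2 log of the 2.5th percentile of `Gamma(shape = a + 0.5,
#' rate = E + 0.5)`.
#'
#' @param table a [contingency_table()]
#' @return list with `ic`, `ic025`
#' @export
bcpnn_ic <- function(table) {
  # accepts any list carrying `a` and `expected` (e.g. a bare o/e pair)
  stopifnot(is.numeric(table$a), is.numeric(table$expected))
  a <- table$a; E <- table$expected
  list(ic = log2((a + 0.5) / (E + 0.5)),
       ic025 = log2(qgamma(0.025, shape = a + 0.5, rate = E + 0.5)))
}

#' Apply the four signal-significance criteria
#'
#' A positive signal requires all four: ROR 95% CI lower bound > 1 with at
#' least `min_count` reports; PRR >= 2 with chi-square >= 4 (the MHRA
#' criterion); EBGM05 >= 2; IC025 > 0.
#'
#' @param result a `signal_result` from [signal_stats()], or a list with
#'   fields `a`, `ror_low`, `prr`, `chi2`, `ebgm05`, `ic025` (missing
#'   `ebgm05` marks that criterion `NA`)
#' @param min_count minimum report count for the ROR criterion (default 3)
#' @return list of logical flags `criterion_ror`, `criterion_mhra`,
#'   `criterion_ebgm`, `criterion_ic`, `overall`
#' @export
classify_signal <- function(result, min_count = 3) {
  ror <- isTRUE(result$ror_low > 1) && isTRUE(result$a >= min_count)
  mhra <- isTRUE(result$prr >= 2) && isTRUE(result$chi2 >= 4)
  ebgm <- if (is.null(result$ebgm05) || is.na(result$ebgm05)) NA else
    result$ebgm05 >= 2
  ic <- isTRUE(result$ic025 > 0)
  flags <- list(criterion_ror = ror, criterion_mhra = mhra,
                criterion_ebgm = ebgm, criterion_ic = ic)
  flags$overall <- isTRUE(ror) && isTRUE(mhra) && isTRUE(ebgm) && isTRUE(ic)
  flags
}

#' Compute all four signal statistics for one table
#'
#' @param table a [contingency_table()]
#' @param prior optional [fit_mgps_prior()] result; without it the
#'   empirical-Bayes statistics are `NA` and the EBGM criterion undecided
#' @param haldane,correct passed to [ror_ci()] / [prr_chi2()]
#' @param min_count minimum report count for the ROR criterion
#' @return a `signal_result` list: cells, the four statistics with their
#'   interval bounds, and the criterion flags
#' @export
signal_stats <- function(table, prior = NULL, haldane = FALSE,
                         correct = TRUE, min_count = 3) {
  r <- ror_ci(table, haldane = haldane)
  p <- prr_chi2(table, correct = correct)
  ic <- bcpnn_ic(table)
  eb <- if (!is.null(prior)) ebgm(table, prior) else
    list(ebgm = NA_real_, ebgm05 = NA_real_)
  out <- list(label = table$label, a = table$a, n = table$n,
              expected = table$expected,
              ror = r$ror, ror_low = r$ror_low, ror_high = r$ror_high,
              corrected = r$corrected,
              prr = p$prr, chi2 = p$chi2,
              ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
              ic = ic$ic, ic025 = ic$ic025)
  out$flags <- classify_signal(out, min_count = min_count)
  structure(out, class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("signal result%s\n",
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  cat(sprintf("  N = %d, E = %.3f\n", x$a, x$expected))
  cat(sprintf("  ROR  %s\n", fmt_ci(x$ror, x$ror_low, x$ror_high)))
  cat(sprintf("  PRR  %s, chi2 = %s\n", fmt_num(x$prr), fmt_num(x$chi2)))
  if (!is.na(x$ebgm))
    cat(sprintf("  EBGM %s (EBGM05 %s)\n", fmt_num(x$ebgm), fmt_num(x$ebgm05)))
  cat(sprintf("  IC   %s (IC025 %s)\n", fmt_num(x$ic), fmt_num(x$ic025)))
  cat(sprintf("  signal: %s\n", if (x$flags$overall) "POSITIVE" else "negative"))
  invisible(x)
}
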