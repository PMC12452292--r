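# Instrument selection (region + p-value filter + greedy LD clumping)
# and exposure/outcome allele harmonization.

#' Select cis-region instruments by p-value filtering and LD clumping
#'
#' Keeps SNPs inside `[region[1], region[2]]` (1-based, inclusive) with
#' `P < p_threshold`, then clumps greedily: candidates are sorted by
#' ascending p-value (position breaks ties, for determinism), the best is
#' accepted, and every remaining SNP within `window_kb` kilobases of *any*
#' accepted SNP **and** with squared correlation above `r2_max` to it is
#' discarded; repeat until exhausted.
#'
#' @param exposure data.table of GWAS records (columns SNP, POS, P, ...)
#' @param region length-2 numeric `c(start, end)` in base pairs
#' @param p_threshold genome-wide significance cutoff (default `5e-8`)
#' @param ld square LD correlation matrix covering all candidate SNPs
#'   (its entries are correlations `r`; the clump rule uses `r^2`)
#' @param r2_max clumping r-squared cutoff (default 0.3)
#' @param window_kb clumping distance in kilobases (default 100)
#' @return character vector of retained SNP ids, in acceptance order
#' @export
select_instruments <- function(exposure, region, p_threshold = 5e-8,
                               ld = NULL, r2_max = 0.3, window_kb = 100) {
  cand <- exposure[POS >= region[1] & POS <= region[2] & P < p_threshold]
  if (!nrow(cand)) stopf("no instruments: no SNP passes the region and p-value filter")
  if (is.null(ld)) stopf("an LD matrix covering the candidates is required")
  if (!all(cand$SNP %in% rownames(ld)))
    stopf("LD matrix does not cover all candidate SNPs")
  cand <- cand[order(P, POS)]
  accepted <- character(0)
  acc_pos <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$SNP[i]; p <- cand$POS[i]
    if (length(accepted)) {
      near <- abs(acc_pos - p) <= window_kb * 1000
      if (any(near & ld[accepted, s]^2 > r2_max)) next
    }
    accepted <- c(accepted, s)
    acc_pos <- c(acc_pos, p)
  }
  accepted
}

#' Harmonize outcome records to the exposure's effect alleles
#'
#' For every shared SNP the outcome record is aligned to the exposure's
#' effect/other allele pair: swapped alleles flip the sign of the outcome
#' beta (and complement its EAF); strand-flipped records are resolved by
#' complementing the alleles first. Palindromic (A/T, C/G) SNPs cannot be
#' resolved from alleles alone: they are dropped when the exposure EAF is
#' missing or inside the ambiguity band, otherwise the orientation that
#' best matches the allele frequencies is used. Finally every instrument
#' is oriented so that its exposure beta is positive (the sign convention
#' model-based estimators such as MR-Egger require). Every flip and drop
#' is logged.
#'
#' @param exposure,outcome data.tables of GWAS records
#' @param snps optional SNP ids to restrict to (e.g. from
#'   [select_instruments()])
#' @param eaf_band palindromic ambiguity band on the exposure EAF
#'   (default `c(0.42, 0.58)`)
#' @param orient orient all exposure betas positive (default `TRUE`)
#' @return an `instrument_set`: data.table with columns `snp`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, plus attributes `log` (data.table of
#'   per-SNP actions) and `orientation`
#' @export
harmonize_gwas <- function(exposure, outcome, snps = NULL,
                           eaf_band = c(0.42, 0.58), orient = TRUE) {
  ex <- if (is.null(snps)) exposure else exposure[SNP %in% snps]
  shared <- intersect(ex$SNP, outcome$SNP)
  if (!length(shared)) stopf("no shared SNPs between exposure and outcome")
  ex <- ex[match(shared, SNP)]
  ou <- outcome[match(shared, SNP)]

  log_entries <- list()
  note <- function(snp, action, reason)
    log_entries[[length(log_entries) + 1L]] <<-
      data.table(snp = snp, action = action, reason = reason)

  keep <- rep(TRUE, length(shared))
  beta_y <- ou$BETA
  for (i in seq_along(shared)) {
    ea_x <- ex$EA[i]; oa_x <- ex$OA[i]
    ea_y <- ou$EA[i]; oa_y <- ou$OA[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      f <- ex$EAF[i]
      if (is.na(f) || (f > eaf_band[1] && f < eaf_band[2])) {
        keep[i] <- FALSE
        note(shared[i], "drop", "palindromic with ambiguous or missing EAF")
        next
      }
      # frequency-based orientation: outcome EAF nearer to the exposure
      # EAF means same orientation, nearer to its complement means flipped
      g <- ou$EAF[i]
      if (is.na(g)) {
        keep[i] <- FALSE
        note(shared[i], "drop", "palindromic with missing outcome EAF")
        next
      }
      if (abs(g - f) > abs(g - (1 - f))) {
        beta_y[i] <- -beta_y[i]
        note(shared[i], "flip_beta", "palindromic aligned by allele frequency")
      }
      next
    }
    same <- ea_y == ea_x && oa_y == oa_x
    swapped <- ea_y == oa_x && oa_y == ea_x
    if (!same && !swapped) {
      # try the opposite strand
      ea_c <- COMPLEMENT[ea_y]; oa_c <- COMPLEMENT[oa_y]
      if (ea_c == ea_x && oa_c == oa_x) {
        same <- TRUE
        note(shared[i], "strand_flip", "outcome reported on opposite strand")
      } else if (ea_c == oa_x && oa_c == ea_x) {
        swapped <- TRUE
        note(shared[i], "strand_flip", "outcome reported on opposite strand")
      } else {
        keep[i] <- FALSE
        note(shared[i], "drop",
             sprintf("irreconcilable alleles %s/%s vs %s/%s",
                     ea_x, oa_x, ea_y, oa_y))
        next
      }
    }
    if (swapped) {
      beta_y[i] <- -beta_y[i]
      note(shared[i], "flip_beta", "outcome effect allele swapped")
    }
  }
  if (!any(keep)) stopf("all SNPs dropped during harmonization")

  dt <- data.table(snp = shared[keep],
                   beta_x = ex$BETA[keep], se_x = ex$SE[keep],
                   beta_y = beta_y[keep], se_y = ou$SE[keep])
  if (orient) {
    neg <- dt$beta_x < 0
    if (any(neg)) {
      for (s in dt$snp[neg])
        note(s, "orient", "flipped so the effect allele raises the exposure")
      dt[neg, `:=`(beta_x = -beta_x, beta_y = -beta_y)]
    }
  }
  setattr(dt, "log",
          if (length(log_entries)) rbindlist(log_entries) else
            data.table(snp = character(), action = character(),
                       reason = character()))
  setattr(dt, "orientation", if (orient) "beta_x_positive" else "as_reported")
  setattr(dt, "class", c("instrument_set", class(dt)))
  dt[]
}
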