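# Shared fixture builders: everything is generated in code at test time.

# write a tiny hand-rolled FAERS-dialect quarter into `dir`
write_mini_faers <- function(dir,
                             demo_rows,
                             drug_rows = NULL,
                             reac_rows = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("PRIMARYID$CASEID$FDA_DT$AGE$AGE_COD$SEX$OCCP_COD$REPORTER_COUNTRY",
               demo_rows), file.path(dir, "DEMO_2024Q1.txt"))
  writeLines(c("PRIMARYID$DRUG_SEQ$ROLE_COD$DRUGNAME$PROD_AI",
               drug_rows %||% character(0)), file.path(dir, "DRUG_2024Q1.txt"))
  writeLines(c("PRIMARYID$PT", reac_rows %||% character(0)),
             file.path(dir, "REAC_2024Q1.txt"))
  dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain instrument data.frame for estimator tests
make_instruments <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.05,
                             snp = NULL) {
  data.frame(snp = snp %||% paste0("rs", seq_along(beta_x)),
             beta_x = beta_x, se_x = rep_len(se_x, length(beta_x)),
             beta_y = beta_y, se_y = rep_len(se_y, length(beta_x)))
}

# minimal GWAS record table for harmonization tests
gwas_records <- function(snp, ea, oa, beta, se = 0.01, eaf = 0.3,
                         pos = NULL, p = 1e-10) {
  data.table::data.table(SNP = snp, CHR = "1",
                         POS = pos %||% seq(100, by = 100,
                                            length.out = length(snp)),
                         EA = ea, OA = oa,
                         EAF = rep_len(eaf, length(snp)),
                         BETA = beta, SE = rep_len(se, length(snp)),
                         P = rep_len(p, length(snp)))
}

# brute-force numerical oracle for the gamma-Poisson posterior: densities,
# moments and quantiles by quadrature only (independent of the conjugate
# closed form used by the implementation)
quadrature_ebgm <- function(a, E, prior) {
  post_unnorm <- function(l)
    (prior$pi_mix * dgamma(l, prior$alpha1, rate = prior$beta1) +
     (1 - prior$pi_mix) * dgamma(l, prior$alpha2, rate = prior$beta2)) *
      dpois(a, l * E)
  up <- max(1, 60 * (a + 10) / max(E, 1e-3))   # covers the posterior mass
  qi <- function(f, lo, hi) integrate(f, lo, hi, rel.tol = 1e-10,
                                      abs.tol = 0,
                                      subdivisions = 1000L)$value
  norm <- qi(post_unnorm, 0, up)
  elog <- qi(function(l) log(l) * post_unnorm(l), 0, up) / norm
  cdf <- function(x) qi(post_unnorm, 0, x) / norm
  hi <- 1
  while (cdf(hi) < 0.05) hi <- hi * 2
  q05 <- uniroot(function(x) cdf(x) - 0.05, c(1e-12, hi),
                 tol = 1e-12)$root
  list(ebgm = exp(elog), ebgm05 = q05)
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  unname(tools::md5sum(files))
}
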