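# Instrument selection (hand-traced clumping fixtures) and allele
# harmonization oracles.

test_that("without LD every region- and p-passing SNP is retained", {
  ex <- gwas_records(paste0("rs", 1:4), ea = c("A", "C", "A", "G"),
                     oa = c("G", "T", "C", "T"), beta = 0.1,
                     pos = c(1000, 2000, 3000, 999999),
                     p = c(1e-12, 1e-9, 1e-10, 1e-20))
  ld <- diag(4); dimnames(ld) <- list(ex$SNP, ex$SNP)
  got <- select_instruments(ex, c(500, 5000), 5e-8, ld, 0.3, 100)
  # rs4 is outside the region; the rest survive, best p first
  expect_setequal(got, c("rs1", "rs3", "rs2"))
  expect_equal(got[1], "rs1")
})

test_that("greedy clumping discards correlated neighbours but honours the window", {
  ex <- gwas_records(c("rsA", "rsB", "rsC"),
                     ea = c("A", "A", "A"), oa = c("G", "G", "G"),
                     beta = 0.1, pos = c(1000, 1500, 201000),
                     p = c(1e-12, 1e-9, 1e-9))
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.9),
                 sqrt(0.5), 1, 0,
                 sqrt(0.9), 0, 1), 3,
               dimnames = list(c("rsA", "rsB", "rsC"),
                               c("rsA", "rsB", "rsC")))
  got <- select_instruments(ex, c(0, 1e6), 5e-8, ld, 0.3, 100)
  # rsB: 500 bp away, r2 = 0.5 > 0.3 -> dropped
  # rsC: r2 = 0.9 but 200 kb away -> outside the 100 kb window, retained
  expect_equal(got, c("rsA", "rsC"))
})

test_that("an empty post-filter set is an error", {
  ex <- gwas_records("rs1", "A", "G", 0.001, p = 0.5)
  ld <- matrix(1, 1, 1, dimnames = list("rs1", "rs1"))
  expect_error(select_instruments(ex, c(0, 1e6), 5e-8, ld), "no instruments")
})

test_that("swapped outcome alleles flip the outcome beta sign", {
  ex <- gwas_records("rs1", "A", "G", beta = 0.1, eaf = 0.3)
  ou <- gwas_records("rs1", "G", "A", beta = 0.05, eaf = 0.7)
  h <- harmonize_gwas(ex, ou)
  expect_equal(h$beta_y, -0.05)
  expect_equal(attr(h, "log")$action, "flip_beta")
})

test_that("palindromic SNPs with ambiguous frequency are dropped, resolvable ones aligned", {
  ex <- gwas_records(c("rs1", "rs2"), c("A", "A"), c("T", "T"),
                     beta = c(0.1, 0.1), eaf = 0.3)
  ex$EAF <- c(0.50, 0.10)
  ou <- gwas_records(c("rs1", "rs2"), c("A", "A"), c("T", "T"),
                     beta = c(0.05, 0.05), eaf = 0.3)
  ou$EAF <- c(0.50, 0.88)   # rs2 frequency matches the complement -> flip
  h <- harmonize_gwas(ex, ou)
  expect_equal(h$snp, "rs2")
  expect_equal(h$beta_y, -0.05)
  lg <- attr(h, "log")
  expect_true(any(lg$snp == "rs1" & lg$action == "drop"))
})

test_that("strand-flipped encodings align without a sign change", {
  ex <- gwas_records("rs1", "C", "T", beta = 0.1, eaf = 0.2)
  ou <- gwas_records("rs1", "G", "A", beta = 0.05, eaf = 0.2)
  h <- harmonize_gwas(ex, ou)
  expect_equal(h$beta_y, 0.05)
  expect_equal(attr(h, "log")$action, "strand_flip")

  # strand flip combined with allele swap: complement then swap -> flip sign
  ou2 <- gwas_records("rs1", "A", "G", beta = 0.05, eaf = 0.8)
  h2 <- harmonize_gwas(ex, ou2)
  expect_equal(h2$beta_y, -0.05)
})

test_that("irreconcilable allele pairs are dropped with a reason; all-drop errors", {
  ex <- gwas_records(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                     beta = 0.1, eaf = 0.3)
  ou <- gwas_records(c("rs1", "rs2"), c("A", "A"), c("C", "G"),
                     beta = 0.05, eaf = 0.3)
  h <- harmonize_gwas(ex, ou)
  expect_equal(h$snp, "rs2")
  expect_match(attr(h, "log")$reason[1], "irreconcilable")
  ou_all <- gwas_records("rs1", "A", "C", beta = 0.05, eaf = 0.3)
  expect_error(harmonize_gwas(ex[1], ou_all), "all SNPs dropped")
})

test_that("instruments are oriented so every exposure beta is positive", {
  ex <- gwas_records(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                     beta = c(-0.1, 0.2), eaf = 0.3)
  ou <- gwas_records(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                     beta = c(0.05, -0.03), eaf = 0.3)
  h <- harmonize_gwas(ex, ou)
  expect_true(all(h$beta_x > 0))
  expect_equal(h[h$snp == "rs1", ]$beta_y, -0.05)  # flipped with its exposure
  expect_equal(attr(h, "orientation"), "beta_x_positive")
  h2 <- harmonize_gwas(ex, ou, orient = FALSE)
  expect_equal(h2$beta_x, c(-0.1, 0.2))
})

test_that("the generator's scrambled encodings are fully recovered end to end", {
  cfg <- gwas_sim_config(n_snps = 120, ld_block_size = 1, within_block_r = 0,
                         causal_theta = -0.4, pleiotropy_sd = 0,
                         swap_fraction = 0.5, strand_flip_fraction = 0.4,
                         palindromic_fraction = 0.25, prop_null = 0,
                         seed = 77)
  s <- simulate_gwas_pair(cfg)
  h <- harmonize_gwas(s$exposure, s$outcome)
  # only palindromic-ambiguous SNPs may be dropped
  dropped <- attr(h, "log")[action == "drop"]
  expect_true(all(dropped$snp %in% s$truth$palindromic))
  # after harmonization the IVW estimate recovers the causal effect, which
  # it cannot do if any swap/flip was mis-resolved
  est <- mr_ivw(h)
  expect_equal(est$beta_hat, -0.4, tolerance = 0.02)
})
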