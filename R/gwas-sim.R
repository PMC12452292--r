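# Two-sample GWAS summary-statistic generator for a cis drug-target
# region. Per LD block one SNP is causal for the exposure; marginal
# effects of its neighbours follow the block correlation, and estimation
# noise is drawn with the same block structure so the written LD matrix is
# the true correlation of the estimates. The outcome effect of SNP j is
#   beta_Yj = causal_theta * beta_Xj + alpha_j + noise,
# with alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2) the direct
# (pleiotropic) effect.

#' Configuration for the two-sample GWAS generator
#'
#' @param n_snps number of SNPs in the cis region
#' @param region_start,region_end base-pair bounds of the region (default:
#'   the PCSK9 cis region on chromosome 1)
#' @param chrom chromosome label
#' @param ld_block_size SNPs per LD block
#' @param within_block_r correlation between SNPs of a block, in `[0, 1)`
#' @param maf_range minor-allele-frequency interval in `(0, 0.5]`
#' @param exposure_effect_scale per-allele effect scale; also the numerator
#'   of the standard-error approximation
#'   `se = scale / sqrt(2 MAF (1-MAF) n)`
#' @param n_exposure,n_outcome GWAS sample sizes
#' @param causal_theta true outcome effect per unit exposure
#' @param pleiotropy_mean,pleiotropy_sd direct-effect distribution
#' @param prop_null fraction of LD blocks with no exposure effect
#'   (exercises the p-value filter)
#' @param palindromic_fraction fraction of SNPs with A/T or C/G alleles
#' @param swap_fraction fraction of outcome rows reported on swapped
#'   alleles (beta sign and EAF complemented)
#' @param strand_flip_fraction fraction of non-palindromic outcome rows
#'   reported on the opposite strand
#' @param neg_orientation_fraction fraction of causal effects oriented so
#'   the effect allele *lowers* the exposure (forces the orientation step)
#' @param seed integer seed; fixes all output
#' @return a validated `gwas_sim_config` list
#' @export
gwas_sim_config <- function(n_snps = 100L,
                            region_start = 55505221L,
                            region_end = 55530525L,
                            chrom = "1",
                            ld_block_size = 5L,
                            within_block_r = 0.5,
                            maf_range = c(0.05, 0.5),
                            exposure_effect_scale = 0.1,
                            n_exposure = 1300000L,
                            n_outcome = 300000L,
                            causal_theta = 0,
                            pleiotropy_mean = 0,
                            pleiotropy_sd = 0,
                            prop_null = 0.1,
                            palindromic_fraction = 0.2,
                            swap_fraction = 0.3,
                            strand_flip_fraction = 0.2,
                            neg_orientation_fraction = 0.3,
                            seed = 1L) {
  if (region_start >= region_end) stopf("region_start must be < region_end")
  if (n_snps < 1) stopf("n_snps must be positive")
  if (region_end - region_start + 1L < n_snps)
    stopf("region too small for %d distinct positions", n_snps)
  if (within_block_r < 0 || within_block_r >= 1)
    stopf("within_block_r must be in [0, 1)")
  if (n_exposure <= 0 || n_outcome <= 0)
    stopf("GWAS sample sizes must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("maf_range must lie in (0, 0.5]")
  structure(as.list(environment()), class = "gwas_sim_config")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

# block-correlated noise: z ~ N(0, diag(se) R diag(se)) drawn block-wise
block_noise <- function(se, blocks, r) {
  z <- rnorm(length(se))
  out <- numeric(length(se))
  for (b in blocks) {
    m <- length(b)
    if (m == 1L || r == 0) { out[b] <- z[b]; next }
    R <- matrix(r, m, m); diag(R) <- 1
    out[b] <- as.vector(t(chol(R)) %*% z[b])
  }
  out * se
}

#' Generate an exposure/outcome GWAS pair with LD matrix and ground truth
#'
#' @param config a [gwas_sim_config()]
#' @param dir optional output directory; when given, writes
#'   `exposure.tsv` and `outcome.tsv` (tab-separated columns SNP, CHR,
#'   POS, EA, OA, EAF, BETA, SE, P), `ld_matrix.txt` (square matrix with
#'   SNP-ID header) and `truth_ledger.txt`
#' @return a `gwas_sim` object: data.tables `exposure` and `outcome`, the
#'   block-diagonal LD (correlation) matrix `ld`, and `truth` (true
#'   marginal exposure effects, causal theta, per-SNP pleiotropy, and the
#'   indices of swapped / strand-flipped / palindromic SNPs)
#' @export
simulate_gwas_pair <- function(config, dir = NULL) {
  stopifnot(inherits(config, "gwas_sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  pos <- sort(sample(seq.int(config$region_start, config$region_end), n))
  snp <- paste0("rs", pos)
  maf <- runif(n, config$maf_range[1], config$maf_range[2])

  blocks <- split(seq_len(n), ceiling(seq_len(n) / config$ld_block_size))
  r <- config$within_block_r
  ld <- matrix(0, n, n, dimnames = list(snp, snp))
  for (b in blocks) { ld[b, b] <- r; }
  diag(ld) <- 1

  # one causal SNP per non-null block; marginal effects follow the block
  # correlation (standardized-genotype approximation)
  beta_marg <- numeric(n)
  for (b in blocks) {
    if (runif(1) < config$prop_null) next
    j <- b[sample.int(length(b), 1L)]
    mag <- config$exposure_effect_scale * runif(1, 0.5, 1.5)
    sgn <- if (runif(1) < config$neg_orientation_fraction) -1 else 1
    beta_marg[b] <- ld[b, j] * sgn * mag
  }

  se_x <- config$exposure_effect_scale /
    sqrt(2 * maf * (1 - maf) * config$n_exposure)
  se_y <- config$exposure_effect_scale /
    sqrt(2 * maf * (1 - maf) * config$n_outcome)
  beta_x <- beta_marg + block_noise(se_x, blocks, r)
  alpha <- rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd)
  beta_y_true <- config$causal_theta * beta_marg + alpha
  beta_y <- beta_y_true + block_noise(se_y, blocks, r)

  pval <- function(b, s) pmax(2 * pnorm(-abs(b / s)), 1e-300)

  # allele pairs: palindromic (A/T, C/G) for a configurable fraction
  pal <- runif(n) < config$palindromic_fraction
  ea <- oa <- character(n)
  pal_pairs <- rbind(c("A", "T"), c("C", "G"))
  npal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick <- function(pairs, k) {
    i <- sample.int(nrow(pairs), k, replace = TRUE)
    sw <- runif(k) < 0.5
    cbind(ifelse(sw, pairs[i, 2], pairs[i, 1]),
          ifelse(sw, pairs[i, 1], pairs[i, 2]))
  }
  if (any(pal)) { p <- pick(pal_pairs, sum(pal)); ea[pal] <- p[, 1]; oa[pal] <- p[, 2] }
  if (any(!pal)) { p <- pick(npal_pairs, sum(!pal)); ea[!pal] <- p[, 1]; oa[!pal] <- p[, 2] }
  eaf <- ifelse(runif(n) < 0.5, maf, 1 - maf)

  exposure <- data.table(SNP = snp, CHR = config$chrom, POS = pos,
                         EA = ea, OA = oa, EAF = eaf,
                         BETA = beta_x, SE = se_x, P = pval(beta_x, se_x))

  # outcome encoding: start aligned, then swap alleles for a fraction and
  # strand-flip a fraction of the non-palindromic rows
  o_ea <- ea; o_oa <- oa; o_beta <- beta_y; o_eaf <- eaf
  swap <- runif(n) < config$swap_fraction
  o_ea[swap] <- oa[swap]; o_oa[swap] <- ea[swap]
  o_beta[swap] <- -o_beta[swap]; o_eaf[swap] <- 1 - o_eaf[swap]
  flip <- !pal & runif(n) < config$strand_flip_fraction
  o_ea[flip] <- COMPLEMENT[o_ea[flip]]
  o_oa[flip] <- COMPLEMENT[o_oa[flip]]
  outcome <- data.table(SNP = snp, CHR = config$chrom, POS = pos,
                        EA = o_ea, OA = o_oa, EAF = o_eaf,
                        BETA = o_beta, SE = se_y, P = pval(beta_y, se_y))

  truth <- list(beta_marg = setNames(beta_marg, snp),
                causal_theta = config$causal_theta,
                pleiotropy = setNames(alpha, snp),
                swapped = snp[swap], strand_flipped = snp[flip],
                palindromic = snp[pal])
  out <- structure(list(exposure = exposure, outcome = outcome, ld = ld,
                        truth = truth, config = config),
                   class = "gwas_sim")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(exposure, file.path(dir, "exposure.tsv"), sep = "\t", eol = "\n")
    fwrite(outcome, file.path(dir, "outcome.tsv"), sep = "\t", eol = "\n")
    ldt <- data.table(SNP = snp)
    for (j in seq_len(n)) set(ldt, j = snp[j], value = ld[, j])
    fwrite(ldt, file.path(dir, "ld_matrix.txt"), sep = "\t", eol = "\n")
    writeLines(c(sprintf("n_snps=%d", n),
                 sprintf("causal_theta=%.8f", config$causal_theta),
                 sprintf("pleiotropy_mean=%.8f", config$pleiotropy_mean),
                 sprintf("pleiotropy_sd=%.8f", config$pleiotropy_sd),
                 sprintf("seed=%d", config$seed)),
               file.path(dir, "truth_ledger.txt"))
    out$dir <- dir
  }
  out
}

#' Read GWAS summary statistics from tab-separated text
#'
#' Expects the columns SNP, CHR, POS, EA, OA, EAF, BETA, SE, P (extra
#' columns pass through). Missing mandatory columns are a hard failure.
#'
#' @param path file path
#' @return data.table of per-SNP records
#' @export
read_gwas <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stopf("GWAS file '%s' is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  if (any(dt$SE <= 0, na.rm = TRUE)) stopf("non-positive SE in '%s'", path)
  dt
}

#' Read a plain-text LD matrix with SNP-ID header
#'
#' @param path file path (first column `SNP`, remaining columns one per SNP)
#' @return square numeric matrix with SNP dimnames
#' @export
read_ld_matrix <- function(path) {
  dt <- fread(path, sep = "\t")
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1])
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) stopf("LD matrix header/rows disagree")
  m
}
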