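# Synthetic spontaneous-report generator.
#
# Generation model (kept deliberately simple so every expected 2x2 cell is
# available in closed form):
#   * each report is one case carrying one drug *family* (1-3 co-reported
#     alias rows, e.g. brand + generic of the same product) and 1-4 PT
#     occurrences drawn i.i.d. from the family-conditional event
#     distribution q(e|f) proportional to baseline_event_probs[e] *
#     lift(f, e);
#   * duplicates are clones of existing cases with a larger PRIMARYID, a
#     receipt date shifted +1..+90 days and possibly one mutated
#     demographic field, so the CASEID deduplication rule is exercised on
#     every branch.

DRUG_COUNT_PROBS  <- c(0.60, 0.30, 0.10)        # 1-3 alias rows per report
EVENT_COUNT_PROBS <- c(0.55, 0.27, 0.13, 0.05)  # 1-4 PT occurrences

#' Configuration for the spontaneous-report generator
#'
#' @param n_reports number of unique cases to generate
#' @param drug_vocabulary named list: family name -> character vector of
#'   co-reported alias strings. The default contains the PCSK9-inhibitor
#'   agents (covering all seven standard search terms), several
#'   lipid-lowering comparators and non-lipid background drugs.
#' @param event_vocabulary character vector of MedDRA-style PT strings;
#'   the default includes the nine memory-loss PTs.
#' @param baseline_drug_probs named simplex vector over families (must sum
#'   to 1 within 1e-9)
#' @param baseline_event_probs simplex vector over `event_vocabulary`
#' @param association_lift data.frame with columns `drug` (family name),
#'   `event` (PT string) and `lift` (reporting rate ratio >= 0) giving
#'   ground-truth departures from independence; empty means full
#'   independence
#' @param duplicate_fraction fraction of cases that receive one duplicate
#'   row (in `[0, 1)`)
#' @param missing_age_fraction,missing_gender_fraction missingness rates
#' @param serious_fraction fraction of cases with >= 1 serious outcome code
#' @param quarters character vector of quarter labels `"YYYYQn"`
#' @param seed integer seed; fixes all output bit-for-bit
#' @return a validated `faers_sim_config` list
#' @export
faers_sim_config <- function(n_reports,
                             drug_vocabulary = default_drug_vocabulary(),
                             event_vocabulary = default_event_vocabulary(),
                             baseline_drug_probs = NULL,
                             baseline_event_probs = NULL,
                             association_lift = NULL,
                             duplicate_fraction = 0.05,
                             missing_age_fraction = 0.30,
                             missing_gender_fraction = 0.05,
                             serious_fraction = 0.35,
                             quarters = default_quarters(),
                             seed = 1L) {
  if (length(drug_vocabulary) < 2L)
    stopf("drug_vocabulary must contain at least 2 drug families; a 2x2 background is impossible with %d", length(drug_vocabulary))
  if (length(event_vocabulary) < 2L)
    stopf("event_vocabulary must contain at least 2 events; a 2x2 background is impossible with %d", length(event_vocabulary))
  if (is.null(names(drug_vocabulary)) || anyDuplicated(names(drug_vocabulary)))
    stopf("drug_vocabulary must be a uniquely named list of families")
  if (is.null(baseline_drug_probs))
    baseline_drug_probs <- default_drug_probs(names(drug_vocabulary))
  if (is.null(baseline_event_probs))
    baseline_event_probs <- default_event_probs(event_vocabulary)
  check_simplex(baseline_drug_probs, length(drug_vocabulary), "baseline_drug_probs")
  check_simplex(baseline_event_probs, length(event_vocabulary), "baseline_event_probs")
  if (is.null(names(baseline_drug_probs)))
    names(baseline_drug_probs) <- names(drug_vocabulary)
  if (is.null(names(baseline_event_probs)))
    names(baseline_event_probs) <- event_vocabulary
  if (is.null(association_lift))
    association_lift <- data.frame(drug = character(), event = character(),
                                   lift = numeric())
  stopifnot(all(c("drug", "event", "lift") %in% names(association_lift)))
  if (any(association_lift$lift < 0)) stopf("association lifts must be >= 0")
  if (!all(association_lift$drug %in% names(drug_vocabulary)))
    stopf("association_lift refers to unknown drug families")
  if (!all(association_lift$event %in% event_vocabulary))
    stopf("association_lift refers to unknown events")
  if (n_reports < 1L) stopf("n_reports must be positive")
  if (duplicate_fraction < 0 || duplicate_fraction >= 1)
    stopf("duplicate_fraction must be in [0, 1)")
  for (f in c(missing_age_fraction, missing_gender_fraction, serious_fraction))
    if (f < 0 || f > 1) stopf("fractions must be in [0, 1]")
  structure(list(
    n_reports = as.integer(n_reports),
    drug_vocabulary = drug_vocabulary,
    event_vocabulary = event_vocabulary,
    baseline_drug_probs = baseline_drug_probs,
    baseline_event_probs = baseline_event_probs,
    association_lift = association_lift,
    duplicate_fraction = duplicate_fraction,
    missing_age_fraction = missing_age_fraction,
    missing_gender_fraction = missing_gender_fraction,
    serious_fraction = serious_fraction,
    quarters = quarters,
    seed = as.integer(seed)
  ), class = "faers_sim_config")
}

default_quarters <- function() {
  c(as.vector(t(outer(2022:2024, paste0("Q", 1:4), paste0))), "2025Q1")
}

check_simplex <- function(p, len, what) {
  if (length(p) != len) stopf("%s must have length %d", what, len)
  if (any(p < 0)) stopf("%s must be nonnegative", what)
  if (abs(sum(p) - 1) > 1e-9) stopf("%s must sum to 1 (got %.12f)", what, sum(p))
  invisible(TRUE)
}

default_drug_probs <- function(families) {
  p <- rep(1, length(families))
  names(p) <- families
  # plausible reporting shares: PCSK9 agents are a small slice of FAERS
  pcsk9 <- c(alirocumab = 0.40, evolocumab = 1.60, inclisiran = 0.55,
             pcsk9_other = 0.05)
  for (f in names(pcsk9)) if (f %in% families) p[f] <- pcsk9[f]
  p / sum(p)
}

default_event_probs <- function(events) {
  q <- rep(1, length(events))
  names(q) <- events
  mem <- c("Memory impairment" = 0.30, "Amnesia" = 0.10,
           "Transient global amnesia" = 0.02, "Amnestic disorder" = 0.01)
  rare <- setdiff(memory_loss_pts(), names(mem))
  for (e in names(mem)) if (e %in% events) q[e] <- mem[e]
  for (e in rare) if (e %in% events) q[e] <- 0.004
  q / sum(q)
}

# family-conditional event distribution q(e|f) with lifts applied
conditional_event_probs <- function(config) {
  q <- config$baseline_event_probs
  fams <- names(config$drug_vocabulary)
  out <- matrix(rep(q, length(fams)), nrow = length(fams), byrow = TRUE,
                dimnames = list(fams, names(q)))
  al <- config$association_lift
  if (nrow(al)) for (i in seq_len(nrow(al)))
    out[al$drug[i], al$event[i]] <- out[al$drug[i], al$event[i]] * al$lift[i]
  out / rowSums(out)
}

#' Closed-form ground truth of a report-generator configuration
#'
#' The expected PT-occurrence matrix (family x event), the expected 2x2
#' cells at the event-level counting unit under the full background, and
#' the implied true occurrence-level reporting odds ratio, for an
#' arbitrary target cohort. This is the ledger oracle the generator's
#' output is validated against.
#'
#' @param config a [faers_sim_config()]
#' @param drug_terms,event_pts the cohort to compute expectations for
#' @return list with `occurrence_matrix`, `events_per_report`, `cells`
#'   (named a/b/c/d), `true_ror` and `target_families`
#' @export
faers_expectations <- function(config,
                               drug_terms = pcsk9_terms(),
                               event_pts = memory_loss_pts()) {
  em <- sum(seq_along(EVENT_COUNT_PROBS) * EVENT_COUNT_PROBS)
  cond <- conditional_event_probs(config)
  occ <- config$n_reports * em * config$baseline_drug_probs * cond
  fam_target <- vapply(config$drug_vocabulary, function(aliases)
    any(match_drug(aliases, drug_terms)), logical(1))
  ev_target <- colnames(occ) %in% event_pts
  a <- sum(occ[fam_target, ev_target])
  b <- sum(occ[fam_target, !ev_target])
  c_ <- sum(occ[!fam_target, ev_target])
  d <- sum(occ[!fam_target, !ev_target])
  list(occurrence_matrix = occ, events_per_report = em,
       cells = c(a = a, b = b, c = c_, d = d),
       true_ror = (a * d) / (b * c_),
       target_families = names(which(fam_target)))
}

quarter_dates <- function(q) {
  year <- as.integer(substr(q, 1, 4))
  qn <- as.integer(substr(q, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", year, (qn - 1L) * 3L + 1L))
  end <- seq(start, by = "3 months", length.out = 2L)[2L] - 1L
  c(start, end)
}

date_to_int <- function(d) as.integer(format(d, "%Y%m%d"))

#' Generate FAERS-dialect quarterly tables with known ground truth
#'
#' Writes `DEMO_<quarter>.txt`, `DRUG_<quarter>.txt`, `REAC_<quarter>.txt`
#' and `OUTC_<quarter>.txt` in the `'$'`-delimited ASCII dialect, plus a
#' `truth_ledger.txt` key-value file recording the generator's ground truth
#' (unique-case count, duplicate count, expected 2x2 cells and the true
#' occurrence-level reporting odds ratio for the default target cohort).
#'
#' @param config a [faers_sim_config()]
#' @param dir output directory (created if needed)
#' @return (invisibly) a `faers_sim` object with elements `dir`, `files`,
#'   `ledger` (the ground-truth list, including the closed-form expected
#'   family-by-event occurrence matrix) and `config`
#' @export
simulate_faers <- function(config, dir) {
  stopifnot(inherits(config, "faers_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_reports
  fams <- names(config$drug_vocabulary)

  caseid <- 30000000L + seq_len(n)
  primaryid <- caseid * 10L
  quarter <- sample(config$quarters, n, replace = TRUE)
  qd <- lapply(config$quarters, quarter_dates)
  names(qd) <- config$quarters
  span_end <- max(as.Date(vapply(qd, function(x) as.character(x[2]), "")))
  date <- as.Date(vapply(quarter, function(q) {
    r <- qd[[q]]
    as.character(r[1] + sample.int(as.integer(r[2] - r[1]) + 1L, 1L) - 1L)
  }, ""))
  fda_dt <- date_to_int(date)

  fam_idx <- sample.int(length(fams), n, replace = TRUE,
                        prob = config$baseline_drug_probs)

  age <- pmin(pmax(round(rnorm(n, 72, 9)), 18), 100)
  age[runif(n) < config$missing_age_fraction] <- NA_integer_
  sex <- ifelse(runif(n) < 0.72, "F", "M")
  sex[runif(n) < config$missing_gender_fraction] <- ""
  occp <- sample(c("CN", "HP", "MD", "PH", "OT"), n, replace = TRUE,
                 prob = c(0.80, 0.11, 0.05, 0.02, 0.02))
  country <- ifelse(runif(n) < 0.90, "US",
                    sample(c("CA", "GB", "DE", "FR", "JP", "AU", "IT"), n,
                           replace = TRUE))
  demo <- data.table(PRIMARYID = primaryid, CASEID = caseid, FDA_DT = fda_dt,
                     AGE = age, AGE_COD = ifelse(is.na(age), "", "YR"),
                     SEX = sex, OCCP_COD = occp, REPORTER_COUNTRY = country,
                     quarter = quarter)

  # drug rows: 1-3 distinct aliases of the report's family
  fam_sizes <- lengths(config$drug_vocabulary)
  ndrug <- pmin(sample.int(3L, n, replace = TRUE, prob = DRUG_COUNT_PROBS),
                fam_sizes[fam_idx])
  drug_pid <- rep(primaryid, ndrug)
  drug_name <- unlist(lapply(seq_len(n), function(i) {
    al <- config$drug_vocabulary[[fam_idx[i]]]
    al[sample.int(length(al), ndrug[i])]
  }), use.names = FALSE)
  role <- unlist(lapply(ndrug, function(k)
    c("PS", sample(c("SS", "C"), k - 1L, replace = TRUE))), use.names = FALSE)
  drug <- data.table(PRIMARYID = drug_pid,
                     DRUG_SEQ = unlist(lapply(ndrug, seq_len), use.names = FALSE),
                     ROLE_COD = role, DRUGNAME = drug_name,
                     PROD_AI = drug_name)

  # reaction rows: 1-4 PT occurrences i.i.d. from q(e|family)
  cond <- conditional_event_probs(config)
  nev <- sample.int(4L, n, replace = TRUE, prob = EVENT_COUNT_PROBS)
  reac_pid <- rep(primaryid, nev)
  reac_fam <- rep(fam_idx, nev)
  pt <- character(length(reac_pid))
  for (f in seq_along(fams)) {
    sel <- reac_fam == f
    if (any(sel))
      pt[sel] <- sample(config$event_vocabulary, sum(sel), replace = TRUE,
                        prob = cond[f, ])
  }
  reac <- data.table(PRIMARYID = reac_pid, PT = pt)

  # serious-outcome rows for a fraction of cases
  is_serious <- runif(n) < config$serious_fraction
  outc_codes <- c("HO", "OT", "DS", "LT", "DE")
  outc_probs <- c(0.29, 0.58, 0.06, 0.02, 0.05)
  sid <- primaryid[is_serious]
  ncode <- 1L + (runif(length(sid)) < 0.15)
  outc <- data.table(
    PRIMARYID = rep(sid, ncode),
    OUTC_COD = unlist(lapply(ncode, function(k)
      sample(outc_codes, k, prob = outc_probs)), use.names = FALSE))

  # duplicates: clone a case under a higher PRIMARYID and later FDA_DT,
  # possibly mutating one demographic field
  n_dup <- floor(config$duplicate_fraction * n)
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    clone <- demo[di]
    clone[, PRIMARYID := PRIMARYID + 1L]
    clone[, FDA_DT := date_to_int(pmin(date[di] + sample.int(90L, n_dup,
                                                             replace = TRUE),
                                       span_end))]
    mut <- runif(n_dup) < 0.30
    mut_age <- mut & runif(n_dup) < 0.5
    sel_age <- which(mut_age & !is.na(clone$AGE))
    sel_sex <- which(mut & !mut_age)
    if (length(sel_age))
      clone[sel_age, AGE := AGE + sample(c(-3:-1, 1:3), length(sel_age),
                                         replace = TRUE)]
    if (length(sel_sex))
      clone[sel_sex, SEX := sample(c("F", "M"), length(sel_sex),
                                   replace = TRUE)]
    demo <- rbind(demo, clone)
    cl_pid <- primaryid[di]
    dclone <- drug[PRIMARYID %in% cl_pid]; dclone[, PRIMARYID := PRIMARYID + 1L]
    rclone <- reac[PRIMARYID %in% cl_pid]; rclone[, PRIMARYID := PRIMARYID + 1L]
    oclone <- outc[PRIMARYID %in% cl_pid]; oclone[, PRIMARYID := PRIMARYID + 1L]
    drug <- rbind(drug, dclone); reac <- rbind(reac, rclone)
    outc <- rbind(outc, oclone)
  }

  files <- character(0)
  for (q in config$quarters) {
    dsub <- demo[quarter == q][order(PRIMARYID)]
    pids <- dsub$PRIMARYID
    paths <- file.path(dir, paste0(c("DEMO_", "DRUG_", "REAC_", "OUTC_"),
                                   q, ".txt"))
    fwrite(dsub[, !"quarter"], paths[1], sep = "$", eol = "\n", quote = FALSE)
    fwrite(drug[PRIMARYID %in% pids][order(PRIMARYID, DRUG_SEQ)], paths[2],
           sep = "$", eol = "\n", quote = FALSE)
    fwrite(reac[PRIMARYID %in% pids][order(PRIMARYID, PT)], paths[3],
           sep = "$", eol = "\n", quote = FALSE)
    fwrite(outc[PRIMARYID %in% pids][order(PRIMARYID, OUTC_COD)], paths[4],
           sep = "$", eol = "\n", quote = FALSE)
    files <- c(files, paths)
  }

  exp <- faers_expectations(config)
  ledger <- list(n_unique_cases = n, n_duplicates = n_dup,
                 n_demo_rows = nrow(demo), n_reac_rows = nrow(reac),
                 expected_cells = exp$cells, true_ror = exp$true_ror,
                 events_per_report = exp$events_per_report,
                 target_families = exp$target_families,
                 occurrence_matrix = exp$occurrence_matrix)
  ledger_path <- file.path(dir, "truth_ledger.txt")
  writeLines(c(
    sprintf("n_unique_cases=%d", n),
    sprintf("n_duplicates=%d", n_dup),
    sprintf("expected_a=%.6f", exp$cells["a"]),
    sprintf("expected_b=%.6f", exp$cells["b"]),
    sprintf("expected_c=%.6f", exp$cells["c"]),
    sprintf("expected_d=%.6f", exp$cells["d"]),
    sprintf("true_ror=%.8f", exp$true_ror),
    sprintf("seed=%d", config$seed)
  ), ledger_path)
  invisible(structure(list(dir = dir, files = c(files, ledger_path),
                           ledger = ledger, config = config),
                      class = "faers_sim"))
}

#' Simulate independent 2x2 contingency tables with a known lift
#'
#' Draws occurrence-level tables from a multinomial whose cell
#' probabilities put a reporting rate ratio `lift` on the (drug, event)
#' cell relative to independence: within the target drug the event
#' probability is `p_event * lift / (1 + p_event * (lift - 1))`.
#' Used for calibration studies of the signal criteria.
#'
#' @param n_tables number of tables
#' @param n total occurrence count per table
#' @param p_drug,p_event marginal probabilities of the target drug and event
#' @param lift true reporting rate ratio (1 = independence)
#' @param seed integer seed
#' @return list of [contingency_table()] objects; attribute `true_or` holds
#'   the occurrence-level odds ratio implied by `lift`
#' @export
simulate_contingency_tables <- function(n_tables, n, p_drug, p_event,
                                        lift = 1, seed = 1L) {
  stopifnot(p_drug > 0, p_drug < 1, p_event > 0, p_event < 1, lift >= 0)
  set.seed(seed)
  pe_t <- p_event * lift / (1 + p_event * (lift - 1))
  probs <- c(p_drug * pe_t, p_drug * (1 - pe_t),
             (1 - p_drug) * p_event, (1 - p_drug) * (1 - p_event))
  draws <- rmultinom(n_tables, n, probs)
  out <- lapply(seq_len(n_tables), function(i)
    contingency_table(draws[1, i], draws[2, i], draws[3, i], draws[4, i],
                      label = sprintf("sim_%d", i)))
  attr(out, "true_or") <- (pe_t / (1 - pe_t)) / (p_event / (1 - p_event))
  out
}
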