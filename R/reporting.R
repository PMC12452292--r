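# Descriptive summaries, rendered signal tables and the end-to-end
# orchestrated run with its JSON manifest.

#' Counts-to-percentages summary block
#'
#' The elementary operation behind every block of a descriptive
#' ("Table 1"-style) summary: counts with percentages of a stated
#' denominator, rounded half-up to two decimals.
#'
#' @param counts named integer vector
#' @param denominator denominator for the percentages (default
#'   `sum(counts)`)
#' @return data.frame with columns `category`, `count`, `pct`
#' @export
summarize_counts <- function(counts, denominator = sum(counts)) {
  counts <- setNames(as.numeric(counts), names(counts))  # tables welcome
  pct <- if (denominator > 0) round_half_up(100 * counts / denominator, 2) else
    rep(NA_real_, length(counts))
  data.frame(category = names(counts), count = as.integer(counts), pct = pct,
             row.names = NULL)
}

AGENT_TERMS <- list(alirocumab = c("alirocumab", "praluent"),
                    evolocumab = c("evolocumab", "repatha"),
                    inclisiran = c("inclisiran", "leqvio"))
OCCP_LABELS <- c(CN = "Consumer", HP = "Health professional",
                 MD = "Physician", PH = "Pharmacist", OT = "Other")
OUTC_LABELS <- c(DE = "Death", HO = "Hospitalization", LT = "Life-threatening",
                 DS = "Disability", OT = "Other serious outcomes")

#' Descriptive summary of the target cohort
#'
#' Characterises the deduplicated reports that carry both a target drug
#' and at least one target event: matched event PTs (denominator = AE
#' occurrences), agent, gender, age group, reporter type, country and
#' reporting year (denominator = patients), and serious outcomes
#' (denominator = serious-outcome mentions). Percentages are half-up at
#' two decimals. An empty cohort yields an empty summary with explicit
#' zero denominators.
#'
#' @param raw deduplicated `faers_raw`
#' @param cohort a [cohort_definition()]
#' @return data.frame with columns `section`, `category`, `count`, `pct`;
#'   attributes `n_patients`, `n_events`, `age_median`, `age_iqr`
#' @export
descriptive_summary <- function(raw, cohort = cohort_definition()) {
  stopifnot(inherits(raw, "faers_raw"))
  target_ids <- matched_report_ids(raw, cohort$drug_terms, cohort$roles)
  reac_t <- raw$reac[PRIMARYID %in% target_ids]
  matched <- reac_t[match_event(PT, cohort$event_pts)]
  case_ids <- unique(matched$PRIMARYID)
  demo <- raw$demo[PRIMARYID %in% case_ids]
  n_pat <- nrow(demo)
  n_ev <- nrow(matched)

  block <- function(section, df) {
    if (!nrow(df)) return(NULL)
    cbind(section = section, df)
  }
  out <- list()

  ev_counts <- sort(table(matched$PT), decreasing = TRUE)
  out$events <- block("Memory loss events",
                      summarize_counts(c(ev_counts), denominator = n_ev))

  if (n_pat) {
    agent <- vapply(AGENT_TERMS, function(terms) {
      length(intersect(case_ids, matched_report_ids(raw, terms, cohort$roles)))
    }, integer(1))
    out$agents <- block("Agent", summarize_counts(agent, denominator = n_pat))
  }

  if (n_pat) {
    sx <- toupper(demo$SEX %||% rep("", n_pat))
    gender <- c(Male = sum(sx == "M"), Female = sum(sx == "F"),
                Missing = sum(sx != "M" & sx != "F"))
    out$gender <- block("Gender", summarize_counts(gender, denominator = n_pat))

    yrs <- age_in_years(demo$AGE, demo$AGE_COD %||% rep("YR", n_pat))
    age <- c(`<18` = sum(!is.na(yrs) & yrs < 18),
             `18-64` = sum(!is.na(yrs) & yrs >= 18 & yrs < 65),
             `>=65` = sum(!is.na(yrs) & yrs >= 65),
             Missing = sum(is.na(yrs)))
    age <- age[age > 0 | names(age) != "<18"]
    out$age <- block("Age (years)", summarize_counts(age, denominator = n_pat))

    occ <- OCCP_LABELS[demo$OCCP_COD %||% rep(NA_character_, n_pat)]
    occ[is.na(occ)] <- "Other"
    out$reporter <- block("Reported person",
                          summarize_counts(table(occ), denominator = n_pat))

    ctry <- ifelse((demo$REPORTER_COUNTRY %||% rep("", n_pat)) == "US",
                   "United States", "Other country")
    out$country <- block("Reported countries",
                         summarize_counts(table(ctry), denominator = n_pat))

    yr <- substr(as.character(demo$FDA_DT), 1, 4)
    out$year <- block("Reported year",
                      summarize_counts(table(yr), denominator = n_pat))
  }

  outc <- raw$outc[PRIMARYID %in% case_ids]
  if (nrow(outc)) {
    oc <- OUTC_LABELS[outc$OUTC_COD]
    oc_counts <- table(factor(oc, levels = unname(OUTC_LABELS)))
    oc_counts <- oc_counts[oc_counts > 0]
    out$serious <- block("Serious outcomes", summarize_counts(oc_counts))
  }

  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(section = character(), category = character(),
                      count = integer(), pct = numeric())
  rownames(res) <- NULL
  yrs_all <- if (n_pat) age_in_years(demo$AGE, demo$AGE_COD %||% rep("YR", n_pat)) else numeric(0)
  structure(res, n_patients = n_pat, n_events = n_ev,
            age_median = median(yrs_all, na.rm = TRUE),
            age_iqr = unname(stats::quantile(yrs_all, c(0.25, 0.75),
                                             na.rm = TRUE, names = FALSE)))
}

#' Render signal results as a delimited report table
#'
#' One row per adverse-event grouping with the standard column layout
#' (AEs, N, ROR (95% CI), PRR, chi2, EBGM05, IC025, signal), all interval
#' statistics formatted at two decimals with half-up rounding. Groupings
#' below the minimum case count are excluded from the table and listed in
#' the `excluded` attribute.
#'
#' @param results list of `signal_result` objects (named by AE grouping)
#' @param path optional file to write the tab-separated table to
#' @param min_count minimum report count for a row (default 3)
#' @return data.frame (invisibly when `path` is given); attribute
#'   `excluded` names the groupings left out
#' @export
render_signal_table <- function(results, path = NULL, min_count = 3) {
  keep <- vapply(results, function(r) r$a >= min_count, logical(1))
  rows <- lapply(results[keep], function(r) {
    data.frame(AEs = r$label, N = r$a,
               `ROR (95% CI)` = fmt_ci(r$ror, r$ror_low, r$ror_high),
               PRR = fmt_num(r$prr), chi2 = fmt_num(r$chi2),
               EBGM05 = if (is.na(r$ebgm05)) "" else fmt_num(r$ebgm05),
               IC025 = fmt_num(r$ic025),
               signal = if (r$flags$overall) "yes" else "no",
               check.names = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(AEs = character(), N = integer(), `ROR (95% CI)` = character(),
               PRR = character(), chi2 = character(), EBGM05 = character(),
               IC025 = character(), signal = character(), check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- names(results)[!keep]
  if (!is.null(path)) {
    fwrite(out, path, sep = "\t", eol = "\n", quote = FALSE)
    return(invisible(out))
  }
  out
}

#' End-to-end run configuration
#'
#' Bundles every knob of an orchestrated run. All stochastic stages derive
#' their seeds from the single `seed`.
#'
#' @param outdir output directory
#' @param seed master integer seed
#' @param faers_config a [faers_sim_config()] (synthetic input), or `NULL`
#'   to read existing tables from `faers_dir`
#' @param faers_dir directory of FAERS-dialect tables (written to, for a
#'   synthetic run)
#' @param cohort a [cohort_definition()]; its `background` field is
#'   ignored (both backgrounds are always run)
#' @param mr_control a [gwas_sim_config()] for the positive-control
#'   outcome (its `causal_theta` must match `control_direction`)
#' @param control_direction expected IVW direction of the control
#' @param mr_outcomes named list of [gwas_sim_config()]s, one per outcome
#' @param p_threshold,r2_max,window_kb instrument-selection settings
#' @param n_boot bootstrap replicates for median/mode standard errors
#' @return a `run_config` list
#' @export
run_config <- function(outdir, seed = 1L,
                       faers_config = NULL, faers_dir = NULL,
                       cohort = cohort_definition(),
                       mr_control = NULL,
                       control_direction = "protective",
                       mr_outcomes = list(),
                       p_threshold = 5e-8, r2_max = 0.3, window_kb = 100,
                       n_boot = 500L) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 faers_config = faers_config,
                 faers_dir = faers_dir %||% file.path(outdir, "faers"),
                 cohort = cohort, mr_control = mr_control,
                 control_direction = control_direction,
                 mr_outcomes = mr_outcomes,
                 p_threshold = p_threshold, r2_max = r2_max,
                 window_kb = window_kb, n_boot = as.integer(n_boot)),
            class = "run_config")
}

#' Default demonstration run configuration
#'
#' A synthetic study shaped like the motivating safety question: a
#' PCSK9-inhibitor-like target family with a mild *negative* association
#' with the memory-loss composite (lift 0.8), an LDL-C-like exposure, a
#' protective positive-control outcome (true odds ratio about 0.52 per
#' unit exposure) and three null memory outcomes.
#'
#' @param outdir output directory
#' @param seed master seed
#' @param n_reports synthetic report count
#' @return a [run_config()]
#' @export
default_run_config <- function(outdir, seed = 1L, n_reports = 20000L) {
  lift <- data.frame(drug = "evolocumab", event = "Memory impairment",
                     lift = 0.8)
  fc <- faers_sim_config(n_reports = n_reports, association_lift = lift,
                         seed = derive_seed(seed, 1L))
  gw <- function(theta, stream) gwas_sim_config(
    causal_theta = theta, seed = derive_seed(seed, stream))
  run_config(outdir, seed = seed, faers_config = fc,
             mr_control = gw(log(0.52), 2L),
             mr_outcomes = list(`Memory loss` = gw(0, 3L),
                                `Memory impairment` = gw(0, 4L),
                                Amnesia = gw(0, 5L)),
             n_boot = 500L)
}

run_signal_block <- function(raw, cohort, prior, min_count = 3) {
  pts <- cohort$event_pts
  tabs <- list()
  tabs[["Memory loss"]] <- build_contingency(raw, cohort)
  for (pt in pts) {
    co <- cohort
    co$event_pts <- pt
    tb <- tryCatch(build_contingency(raw, co), error = function(e) NULL)
    if (!is.null(tb) && tb$a > 0) tabs[[pt]] <- tb
  }
  results <- lapply(names(tabs), function(nm) {
    tb <- tabs[[nm]]
    tb$label <- nm
    signal_stats(tb, prior = prior, haldane = TRUE)
  })
  names(results) <- names(tabs)
  results
}

#' Execute the full dual-evidence pipeline
#'
#' Simulate (when configured) -> read -> deduplicate -> descriptive
#' summary -> disproportionality under both backgrounds, per agent and per
#' gender/age stratum -> Mendelian randomization (positive control first,
#' then each outcome). All artifacts are tab-separated text plus a JSON
#' manifest recording parameters, seeds, exclusion counters and md5
#' checksums; with a fixed seed two runs are byte-identical. Any stage
#' error aborts with the stage name after persisting a partial manifest;
#' a failed positive control aborts with the distinct condition class
#' `positive_control_error`.
#'
#' @param config a [run_config()]
#' @return (invisibly) list with the manifest and in-memory results
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("signalmr")),
                   seed = config$seed, stages = character(0),
                   parameters = list(p_threshold = config$p_threshold,
                                     r2_max = config$r2_max,
                                     window_kb = config$window_kb,
                                     n_boot = config$n_boot))
  outputs <- character(0)
  finish_stage <- function(name) manifest$stages <<- c(manifest$stages, name)
  persist <- function() {
    ck <- tools::md5sum(file.path(config$outdir, outputs))
    manifest$outputs <<- as.list(setNames(unname(ck), outputs))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      persist()
      if (inherits(e, "positive_control_error")) stop(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  save_table <- function(df, file) {
    fwrite(df, file.path(config$outdir, file), sep = "\t", eol = "\n",
           quote = FALSE)
    outputs <<- c(outputs, file)
  }

  # --- spontaneous-report arm ------------------------------------------
  if (!is.null(config$faers_config)) {
    run_stage("simulate_faers",
              simulate_faers(config$faers_config, config$faers_dir))
    finish_stage("simulate_faers")
  }
  raw <- run_stage("read_faers", read_faers_tables(config$faers_dir))
  finish_stage("read_faers")
  dedup <- run_stage("deduplicate", deduplicate_reports(raw))
  manifest$counts <- list(raw_reports = nrow(raw$demo),
                          unique_cases = nrow(dedup$demo),
                          exclusions = raw$exclusions)
  finish_stage("deduplicate")

  summ <- run_stage("descriptive_summary",
                    descriptive_summary(dedup, config$cohort))
  save_table(summ, "table1_descriptive.tsv")
  manifest$cohort <- list(n_patients = attr(summ, "n_patients"),
                          n_events = attr(summ, "n_events"))
  finish_stage("descriptive_summary")

  signal_results <- list()
  run_stage("disproportionality", {
    for (bg in c("full", "lipid_lowering")) {
      cohort <- config$cohort
      cohort$background <- bg
      universe <- if (bg == "full") dedup else {
        ids <- matched_report_ids(dedup, cohort$lipid_lowering_terms,
                                  cohort$roles)
        subset_raw(dedup, ids)
      }
      prior <- fit_mgps_prior(pair_counts(universe))
      res <- run_signal_block(dedup, cohort, prior)
      signal_results[[bg]] <- res
      save_table(render_signal_table(res),
                 sprintf("signal_%s.tsv", sub("_lowering", "", bg)))
      # per-agent tables under this background
      agent_rows <- list()
      for (ag in names(AGENT_TERMS)) {
        co <- cohort
        co$drug_terms <- AGENT_TERMS[[ag]]
        co$label <- ag
        tb <- tryCatch(build_contingency(dedup, co), error = function(e) NULL)
        if (!is.null(tb))
          agent_rows[[ag]] <- signal_stats(tb, prior = prior, haldane = TRUE)
        if (!is.null(agent_rows[[ag]])) agent_rows[[ag]]$label <- ag
      }
      save_table(render_signal_table(agent_rows),
                 sprintf("signal_%s_by_agent.tsv", sub("_lowering", "", bg)))
      if (bg == "full") {
        for (by in c("gender", "age")) {
          strata <- stratify_reports(dedup, by)
          srows <- list()
          for (s in names(strata)) {
            tb <- tryCatch(build_contingency(strata[[s]], cohort),
                           error = function(e) NULL)
            if (is.null(tb)) next
            r <- signal_stats(tb, prior = prior, haldane = TRUE)
            r$label <- s
            srows[[s]] <- r
          }
          save_table(render_signal_table(srows),
                     sprintf("signal_by_%s.tsv", by))
        }
      }
    }
  })
  finish_stage("disproportionality")

  # --- genetic arm ------------------------------------------------------
  mr_rows <- list()
  harmon_logs <- list()
  region <- NULL
  run_mr_one <- function(cfg, label) {
    sim <- simulate_gwas_pair(cfg)
    snps <- select_instruments(sim$exposure,
                               c(cfg$region_start, cfg$region_end),
                               config$p_threshold, sim$ld,
                               config$r2_max, config$window_kb)
    instr <- harmonize_gwas(sim$exposure, sim$outcome, snps = snps)
    harmon_logs[[label]] <<- cbind(outcome = label, attr(instr, "log"))
    instr
  }
  if (!is.null(config$mr_control)) {
    ctrl <- run_stage("positive_control", {
      instr <- run_mr_one(config$mr_control, "control")
      positive_control(instr, direction = config$control_direction,
                       n_boot = config$n_boot,
                       seed = derive_seed(config$seed, 10L))
    })
    mr_rows[["control"]] <- as.data.frame(ctrl$battery,
                                          exposure = "target exposure",
                                          outcome = "positive control")
    manifest$positive_control <- list(passed = TRUE,
                                      ivw_or = ctrl$battery$ivw$or_hat)
    finish_stage("positive_control")
  }
  if (length(config$mr_outcomes)) {
    run_stage("mr_outcomes", {
      for (i in seq_along(config$mr_outcomes)) {
        nm <- names(config$mr_outcomes)[i]
        instr <- run_mr_one(config$mr_outcomes[[i]], nm)
        bat <- mr_all(instr, n_boot = config$n_boot,
                      seed = derive_seed(config$seed, 20L + i))
        mr_rows[[nm]] <- as.data.frame(bat, exposure = "target exposure",
                                       outcome = nm)
      }
    })
    finish_stage("mr_outcomes")
  }
  if (length(mr_rows)) {
    save_table(do.call(rbind, mr_rows), "mr_results.tsv")
    save_table(rbindlist(harmon_logs), "harmonization_log.tsv")
  }
  persist()
  invisible(list(manifest = manifest, summary = summ,
                 signal = signal_results, mr = mr_rows))
}

# restrict a faers_raw to a set of PRIMARYIDs
subset_raw <- function(raw, ids) {
  structure(list(demo = raw$demo[PRIMARYID %in% ids],
                 drug = raw$drug[PRIMARYID %in% ids],
                 reac = raw$reac[PRIMARYID %in% ids],
                 outc = raw$outc[PRIMARYID %in% ids],
                 exclusions = raw$exclusions,
                 deduplicated = raw$deduplicated),
            class = "faers_raw")
}
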