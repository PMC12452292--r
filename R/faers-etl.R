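# Reading, deduplication and cohort construction for FAERS-style
# quarterly report tables ('$'-delimited DEMO/DRUG/REAC, optional OUTC).

DEMO_COLS <- c("PRIMARYID", "CASEID", "FDA_DT")
DRUG_COLS <- c("PRIMARYID", "DRUGNAME")
REAC_COLS <- c("PRIMARYID", "PT")

#' Read FAERS-dialect quarterly tables
#'
#' Reads all `DEMO*`/`DRUG*`/`REAC*` (and, when present, `OUTC*`) files in
#' `dir`, or the explicit files given in `paths`. Rows whose `FDA_DT` does
#' not parse as an 8-digit `YYYYMMDD` integer, or whose `PRIMARYID`/`CASEID`
#' is non-numeric, are excluded and counted, never silently dropped. A
#' missing mandatory column is a hard failure naming the file and column.
#'
#' @param dir directory containing quarterly files (used when `paths` is
#'   `NULL`)
#' @param paths optional named list with elements `demo`, `drug`, `reac`,
#'   `outc`, each a character vector of file paths
#' @return a `faers_raw` object: data.tables `demo`, `drug`, `reac`, `outc`
#'   plus an `exclusions` counter list
#' @export
read_faers_tables <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    lf <- function(p) sort(list.files(dir, pattern = p, full.names = TRUE))
    paths <- list(demo = lf("^DEMO"), drug = lf("^DRUG"),
                  reac = lf("^REAC"), outc = lf("^OUTC"))
  }
  if (!length(paths$demo)) stopf("no DEMO files found")
  read_one <- function(files, mandatory) {
    rbindlist(lapply(files, function(f) {
      dt <- fread(f, sep = "$", colClasses = "character", header = TRUE)
      miss <- setdiff(mandatory, names(dt))
      if (length(miss))
        stopf("file '%s' is missing mandatory column(s): %s", f,
              paste(miss, collapse = ", "))
      dt
    }), fill = TRUE)
  }
  demo <- read_one(paths$demo, DEMO_COLS)
  drug <- read_one(paths$drug, DRUG_COLS)
  reac <- read_one(paths$reac, REAC_COLS)
  outc <- if (length(paths$outc))
    read_one(paths$outc, c("PRIMARYID", "OUTC_COD")) else
    data.table(PRIMARYID = character(), OUTC_COD = character())

  excl <- list(bad_fda_dt = 0L, bad_id = 0L)
  fda <- suppressWarnings(as.integer(demo$FDA_DT))
  ok_dt <- !is.na(fda) & nchar(demo$FDA_DT) == 8L
  excl$bad_fda_dt <- sum(!ok_dt)
  pid <- suppressWarnings(as.numeric(demo$PRIMARYID))
  cid <- suppressWarnings(as.numeric(demo$CASEID))
  ok_id <- !is.na(pid) & !is.na(cid)
  excl$bad_id <- sum(ok_dt & !ok_id)
  keep <- ok_dt & ok_id
  demo <- demo[keep]
  demo[, `:=`(PRIMARYID = as.numeric(PRIMARYID), CASEID = as.numeric(CASEID),
              FDA_DT = as.integer(FDA_DT))]
  if ("AGE" %in% names(demo))
    demo[, AGE := suppressWarnings(as.numeric(AGE))]
  drug[, PRIMARYID := suppressWarnings(as.numeric(PRIMARYID))]
  reac[, PRIMARYID := suppressWarnings(as.numeric(PRIMARYID))]
  outc[, PRIMARYID := suppressWarnings(as.numeric(PRIMARYID))]
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 exclusions = excl, deduplicated = FALSE),
            class = "faers_raw")
}

#' Deduplicate spontaneous reports by case
#'
#' Keeps exactly one report per `CASEID`: among rows sharing a `CASEID` the
#' latest `FDA_DT` wins; when `FDA_DT` ties, the highest `PRIMARYID` is
#' retained. Drug, reaction and outcome rows of discarded versions are
#' dropped with them. The operation is idempotent and its output is sorted
#' by `CASEID`.
#'
#' @param raw a `faers_raw` object (or an already deduplicated one)
#' @return a `faers_raw` object with `deduplicated = TRUE`
#' @export
deduplicate_reports <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$demo
  if (nrow(demo)) {
    demo <- demo[order(CASEID, FDA_DT, PRIMARYID)]
    demo <- demo[, .SD[.N], by = CASEID]
    setcolorder(demo, intersect(names(raw$demo), names(demo)))
    demo <- demo[order(CASEID)]
  }
  keep <- demo$PRIMARYID
  structure(list(demo = demo,
                 drug = raw$drug[PRIMARYID %in% keep],
                 reac = raw$reac[PRIMARYID %in% keep],
                 outc = raw$outc[PRIMARYID %in% keep],
                 exclusions = raw$exclusions, deduplicated = TRUE),
            class = "faers_raw")
}

#' Match drug name strings against search terms
#'
#' Case-insensitive substring match: `TRUE` where any term occurs anywhere
#' in the string (so `"REPATHA (EVOLOCUMAB)"` matches both `"repatha"` and
#' `"evolocumab"`).
#'
#' @param x character vector of drug name / active-ingredient strings
#' @param terms non-empty character vector of search terms
#' @return logical vector along `x`
#' @export
match_drug <- function(x, terms) {
  if (!length(terms)) stopf("drug search terms must be non-empty")
  xl <- tolower(x)
  hit <- rep(FALSE, length(xl))
  for (t in tolower(terms)) hit <- hit | grepl(t, xl, fixed = TRUE)
  hit
}

#' Match reaction PT strings against an event list
#'
#' Case-insensitive *exact* PT match (PTs are controlled vocabulary, so
#' substring matching would over-capture). Each occurrence matches
#' independently: a report listing two target PTs contributes two matched
#' events.
#'
#' @param pts character vector of PT strings
#' @param event_pts character vector of target PTs
#' @return logical vector along `pts`
#' @export
match_event <- function(pts, event_pts) {
  tolower(pts) %in% tolower(event_pts)
}

# PRIMARYIDs whose drug rows match `terms` (optionally restricted to roles)
matched_report_ids <- function(raw, terms, roles = NULL) {
  drug <- raw$drug
  if (!is.null(roles) && "ROLE_COD" %in% names(drug))
    drug <- drug[ROLE_COD %in% roles]
  hit <- match_drug(drug$DRUGNAME, terms)
  if ("PROD_AI" %in% names(drug))
    hit <- hit | match_drug(drug$PROD_AI, terms)
  unique(drug$PRIMARYID[hit])
}

#' Cohort definition for contingency-table construction
#'
#' @param drug_terms target-drug search terms (default the seven
#'   PCSK9-inhibitor brand/generic terms)
#' @param event_pts target event PTs (default the nine memory-loss PTs)
#' @param background `"full"` (whole database) or `"lipid_lowering"`
#'   (universe restricted to reports matching `lipid_lowering_terms`)
#' @param lipid_lowering_terms match strings defining the within-class
#'   background; required when `background = "lipid_lowering"` and must
#'   contain the target universe
#' @param unit counting unit: `"event"` (each matched PT occurrence is one
#'   count; the default) or `"report"` (each report counts once)
#' @param roles optional drug role codes to count (e.g. `c("PS", "SS")`);
#'   `NULL` counts all roles
#' @param label cohort label carried into results
#' @return a `cohort_definition` list
#' @export
cohort_definition <- function(drug_terms = pcsk9_terms(),
                              event_pts = memory_loss_pts(),
                              background = c("full", "lipid_lowering"),
                              lipid_lowering_terms = signalmr::lipid_lowering_terms(),
                              unit = c("event", "report"),
                              roles = NULL,
                              label = "target cohort") {
  background <- match.arg(background)
  unit <- match.arg(unit)
  if (!length(drug_terms) || !length(event_pts))
    stopf("drug_terms and event_pts must be non-empty")
  if (background == "lipid_lowering" && !length(lipid_lowering_terms))
    stopf("lipid_lowering_terms required for the lipid_lowering background")
  structure(list(drug_terms = drug_terms, event_pts = event_pts,
                 background = background,
                 lipid_lowering_terms = lipid_lowering_terms,
                 unit = unit, roles = roles, label = label),
            class = "cohort_definition")
}

#' Build the 2x2 contingency table for a cohort
#'
#' Cross-classifies the counting units of the reporting universe by target
#' drug (rows) and target event (columns). At the default event-level unit,
#' each reaction row of the universe is one unit (mirroring databases that
#' report more adverse events than patients); at the report level each
#' report counts once, with "event" meaning at least one matched PT. Under
#' the `lipid_lowering` background the universe is first restricted to
#' reports matching the class term list; the target cohort must be a subset
#' of that universe.
#'
#' @param raw a deduplicated `faers_raw` object
#' @param cohort a [cohort_definition()]
#' @return a [contingency_table()]
#' @export
build_contingency <- function(raw, cohort) {
  stopifnot(inherits(raw, "faers_raw"), inherits(cohort, "cohort_definition"))
  if (!isTRUE(raw$deduplicated))
    warnf("building a contingency table from non-deduplicated reports")
  target_ids <- matched_report_ids(raw, cohort$drug_terms, cohort$roles)
  universe_ids <- raw$demo$PRIMARYID
  if (cohort$background == "lipid_lowering") {
    class_ids <- matched_report_ids(raw, cohort$lipid_lowering_terms,
                                    cohort$roles)
    if (length(setdiff(target_ids, class_ids)))
      stopf("target cohort is not a subset of the lipid-lowering universe; extend lipid_lowering_terms")
    universe_ids <- intersect(universe_ids, class_ids)
  }
  reac <- raw$reac[PRIMARYID %in% universe_ids]
  if (!nrow(reac)) stopf("reporting universe has no reaction rows")
  is_target_drug <- reac$PRIMARYID %in% target_ids
  is_target_event <- match_event(reac$PT, cohort$event_pts)
  if (cohort$unit == "event") {
    a <- sum(is_target_drug & is_target_event)
    b <- sum(is_target_drug & !is_target_event)
    c_ <- sum(!is_target_drug & is_target_event)
    d <- sum(!is_target_drug & !is_target_event)
  } else {
    rep_ev <- reac[, .(hit = any(match_event(PT, cohort$event_pts))),
                   by = PRIMARYID]
    tgt <- rep_ev$PRIMARYID %in% target_ids
    a <- sum(tgt & rep_ev$hit)
    b <- sum(tgt & !rep_ev$hit)
    c_ <- sum(!tgt & rep_ev$hit)
    d <- sum(!tgt & !rep_ev$hit)
    # reports with no reaction rows cannot occur: reac is keyed on reports
  }
  contingency_table(a, b, c_, d,
                    label = sprintf("%s [%s background, %s-level]",
                                    cohort$label, cohort$background,
                                    cohort$unit))
}

# AGE + AGE_COD -> years (FAERS unit codes)
age_in_years <- function(age, cod) {
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143, DY = 1 / 365.25,
            HR = 1 / 8766)
  m <- mult[toupper(cod)]
  m[is.na(m) & !is.na(age)] <- 1  # blank/unknown unit: assume years
  unname(age * m)
}

#' Split a deduplicated dataset into gender or age strata
#'
#' Gender strata are `male`, `female` and `missing`. Age strata follow the
#' adult convention `18-64`, `>=65` plus `missing`; subjects younger than
#' 18 form their own `<18` stratum so that the non-missing universe is
#' partitioned.
#'
#' @param raw deduplicated `faers_raw`
#' @param by `"gender"` or `"age"`
#' @return named list of `faers_raw` subsets
#' @export
stratify_reports <- function(raw, by = c("gender", "age")) {
  by <- match.arg(by)
  demo <- raw$demo
  if (by == "gender") {
    sx <- toupper(demo$SEX %||% rep("", nrow(demo)))
    stratum <- ifelse(sx == "M", "male", ifelse(sx == "F", "female", "missing"))
  } else {
    yrs <- age_in_years(demo$AGE, demo$AGE_COD %||% rep("YR", nrow(demo)))
    stratum <- ifelse(is.na(yrs), "missing",
                      ifelse(yrs < 18, "<18",
                             ifelse(yrs < 65, "18-64", ">=65")))
  }
  out <- lapply(split(demo$PRIMARYID, stratum), function(pids) {
    structure(list(demo = demo[PRIMARYID %in% pids],
                   drug = raw$drug[PRIMARYID %in% pids],
                   reac = raw$reac[PRIMARYID %in% pids],
                   outc = raw$outc[PRIMARYID %in% pids],
                   exclusions = raw$exclusions,
                   deduplicated = raw$deduplicated),
              class = "faers_raw")
  })
  out
}
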