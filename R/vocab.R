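#' Default search-term vocabularies
#'
#' Term lists used throughout the pipeline. `pcsk9_terms()` returns the seven
#' brand/generic search strings that define the PCSK9-inhibitor target-drug
#' cohort. `memory_loss_pts()` returns the nine MedDRA preferred terms (PTs)
#' that make up the composite memory-loss event. `lipid_lowering_terms()`
#' returns an editable generic-name list standing in for ATC class C10
#' (lipid-modifying agents): FAERS rows carry no ATC codes, so the
#' within-class reporting background is defined by name matching against this
#' list, which contains the PCSK9 terms as a subset.
#'
#' @return character vector of lower-case match strings (PT strings keep
#'   their conventional capitalisation; all matching is case-insensitive)
#' @export
pcsk9_terms <- function() {
  c("inclisiran", "alirocumab", "evolocumab", "pcsk9",
    "praluent", "leqvio", "repatha")
}

#' @rdname pcsk9_terms
#' @export
memory_loss_pts <- function() {
  c("Memory impairment", "Amnesia", "Amnestic disorder",
    "Anterograde amnesia", "Korsakoff's syndrome",
    "Post-traumatic memory disorder", "Retrograde amnesia",
    "Transient global amnesia", "Wernicke-Korsakoff syndrome")
}

#' @rdname pcsk9_terms
#' @export
lipid_lowering_terms <- function() {
  c(pcsk9_terms(),
    # statins
    "atorvastatin", "simvastatin", "rosuvastatin", "pravastatin",
    "lovastatin", "fluvastatin", "pitavastatin",
    "lipitor", "crestor", "zocor",
    # other C10 agents
    "ezetimibe", "zetia", "fenofibrate", "gemfibrozil", "bempedoic",
    "nexletol", "icosapent", "vascepa", "niacin", "colesevelam",
    "cholestyramine", "lomitapide", "evinacumab")
}

# default generator vocabulary: each element is one drug "family" whose
# strings are co-reported aliases of the same product (brand/generic rows of
# a single report), so family membership is the report-level ground truth
default_drug_vocabulary <- function() {
  list(
    alirocumab   = c("ALIROCUMAB", "PRALUENT", "PRALUENT (ALIROCUMAB)"),
    evolocumab   = c("EVOLOCUMAB", "REPATHA", "REPATHA (EVOLOCUMAB)"),
    inclisiran   = c("INCLISIRAN", "LEQVIO", "LEQVIO (INCLISIRAN)"),
    pcsk9_other  = c("PCSK9 INHIBITOR NOS"),
    atorvastatin = c("ATORVASTATIN", "LIPITOR"),
    simvastatin  = c("SIMVASTATIN", "ZOCOR"),
    rosuvastatin = c("ROSUVASTATIN", "CRESTOR"),
    ezetimibe    = c("EZETIMIBE", "ZETIA"),
    fenofibrate  = c("FENOFIBRATE"),
    metformin    = c("METFORMIN", "GLUCOPHAGE"),
    lisinopril   = c("LISINOPRIL"),
    omeprazole   = c("OMEPRAZOLE", "PRILOSEC"),
    sertraline   = c("SERTRALINE", "ZOLOFT"),
    adalimumab   = c("ADALIMUMAB", "HUMIRA"),
    warfarin     = c("WARFARIN", "COUMADIN")
  )
}

# default generator event vocabulary: the nine memory-loss PTs plus common
# background PTs
default_event_vocabulary <- function() {
  c(memory_loss_pts(),
    "Nausea", "Headache", "Dizziness", "Fatigue", "Myalgia", "Arthralgia",
    "Injection site pain", "Diarrhoea", "Rash", "Pruritus", "Dyspnoea",
    "Insomnia", "Vomiting", "Pain in extremity", "Influenza like illness",
    "Drug ineffective", "Hypertension", "Cough", "Constipation",
    "Muscle spasms", "Back pain", "Abdominal pain", "Pyrexia", "Asthenia",
    "Malaise", "Chest pain", "Oedema peripheral", "Anxiety", "Tremor",
    "Vision blurred", "Alopecia")
}
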