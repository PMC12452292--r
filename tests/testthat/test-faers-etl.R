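# Reader, deduplication, matching, contingency construction, stratification.

test_that("reader returns one record per row on clean input and counts malformed rows", {
  dir <- withr::local_tempdir()
  n <- 1000
  demo <- sprintf("%d$%d$2024%02d%02d$65$YR$F$CN$US", 1000 + 1:n, 2000 + 1:n,
                  rep(1:3, length.out = n), rep(1:28, length.out = n))
  drug <- sprintf("%d$1$PS$ASPIRIN$ASPIRIN", 1000 + 1:n)
  reac <- sprintf("%d$Nausea", 1000 + 1:n)
  write_mini_faers(dir, demo, drug, reac)
  raw <- read_faers_tables(dir)
  expect_equal(nrow(raw$demo), n)
  expect_equal(raw$exclusions$bad_fda_dt, 0L)

  # one corrupted FDA_DT: excluded, counter incremented by exactly 1
  dir2 <- withr::local_tempdir()
  demo2 <- demo
  demo2[17] <- sub("2024", "20XX", demo2[17])
  write_mini_faers(dir2, demo2, drug, reac)
  raw2 <- read_faers_tables(dir2)
  expect_equal(nrow(raw2$demo), n - 1L)
  expect_equal(raw2$exclusions$bad_fda_dt, 1L)
})

test_that("a missing mandatory column fails hard, naming file and column", {
  dir <- withr::local_tempdir()
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("PRIMARYID$CASEID", "1$2"), file.path(dir, "DEMO_2024Q1.txt"))
  writeLines("PRIMARYID$DRUG_SEQ$ROLE_COD$DRUGNAME$PROD_AI",
             file.path(dir, "DRUG_2024Q1.txt"))
  writeLines("PRIMARYID$PT", file.path(dir, "REAC_2024Q1.txt"))
  expect_error(read_faers_tables(dir), "FDA_DT")
  expect_error(read_faers_tables(dir), "DEMO_2024Q1")
})

test_that("deduplication keeps latest FDA_DT, then highest PRIMARYID, and is idempotent", {
  dir <- withr::local_tempdir()
  write_mini_faers(dir, c(
    "101$500$20240101$60$YR$F$CN$US",   # same case, earlier receipt
    "102$500$20240301$60$YR$F$CN$US",   # -> kept (latest FDA_DT)
    "100$501$20240501$70$YR$M$CN$US",   # same case + date, lower PRIMARYID
    "200$501$20240501$70$YR$M$CN$US",   # -> kept (highest PRIMARYID)
    "300$502$20240601$50$YR$F$CN$US"),
    drug_rows = sprintf("%d$1$PS$ASPIRIN$ASPIRIN", c(101, 102, 100, 200, 300)),
    reac_rows = sprintf("%d$Nausea", c(101, 102, 100, 200, 300)))
  raw <- read_faers_tables(dir)
  ded <- deduplicate_reports(raw)
  expect_equal(sort(ded$demo$PRIMARYID), c(102, 200, 300))
  expect_equal(ded$demo$CASEID, c(500, 501, 502))  # sorted by case
  # drug/reaction rows of discarded versions dropped with them
  expect_setequal(ded$drug$PRIMARYID, c(102, 200, 300))
  # idempotent
  expect_identical(deduplicate_reports(ded)$demo, ded$demo)
})

test_that("deduplication leaves distinct cases unchanged up to ordering", {
  dir <- withr::local_tempdir()
  write_mini_faers(dir,
    sprintf("%d$%d$20240101$60$YR$F$CN$US", 5:1 * 10, 5:1),
    reac_rows = sprintf("%d$Nausea", 5:1 * 10))
  ded <- deduplicate_reports(read_faers_tables(dir))
  expect_equal(ded$demo$CASEID, 1:5)
  expect_equal(nrow(ded$demo), 5L)
})

test_that("drug matching is case-insensitive substring; event matching is exact PT", {
  expect_true(match_drug("REPATHA (EVOLOCUMAB)", pcsk9_terms()))
  expect_false(match_drug("atorvastatin", pcsk9_terms()))
  expect_true(match_drug("Pcsk9 Inhibitor NOS", pcsk9_terms()))
  expect_equal(match_drug(c("LEQVIO", "WARFARIN"), pcsk9_terms()),
               c(TRUE, FALSE))

  expect_equal(match_event(c("Memory impairment", "Amnesia"),
                           memory_loss_pts()), c(TRUE, TRUE))
  expect_false(match_event("Dizziness", memory_loss_pts()))
  expect_true(match_event("MEMORY IMPAIRMENT", memory_loss_pts()))
  # exact PT match: no substring over-capture
  expect_false(match_event("Memory impairment aggravated somehow",
                           memory_loss_pts()))
})

make_cohort_fixture <- function() {
  dir <- tempfile("faers")
  # 2 target reports (one with 2 matched PTs), 2 statin reports, 2 others
  write_mini_faers(dir, c(
    "11$1$20240101$70$YR$F$CN$US",
    "12$2$20240102$50$YR$M$CN$US",
    "13$3$20240103$66$YR$F$CN$US",
    "14$4$20240104$$$$CN$US",
    "15$5$20240105$17$YR$M$CN$US",
    "16$6$20240106$80$YR$F$CN$US"),
    drug_rows = c("11$1$PS$REPATHA$EVOLOCUMAB",
                  "12$1$PS$PRALUENT$ALIROCUMAB",
                  "13$1$PS$ATORVASTATIN$ATORVASTATIN",
                  "14$1$PS$LIPITOR$ATORVASTATIN",
                  "15$1$PS$METFORMIN$METFORMIN",
                  "16$1$PS$WARFARIN$WARFARIN"),
    reac_rows = c("11$Memory impairment", "11$Amnesia", "12$Nausea",
                  "13$Memory impairment", "14$Headache", "15$Nausea",
                  "16$Amnesia"))
  deduplicate_reports(read_faers_tables(dir))
}

test_that("contingency cells sum to the universe and respect the background", {
  ded <- make_cohort_fixture()
  tb_full <- build_contingency(ded, cohort_definition())
  # event level: 7 reaction rows in the universe
  expect_equal(tb_full$a + tb_full$b + tb_full$c + tb_full$d, 7)
  expect_equal(tb_full$a, 2)  # two matched PTs on report 11
  expect_equal(tb_full$b, 1)  # report 12's Nausea
  expect_equal(tb_full$c, 2)  # statin memory + warfarin amnesia

  tb_class <- build_contingency(ded,
                                cohort_definition(background = "lipid_lowering"))
  # class universe: reports 11-14 only (5 reaction rows)
  expect_equal(tb_class$n, 5)
  expect_equal(tb_class$a, tb_full$a)        # target cells identical
  expect_gte(tb_full$d, tb_class$d)          # background shrinks

  tb_rep <- build_contingency(ded, cohort_definition(unit = "report"))
  expect_equal(tb_rep$n, 6)
  expect_equal(tb_rep$a, 1)
})

test_that("contingency counts are invariant under input-order permutation", {
  ded <- make_cohort_fixture()
  perm <- ded
  set.seed(1)
  perm$demo <- perm$demo[sample(.N)]
  perm$reac <- perm$reac[sample(.N)]
  perm$drug <- perm$drug[sample(.N)]
  t1 <- build_contingency(ded, cohort_definition())
  t2 <- build_contingency(perm, cohort_definition())
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(t2$a, t2$b, t2$c, t2$d))
})

test_that("a target cohort outside the class universe is rejected", {
  ded <- make_cohort_fixture()
  expect_error(
    build_contingency(ded, cohort_definition(
      drug_terms = "warfarin", background = "lipid_lowering")),
    "subset")
})

test_that("stratification partitions by gender and by the adult age bounds", {
  ded <- make_cohort_fixture()
  g <- stratify_reports(ded, "gender")
  expect_equal(sort(names(g)), c("female", "male", "missing"))
  expect_equal(nrow(g$missing$demo), 1L)
  expect_equal(sum(vapply(g, function(s) nrow(s$demo), integer(1))), 6L)

  a <- stratify_reports(ded, "age")
  # ages 70, 50, 66, missing, 17, 80
  expect_equal(nrow(a$`18-64`$demo), 1L)
  expect_equal(nrow(a$`>=65`$demo), 3L)   # 66 and 80 and 70; 65 boundary below
  expect_equal(nrow(a$missing$demo), 1L)
  expect_equal(nrow(a$`<18`$demo), 1L)    # age 17 excluded from adult strata

  # boundary: exactly 65 belongs to the >=65 stratum
  dir <- withr::local_tempdir()
  write_mini_faers(dir, "1$1$20240101$65$YR$F$CN$US",
                   reac_rows = "1$Nausea")
  a65 <- stratify_reports(deduplicate_reports(read_faers_tables(dir)), "age")
  expect_equal(names(a65), ">=65")
})
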