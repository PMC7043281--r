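cfg <- phenotype_config()

test_that("persistent ALT elevation needs two qualifying values > 183 days apart", {
  mk <- function(dates, values, setting = "ambulatory")
    data.frame(patient_id = "p", date = as.Date(dates), test_name = "ALT",
               value_text = "", value_num = values, ref_low = 7,
               ref_high = 40, setting = setting, stringsAsFactors = FALSE)
  d0 <- as.Date("2014-01-01")
  r <- persistent_alt_elevation(mk(c(d0, d0 + 200), c(45, 50)), "M", cfg)
  expect_true(r$met)
  expect_identical(r$date, d0 + 200)
  # gap of 90 days fails; 183 exactly fails ("more than 6 months")
  expect_false(persistent_alt_elevation(mk(c(d0, d0 + 90),
                                           c(45, 50)), "M", cfg)$met)
  expect_false(persistent_alt_elevation(mk(c(d0, d0 + 183),
                                           c(45, 50)), "M", cfg)$met)
  expect_true(persistent_alt_elevation(mk(c(d0, d0 + 184),
                                          c(45, 50)), "M", cfg)$met)
  # female threshold 31 applies
  expect_true(persistent_alt_elevation(mk(c(d0, d0 + 400),
                                          c(35, 33)), "F", cfg)$met)
  expect_false(persistent_alt_elevation(mk(c(d0, d0 + 400),
                                           c(35, 33)), "M", cfg)$met)
  # a single extreme value is not persistent elevation
  expect_false(persistent_alt_elevation(mk(d0, 300), "M", cfg)$met)
  # inpatient measurements do not count
  expect_false(persistent_alt_elevation(mk(c(d0, d0 + 200), c(45, 50),
                                           setting = "inpatient"),
                                        "M", cfg)$met)
  # unknown sex: male threshold with a trace note
  r <- persistent_alt_elevation(mk(c(d0, d0 + 200), c(35, 33)), NA, cfg)
  expect_false(r$met)
  expect_match(r$note, "male")
  # qualifying date is the earliest day the rule is satisfied
  r <- persistent_alt_elevation(mk(c(d0, d0 + 250, d0 + 500),
                                   c(45, 50, 60)), "M", cfg)
  expect_identical(r$date, d0 + 250)
})

test_that("inclusion codes match the chronic non-alcoholic liver disease set", {
  mk <- function(system, code)
    data.frame(patient_id = "p", date = as.Date("2016-04-01"),
               system = system, code = code, setting = "ambulatory",
               stringsAsFactors = FALSE)
  r <- has_liver_disease_code(mk("ICD9", "571.8"), cfg)
  expect_true(r$met)
  expect_identical(r$date, as.Date("2016-04-01"))
  expect_true(has_liver_disease_code(mk("ICD10", "K76.9"), cfg)$met)
  expect_false(has_liver_disease_code(mk("ICD9", "571.2"), cfg)$met)
})

test_that("exclusion screen catches codes, viral labs and steatogenic drugs", {
  b <- phenotype_fixture()
  sl <- function(id) lapply(b, function(t)
    t[t$patient_id == id, , drop = FALSE])
  d <- sl("D")
  r <- is_excluded(d$code_events, d$lab_results, d$med_orders, cfg)
  expect_true(r$excluded)
  expect_match(r$reasons, "HCV RNA")
  e <- sl("E")
  r <- is_excluded(e$code_events, e$lab_results, e$med_orders, cfg)
  expect_true(r$excluded)
  expect_match(r$reasons, "amiodarone")
  a <- sl("A")
  r <- is_excluded(a$code_events, a$lab_results, a$med_orders, cfg)
  expect_false(r$excluded)
  expect_length(r$reasons, 0)
})

test_that("hand-built rule-branch fixture yields the hand-derived decisions", {
  dec <- classify_cohort(phenotype_fixture(), cfg)
  truth <- phenotype_fixture_truth()
  expect_identical(dec$patient_id, truth$patient_id)
  expect_identical(dec$eligible, truth$eligible)
  expect_identical(dec$nafld_date, truth$nafld_date)
})

test_that("NAFLD date is the latest earliest-satisfaction date and must fall in the window", {
  b <- empty_bundle()
  b <- add_patient(b, "W", sex = "M")
  b <- add_alt(b, "W", "2013-06-01", 45)
  b <- add_alt(b, "W", "2014-02-01", 50)
  b <- add_doc(b, "W", "2015-06-01", "Ultrasound shows hepatic steatosis.")
  d <- decide_patient(lapply(b, function(t)
    t[t$patient_id == "W", , drop = FALSE]), cfg)
  expect_true(d$eligible)
  expect_identical(d$nafld_date, as.Date("2015-06-01"))

  # all criteria satisfied before the window start -> ineligible
  b2 <- empty_bundle()
  b2 <- add_patient(b2, "V", sex = "M")
  b2 <- add_alt(b2, "V", "2011-01-01", 45)
  b2 <- add_alt(b2, "V", "2011-09-01", 50)
  b2 <- add_doc(b2, "V", "2012-11-30", "Biopsy shows steatosis.")
  d2 <- decide_patient(lapply(b2, function(t)
    t[t$patient_id == "V", , drop = FALSE]), cfg)
  expect_false(d2$eligible)
  expect_true("in_window" %in% d2$failed_rules)
})

test_that("decisions are monotone under added exclusions and invariant to row order", {
  b <- phenotype_fixture()
  dec <- classify_cohort(b, cfg)
  expect_true(dec$eligible[dec$patient_id == "A"])
  # adding an exclusion trigger can only remove eligibility
  b_ex <- add_med(add_med(b, "A", "2013-01-01", "methotrexate"),
                  "A", "2013-08-01", "methotrexate")
  dec_ex <- classify_cohort(b_ex, cfg)
  expect_false(dec_ex$eligible[dec_ex$patient_id == "A"])
  expect_true(all(dec_ex$eligible[dec_ex$patient_id != "A"] ==
                    dec$eligible[dec$patient_id != "A"]))
  # permuting event rows leaves every decision and date unchanged
  set.seed(3)
  b_perm <- b
  for (nm in names(b_perm))
    b_perm[[nm]] <- b_perm[[nm]][sample(nrow(b_perm[[nm]])), , drop = FALSE]
  dec_perm <- classify_cohort(b_perm, cfg)
  o <- match(dec$patient_id, dec_perm$patient_id)
  expect_identical(dec$eligible, dec_perm$eligible[o])
  expect_identical(dec$nafld_date, dec_perm$nafld_date[o])
  # adding or removing a non-triggering event does not change decisions
  b_rm <- add_lab(b, "A", "2014-03-01", "creatinine", num = 0.9,
                  low = 0.6, high = 1.2)
  dec_add <- classify_cohort(b_rm, cfg)
  expect_identical(dec_add$eligible, dec$eligible)
  expect_identical(dec_add$nafld_date, dec$nafld_date)
})

test_that("empty bundles and zero-mention cohorts classify cleanly", {
  expect_identical(nrow(classify_cohort(empty_bundle(), cfg)), 0L)
  sim <- generate_cohort(cohort_config(
    60, seed = 5,
    subtype_specs = lapply(noise_specs(2), function(s) {
      s$note_mention_profile <- c(positive = 0, negated = 0.5,
                                  family = 0, absent = 0.5)
      s$mixing_proportion <- 0.5
      s
    })))
  dec <- classify_cohort(sim$bundle, cfg)
  expect_identical(sum(dec$eligible), 0L)
})

test_that("require_both switch demands ALT and inclusion code jointly", {
  b <- phenotype_fixture()   # A has ALT but no inclusion code
  cfg_and <- phenotype_config(require_both = TRUE)
  dec <- classify_cohort(b, cfg_and)
  expect_false(dec$eligible[dec$patient_id == "A"])
  b2 <- add_code(b, "A", "2014-03-01", "ICD10", "K76.0")
  dec2 <- classify_cohort(b2, cfg_and)
  expect_true(dec2$eligible[dec2$patient_id == "A"])
})
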