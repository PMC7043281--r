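maps <- mapping_tables()

test_that("age bins are mutually exclusive and follow the published cut points", {
  m <- age_bin_features(c(53, 20, 105, 18, 30, 31, 100.5))
  expect_true(all(rowSums(m) == 1))
  expect_identical(colnames(m)[apply(m, 1, which.max)],
                   c("age_51_60", "age_18_20", "age_101_plus",
                     "age_18_20", "age_21_30", "age_31_40",
                     "age_91_100"))
  expect_error(age_bin_features(17), "18")
})

test_that("phecode features respect the 0.1% prevalence floor", {
  patients <- sprintf("q%04d", 1:1000)
  ev <- data.frame(patient_id = "q0001", date = as.Date("2015-01-01"),
                   system = "ICD10", code = "E11.9",
                   setting = "ambulatory", stringsAsFactors = FALSE)
  m <- phecode_features(ev, patients, maps)
  # 1/1000 = exactly 0.1%: "at least" keeps it
  expect_identical(colnames(m), "phecode_250.2")
  # below the floor at 1/1001 patients: dropped
  m2 <- phecode_features(ev, c(patients, "q1001"), maps)
  expect_identical(ncol(m2), 0L)
  # two ICD codes mapping to the same phecode yield a single 1
  ev3 <- rbind(ev, data.frame(patient_id = "q0001",
                              date = as.Date("2015-02-01"),
                              system = "ICD9", code = "250.00",
                              setting = "ambulatory"))
  m3 <- phecode_features(ev3, patients, maps)
  expect_identical(sum(m3), 1L)
  # unmapped codes are logged, not fatal
  ev4 <- rbind(ev, data.frame(patient_id = "q0002",
                              date = as.Date("2015-02-01"),
                              system = "ICD10", code = "Z99.99",
                              setting = "ambulatory"))
  m4 <- phecode_features(ev4, patients, maps)
  expect_identical(attr(m4, "unmapped"), "ICD10 Z99.99")
})

test_that("CPT events map to their second-level range groups", {
  mk <- function(code) data.frame(patient_id = "p1",
                                  date = as.Date("2015-01-01"),
                                  system = "CPT", code = code,
                                  setting = "inpatient",
                                  stringsAsFactors = FALSE)
  m <- cpt_group_features(mk("35001"), "p1", maps)
  expect_identical(colnames(m), "cpt_Surgery-Cardiovascular")
  m2 <- cpt_group_features(mk("33009"), "p1", maps)
  expect_false("cpt_Surgery-Cardiovascular" %in% colnames(m2))
  expect_identical(attr(m2, "ungrouped"), "33009")
  m3 <- cpt_group_features(mk("99999")[0, ], "p1", maps)
  expect_identical(ncol(m3), 0L)
})

test_that("medication features require two orders at least six months apart", {
  patients <- c("p1", "p2", "p3")
  mk <- function(id, dates, drug)
    data.frame(patient_id = id, date = as.Date(dates), drug_name = drug,
               stringsAsFactors = FALSE)
  d0 <- as.Date("2015-01-01")
  orders <- rbind(mk("p1", c(d0, d0 + 200), "metformin"),
                  mk("p2", c(d0, d0 + 30), "oxycodone"),
                  mk("p3", c(d0, d0 + 200), c("Lipitor", "atorvastatin")))
  m <- medication_features(orders, patients, maps, min_prevalence = 0)
  expect_identical(m["p1", "med_metformin"], 1L)
  expect_false("med_oxycodone" %in% colnames(m))
  # brand and generic map to one ingredient before the persistence rule
  expect_identical(m["p3", "med_atorvastatin"], 1L)
  # boundary: exactly 183 days apart satisfies "6 months or more"
  m2 <- medication_features(mk("p1", c(d0, d0 + 183), "aspirin"),
                            patients, maps, min_prevalence = 0)
  expect_identical(m2["p1", "med_aspirin"], 1L)
  m3 <- medication_features(mk("p1", c(d0, d0 + 182), "aspirin"),
                            patients, maps, min_prevalence = 0)
  expect_false("med_aspirin" %in% colnames(m3))
})

test_that("lab abnormality uses qualitative terms and strict range bounds", {
  patients <- c("p1", "p2", "p3", "p4")
  mk <- function(id, test, text = "", num = NA, low = NA, high = NA)
    data.frame(patient_id = id, date = as.Date("2015-01-01"),
               test_name = test, value_text = text, value_num = num,
               ref_low = low, ref_high = high, setting = "ambulatory",
               stringsAsFactors = FALSE)
  labs <- rbind(
    mk("p1", "platelets", num = 120, low = 150, high = 400),
    mk("p2", "HBV surface antigen", text = "reactive"),
    mk("p3", "platelets", num = 150, low = 150, high = 400),  # boundary
    mk("p4", "platelets", num = 200, low = 150, high = 400))
  m <- lab_abnormal_features(labs, patients, maps)
  expect_identical(m["p1", "lab_platelets"], 1L)
  expect_identical(m["p2", "lab_HBV_surface_antigen"], 1L)
  expect_identical(m["p3", "lab_platelets"], 0L)
  expect_identical(m["p4", "lab_platelets"], 0L)
  # reference map fills missing row ranges
  m2 <- lab_abnormal_features(mk("p1", "ALT", num = 90), patients, maps)
  expect_identical(m2["p1", "lab_ALT"], 1L)
  # numeric result with no range anywhere: omitted and logged
  m3 <- lab_abnormal_features(mk("p1", "mystery assay", num = 5),
                              patients, maps)
  expect_identical(attr(m3, "omitted"), "mystery assay")
  expect_identical(ncol(m3), 0L)
})

test_that("vital flags implement the published thresholds", {
  patients <- "p1"
  mk <- function(kind, value, unit)
    data.frame(patient_id = "p1", date = as.Date("2015-01-01"),
               kind = kind, value = value, unit = unit,
               stringsAsFactors = FALSE)
  flag <- function(v) {
    m <- vital_abnormal_features(v, patients)
    colnames(m)[m[1, ] == 1]
  }
  expect_identical(flag(mk("temperature", 102.5, "F")), "vital_temperature")
  expect_identical(flag(mk("temperature", 101, "F")), character(0))
  expect_identical(flag(mk("temperature", 39.5, "C")), "vital_temperature")
  # BP 128/85 abnormal through the diastolic arm
  expect_identical(flag(rbind(mk("sbp", 128, "mmHg"),
                              mk("dbp", 85, "mmHg"))), "vital_bp")
  expect_identical(flag(rbind(mk("sbp", 130, "mmHg"),
                              mk("dbp", 80, "mmHg"))), character(0))
  expect_identical(flag(mk("pain", 8, "score")), character(0))
  expect_identical(flag(mk("pain", 9, "score")), "vital_pain")
  expect_identical(flag(mk("heart_rate", 131, "bpm")), "vital_heart_rate")
  expect_identical(flag(mk("respiratory_rate", 41, "bpm")),
                   "vital_respiratory_rate")
})

test_that("assembled matrices are binary, deduplicated, idempotent and order-invariant", {
  res <- simulate_and_featurize(150, separated_specs(), seed = 21)
  fm <- res$fm
  expect_true(all(fm$values %in% 0:1))
  expect_false(anyDuplicated(fm$features$name) > 0)
  expect_identical(ncol(fm$values), nrow(fm$features))
  # prevalence-filtered domains respect the 0.1% floor; the fixed vital
  # block may legitimately contain unused flags
  filt <- fm$features$domain %in% c("diagnosis", "medication")
  expect_true(all(colMeans(fm$values[, filt, drop = FALSE]) >= 0.001))
  # idempotence
  fm2 <- build_feature_matrix(res$sim$bundle, res$decisions)
  expect_identical(fm$values, fm2$values)
  # permuting bundle rows leaves the matrix unchanged (rows keyed by id)
  set.seed(9)
  b <- res$sim$bundle
  for (nm in setdiff(names(b), "patients"))
    b[[nm]] <- b[[nm]][sample(nrow(b[[nm]])), , drop = FALSE]
  fm3 <- build_feature_matrix(b, res$decisions)
  expect_identical(fm$values, fm3$values)
})
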