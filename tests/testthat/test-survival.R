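test_that("outcome tables implement the 6-month prevalent rule and competing death", {
  b <- empty_bundle()
  mkpat <- function(id, death = NA) {
    b <<- add_patient(b, id, death = death)
    b <<- add_alt(b, id, "2014-01-01", 45)
    b <<- add_alt(b, id, "2014-07-20", 50)
    b <<- add_doc(b, id, "2014-08-01", "Ultrasound shows steatosis.")
  }
  mkpat("H")   # HCC evidence 60 days after diagnosis -> prevalent
  b <- add_code(b, "H", as.Date("2014-08-01") + 60, "ICD10", "C22.0")
  mkpat("K", death = as.Date("2014-08-01") + 700)  # CKD at 400, death 700
  b <- add_code(b, "K", as.Date("2014-08-01") + 400, "ICD10", "N18.3")
  mkpat("D2", death = as.Date("2014-08-01") + 300) # death only
  mkpat("C0") # no events -> administratively censored

  dec <- classify_cohort(b)
  expect_true(all(dec$eligible))
  tte <- build_outcome_table(b, dec)

  h <- tte[tte$patient_id == "H" & tte$outcome == "hcc", ]
  expect_true(h$prevalent)
  k <- tte[tte$patient_id == "K" & tte$outcome == "ckd", ]
  expect_false(k$prevalent)
  expect_identical(k$event, 1L)
  expect_equal(k$time, 400)
  kd <- tte[tte$patient_id == "K" & tte$outcome == "death", ]
  expect_identical(kd$event, 1L)
  expect_equal(kd$time, 700)
  # death before CKD: competing event code 2 at the death time
  d2 <- tte[tte$patient_id == "D2" & tte$outcome == "ckd", ]
  expect_identical(d2$event, 2L)
  expect_equal(d2$time, 300)
  c0 <- tte[tte$patient_id == "C0" & tte$outcome == "ckd", ]
  expect_identical(c0$event, 0L)
  expect_equal(c0$time,
               as.numeric(as.Date("2019-01-31") - as.Date("2014-08-01")))
})

test_that("ICD and CPT range matching follows the published code lists", {
  mk <- function(system, code)
    data.frame(patient_id = "p", date = as.Date("2016-01-01"),
               system = system, code = code, setting = "inpatient",
               stringsAsFactors = FALSE)
  docs <- data.frame(patient_id = character(), date = as.Date(character()),
                     doc_type = character(), text = character())
  defs <- outcome_definitions()
  evd <- function(def, codes)
    !is.na(nafldsubtypes:::outcome_evidence_date(def, codes, docs,
                                                 as.Date(NA)))
  expect_true(evd(defs$mi, mk("ICD10", "I21.4")))
  expect_true(evd(defs$mi, mk("ICD9", "410.71")))
  expect_false(evd(defs$mi, mk("ICD10", "I25.10")))
  expect_true(evd(defs$cvd, mk("ICD10", "I25.10")))
  expect_true(evd(defs$cvd, mk("ICD9", "414.01")))
  expect_false(evd(defs$cvd, mk("ICD10", "I26.0")))
  expect_true(evd(defs$ckd, mk("ICD9", "585.3")))
  expect_true(evd(defs$ckd, mk("CPT", "90940")))
  expect_false(evd(defs$ckd, mk("CPT", "90934")))
  expect_true(evd(defs$hcc, mk("ICD10", "C22.8")))
  expect_false(evd(defs$hcc, mk("ICD10", "C22.1")))
  expect_true(evd(defs$hcc, mk("ICD9", "155.0")))
})

test_that("Kaplan-Meier reproduces the hand product-limit computation", {
  # times {8 event, 5 censored, 12 event}: risk set at 8 is {8, 12}
  km <- kaplan_meier(c(8, 5, 12), c(1, 0, 1))
  expect_equal(km$surv[km$time == 8], 0.5)
  expect_equal(km$surv[km$time == 12], 0)
  # no events: survival stays at 1
  km2 <- kaplan_meier(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # all events, no censoring: complement of the ECDF
  tt <- c(1, 4, 2, 7, 5)
  km3 <- kaplan_meier(tt, rep(1, 5))
  expect_equal(km3$surv, 1 - ecdf(tt)(km3$time))
})

test_that("Aalen-Johansen CIFs match hand computation and conserve mass", {
  # {2 type1, 4 type2, 6 censored}: CIF1(inf)=1/3, CIF2(inf)=1/3
  cif <- cumulative_incidence(c(2, 4, 6), c(1, 2, 0))
  c1 <- cif[cif$event_type == 1, ]
  c2 <- cif[cif$event_type == 2, ]
  expect_equal(max(c1$cif), 1 / 3, tolerance = 1e-12)
  expect_equal(max(c2$cif), 1 / 3, tolerance = 1e-12)
  # no competing events: CIF1 = 1 - KM
  set.seed(12)
  t <- rexp(40); s <- rbinom(40, 1, 0.7)
  cif1 <- cumulative_incidence(t, s)
  km <- kaplan_meier(t, s)
  for (ti in km$time[km$n_event > 0]) {
    expect_equal(max(cif1$cif[cif1$event_type == 1 & cif1$time <= ti]),
                 1 - km$surv[km$time == ti], tolerance = 1e-9)
  }
  # complete data: CIF1 + CIF2 + S = 1 at the last event time
  t <- c(1, 2, 3, 4, 5, 6); e <- c(1, 2, 1, 1, 2, 1)
  cifc <- cumulative_incidence(t, e)
  kmall <- kaplan_meier(t, rep(1, 6))
  total <- max(cifc$cif[cifc$event_type == 1]) +
    max(cifc$cif[cifc$event_type == 2]) + min(kmall$surv)
  expect_equal(total, 1, tolerance = 1e-12)
  # curves are non-decreasing within [0, 1]
  for (et in 1:2) {
    cc <- cifc$cif[cifc$event_type == et]
    expect_true(all(diff(cc) >= 0))
    expect_true(all(cc >= 0 & cc <= 1))
  }
})

test_that("Cox fits match brute-force partial-likelihood maximization", {
  # symmetric toy data: identical event patterns in both arms
  time <- c(1, 2, 3, 1, 2, 3)
  status <- c(1, 1, 0, 1, 1, 0)
  x <- rep(0:1, each = 3)
  fit <- cox_ph(time, status, data.frame(x = x))
  expect_lt(abs(fit$log_hr), 1e-8)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  # 6-subject fixture without ties vs numeric maximization
  time <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9)
  status <- c(1, 0, 1, 1, 0, 1)
  x <- c(1, 1, 0, 1, 0, 0)
  fit <- cox_ph(time, status, data.frame(x = x))
  opt <- optimize(function(b) -cox_pll(b, time, status, x),
                  c(-5, 5), tol = 1e-10)
  expect_equal(fit$log_hr, opt$minimum, tolerance = 1e-6)
  # 8-subject fixture, same check
  set.seed(10)
  time <- round(rexp(8), 3) + (1:8) * 1e-4
  status <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- rbinom(8, 1, 0.5)
  fit <- cox_ph(time, status, data.frame(x = x))
  opt <- optimize(function(b) -cox_pll(b, time, status, x),
                  c(-5, 5), tol = 1e-10)
  expect_equal(fit$log_hr, opt$minimum, tolerance = 1e-6)
  # CI reconstruction on the log scale
  expect_equal(fit$ci_low, exp(fit$log_hr - 1.96 * fit$se))
  expect_equal(fit$ci_high, exp(fit$log_hr + 1.96 * fit$se))
})

test_that("Fine-Gray reduces to Cox without competing events", {
  set.seed(20)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.2 * exp(0.6 * x)) + seq_len(n) * 1e-6  # no ties
  cens <- runif(n, 0, 8)
  time <- pmin(t, cens)
  event <- as.integer(t <= cens)
  fg <- fine_gray(time, event, data.frame(x = x))
  cx <- cox_ph(time, event, data.frame(x = x))
  expect_equal(fg$log_hr, cx$log_hr, tolerance = 1e-6)
  # variance estimators differ slightly (weighted sandwich vs inverse
  # information); the point estimates are what the reduction guarantees
  expect_equal(fg$se, cx$se, tolerance = 0.05)
})

test_that("hazard estimates are invariant to time rescaling", {
  set.seed(30)
  n <- 150
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.3 * exp(0.5 * x))
  cens <- runif(n, 0, 6)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  f1 <- cox_ph(time, ev, data.frame(x = x))
  f2 <- cox_ph(time * 365.25, ev, data.frame(x = x))
  expect_equal(f1$log_hr, f2$log_hr, tolerance = 1e-8)
  ev2 <- ev; ev2[sample(which(ev == 0), 20)] <- 2L
  g1 <- fine_gray(time, ev2, data.frame(x = x))
  g2 <- fine_gray(time * 52, ev2, data.frame(x = x))
  expect_equal(g1$log_hr, g2$log_hr, tolerance = 1e-6)
})

test_that("FIB-4 categories follow the standard formula and cut-offs", {
  expect_identical(as.character(fib4_category(60, 40, 36, 100)), "high")
  # 60 * 40 / (100 * 6) = 4.0
  expect_identical(as.character(fib4_category(40, 20, 25, 250)), "low")
  expect_identical(as.character(fib4_category(65, 30, 25, 300)),
                   "indeterminate")
  expect_identical(as.character(fib4_category(60, 40, 36, NA)), "missing")
  expect_identical(as.character(fib4_category(60, -3, 36, 100)), "missing")
  # boundary 1.3 is indeterminate by stated convention
  # age * AST / (plt * sqrt(ALT)) = 1.3: 52 * 25 / (plt * 5) with plt = 200
  expect_identical(as.character(fib4_category(52, 25, 25, 200)),
                   "indeterminate")
})

test_that("subtype hazard models recover planted hazard ratios end to end", {
  # subtypes differ only in death hazard; features keep them separable
  specs <- separated_specs(3)
  specs[[1]]$outcome_hazards["death"] <- 0.05
  specs[[2]]$outcome_hazards["death"] <- 0.05 * 3
  specs[[3]]$outcome_hazards["death"] <- 0.05
  # keep the high-hazard subtype small so it is never the reference group
  specs[[1]]$mixing_proportion <- 0.45
  specs[[2]]$mixing_proportion <- 0.20
  specs[[3]]$mixing_proportion <- 0.35
  res <- simulate_and_featurize(900, specs, seed = 71)
  cl <- cluster_subtypes(res$fm, k = 3)
  expect_gte(adjusted_rand(cl$assignment, res$truth), 0.9)
  tte <- build_outcome_table(res$sim$bundle, res$decisions)
  covs <- build_covariates(res$sim$bundle, res$decisions, cl$assignment)
  fit <- fit_outcome_models(tte, covs, outcomes = "death")$death
  # identify the cluster matching planted subtype T2 (higher hazard)
  t2 <- names(which.max(table(cl$assignment[res$truth == "T2"])))
  term <- paste0("subtype", t2)
  est <- fit$log_hr[fit$term == term]
  se <- fit$se[fit$term == term]
  expect_lt(abs(est - log(3)), 3 * se)
})
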