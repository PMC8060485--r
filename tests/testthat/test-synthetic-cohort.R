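small_cfg <- function(...) {
  cohort_config(n_symptomatic = 8, n_asymptomatic = 6, seed = 5, ...)
}

test_that("cohort generation is deterministic and respects group sizes", {
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg())
  expect_identical(c1$tacs, c2$tacs)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth, c2$truth)
  expect_equal(sum(c1$clinical$group == "symptomatic"), 8)
  expect_equal(sum(c1$clinical$group == "asymptomatic"), 6)
  # a different seed changes the draw
  c3 <- generate_cohort(cohort_config(n_symptomatic = 8, n_asymptomatic = 6,
                                      seed = 6))
  expect_false(identical(c1$tacs$attenuation_hu, c3$tacs$attenuation_hu))
})

test_that("config validation rejects out-of-range settings", {
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(collateral_poor_prob = c(fast = 1.2, slow = 0.1)),
               "probabilities")
  expect_error(cohort_config(n_symptomatic = -2), "group sizes")
  expect_error(cohort_config(seed = NULL), "seed")
})

test_that("ground truth is consistent with the emitted TACs and clinical rules", {
  co <- generate_cohort(small_cfg())
  sc <- score_cohort(co, visibility_threshold = 50)
  m <- merge(co$truth, sc, by = "patient_id")
  # scored presence equals injected absence flags (noise far below threshold)
  expect_equal(m$smcv_aff == "absent", unname(m$absent_smcv_aff))
  expect_equal(m$vol_contra == "absent", unname(m$absent_vol_contra))
  expect_equal(m$ipsilateral_cvf_minus_n, m$n_ipsilateral_true)
  # clinical decision rules agree with the generator's drawn classes
  cl <- co$clinical
  expect_equal(classify_collateral(cl$collateral_grade_atac,
                                   cl$collateral_grade_vtac),
               co$truth$collateral_status)
  expect_equal(classify_antegrade(cl$antegrade_filling_ratio),
               cl$antegrade_label)
  sym <- !is.na(cl$mrs_3mo)
  expect_equal(ifelse(cl$mrs_3mo[sym] > 2, "poor", "good"),
               co$truth$outcome[sym])
})

test_that("a noiseless cohort recovers the injected onset delay on the grid", {
  # widening switched off so that the onset delay is the only injected shift;
  # with it on, the slower rising edge also moves the visibility crossing
  # (covered by the median-level recovery checks)
  no_widening <- list(shift = 0, meanlog = log(1e-6), sdlog = 0.1)
  cfg <- cohort_config(n_symptomatic = 10, n_asymptomatic = 5, noise_sd = 0,
                       seed = 9,
                       peak_widening = list(symptomatic = no_widening,
                                            asymptomatic = no_widening))
  co <- generate_cohort(cfg)
  sc <- score_cohort(co, visibility_threshold = 50)
  m <- merge(co$truth, sc, by = "patient_id")
  ok <- !is.na(m$rcvf1)
  # grid spacing 2 s: each recovered onset delay within one grid interval
  expect_true(all(abs(m$rcvf1[ok] - m$delta1[ok]) <= 2))
  rr <- recovery_report(co$truth, sc, co$clinical)
  expect_lte(rr$delta1["rmse"], 2)
  # noiseless run: the presence confusion matrix is diagonal
  expect_equal(rr$presence_misclassification_rate, 0)
  pc <- rr$presence_confusion
  expect_equal(sum(pc) - sum(pc[cbind(rownames(pc), rownames(pc))]), 0)
  # derived collateral status agrees with the generator's drawn status
  cc <- rr$collateral_confusion
  expect_equal(sum(cc) - sum(cc[cbind(rownames(cc), rownames(cc))]), 0)
})

test_that("cohort files round-trip through the CSV contracts", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_cfg())
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  tacs <- read_tac_csv(files["tacs"])
  expect_equal(nrow(tacs), nrow(co$tacs))
  clin <- read_clinical_csv(files["clinical"])
  expect_equal(clin$collateral_status, co$clinical$collateral_status)
  manifest <- jsonlite::read_json(files["manifest"])
  expect_equal(manifest$seed, 5)
  expect_error(recovery_report(co$truth[-1, ],
                               score_cohort(co, 50)), "ids")
})

test_that("a YAML config overrides only the listed fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_symptomatic: 4", "n_asymptomatic: 3", "noise_sd: 0",
               "seed: 77"), path)
  cfg <- read_cohort_config(path)
  expect_equal(cfg$n_symptomatic, 4)
  expect_equal(cfg$noise_sd, 0)
  expect_equal(cfg$seed, 77)
  expect_equal(cfg$venous_delay, cohort_config()$venous_delay)
  writeLines("bogus_field: 1", path)
  expect_error(read_cohort_config(path), "unknown config fields")
})
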