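test_that("the default system wires the cohort biomarker universes", {
  sys <- build_system()
  expect_equal(c(sys$prisk1$input1$lo, sys$prisk1$input1$hi),
               c(22.03, 44.08))
  expect_equal(c(sys$prisk1$input2$lo, sys$prisk1$input2$hi), c(83, 237))
  expect_equal(c(sys$prisk2$input1$lo, sys$prisk2$input1$hi), c(112, 290))
  expect_equal(c(sys$prisk2$input2$lo, sys$prisk2$input2$hi), c(63, 320))
  # second level takes the first level's output range as its input universes
  expect_equal(c(sys$pcrisk$input1$lo, sys$pcrisk$input1$hi), c(1, 10))
  expect_equal(c(sys$pcrisk$input2$lo, sys$pcrisk$input2$hi), c(1, 10))
})

test_that("configuration validation names the offending fields", {
  expect_error(risk_config(universes = list(bmi = c(44, 22),
                                            glycemia = c(83, 237),
                                            cholesterol = c(112, 290),
                                            triglycerides = c(63, 320))),
               "universes\\$bmi")
  expect_error(risk_config(output_lo = 10, output_hi = 1), "output range")
  expect_error(risk_config(resolution = 10), "resolution")
})

test_that("a configuration round-trips through YAML unchanged", {
  cfg <- risk_config(resolution = 501L)
  cfg$rules$prisk2[1, 4] <- 3L
  cfg$rules$prisk2[4, 1] <- 3L
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$universes, cfg$universes)
  expect_equal(back$resolution, cfg$resolution)
  expect_equal(unname(back$rules$prisk2), unname(cfg$rules$prisk2))
  expect_equal(c(back$output_lo, back$output_hi), c(1, 10))
})

test_that("unknown configuration keys are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("resolution: 1001", "spline_order: 3"), path)
  expect_error(read_config(path), "unknown config key")
  writeLines(c("universes:", "  hba1c: {lo: 4, hi: 12}"), path)
  expect_error(read_config(path), "unknown biomarker")
})

test_that("cascade extremes hit the analytic end-triangle centroids", {
  at_min <- assess_patient(list(bmi = 22.03, glycemia = 83,
                                cholesterol = 112, triglycerides = 63))
  expect_equal(at_min$prisk1, 1.75, tolerance = 1e-3)
  expect_equal(at_min$prisk2, 1.75, tolerance = 1e-3)
  # second level fires {(Vs,Vs), (Vs,s), (s,Vs)} -> Vs (total weight 8/9)
  # and (s,s) -> s (weight 1/9); checked against the fine-grid oracle
  expect_equal(at_min$pcrisk, oracle_centroid(c(8 / 9, 1 / 9, 0, 0, 0)),
               tolerance = 1e-3)
  mid <- assess_patient(list(bmi = 33.055, glycemia = 160,
                             cholesterol = 201, triglycerides = 191.5))
  expect_equal(mid$prisk1, 5.5, tolerance = 1e-3)
  expect_equal(mid$prisk2, 5.5, tolerance = 1e-3)
  expect_equal(mid$pcrisk, 5.5, tolerance = 1e-3)
  at_max <- assess_patient(list(bmi = 44.08, glycemia = 237,
                                cholesterol = 290, triglycerides = 320))
  expect_equal(at_max$prisk1, 9.25, tolerance = 1e-3)
  expect_equal(at_max$prisk2, 9.25, tolerance = 1e-3)
  expect_equal(at_max$pcrisk, oracle_centroid(c(0, 0, 0, 1 / 9, 8 / 9)),
               tolerance = 1e-3)
})

test_that("invalid patient records fail with the patient id in the message", {
  expect_error(assess_patient(list(patient_id = "P07", bmi = NaN,
                                   glycemia = 100, cholesterol = 200,
                                   triglycerides = 150)),
               "P07")
})

test_that("cohort scoring preserves order and collects failures", {
  df <- data.frame(patient_id = c("a", "b", "c"),
                   bmi = c(25, 30, 40), glycemia = c(90, 150, 200),
                   cholesterol = c(150, 200, 250),
                   triglycerides = c(80, 150, 300))
  out <- assess_cohort(df)
  expect_equal(out$patient_id, c("a", "b", "c"))
  expect_true(all(is.finite(out$pcrisk)))
  log <- attr(out, "run_log")
  expect_equal(log$n_read, 3)
  expect_equal(log$n_scored, 3)
  expect_equal(log$n_failed, 0)

  df$bmi[2] <- NA
  out <- assess_cohort(df)
  log <- attr(out, "run_log")
  expect_equal(log$n_scored, 2)
  expect_equal(log$failures$patient_id, "b")
  expect_true(is.na(out$pcrisk[2]))
  expect_true(all(is.finite(out$pcrisk[c(1, 3)])))

  # determinism: identical records score identically
  two <- assess_cohort(df[c(1, 1), ])
  expect_equal(two$pcrisk[1], two$pcrisk[2])
  expect_error(assess_cohort(df[0, ]), "empty cohort")
})

test_that("raising any single biomarker never lowers the cumulative risk", {
  u <- default_universes()
  base <- list(bmi = 30, glycemia = 120, cholesterol = 180,
               triglycerides = 150)
  sys <- build_system()
  for (b in names(u)) {
    grid <- seq(u[[b]][1], u[[b]][2], length.out = 25)
    pc <- vapply(grid, function(val) {
      rec <- base
      rec[[b]] <- val
      assess_patient(rec, sys)$pcrisk
    }, numeric(1))
    expect_true(all(diff(pc) >= -1e-6), label = paste("monotone in", b))
  }
})

test_that("surface grids are row-major with the expected corner values", {
  g <- surface_grid("prisk1", 2)
  expect_equal(nrow(g), 4)
  expect_equal(g$x1, c(22.03, 22.03, 44.08, 44.08))
  expect_equal(g$value[1], 1.75, tolerance = 1e-3)
  expect_equal(g$value[4], 9.25, tolerance = 1e-3)
  expect_error(surface_grid("prisk1", 1), "n must be")
  expect_error(surface_grid("prisk9", 5), "unknown subsystem")
})

test_that("risk outputs always lie on the configured 1-10 scale", {
  set.seed(31)
  df <- data.frame(bmi = runif(100, 10, 60), glycemia = runif(100, 50, 400),
                   cholesterol = runif(100, 80, 400),
                   triglycerides = runif(100, 30, 500))
  out <- assess_cohort(df)
  for (col in c("prisk1", "prisk2", "pcrisk")) {
    expect_true(all(out[[col]] >= 1 & out[[col]] <= 10))
  }
  # out-of-range values are reported in the run log as clamped
  expect_gt(attr(out, "run_log")$n_clamped, 0)
})
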