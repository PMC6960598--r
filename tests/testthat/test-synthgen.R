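test_that("subject profiles are deterministic with derived BMI and valid pressures", {
  s <- make_subject(1, height = 1.70, weight = 65)
  expect_equal(s$bmi, 65 / 1.70^2, tolerance = 1e-12)
  expect_identical(make_subject(42), make_subject(42))
  expect_error(make_subject(1, height = -1), "positive")
  # diastolic below systolic across a wide sweep of seeds
  for (sd in seq_len(1000)) {
    s <- make_subject(sd)
    expect_lt(s$base_dbp, s$base_sbp)
    expect_true(s$gender %in% c(0, 1))
  }
})

test_that("noiseless renders have the documented beat count and fiducial geometry", {
  s <- make_subject(2)
  r <- render_record(s, duration = 20, hr = 60, noise = noise_none(), seed = 3)
  expect_length(r$beats, 20)
  expect_equal(length(r$ppg), 20 * 500)
  expect_equal(length(r$ppg), length(r$ecg))
  for (b in r$beats) {
    expect_true(b$t_b < b$t_a && b$t_a < b$t_c && b$t_c < b$t_e &&
                  b$t_e < b$t_f && b$t_f < b$t_g && b$t_g < b$period)
    expect_gt(b$r_offset, 0)
    # systolic peak is the beat maximum
    expect_true(all(b$amp_c >= c(b$amp_b, b$amp_a, b$amp_e, b$amp_f, b$amp_g)))
  }
  expect_gt(r$sbp_ref, r$dbp_ref)
})

test_that("rendering is bit-identical for a fixed seed", {
  s <- make_subject(5)
  r1 <- render_record(s, seed = 11)
  r2 <- render_record(s, seed = 11)
  expect_identical(r1$ppg, r2$ppg)
  expect_identical(r1$ecg, r2$ecg)
  expect_identical(r1$sbp_ref, r2$sbp_ref)
})

test_that("the ground-truth pressure function responds to transit time in closed form", {
  s <- make_subject(4, noise_sd = 0)
  r1 <- render_record(s, hr = 70, r_offset = 0.20, ra = 0.35,
                      noise = noise_none(), seed = 1)
  r2 <- render_record(s, hr = 70, r_offset = 0.25, ra = 0.35,
                      noise = noise_none(), seed = 1)
  beta1 <- s$coupling$sbp[2]
  expect_equal(r1$sbp_ref - r2$sbp_ref, beta1 * (1 / 0.20 - 1 / 0.25),
               tolerance = 1e-9)
})

test_that("regression on noiseless records recovers the coupling coefficients", {
  s <- make_subject(9, noise_sd = 0)
  recs <- lapply(seq_len(500), function(i)
    render_record(s, duration = 2, seed = i, noise = noise_none()))
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(inv_ptt = 1 / r$latent$r_offset, hr = r$latent$hr,
               ra = r$latent$ra, sbp = r$sbp_ref)))
  fit <- stats::lm(sbp ~ inv_ptt + hr + ra, data = df)
  expect_equal(unname(coef(fit)), s$coupling$sbp, tolerance = 1e-6)
})

test_that("cohort layout reproduces the campaign bookkeeping", {
  co <- make_cohort(17, 10, seed = 7, render_signals = FALSE)
  expect_equal(sum(co$manifest$split == "train"), 775)
  expect_equal(sum(co$manifest$split == "test"), 120)
  expect_equal(length(co$subjects), 27)
  # every test subject contributes exactly 12 records
  tab <- table(co$manifest$subject_id[co$manifest$split == "test"])
  expect_true(all(tab == 12))
  # no test partition is fine
  co0 <- make_cohort(2, 0, records_per_subject = list(train = 5), seed = 1,
                     render_signals = FALSE)
  expect_equal(sum(co0$manifest$split == "test"), 0)
  # determinism
  co2 <- make_cohort(17, 10, seed = 7, render_signals = FALSE)
  expect_identical(co$manifest, co2$manifest)
})

test_that("records serialize to plain-text channel files with a JSON sidecar", {
  s <- make_subject(3)
  r <- render_record(s, duration = 4, hr = 75, noise = noise_none(), seed = 2)
  r$record_id <- "demo"
  d <- withr::local_tempdir()
  paths <- write_record(r, d)
  expect_true(all(file.exists(paths)))
  sig <- utils::read.csv(paths[1])
  expect_equal(nrow(sig), length(r$ppg))
  meta <- jsonlite::read_json(paths[3])
  expect_equal(meta$fs, 500)
  expect_match(meta$bp_function, "r_offset")
})

test_that("rendering rejects impossible requests", {
  s <- make_subject(1)
  expect_error(render_record(s, duration = 0.5, hr = 60), "one beat")
  expect_error(render_record(s, hr = 20), "30-200")
})
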