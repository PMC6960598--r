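make_fids <- function(df) {
  structure(df, class = c("bp_fiducials", "data.frame"), fs = 500)
}

feat_rec <- local({
  s <- make_subject(1)
  r <- render_record(s, duration = 20, hr = 60, noise = noise_none(), seed = 5)
  rp <- detect_r_peaks(r$ecg, r$fs)
  fid <- detect_ppg_fiducials(r$ppg, rp$peaks, r$fs)
  list(rec = r, fid = fid, bf = beat_features(fid, r$ppg, r$fs),
       subj = make_subject(1))
})

test_that("a symmetric triangular pulse splits the cycle evenly", {
  fs <- 500
  ppg <- c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 101)[-1])
  ppg <- c(ppg, ppg[-1])                      # two cycles
  fid <- make_fids(data.frame(beat = 1, R = NA, b = 1, a = 51, c = 101,
                              e = 151, f = 171, g = 181, next_b = 201,
                              next_R = NA))
  fid$R <- 1; fid$next_R <- 201               # arbitrary consistent R timing
  bf <- beat_features(fid, ppg, fs)
  expect_equal(bf$t_upr, 0.5, tolerance = 1e-9)
  expect_equal(bf$t_downr, 0.5, tolerance = 1e-9)
})

test_that("a linear sawtooth yields the closed-form waveform factor 0.5", {
  fs <- 500
  ppg <- (seq_len(401) - 1) / 200             # rising ramp, b at 1
  fid <- make_fids(data.frame(beat = 1, R = 1, b = 1, a = 100, c = 201,
                              e = 201, f = 201, g = 201, next_b = 201,
                              next_R = 201))
  bf <- beat_features(fid, ppg, fs)
  expect_equal(bf$K, 0.5, tolerance = 1e-9)
  # the two partial areas always recompose the full-cycle area
  full <- pulsebp:::trapz_uniform(ppg[1:201] - ppg[1], 1 / fs)
  expect_equal(bf$S_bf + bf$S_fb, full, tolerance = 1e-9)
})

test_that("transit times match planted truth on noiseless beats", {
  r <- feat_rec$rec; fid <- feat_rec$fid; bf <- feat_rec$bf
  planted_ptt_c <- sapply(r$beats, function(b) b$r_offset + b$t_c)
  expect_true(all(abs(bf$PTT_c - planted_ptt_c[bf$beat]) <= 2 / r$fs + 1e-12))
  expect_true(all(bf$PTT_b < bf$PTT_a & bf$PTT_a < bf$PTT_c))
})

test_that("ratio identities and area decomposition hold for every beat", {
  bf <- feat_rec$bf
  expect_equal(bf$t_upr + bf$t_downr, rep(1, nrow(bf)), tolerance = 1e-9)
  expect_equal(bf$t_bfr + bf$t_fbr, rep(1, nrow(bf)), tolerance = 1e-9)
  expect_true(all(bf$H_ar > 0 & bf$H_ar <= 1))
  expect_true(all(bf$H_er > 0 & bf$H_er <= 1))
  expect_true(all(bf$H_fr > 0 & bf$H_fr <= 1))
  expect_true(all(bf$H_gr > 0 & bf$H_gr <= 1))
  r <- feat_rec$rec; fid <- feat_rec$fid
  full <- sapply(seq_len(nrow(fid)), function(i)
    pulsebp:::trapz_uniform(r$ppg[fid$b[i]:fid$next_b[i]] - r$ppg[fid$b[i]],
                            1 / r$fs))
  expect_equal(bf$S_bf + bf$S_fb, full, tolerance = 1e-9)
})

test_that("positive rescaling of the PPG leaves shape features unchanged", {
  r <- feat_rec$rec; fid <- feat_rec$fid; bf <- feat_rec$bf
  bf2 <- beat_features(fid, 3.7 * r$ppg, r$fs)
  shape <- c("t_up", "t_bf", "t_down", "t_fb", "t_ae", "t_upr", "t_bfr",
             "t_downr", "t_fbr", "t_aer", "PTT_b", "PTT_a", "PTT_c",
             "H_ar", "H_er", "H_fr", "H_gr", "K", "HR")
  for (nm in shape) expect_equal(bf2[[nm]], bf[[nm]], tolerance = 1e-12)
  expect_equal(bf2$S_bf, 3.7 * bf$S_bf, tolerance = 1e-12)
  expect_equal(bf2$C_slope, 3.7 * bf$C_slope, tolerance = 1e-12)
})

test_that("record aggregation is the beat median with BMI and gender appended", {
  bf <- feat_rec$bf
  one <- bf[rep(1, 10), ]
  fv <- record_features(one, feat_rec$subj)
  expect_length(fv, 24)
  expect_equal(unname(fv["t_up"]), bf$t_up[1])
  expect_equal(unname(fv["BMI"]), feat_rec$subj$bmi)
  # one wild outlier among identical beats does not move the aggregate
  out <- one
  out[5, -1] <- out[5, -1] * 100
  fv2 <- record_features(out, feat_rec$subj)
  expect_equal(fv2, fv)
  expect_error(record_features(bf[1:2, ], feat_rec$subj), "3 valid beats")
})

test_that("a small synthetic cohort yields a complete 24-column feature matrix", {
  co <- make_cohort(2, 1, records_per_subject = list(train = 6, test = 6),
                    seed = 3, duration = 10, noise = noise_none())
  fm <- cohort_features(co, denoise = FALSE)
  expect_equal(ncol(fm$X), 24)
  expect_equal(nrow(fm$X) + length(fm$dropped), 18)
  expect_false(anyNA(fm$X))
  expect_identical(colnames(fm$X), pulsebp:::feature_names())
})
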