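# Fixed numeric inputs from the cuffless-BP validation literature, used to
# exercise the contribution/screening/pooling arithmetic on realistic values.

# published mean impact values of the 18 round-two SBP screening features
ref_miv_sbp <- c(
  BMI = 12.5567, t_downr = 11.5329, t_bf = 7.4782, t_fbr = 6.9880,
  PTT_c = 4.7147, t_up = 3.8678, t_bfr = 3.7754, t_down = 3.2777,
  H_er = 3.1959, t_aer = 2.6251, t_upr = 2.6234, HR = 2.5713,
  K = 2.5514, PTT_a = 2.4541, t_ae = 2.4190, gender = 2.0847,
  H_fr = 2.0090, t_fb = 1.7716
)

# published mean impact values of the 18 round-two DBP screening features
ref_miv_dbp <- c(
  t_downr = 10.3509, H_er = 7.1181, t_bf = 6.7586, t_fbr = 6.3810,
  BMI = 5.5027, t_bfr = 4.9504, t_ae = 4.4072, t_up = 3.5946,
  HR = 3.2784, t_aer = 3.1370, t_fb = 2.4708, t_down = 2.4611,
  t_upr = 2.3780, PTT_a = 2.0499, H_gr = 2.0185, K = 1.8294,
  H_ar = 1.3742, PTT_c = 1.1615
)

ref_sel_sbp <- c("BMI", "t_downr", "t_bf", "t_fbr", "PTT_c", "t_up", "t_bfr",
                 "t_down", "H_er", "t_aer", "t_upr", "HR", "K", "PTT_a")
ref_sel_dbp <- c("t_downr", "H_er", "t_bf", "t_fbr", "BMI", "t_bfr", "t_ae",
                 "t_up", "HR", "t_aer", "t_fb", "t_down", "t_upr", "PTT_a")

# published per-individual test errors (10 individuals, 6 test records each)
ref_ind_rmse_sbp <- c(3.3667, 1.9918, 6.03, 2.6706, 2.7154,
                      1.7656, 2.1268, 2.7512, 4.7518, 3.4544)
ref_ind_rmse_dbp <- c(3.5002, 4.2858, 2.3613, 4.9515, 4.346,
                      1.4618, 2.5727, 2.3513, 2.7733, 2.5732)
ref_ind_mad_dbp <- c(3.1502, 4.0309, 1.726, 4.5651, 3.4716,
                     1.3235, 2.3415, 1.8745, 2.2527, 2.1541)

# per-subject record counts of the emulated acquisition campaign
ref_train_counts <- c(44, 61, 51, 52, 52, 31, 40, 53,
                      27, 47, 41, 28, 64, 55, 20, 55, 54)
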