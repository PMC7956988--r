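test_that("internal noise is the HL-shifted reference transfer", {
  tab <- presbyfit_table("hl_to_spl")
  f <- c(250, 500, 1000, 2000, 4000)
  flat0 <- c("0.25" = 0, "0.5" = 0, "1" = 0, "2" = 0, "4" = 0)
  base <- internal_noise_levels(flat0, f)
  expect_equal(base[f == 1000], tab$ref_db_spl[tab$freq_hz == 1000])
  expect_equal(internal_noise_levels(flat0 + 20, f), base + 20)
  # sloping loss: internal noise rises with frequency
  slope <- c("0.25" = 10, "0.5" = 20, "1" = 35, "2" = 55, "4" = 75)
  lev <- internal_noise_levels(slope, f)
  expect_true(all(diff(lev) > 0))
  expect_error(internal_noise_levels(flat0, 20), "outside the span")
})

test_that("frame index implements clipped band audibility", {
  w <- rep(1 / 4, 4)
  expect_equal(frame_sii(rep(50, 4), rep(20, 4), w), 1)   # >= +15 dB
  expect_equal(frame_sii(rep(10, 4), rep(40, 4), w), 0)   # <= -15 dB
  expect_equal(frame_sii(30, 30, 1), 0.5)                 # (0+15)/30
  expect_equal(frame_sii(c(50, 10), c(20, 40), c(0.5, 0.5)), 0.5)
  expect_error(frame_sii(1:3, 1:2, c(0.5, 0.5)), "band grid")
})

test_that("forward masking decays log-linearly to the listener threshold", {
  f <- c(500, 1000)
  # steady masker: unchanged
  steady <- presbyfit:::new_band_grid(f, seq(0, 0.09, 0.01),
                                      matrix(60, 10, 2))
  out <- forward_masking_extend(steady, c(10, 10))
  expect_equal(out$levels, steady$levels)
  # single burst then silence
  lv <- matrix(-100, 11, 2)
  lv[1, ] <- 70
  burst <- presbyfit:::new_band_grid(f, seq(0, 0.1, 0.01), lv)
  Tn <- c(5, 5); Th <- c(40, 40)
  nh <- forward_masking_extend(burst, Tn, duration_s = 0.1, t0_s = 0.01)
  hi <- forward_masking_extend(burst, Th, duration_s = 0.1, t0_s = 0.01)
  # elevated thresholds leave higher effective levels at every post-burst
  # frame (the decay reaches threshold after the same fixed duration)
  expect_true(all(hi$levels[2:10, ] > nh$levels[2:10, ]))
  # endpoint identity: at t = D the trail equals the threshold
  expect_equal(nh$levels[11, 1], 5, tolerance = 1e-9)
  # hand-computed interior point: t = 0.05 after the burst
  expected <- 70 - (70 - 5) * log(1 + 0.05 / 0.01) / log(1 + 0.1 / 0.01)
  expect_equal(nh$levels[6, 1], expected, tolerance = 1e-9)
})

test_that("audibility index is bounded, monotone and reduces to the SII", {
  ag_nh <- c("0.5" = 8, "1" = 9, "2" = 11, "4" = 14)
  ag_hi <- c("0.5" = 35, "1" = 40, "2" = 55, "4" = 70)
  sp <- speech_band_levels()
  # quiet, normal-hearing audiogram: essentially full audibility
  q <- esii(sp, NULL, ag_nh)
  expect_gte(q$value, 0.93)
  expect_lte(q$value, 1)
  expect_true(all(q$per_frame >= 0 & q$per_frame <= 1))
  expect_equal(q$value, mean(q$per_frame))
  # monotone in SNR
  vals <- vapply(c(-20, -10, 0, 10), function(snr) {
    mk <- masker_band_grid(sp, snr_db = snr, duration_s = 0.25, seed = 7)
    esii(sp, mk, ag_nh)$value
  }, 0)
  expect_true(all(diff(vals) >= 0))
  # anti-monotone in threshold elevation
  mk <- masker_band_grid(sp, duration_s = 0.25, seed = 7)
  e_lo <- esii(sp, mk, ag_nh)$value
  e_mid <- esii(sp, mk, ag_nh + 30)$value
  e_hi <- esii(sp, mk, ag_nh + 60)$value
  expect_true(e_lo >= e_mid && e_mid >= e_hi)
  expect_true(all(c(e_lo, e_mid, e_hi) >= 0 & c(e_lo, e_mid, e_hi) <= 1))
  # steady masker: extended index equals the single-frame standard index
  st <- masker_band_grid(sp, am_depth = 0, ripple_on = FALSE,
                         duration_s = 0.2, seed = 1)
  res <- esii(sp, st, ag_hi)
  w <- band_importance(sp$frequencies_hz, "SPIN")
  internal <- internal_noise_levels(ag_hi, sp$frequencies_hz)
  dist <- presbyfit:::power_sum_db(st$levels[1, ], internal)
  expect_equal(res$value,
               frame_sii(sp$levels[1, ], dist, w))
  expect_true(all(res$per_frame == res$per_frame[1]))
})

test_that("importance weights are a normalized nonnegative set", {
  for (wt in c("SPIN", "NNS", "flat")) {
    w <- band_importance(gammatone_centers(), wt)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1)
  }
  expect_error(band_importance(gammatone_centers(), "XXX"), "unknown")
})

test_that("cohort-level ESII separates conditions and tracks hearing loss", {
  ch <- tiny_cohort(n_hi = 25, n_nh = 8, seed = 12)
  q <- esii_for_cohort(ch$participants, 0)
  n <- esii_for_cohort(ch$participants, 1, seed = 3)
  expect_true(all(q >= 0 & q <= 1) && all(n >= 0 & n <= 1))
  expect_true(all(n <= q))                # noise can only reduce audibility
  hi <- ch$participants$group == "HI"
  # more hearing loss, less audibility (rank association, quiet)
  expect_lt(stats::cor(ch$participants$pta[hi], q[hi], method = "spearman"), 0)
})
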