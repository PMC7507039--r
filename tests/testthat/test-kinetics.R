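test_that("signal-to-concentration inverts the SPGR forward model", {
  p <- scan_protocol()
  # forward-generate a frame at a known R1, invert, compare
  t1_0 <- 1000; r1_t <- 2.6
  m0 <- 500
  maps <- structure(list(t1_ms = t1_0, m0 = m0, fit_ok = TRUE, tr_s = p$tr),
                    class = "t1_maps")
  s_base <- spgr_signal(m0, t1_0, p$flip_angle_dyn, p$tr)
  s_high <- spgr_signal(m0, 1000 / r1_t, p$flip_angle_dyn, p$tr)
  sig <- matrix(s_base, 1, p$n_dynamics)
  sig[1, 10] <- s_high
  cs <- signal_to_concentration(sig, maps, p)
  # frames equal to baseline give exactly zero concentration
  expect_equal(cs$conc[1, 1], 0, tolerance = 1e-12)
  # the enhanced frame gives C = (R1 - R1_0)/r1 = (2.6 - 1)/3.6
  expect_equal(cs$conc[1, 10], (r1_t - 1000 / t1_0) / p$relaxivity_r1,
               tolerance = 1e-9)
  expect_equal(cs$conc[1, 10], 0.4444444, tolerance = 1e-6)
})

test_that("saturated signals and rejected voxels become missing with QC counts", {
  p <- scan_protocol()
  maps <- structure(list(t1_ms = c(1000, NA), m0 = c(500, NA),
                         fit_ok = c(TRUE, FALSE), tr_s = p$tr),
                    class = "t1_maps")
  sig <- matrix(spgr_signal(500, 1000, p$flip_angle_dyn, p$tr), 2,
                p$n_dynamics)
  sig[1, 7] <- 500 * sin(p$flip_angle_dyn * pi / 180) * 1.01  # beyond bound
  cs <- signal_to_concentration(sig, maps, p)
  expect_true(is.na(cs$conc[1, 7]))
  expect_false(anyNA(cs$conc[1, -7]))
  expect_true(all(is.na(cs$conc[2, ])))
  expect_equal(cs$qc$n_noninvertible, 1)
  expect_equal(cs$qc$n_rejected_voxels, 1)
})

test_that("noiseless phantom concentration round-trips through signal", {
  ph <- generate_phantom(1, grid_shape = c(6, 6, 1))
  maps <- fit_t1_vfa(ph$vfa, ph$protocol$flip_angles, ph$protocol$tr)
  cs <- signal_to_concentration(ph$dyn, maps, ph$protocol)
  cm <- matrix(cs$conc, ncol = dim(cs$conc)[4])
  for (r in seq_len(nrow(ph$truth))) {
    v <- which(as.vector(ph$labels) == ph$truth$region_label[r])[1]
    expect_lt(max(abs(cm[v, ] - ph$conc_truth[r, ])), 1e-6)
  }
})

test_that("AIF extraction scales blood to plasma and round-trips the generator", {
  p <- scan_protocol()
  tt <- frame_times(p)
  # uniform blood concentration 1 mM, Hct 0.45 -> cp = 1/0.55 everywhere
  conc <- structure(list(conc = matrix(1, 4, p$n_dynamics), times = tt,
                         qc = list()), class = "conc_series")
  a <- extract_aif(conc, rep(TRUE, 4), 0.45)
  expect_equal(a$cp, rep(1 / 0.55, p$n_dynamics), tolerance = 1e-12)
  # hematocrit 0 leaves the mean blood curve unchanged
  a0 <- extract_aif(conc, rep(TRUE, 4), 0)
  expect_equal(a0$cp, rep(1, p$n_dynamics))
  expect_error(extract_aif(conc, rep(FALSE, 4), 0.45), "empty")
  # voxels with missing curves are excluded and counted
  conc$conc[1, 3] <- NA
  a3 <- extract_aif(conc, rep(TRUE, 4), 0.45)
  expect_equal(a3$n_voxels, 3)

  # phantom sinus region reproduces the generating plasma curve
  ph <- generate_phantom(1, grid_shape = c(6, 6, 1))
  maps <- fit_t1_vfa(ph$vfa, ph$protocol$flip_angles, ph$protocol$tr)
  cs <- signal_to_concentration(ph$dyn, maps, ph$protocol)
  af <- extract_aif(cs, ph$sinus_mask, ph$protocol$hematocrit)
  expect_lt(max(abs(af$cp - ph$aif$cp)), 1e-6)
})

test_that("population AIF is zero pre-bolus, linear in amplitude, peaks early", {
  tt <- default_times()
  a <- population_aif(tt)
  expect_true(all(a$cp[tt < 40] == 0))
  expect_true(all(a$cp >= 0))
  peak_frame <- which.max(a$cp)
  expect_gte(peak_frame, 6); expect_lte(peak_frame, 10)
  a2 <- population_aif(tt, params = list(amplitude = 13, m1 = 0.17,
                                         m2 = 8, t0 = 40))
  expect_equal(a2$cp, 2 * a$cp, tolerance = 1e-12)
})

test_that("tofts_forward obeys its structural identities", {
  a <- population_aif(default_times())
  # ktrans = 0: pure plasma term
  expect_equal(tofts_forward(0, NA, 0.05, a), 0.05 * a$cp)
  # linear in the input
  a2 <- aif(a$times, 2 * a$cp)
  expect_equal(tofts_forward(0.1, 0.2, 0.02, a2),
               2 * tofts_forward(0.1, 0.2, 0.02, a), tolerance = 1e-12)
  expect_error(tofts_forward(0.1, 0, 0.02, a), "ve")
  expect_error(tofts_forward(0.1, 0.99, 0.02, a), "exceed 1")
})

test_that("tofts_forward matches the constant-input closed form within 0.1%", {
  tt <- seq(0, 600, by = 8)
  conc <- 2
  a <- aif(tt, rep(conc, length(tt)))
  ct <- tofts_forward(0.1, 0.2, 0.03, a)
  closed <- tofts_const_input(0.1, 0.2, 0.03, conc, tt)
  expect_lt(max(abs(ct[-1] - closed[-1]) / closed[-1]), 1e-3)
  # long-time limit: Ct -> (ve + vp) c once the exchange has equilibrated
  tl <- seq(0, 3600, by = 8)
  ctl <- tofts_forward(0.1, 0.2, 0.03, aif(tl, rep(conc, length(tl))))
  expect_equal(ctl[length(tl)], (0.2 + 0.03) * conc, tolerance = 1e-3)
})

test_that("halving the frame spacing monotonically improves the quadrature", {
  errs <- vapply(c(16, 8, 4, 2), function(dt) {
    tt <- seq(0, 480, by = dt)
    a <- aif(tt, rep(1.5, length(tt)))
    ct <- tofts_forward(0.15, 0.25, 0, a)
    closed <- tofts_const_input(0.15, 0.25, 0, 1.5, tt)
    max(abs(ct[-1] - closed[-1]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("linear fit recovers noiseless forward curves and handles edge cases", {
  a <- population_aif(default_times())
  p <- fit_extended_tofts_linear(tofts_forward(0.1, 0.2, 0.02, a), a)
  expect_equal(p$ktrans, 0.1, tolerance = 0.01)
  expect_equal(p$ve, 0.2, tolerance = 0.01)
  expect_equal(p$vp, 0.02, tolerance = 0.01)
  expect_length(p$flags, 0)
  expect_equal(p$kep, p$ktrans / p$ve)

  # identically zero curve: zero ktrans and vp, flagged ve
  z <- fit_extended_tofts_linear(rep(0, 45), a)
  expect_equal(z$ktrans, 0)
  expect_equal(z$vp, 0)
  expect_true(is.na(z$ve))
  expect_gt(length(z$flags), 0)

  expect_error(fit_extended_tofts_linear(rep(0, 45),
                                         aif(default_times(), rep(0, 45))),
               "AIF")
  expect_error(fit_extended_tofts_linear(rep(NA_real_, 45), a), "4 usable")
})

test_that("linear and nonlinear fits agree on noiseless data (oracle equivalence)", {
  a <- population_aif(default_times())
  for (tp in list(c(0.1, 0.2, 0.02), c(0.02, 0.3, 0.05),
                  c(0.098, 0.2, 0.02))) {
    ct <- tofts_forward(tp[1], tp[2], tp[3], a)
    pl <- fit_extended_tofts_linear(ct, a)
    pn <- fit_extended_tofts_nls(ct, a, init = pl)
    expect_equal(pn$ktrans, pl$ktrans, tolerance = 1e-3)
    expect_equal(pn$ve, pl$ve, tolerance = 1e-3)
    expect_equal(pn$vp, pl$vp, tolerance = 1e-3)
  }
  # init at truth: immediate convergence with essentially zero residual
  ct <- tofts_forward(0.1, 0.2, 0.02, a)
  pn <- fit_extended_tofts_nls(ct, a,
                               init = list(ktrans = 0.1, ve = 0.2, vp = 0.02,
                                           flags = character(0)))
  expect_lt(pn$rss, 1e-12)
  # zero-ktrans truth pins the estimate at the lower bound
  ct0 <- tofts_forward(0, NA, 0.03, a)
  pn0 <- fit_extended_tofts_nls(ct0, a,
                                init = list(ktrans = 0.01, ve = 0.2,
                                            vp = 0.03, flags = character(0)))
  expect_lt(pn0$ktrans, 1e-6)
})

test_that("noiseless end-to-end recovery holds across the parameter box", {
  a <- population_aif(default_times())
  set.seed(7)
  for (i in 1:8) {
    kt <- runif(1, 0.005, 0.2); ve <- runif(1, 0.1, 0.4)
    vp <- runif(1, 0.01, 0.1)
    p <- fit_extended_tofts_linear(tofts_forward(kt, ve, vp, a), a)
    expect_equal(p$ktrans, kt, tolerance = 0.01)
    expect_equal(p$ve, ve, tolerance = 0.01)
    expect_equal(p$vp, vp, tolerance = 0.01)
  }
})

test_that("ROI statistics: uniform maps, phantom truth, permutation invariance", {
  vals <- c(rep(0.05, 10), rep(0.01, 10))
  roi <- c(rep(TRUE, 10), rep(FALSE, 10))
  s <- roi_ktrans_stats(vals, roi, !roi)
  expect_equal(s$lesion$mean, 0.05)
  expect_equal(s$lesion$sd, 0)
  expect_equal(s$lesion$n, 10)
  expect_equal(s$difference, 0.04)
  # voxel order cannot matter
  set.seed(3)
  perm <- sample(20)
  s2 <- roi_ktrans_stats(vals[perm], roi[perm], (!roi)[perm])
  expect_equal(s2, s)
  expect_error(roi_ktrans_stats(vals, rep(FALSE, 20), !roi), "empty")
  roi_big <- roi; roi_big[12] <- TRUE   # 11 vs 10 voxels
  expect_warning(roi_ktrans_stats(vals, roi_big, !roi), "size")

  # noiseless phantom: lesion/mirror means equal the generating truths
  ph <- generate_phantom(1, grid_shape = c(9, 5, 1))
  maps <- fit_t1_vfa(ph$vfa, ph$protocol$flip_angles, ph$protocol$tr)
  cs <- signal_to_concentration(ph$dyn, maps, ph$protocol)
  fm <- fit_tofts_map(cs, extract_aif(cs, ph$sinus_mask,
                                      ph$protocol$hematocrit))
  kt <- array(NA_real_, dim(ph$labels)); kt[fm$voxel] <- fm$ktrans
  s <- roi_ktrans_stats(kt, ph$labels == 1, ph$labels == 2,
                        use_flagged = TRUE)
  expect_equal(s$lesion$mean, 0.098, tolerance = 1e-6)
  expect_equal(s$mirror$mean, 0.003, tolerance = 1e-6)
})
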