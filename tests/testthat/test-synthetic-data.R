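test_that("toy leadfield has the contracted shape, rank and determinism", {
  lf <- make_toy_leadfield(19, 1, seed = 1)
  expect_equal(dim(lf$gain), c(19, 68))
  expect_length(lf$source_labels, 68)
  expect_true(all(is.finite(lf$gain)))
  expect_equal(qr(lf$gain)$rank, 19)           # full row rank
  expect_true(kappa(lf$gain) < 1e12)
  lf2 <- make_toy_leadfield(19, 2, seed = 1)
  lf3 <- make_toy_leadfield(19, 2, seed = 1)
  expect_identical(lf2$gain, lf3$gain)
  expect_equal(ncol(lf2$gain), 136)
  expect_true(all(tabulate(lf2$roi_of_source, 68) == 2))
  expect_error(make_toy_leadfield(1, 1), "n_sensors")
  expect_error(make_toy_leadfield(19, 0), "sources_per_roi")
})

test_that("region signals are seeded, zero-mean, with a 1/f background", {
  truth <- simulation_truth(band_amplitudes = c(delta = 0, theta = 0,
                                                alpha1 = 0, alpha2 = 0,
                                                beta1 = 0, beta2 = 0,
                                                beta3 = 0, gamma = 0),
                            background_sd = 1)
  x <- simulate_roi_signals(truth, n_rois = 4, fs = 128, duration = 60,
                            seed = 7)
  x2 <- simulate_roi_signals(truth, n_rois = 4, fs = 128, duration = 60,
                             seed = 7)
  expect_identical(x, x2)
  expect_true(all(abs(rowMeans(x)) < 1e-8 * apply(x, 1, sd)))
  # amplitudes zero + background on: log-log spectral slope close to -1
  ep <- as_epochs(x, fs = 128, epoch_length = 4)
  spec <- power_spectrum(ep)
  sel <- spec$freq >= 2 & spec$freq <= 40
  for (r in 1:4) {
    fit <- lm(log10(spec$psd[r, sel]) ~ log10(spec$freq[sel]))
    # within 3 dB of a pure 1/f line over 2-40 Hz
    resid_db <- 10 * abs(residuals(fit))
    expect_lt(stats::median(resid_db), 3)
    expect_lt(abs(coef(fit)[2] + 1), 0.35)
  }
})

test_that("a planted lagged coupling produces elevated imaginary coherence", {
  edges <- data.frame(source = 1, target = 2, band = "alpha1",
                      lag_seconds = 0.025, strength = 0.9)
  truth <- simulation_truth(coupling_edges = edges)
  x <- simulate_roi_signals(truth, n_rois = 20, fs = 128, duration = 60,
                            seed = 3)
  ep <- as_epochs(x[, , drop = FALSE], fs = 128, epoch_length = 4)
  coh <- coherency(cross_spectra(ep$epochs, fs = 128, fmax = 45))
  ic <- imaginary_coherence(coh, bands = "alpha1")$alpha1
  ut <- upper.tri(ic)
  others <- ic[ut][-1]                       # all pairs except (1,2)
  expect_gt(ic[1, 2], quantile(others, 0.95))
})

test_that("signal generator rejects bad arguments", {
  truth <- simulation_truth()
  expect_error(simulate_roi_signals(truth, fs = 80, n_rois = 4,
                                    duration = 10),
               "twice the highest band edge")
  edges <- data.frame(source = 1, target = 2, band = "alpha1",
                      lag_seconds = 20, strength = 0.5)
  truth2 <- simulation_truth(coupling_edges = edges)
  expect_error(simulate_roi_signals(truth2, n_rois = 4, fs = 128,
                                    duration = 10), "lag")
  expect_error(simulation_truth(coupling_edges = data.frame(
    source = 1, target = 2, band = "alpha1", lag_seconds = 0.01,
    strength = 1.2)), "strengths")
})

test_that("sensor projection is instantaneous, noise-calibrated and linear", {
  lf <- make_toy_leadfield(19, 1, seed = 1)
  n <- 128 * 40
  # one active region, zero noise: coherency of every sensor pair is real
  x <- matrix(0, 68, n)
  x[5, ] <- bandlimited_noise(n, 8, 10, 128)
  rec <- project_to_sensors(x, lf, sensor_noise_sd = 0, seed = 1, fs = 128)
  ep <- epoch_recording(rec, 4)
  coh <- coherency(cross_spectra(ep$epochs, fs = 128, fmax = 45))
  expect_lt(max(abs(Im(coh$C)), na.rm = TRUE), 0.05)
  # exact linear image with zero noise
  expect_equal(rec$data, lf$gain %*% x, ignore_attr = TRUE)
  # zero sources, unit noise: sensor variance about 1
  rec2 <- project_to_sensors(matrix(0, 68, n), lf, sensor_noise_sd = 1,
                             seed = 2, fs = 128)
  expect_equal(mean(apply(rec2$data, 1, var)), 1, tolerance = 0.05)
  expect_error(project_to_sensors(matrix(0, 10, 100), lf),
               "must match")
})

test_that("artifact injection annotates events and is a seeded no-op at rate 0", {
  lf <- make_toy_leadfield(19, 1, seed = 1)
  x <- simulate_roi_signals(simulation_truth(), n_rois = 68, fs = 128,
                            duration = 30, seed = 5)
  rec <- project_to_sensors(x, lf, 1, seed = 5, fs = 128)
  out0 <- inject_artifacts(rec, events_per_minute = 0)
  expect_identical(out0$recording$data, rec$data)
  expect_equal(nrow(out0$annotations), 0)
  outa <- inject_artifacts(rec, kinds = "blink", events_per_minute = 4,
                           blink_amplitude = 400, seed = 9)
  outb <- inject_artifacts(rec, kinds = "blink", events_per_minute = 4,
                           blink_amplitude = 400, seed = 9)
  expect_identical(outa$annotations, outb$annotations)
  expect_true(all(outa$annotations$kind == "blink"))
  expect_error(inject_artifacts(rec, kinds = "spaceship"), "unknown")
})

test_that("blink artifacts are later rejected by the amplitude rule", {
  lf <- make_toy_leadfield(19, 1, seed = 1)
  x <- simulate_roi_signals(simulation_truth(), n_rois = 68, fs = 128,
                            duration = 40, seed = 6)
  rec <- project_to_sensors(x, lf, 1, seed = 6, fs = 128)
  out <- inject_artifacts(rec, kinds = "blink", events_per_minute = 1.5,
                          blink_amplitude = 400, seed = 2)
  ep <- reject_bad_epochs(epoch_recording(out$recording, 4),
                          amplitude_threshold = 100)
  rep <- ep$rejection_report
  # every annotated blink lies inside a rejected epoch
  for (i in seq_len(nrow(out$annotations))) {
    hit <- floor(out$annotations$start[i] / 4) + 1
    expect_false(rep$kept[hit])
    expect_equal(rep$reason[hit], "amplitude")
  }
})

test_that("permuted-block randomization balances within complete blocks", {
  a <- permuted_block_randomize(paste0("s", 1:6), rep("C1", 6),
                                block_sizes = 3, seed = 4)
  expect_equal(unname(table(a)), rep(2L, 3), ignore_attr = TRUE)
  # 152 subjects across 8 centers: totals within worst-case partial blocks
  ids <- paste0("s", 1:152)
  ctr <- rep(paste0("C", 1:8), length.out = 152)
  for (s in 1:5) {
    a <- permuted_block_randomize(ids, ctr, seed = s)
    expect_true(all(table(a) >= 48 & table(a) <= 54))
    expect_length(a, 152)              # a permutation: everyone assigned once
  }
  a1 <- permuted_block_randomize(ids, ctr, seed = 11)
  a2 <- permuted_block_randomize(ids, ctr, seed = 11)
  expect_identical(a1, a2)
  expect_error(permuted_block_randomize(character(), character()), "empty")
})

test_that("cohort simulation applies the stated missingness and determinism", {
  truth <- default_truth(missing_rate = 0.3)
  co <- simulate_cohort(30, truth, fs = 128, duration = 8, seed = 21)
  co2 <- simulate_cohort(30, truth, fs = 128, duration = 8, seed = 21)
  expect_identical(co$table, co2$table)
  n_missing <- sum(co$table$eeg_missing_end)
  # binomial(90, 0.3): mean 27, sd 4.35
  expect_gt(n_missing, 27 - 3 * 4.35)
  expect_lt(n_missing, 27 + 3 * 4.35)
  expect_equal(unname(table(co$table$arm)), rep(30L, 3), ignore_attr = TRUE)
  # follow-up recording of a missing subject is NULL
  miss <- co$table$subject[co$table$eeg_missing_end][1]
  if (!is.na(miss)) expect_null(cohort_recording(co, miss, "end"))
  expect_error(simulate_cohort(30, default_truth(group_effect = 0.9),
                               fs = 128, duration = 8, seed = 1),
               "above 1")
})

test_that("cohort recordings are deterministic and visit-specific", {
  co <- simulate_cohort(2, default_truth(missing_rate = 0), fs = 128,
                        duration = 8, seed = 3)
  r1 <- cohort_recording(co, "S001", "baseline")
  r2 <- cohort_recording(co, "S001", "baseline")
  expect_identical(r1$data, r2$data)
  r3 <- cohort_recording(co, "S001", "end")
  expect_false(identical(r1$data, r3$data))
})

test_that("planted alpha1 iCoh increases with coupling strength", {
  lf <- make_toy_leadfield(19, 1, seed = 1)
  inv <- build_inverse(lf)
  strengths <- c(0, 0.3, 0.6, 0.9)
  means <- sapply(strengths, function(s) {
    vals <- sapply(1:10, function(k) {
      edges <- data.frame(source = 30, target = 64, band = "alpha1",
                          lag_seconds = 0.025, strength = s)
      truth <- simulation_truth(coupling_edges = edges)
      x <- simulate_roi_signals(truth, n_rois = 68, fs = 128,
                                duration = 30, seed = 40 + k)
      rec <- project_to_sensors(x, lf, 1, seed = 50 + k, fs = 128)
      ep <- epoch_recording(bandpass_filter(rec, 0.5, 45), 4)
      roi <- aggregate_rois(apply_inverse(ep, inv), inv)
      coh <- coherency(cross_spectra(roi, fs = 128, fmax = 10))
      imaginary_coherence(coh, bands = "alpha1")$alpha1[30, 64]
    })
    mean(vals)
  })
  expect_true(all(diff(means) > 0))
})

test_that("MAR-by-age missingness targets older subjects", {
  truth <- default_truth(missing_rate = 0.3, missing_mechanism = "MAR-age")
  miss_age <- obs_age <- numeric(0)
  for (s in 1:6) {
    co <- simulate_cohort(20, truth, fs = 128, duration = 8, seed = 60 + s)
    miss_age <- c(miss_age, co$table$age[co$table$eeg_missing_end])
    obs_age <- c(obs_age, co$table$age[!co$table$eeg_missing_end])
  }
  expect_gt(mean(miss_age), mean(obs_age) + 1)
})
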