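test_that("spectral responses peak in each fluorophore's own channel", {
  optics <- default_optics()
  panel <- default_panel(optics)
  expect_identical(unname(primary_channels(panel, optics)["mCherry"]),
                   "561-611/31")
  expect_identical(unname(primary_channels(panel, optics)["sYFP2"]),
                   "488-528/46")
  expect_identical(unname(primary_channels(panel, optics)["mTagBFP"]),
                   "405-456/51")
  # frozen calibration: primary-channel median signal is 5000 FI
  for (f in panel)
    expect_equal(f$brightness * max(channel_response(f, optics)), 5000)
})

test_that("spec constructors enforce their invariants", {
  expect_error(fluorophore_spec("x", 600, 500), "Stokes")
  expect_error(strain_spec("x", c("mCherry", "sYFP2", "mTagBFP")),
               "at most two")
  expect_error(strain_spec("x", "GFPmut3"), "unknown fluorophore")
  expect_error(noise_model(expr_gsd = 0.5), "expr_gsd")
  expect_error(noise_model(doublet_rate = 1.5), "rates")
  expect_error(simulate_events(strain_spec("R", "mCherry"), 0), "n must")
  expect_error(
    simulate_events(strain_spec("R", "mCherry"), 10,
                    panel = default_panel()["sYFP2"]),
    "not in panel")
})

test_that("unlabelled blue tail matches the analytic log-normal oracle", {
  # oracle: P(autofluor > 450) for a log-normal with median 80, GSD 2.2
  p_blue <- pnorm(log(450 / 80) / log(2.2), lower.tail = FALSE)
  expect_equal(p_blue, 0.014240, tolerance = 1e-4)  # frozen from the oracle
  ev <- simulate_events(strain_spec("U"), 10000, noise = clean_noise())
  lab <- gate_chain(ev, gate_all())
  frac <- colMeans(lab$colours[lab$in_singlets, , drop = FALSE])
  se3 <- 3 * sqrt(p_blue * (1 - p_blue) / sum(lab$in_singlets))
  expect_lt(abs(frac[["Blue"]] - p_blue), se3 + 1e-3)
  # yellow/red tails are orders of magnitude smaller
  expect_lt(frac[["Yellow"]], 0.005)
  expect_lt(frac[["Red"]], 0.005)
})

test_that("noise-free single-fluorophore events are degenerate", {
  spec <- strain_spec("R", "mCherry")
  noise <- noise_model(expr_gsd = 1, autofluor = no_autofluor(),
                       doublet_rate = 0, debris_rate = 0, seed = 1)
  ev <- simulate_events(spec, 50, noise = noise)
  red <- ev[["561-611/31"]]
  expect_true(all(red == red[1]))
  expect_gt(red[1], 550)
  expect_true(all(ev[["488-528/46"]] == 0))
  expect_true(all(ev[["405-456/51"]] == 0))
})

test_that("generators are bit-identical under the same seed", {
  spec <- strain_spec("RY", c("mCherry", "sYFP2"))
  a <- simulate_events(spec, 500, noise = noise_model(seed = 42))
  b <- simulate_events(spec, 500, noise = noise_model(seed = 42))
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_events(spec, 500, noise = noise_model(seed = 43))))
  m1 <- simulate_mixture(dfm_strains(), rep(1 / 6, 6), 600, seed = 7)
  m2 <- simulate_mixture(dfm_strains(), rep(1 / 6, 6), 600, seed = 7)
  expect_identical(m1, m2)
  b1 <- simulate_root_background(200, root_noise_model(seed = 9))
  b2 <- simulate_root_background(200, root_noise_model(seed = 9))
  expect_identical(b1, b2)
})

test_that("mixture composition follows the requested proportions", {
  specs <- dfm_strains()
  mix <- simulate_mixture(specs, rep(1 / 6, 6), 60000, seed = 3841)
  counts <- table(mix$truth)
  sd3 <- 3 * sqrt(60000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 10000) <= sd3))
  expect_equal(nrow(mix), 60000)

  one <- simulate_mixture(specs["R"], 1, 100, seed = 1)
  expect_true(all(one$truth == "R"))
  zero <- simulate_mixture(specs[c("R", "Y", "B")], c(0.5, 0.5, 0), 400,
                           seed = 1)
  expect_false("B" %in% zero$truth)

  expect_error(simulate_mixture(specs, rep(1 / 6, 5), 100), "length")
  expect_error(simulate_mixture(specs, c(rep(0.4, 2), rep(0.1, 3), -0.1),
                                100), "negative")
  expect_error(simulate_mixture(specs, rep(0.2, 6), 100), "sum to 1")
})

test_that("root background is blue-dominated debris", {
  ev <- simulate_root_background(10000, root_noise_model("pea", seed = 3841))
  expect_true(all(ev$truth == "background"))
  lab <- gate_chain(ev, gate_all())
  frac <- colMeans(lab$colours[lab$in_singlets, , drop = FALSE])
  expect_gt(frac[["Blue"]], frac[["Red"]])
  expect_gt(frac[["Blue"]], frac[["Yellow"]])

  silent <- noise_model(expr_gsd = 1, autofluor = no_autofluor(),
                        doublet_rate = 0, debris_rate = 0, seed = 1)
  ev0 <- simulate_root_background(500, silent)
  lab0 <- gate_chain(ev0, gate_all())
  expect_equal(sum(lab0$colours[lab0$in_singlets, ]), 0)
  expect_error(simulate_root_background(0), "n must")
})

test_that("growth generator doubles every mgt in early exponential phase", {
  gc <- simulate_growth_curve(mgt = 3.4, lag = 2, od0 = 1e-6, od_max = 10,
                              dt = 0.1, t_end = 30, noise_sd = 0, blank = 0)
  i <- which(gc$t >= 3 & gc$t <= 6)          # od << od_max here
  j <- vapply(i, function(k) which.min(abs(gc$t - (gc$t[k] + 3.4))),
              integer(1))
  expect_equal(gc$od[j] / gc$od[i], rep(2, length(i)), tolerance = 1e-6)

  flat <- simulate_growth_curve(mgt = 1, od0 = 0.3, od_max = 0.3,
                                noise_sd = 0, blank = 0.05)
  expect_true(all(flat$od == 0.35))

  g0 <- simulate_growth_curve(mgt = 2, lag = 0, od0 = 0.01, noise_sd = 0,
                              blank = 0)
  expect_equal(g0$od[1], 0.01, tolerance = 1e-12)
  expect_error(simulate_growth_curve(mgt = -1), "mgt")
  expect_error(simulate_growth_curve(mgt = 1, dt = 0), "dt")
})

test_that("noise-free log growth is linear with slope ln2/mgt", {
  for (mgt in c(1.5, 3.4)) {
    gc <- simulate_growth_curve(mgt = mgt, lag = 1, od0 = 1e-4,
                                od_max = 50, dt = 0.25, t_end = 12,
                                noise_sd = 0, blank = 0)
    i <- gc$t >= 2 & gc$t <= 8
    fit <- lm(log(gc$od[i]) ~ gc$t[i])
    expect_equal(unname(coef(fit)[2]), log(2) / mgt, tolerance = 1e-3)
    expect_gt(summary(fit)$r.squared, 0.999999)
  }
})

test_that("make_junction encodes offset and duplication ground truth", {
  gl <- paste0(random_dna(57, seed = 1), "TAA")
  dn <- random_dna(50, seed = 2)
  tn <- random_dna(30, seed = 3)
  jr <- make_junction(gl, dn, offset = 25, dup_len = 5, tn7r_seq = tn)
  expect_identical(jr$truth_dup, substring(dn, 21, 25))
  expect_identical(jr$read_seq, paste0(gl, substring(dn, 1, 25), tn))
  expect_identical(jr$truth_offset, 25)

  j0 <- make_junction(gl, dn, offset = 0, dup_len = 0, tn7r_seq = tn)
  expect_identical(j0$truth_dup, "")
  expect_identical(j0$read_seq, paste0(gl, tn))

  for (off in c(24, 26))
    expect_identical(
      make_junction(gl, dn, offset = off, tn7r_seq = tn)$truth_offset, off)

  expect_error(make_junction(gl, dn, offset = 60, tn7r_seq = tn),
               "exceeds downstream")
  expect_error(make_junction(gl, dn, offset = 3, dup_len = 5,
                             tn7r_seq = tn), "dup_len")
  expect_error(make_junction(random_dna(30, seed = 4), dn, offset = 10,
                             tn7r_seq = tn), "stop codon")
})
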