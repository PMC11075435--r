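test_that("events_to_emL handles volume and rate x time metadata", {
  m_vol <- sample_meta("s", analysed_volume_mL = 0.1, root_mass_g = 0.5)
  expect_equal(events_to_emL(1000, m_vol), 10000)
  expect_equal(events_to_emL(0, m_vol), 0)
  # 3.66 uL/min for 10 min analyses 0.0366 mL; 366 events -> 10,000 emL
  m_rt <- sample_meta("s", acquisition_time_min = 10, root_mass_g = 0.5)
  expect_equal(events_to_emL(366, m_rt), 10000)
  # both or neither acquisition descriptions are rejected
  expect_error(sample_meta("s", root_mass_g = 1), "exactly one")
  expect_error(sample_meta("s", analysed_volume_mL = 0.1,
                           acquisition_time_min = 5), "exactly one")
  expect_error(sample_meta("s", analysed_volume_mL = 0), "> 0")
})

test_that("emL_to_egr scales by harvest volume over root mass", {
  m <- sample_meta("s", analysed_volume_mL = 0.1, harvest_volume_mL = 25,
                   root_mass_g = 0.5)
  expect_equal(emL_to_egr(1000, m), 50000)
  expect_equal(emL_to_egr(0, m), 0)
  m2 <- sample_meta("s", analysed_volume_mL = 0.1, harvest_volume_mL = 25,
                    root_mass_g = 1.0)
  expect_equal(emL_to_egr(1000, m2), emL_to_egr(1000, m) / 2)
  expect_error(emL_to_egr(1, sample_meta("s", analysed_volume_mL = 0.1)),
               "root_mass_g")
})

test_that("unit chain is linear and invariant to acquisition splitting", {
  meta_full <- sample_meta("s", analysed_volume_mL = 0.2, root_mass_g = 0.4)
  counts <- c(120, 480, 600)
  egr_full <- emL_to_egr(events_to_emL(sum(counts), meta_full), meta_full)
  # three sub-acquisitions of one third the volume each
  meta_sub <- sample_meta("s", analysed_volume_mL = 0.2 / 3,
                          root_mass_g = 0.4)
  emL_sub <- mean(events_to_emL(counts, meta_sub))
  expect_equal(emL_to_egr(emL_sub, meta_sub), egr_full)
  # linearity in count
  expect_equal(events_to_emL(7 * 120, meta_full),
               7 * events_to_emL(120, meta_full))
})

test_that("background subtraction clamps at zero and flags", {
  samples <- data.frame(
    sample_id = "a", plant = "pea",
    population = c("R", "Y"), egr = c(1e6, 1e5))
  background <- data.frame(
    plant = "pea", population = c("R", "R", "Y"), egr = c(1e5, 3e5, 2e5))
  out <- subtract_background(samples, background)
  expect_equal(out$egr_corrected, c(1e6 - 2e5, 0))
  expect_equal(out$below_background, c(FALSE, TRUE))
  # missing key is a hard error, not a silent zero
  bad <- data.frame(sample_id = "a", plant = "barley", population = "R",
                    egr = 1)
  expect_error(subtract_background(bad, background), "barley/R")
})

test_that("self-subtraction of simulated background centres on zero", {
  cfg <- gating_config()
  tabs <- lapply(1:3, function(j) {
    ev <- simulate_root_background(5000, root_noise_model(seed = 100 + j))
    abundance_table(gate_chain(ev, cfg),
                    sample_meta(paste0("bg", j), analysed_volume_mL = 0.1,
                                root_mass_g = 0.5, replicate = j))
  })
  all_bg <- do.call(rbind, tabs)
  out <- subtract_background(all_bg, all_bg)
  # signed deviations from the pooled mean cancel exactly per population
  for (p in unique(all_bg$population)) {
    raw <- all_bg$egr[all_bg$population == p] -
      mean(all_bg$egr[all_bg$population == p])
    expect_equal(mean(raw), 0)
  }
  expect_true(all(out$egr_corrected >= 0))
  # order of populations does not change the result
  set.seed(1)
  perm <- sample(nrow(all_bg))
  out2 <- subtract_background(all_bg[perm, ], all_bg)
  expect_equal(out2$egr_corrected[order(perm)], out$egr_corrected)
})

test_that("to_relative normalises the six populations per sample", {
  tab <- data.frame(
    sample_id = rep(c("a", "b"), each = 6),
    population = rep(c("R", "Y", "B", "RY", "RB", "YB"), 2),
    egr_corrected = c(rep(2e5, 6), c(7e5, 0, 0, 0, 0, 0)))
  rel <- to_relative(tab)
  expect_equal(rel$rel[rel$sample_id == "a"], rep(1 / 6, 6))
  expect_equal(rel$rel[rel$sample_id == "b"], c(1, 0, 0, 0, 0, 0))
  # scalar rescaling leaves fractions unchanged
  tab2 <- tab
  tab2$egr_corrected <- tab2$egr_corrected * 17
  expect_equal(to_relative(tab2)$rel, rel$rel)
  # all-zero sample flagged undefined, not dropped
  tab$egr_corrected[tab$sample_id == "b"] <- 0
  rel0 <- to_relative(tab)
  expect_true(all(rel0$undefined[rel0$sample_id == "b"]))
  expect_true(all(is.na(rel0$rel[rel0$sample_id == "b"])))
})

test_that("constant absolute abundance falls in relative terms as others grow", {
  tab <- expand.grid(population = c("R", "Y"), timepoint = c(1, 2, 3),
                     stringsAsFactors = FALSE)
  tab$sample_id <- paste0("t", tab$timepoint)
  tab$egr_corrected <- ifelse(tab$population == "R", 1e5,
                              1e5 * 2^tab$timepoint)
  rel <- to_relative(tab)
  r_rel <- rel$rel[rel$population == "R"][order(tab$timepoint[tab$population == "R"])]
  expect_true(all(diff(r_rel) < 0))
})
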