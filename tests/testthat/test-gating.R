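test_that("combined-population mapping covers all 8 flag combinations", {
  flags <- expand.grid(Red = c(TRUE, FALSE), Yellow = c(TRUE, FALSE),
                       Blue = c(TRUE, FALSE))
  m <- as.matrix(flags)
  got <- as.character(assign_combined(m))
  want <- apply(flags, 1, function(f) {
    k <- paste0(if (f["Red"]) "R" else "", if (f["Yellow"]) "Y" else "",
                if (f["Blue"]) "B" else "")
    if (k %in% c("R", "Y", "B", "RY", "RB", "YB")) k else "Unassigned"
  })
  expect_identical(got, unname(want))
  # triple-positive and all-negative both land in Unassigned
  expect_identical(got[1], "Unassigned")      # RYB
  expect_identical(got[8], "Unassigned")      # none
  # NA flags (non-singlets) map to NotSinglet
  expect_identical(as.character(assign_combined(
    matrix(NA, 1, 3, dimnames = list(NULL, c("Red", "Yellow", "Blue"))))),
    "NotSinglet")
})

test_that("colour thresholds are strict 'above N FI units'", {
  ev <- tiny_events(rbind(
    c(0,   0,   600),    # red positive
    c(0,   0,   550),    # exactly at threshold: negative
    c(451, 501, 0),      # blue + yellow positive
    c(450, 500, 550)))   # all exactly at threshold: negative
  lab <- gate_chain(ev, gate_all())
  expect_equal(unname(lab$colours[, "Red"]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(lab$colours[, "Yellow"]),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(lab$colours[, "Blue"]), c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(as.character(lab$combined),
                   c("R", "Unassigned", "YB", "Unassigned"))
})

test_that("singlet gate uses strict FSC > 0 and aspect-ratio > 0.4", {
  ev <- tiny_events(matrix(0, 4, 3), fsc = c(1, 1, 0, 1),
                    ar = c(0.4, 0.41, 0.9, 0.39))
  in_b <- rep(TRUE, 4)
  expect_equal(gate_singlets(ev, in_b, gating_config()),
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("density bacteria gate keeps the concentrated cluster", {
  set.seed(11)
  n_cell <- 9500; n_deb <- 500
  ev <- data.frame(
    fsc = c(rlnorm(n_cell, log(2e4), 0.2), rlnorm(n_deb, log(100), 1.5)),
    ssc = c(rlnorm(n_cell, log(1e4), 0.2), rlnorm(n_deb, log(50), 1.5)),
    ar_ssc = rep(0.9, n_cell + n_deb))
  for (k in chan_keys()) ev[[k]] <- 0
  ev <- event_table(ev, chan_keys())
  in_b <- gate_bacteria(ev, gating_config(density_fraction = 0.95))
  kept_cells <- mean(in_b[seq_len(n_cell)])
  kept_debris <- mean(in_b[n_cell + seq_len(n_deb)])
  expect_gte(kept_cells, 0.99)
  expect_lte(kept_debris, 0.5)

  # fraction 1.0 retains everything; a polygon over the full range agrees
  expect_true(all(gate_bacteria(ev, gating_config(density_fraction = 1))))
  rng <- cbind(range(log10(ev$fsc)) + c(-1, 1),
               range(log10(ev$ssc)) + c(-1, 1))
  poly <- rbind(c(rng[1, 1], rng[1, 2]), c(rng[2, 1], rng[1, 2]),
                c(rng[2, 1], rng[2, 2]), c(rng[1, 1], rng[2, 2]))
  expect_true(all(gate_bacteria(
    ev, gating_config("polygon", polygon = poly))))
})

test_that("non-positive scatter is excluded with a warning count", {
  ev <- tiny_events(matrix(0, 3, 3), fsc = c(1000, 0, 1000))
  expect_warning(in_b <- gate_bacteria(ev, gate_all()), "non-positive")
  expect_false(in_b[2])
  expect_equal(attr(in_b, "n_nonpositive_scatter"), 1)
  expect_error(gate_bacteria(ev[0, ], gate_all()), "empty")
})

test_that("full chain equals exhaustive per-event oracle on a tiny fixture", {
  set.seed(21)
  n <- 20
  int <- cbind(runif(n, 0, 900), runif(n, 0, 900), runif(n, 0, 900))
  ev <- tiny_events(int, fsc = runif(n, 0, 2000), ar = runif(n))
  cfg <- gate_all()
  lab <- gate_chain(ev, cfg)
  keys <- chan_keys()
  for (i in seq_len(n)) {
    in_s <- ev$fsc[i] > 0 && ev$ar_ssc[i] > 0.4
    expect_identical(lab$in_singlets[i], in_s)
    if (!in_s) {
      expect_identical(as.character(lab$combined[i]), "NotSinglet")
      next
    }
    r <- ev[[keys[3]]][i] > 550
    y <- ev[[keys[2]]][i] > 500
    b <- ev[[keys[1]]][i] > 450
    expect_identical(unname(lab$colours[i, ]), c(r, y, b))
    want <- paste0(if (r) "R" else "", if (y) "Y" else "",
                   if (b) "B" else "")
    if (!want %in% c("R", "Y", "B", "RY", "RB", "YB")) want <- "Unassigned"
    expect_identical(as.character(lab$combined[i]), want)
  }
})

test_that("partition invariant: combined classes tile the singlets", {
  for (seed in c(1, 2, 3)) {
    mix <- simulate_mixture(dfm_strains(include_unlabelled = TRUE),
                            rep(1 / 7, 7), 5000, seed = seed)
    lab <- gate_chain(mix)
    tab <- table(lab$combined)
    expect_equal(
      sum(tab[c("R", "Y", "B", "RY", "RB", "YB", "Unassigned")]),
      sum(lab$in_singlets))
    expect_equal(sum(tab), nrow(mix))
  }
})

test_that("raising a colour threshold never grows that population", {
  ev <- simulate_events(strain_spec("RB", c("mCherry", "mTagBFP")), 3000,
                        noise = clean_noise(seed = 5))
  sizes <- vapply(c(100, 300, 550, 1000, 5000, 2e4), function(thr) {
    ct <- default_colour_thresholds()
    ct$threshold[ct$colour == "Red"] <- thr
    lab <- gate_chain(ev, gating_config(colour_thresholds = ct))
    sum(lab$colours[, "Red"], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("gating is deterministic and idempotent", {
  ev <- simulate_events(strain_spec("Y", "sYFP2"), 2000)
  l1 <- gate_chain(ev)
  l2 <- gate_chain(ev)
  expect_identical(l1, l2)
})

test_that("zero-noise simulation is demultiplexed with 100% accuracy", {
  noise <- noise_model(expr_gsd = 1, autofluor = no_autofluor(),
                       doublet_rate = 0, debris_rate = 0, seed = 2)
  specs <- dfm_strains()
  mix <- simulate_mixture(specs, rep(1 / 6, 6), 1200, noise = noise)
  lab <- gate_chain(mix, gate_all())
  sc <- score_assignments(lab, mix$truth)
  expect_equal(sc$overall_accuracy, 1)
  expect_true(all(diag(sc$matrix[c("R", "Y", "B", "RY", "RB", "YB"),
                                 c("R", "Y", "B", "RY", "RB", "YB")]) ==
                    rowSums(sc$matrix)[c("R", "Y", "B", "RY", "RB", "YB")]))
})

test_that("confusion matrix equals a hand-counted 12-event fixture", {
  # 2 events per strain; one Y event deliberately crosses the blue
  # threshold (misassigned YB), everything else clean
  int <- rbind(
    c(0, 0, 600),   c(0, 0, 700),      # R, R
    c(0, 600, 0),   c(500, 600, 0),    # Y, YB (miscalled)
    c(500, 0, 0),   c(600, 0, 0),      # B, B
    c(0, 600, 600), c(0, 550, 700),    # RY, RY
    c(500, 0, 600), c(700, 0, 800),    # RB, RB
    c(500, 600, 0), c(460, 510, 0))    # YB, YB
  truth <- rep(c("R", "Y", "B", "RY", "RB", "YB"), each = 2)
  ev <- tiny_events(int, truth = truth)
  lab <- gate_chain(ev, gate_all())
  sc <- score_assignments(lab, ev$truth)
  expect_equal(sc$n_singlets, 12)
  cm <- sc$matrix
  expect_equal(unname(cm["R", "R"]), 2)
  expect_equal(unname(cm["Y", "Y"]), 1)
  expect_equal(unname(cm["Y", "YB"]), 1)
  expect_equal(unname(cm["B", "B"]), 2)
  expect_equal(unname(cm["RY", "RY"]), 2)
  expect_equal(unname(cm["RB", "RB"]), 2)
  expect_equal(unname(cm["YB", "YB"]), 2)
  expect_equal(sum(cm), 12)
  expect_equal(unname(sc$per_class_accuracy["Y"]), 0.5)
  expect_equal(sc$overall_accuracy, 11 / 12)
  expect_error(score_assignments(lab, truth[-1]), "length")
})
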