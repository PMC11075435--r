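#' Construct / validate a per-event table
#'
#' The event table is the central container: one row per flow-cytometry
#' event with forward scatter (`fsc`), side scatter (`ssc`), the
#' aspect-ratio of SSC (`ar_ssc`, in \[0, 1\]), one fluorescence-intensity
#' column per detection channel (named by channel key, e.g. "561-611/31"),
#' and an optional ground-truth strain label (`truth`).
#'
#' @param df Data frame with the columns above.
#' @param channel_keys Character vector of intensity column names.
#' @return `df` with class `event_table` and a `channel_keys` attribute.
#' @export
event_table <- function(df, channel_keys) {
  need <- c("fsc", "ssc", "ar_ssc", channel_keys)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_dfm("event table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$ar_ssc < 0 | df$ar_ssc > 1))
    stop_dfm("ar_ssc must lie in [0, 1]")
  for (k in channel_keys)
    if (any(df[[k]] < 0)) stop_dfm("negative intensity in channel ", k)
  structure(df, class = c("event_table", "data.frame"),
            channel_keys = channel_keys)
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", nrow(x), " events, channels: ",
      paste(attr(x, "channel_keys"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

# Relative channel responses with a detector noise floor: responses below
# `floor` times the fluorophore's peak response are indistinguishable from
# zero on the instrument and are clipped, so negligible spectral overlap
# does not create phantom sub-FI signal.
.responses <- function(panel, optics, floor = 1e-3) {
  resp <- vapply(panel, channel_response, numeric(nrow(optics$channels)),
                 optics = optics)
  resp <- matrix(resp, nrow = nrow(optics$channels),
                 dimnames = list(optics$channels$key, names(panel)))
  for (j in seq_len(ncol(resp)))
    resp[resp[, j] < floor * max(resp[, j]), j] <- 0
  resp
}

# Core singlet generator; no seeding, no doublets/debris.
.singlet_draws <- function(spec, n, optics, panel, noise) {
  keys <- optics$channels$key
  resp <- .responses(panel, optics)
  sig <- matrix(0, n, length(keys), dimnames = list(NULL, keys))
  for (f in spec$expressed) {
    fl <- panel[[f]]
    L <- rlnorm_mg(n, 1, noise$expr_gsd)
    per_ch <- fl$brightness * resp[, f] * spec$expression_scale
    sig <- sig + outer(L, per_ch)
  }
  af <- noise$autofluor
  for (k in keys) {
    i <- match(k, af$key)
    if (!is.na(i)) sig[, k] <- sig[, k] + rlnorm_mg(n, af$median[i], af$gsd[i])
  }
  data.frame(
    fsc = rlnorm_mg(n, spec$fsc_params[1], spec$fsc_params[2]),
    ssc = rlnorm_mg(n, spec$ssc_params[1], spec$ssc_params[2]),
    ar_ssc = stats::rbeta(n, spec$ar_params[1], spec$ar_params[2]),
    sig, check.names = FALSE, stringsAsFactors = FALSE)
}

.simulate_events_core <- function(spec, n, optics, panel, noise) {
  keys <- optics$channels$key
  type <- sample(c("singlet", "doublet", "debris"), n, replace = TRUE,
                 prob = c(1 - noise$doublet_rate - noise$debris_rate,
                          noise$doublet_rate, noise$debris_rate))
  n_s <- sum(type == "singlet"); n_d <- sum(type == "doublet")
  n_b <- sum(type == "debris")
  out <- vector("list", 3)
  draws <- .singlet_draws(spec, n_s + 2 * n_d, optics, panel, noise)
  out[[1]] <- draws[seq_len(n_s), , drop = FALSE]
  if (n_d > 0) {
    # doublet = channel-wise sum of two singlets, aspect-ratio below the
    # 0.4 singlet cut so the singlet gate is consequential
    a <- draws[n_s + seq_len(n_d), , drop = FALSE]
    b <- draws[n_s + n_d + seq_len(n_d), , drop = FALSE]
    d <- a
    for (col in c("fsc", "ssc", keys)) d[[col]] <- a[[col]] + b[[col]]
    d$ar_ssc <- stats::runif(n_d, 0, 0.4)
    out[[2]] <- d
  }
  if (n_b > 0) {
    af <- noise$autofluor
    sig <- matrix(0, n_b, length(keys), dimnames = list(NULL, keys))
    for (k in keys) {
      i <- match(k, af$key)
      if (!is.na(i))
        sig[, k] <- rlnorm_mg(n_b, af$median[i] / 2, af$gsd[i])
    }
    out[[3]] <- data.frame(
      fsc = rlnorm_mg(n_b, 300, 2.5), ssc = rlnorm_mg(n_b, 150, 2.5),
      ar_ssc = stats::runif(n_b), sig,
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[sample.int(nrow(res)), , drop = FALSE]
  rownames(res) <- NULL
  res$truth <- spec$strain_id
  event_table(res, keys)
}

#' Simulate flow-cytometry events for one strain
#'
#' Generates `n` events for a DFM strain.  Expected fluorescence in channel
#' c sums, over expressed fluorophores, brightness times the Gaussian
#' excitation/emission channel response (see [channel_response()]), scaled
#' by `expression_scale` and a per-event log-normal expression factor
#' (geometric SD `noise$expr_gsd`), plus an additive per-channel
#' autofluorescence draw.  A fraction of events are doublets (channel-wise
#' sums of two singlets with aspect-ratio below 0.4) or low-scatter debris.
#' Fully deterministic given `noise$seed`.
#'
#' @param spec A [strain_spec()].
#' @param n Number of events (>= 1).
#' @param optics An [optical_config()].
#' @param panel Named list of [fluorophore_spec()] covering
#'   `spec$expressed`.
#' @param noise A [noise_model()].
#' @return An [event_table()] with `truth = spec$strain_id`.
#' @export
#' @examples
#' ev <- simulate_events(strain_spec("R", "mCherry"), 1000)
#' summary(ev[["561-611/31"]])
simulate_events <- function(spec, n, optics = default_optics(),
                            panel = default_panel(optics),
                            noise = noise_model()) {
  if (!is.numeric(n) || n < 1) stop_dfm("n must be >= 1")
  miss <- setdiff(spec$expressed, names(panel))
  if (length(miss))
    stop_dfm("fluorophore(s) not in panel: ", paste(miss, collapse = ", "))
  with_seed(noise$seed,
            .simulate_events_core(spec, as.integer(n), optics, panel, noise))
}

#' Simulate a mixed-strain sample
#'
#' Per-strain event counts are drawn multinomially from `proportions`;
#' truth labels are preserved and the rows shuffled.
#'
#' @param specs List of [strain_spec()].
#' @param proportions Numeric vector summing to 1, same length as `specs`.
#' @param n Total number of events.
#' @inheritParams simulate_events
#' @param seed Integer seed (defaults to `noise$seed`).
#' @return An [event_table()].
#' @export
#' @examples
#' mix <- simulate_mixture(dfm_strains(), rep(1/6, 6), 6000)
#' table(mix$truth)
simulate_mixture <- function(specs, proportions, n,
                             optics = default_optics(),
                             panel = default_panel(optics),
                             noise = noise_model(), seed = noise$seed) {
  if (length(specs) != length(proportions))
    stop_dfm("specs and proportions must have the same length")
  if (any(proportions < 0)) stop_dfm("negative proportion")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_dfm("proportions must sum to 1")
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, proportions))
    parts <- lapply(seq_along(specs), function(i) {
      if (counts[i] == 0) return(NULL)
      .simulate_events_core(specs[[i]], counts[i], optics, panel, noise)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    keys <- attr(parts[[1]], "channel_keys")
    res <- do.call(rbind, lapply(parts, as.data.frame))
    res <- res[sample.int(nrow(res)), , drop = FALSE]
    rownames(res) <- NULL
    event_table(res, keys)
  })
}

#' Autofluorescence noise model for uninoculated plant roots
#'
#' Root debris autofluoresces predominantly in the blue channel (lignin and
#' suberin); medians are elevated relative to bacterial autofluorescence.
#'
#' @param plant "pea" or "barley".
#' @inheritParams noise_model
#' @return A [noise_model()].
#' @export
root_noise_model <- function(plant = c("pea", "barley"), seed = 3841) {
  plant <- match.arg(plant)
  med_blue <- switch(plant, pea = 120, barley = 100)
  noise_model(
    expr_gsd = 1,
    autofluor = data.frame(
      key    = c("405-456/51", "488-528/46", "561-611/31"),
      median = c(med_blue, 50, 45),
      gsd    = c(2.5, 2.0, 2.0),
      stringsAsFactors = FALSE),
    doublet_rate = 0, debris_rate = 0, seed = seed)
}

#' Simulate uninoculated-root background events
#'
#' Events with debris-like broad scatter and elevated blue-channel
#' autofluorescence, labelled `truth = "background"`.  These are the events
#' that survive gating in uninoculated plant samples and define the
#' background abundance subtracted from inoculated samples.
#'
#' @param n Number of events (>= 1).
#' @param noise A [noise_model()]; defaults to [root_noise_model()] for the
#'   given plant.
#' @param plant Plant identifier ("pea" or "barley").
#' @param optics An [optical_config()].
#' @return An [event_table()].
#' @export
simulate_root_background <- function(n, noise = root_noise_model(plant),
                                     plant = "pea",
                                     optics = default_optics()) {
  if (!is.numeric(n) || n < 1) stop_dfm("n must be >= 1")
  n <- as.integer(n)
  keys <- optics$channels$key
  with_seed(noise$seed, {
    af <- noise$autofluor
    sig <- matrix(0, n, length(keys), dimnames = list(NULL, keys))
    for (k in keys) {
      i <- match(k, af$key)
      if (!is.na(i)) sig[, k] <- rlnorm_mg(n, af$median[i], af$gsd[i])
    }
    res <- data.frame(
      fsc = rlnorm_mg(n, 5e3, 2.8), ssc = rlnorm_mg(n, 2.5e3, 2.8),
      ar_ssc = stats::rbeta(n, 2, 2), sig,
      check.names = FALSE, stringsAsFactors = FALSE)
    res$truth <- "background"
    event_table(res, keys)
  })
}
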