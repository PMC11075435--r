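# Shared fixture builders: all tiny, all built in code.

chan_keys <- function() default_optics()$channels$key

# Hand-specified event table; intensities given as a 3-column matrix in
# channel order (blue, yellow, red keys as in default_optics()).
tiny_events <- function(intensity, fsc = 1000, ssc = 500, ar = 0.9,
                        truth = NULL) {
  if (!is.matrix(intensity))
    intensity <- matrix(intensity, ncol = 3, byrow = TRUE)
  n <- nrow(intensity)
  df <- data.frame(fsc = rep_len(fsc, n), ssc = rep_len(ssc, n),
                   ar_ssc = rep_len(ar, n))
  keys <- chan_keys()
  for (i in 1:3) df[[keys[i]]] <- intensity[, i]
  if (!is.null(truth)) df$truth <- rep_len(truth, n)
  event_table(df, keys)
}

# Noise model with no doublets/debris (pure singlets), default optics.
clean_noise <- function(seed = 3841, ...) {
  noise_model(doublet_rate = 0, debris_rate = 0, seed = seed, ...)
}

# Zero autofluorescence table.
no_autofluor <- function() {
  af <- default_autofluor()
  af$median <- 0
  af$gsd <- 1
  af
}

gate_all <- function() gating_config(density_fraction = 1)
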