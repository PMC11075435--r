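#' Fluorophore spectral specification
#'
#' Describes one fluorescent protein by Gaussian approximations to its
#' excitation and emission spectra.  Peak positions follow the fpbase
#' reference spectra for the three proteins used for differential
#' fluorescent marking (DFM): mTagBFP (ex 399 / em 456 nm), sYFP2
#' (ex 515 / em 527 nm) and mCherry (ex 587 / em 610 nm).
#'
#' @param name Fluorophore identifier.
#' @param ex_max,em_max Excitation / emission peak wavelength (nm).
#'   `ex_max < em_max` (positive Stokes shift) is enforced.
#' @param ex_sigma,em_sigma Gaussian spectral widths (nm), > 0.
#' @param brightness Relative intensity scale (dimensionless), > 0.
#' @return An object of class `fluorophore_spec`.
#' @export
#' @examples
#' fluorophore_spec("mCherry", 587, 610)
fluorophore_spec <- function(name, ex_max, em_max,
                             ex_sigma = 30, em_sigma = 30,
                             brightness = 1) {
  if (ex_max >= em_max)
    stop_dfm("Stokes shift must be positive: ex_max < em_max for ", name)
  if (ex_sigma <= 0 || em_sigma <= 0)
    stop_dfm("spectral sigmas must be > 0")
  if (brightness <= 0) stop_dfm("brightness must be > 0")
  structure(
    list(name = name, ex_max = ex_max, em_max = em_max,
         ex_sigma = ex_sigma, em_sigma = em_sigma, brightness = brightness),
    class = "fluorophore_spec")
}

#' Instrument optical configuration
#'
#' Lasers and detection channels of the cytometer.  The default instrument
#' carries 405, 488 and 561 nm lasers with one bandpass filter each; channel
#' keys are the conventional "laser-centre/bandwidth" strings.
#'
#' @param lasers Numeric vector of laser wavelengths (nm).
#' @param channels Data frame with columns `laser` (nm), `centre` (nm),
#'   `bandwidth` (nm) and `key` (unique channel identifier).
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(lasers, channels) {
  stopifnot(is.data.frame(channels),
            all(c("laser", "centre", "bandwidth", "key") %in% names(channels)))
  if (anyDuplicated(channels$key))
    stop_dfm("channel keys must be unique")
  if (!all(channels$laser %in% lasers))
    stop_dfm("every channel must reference a configured laser")
  structure(list(lasers = lasers, channels = channels),
            class = "optical_config")
}

#' @rdname optical_config
#' @export
default_optics <- function() {
  optical_config(
    lasers = c(405, 488, 561),
    channels = data.frame(
      laser     = c(405, 488, 561),
      centre    = c(456, 528, 611),
      bandwidth = c(51, 46, 31),
      key       = c("405-456/51", "488-528/46", "561-611/31"),
      stringsAsFactors = FALSE))
}

#' Relative response of a fluorophore in each detection channel
#'
#' The response in channel c is the product of a Gaussian excitation term at
#' the channel's laser line and the emission probability mass falling inside
#' the bandpass filter:
#' \deqn{R_{f,c} = e^{-(\lambda_L - ex)^2 / (2\sigma_{ex}^2)}
#'   \left[\Phi\!\left(\frac{hi - em}{\sigma_{em}}\right) -
#'         \Phi\!\left(\frac{lo - em}{\sigma_{em}}\right)\right]}
#' This is the spillover model: a fluorophore contributes most to the
#' channel whose laser/filter pair best matches its spectra, and a small,
#' physically motivated amount elsewhere.
#'
#' @param fluor A [fluorophore_spec()].
#' @param optics An [optical_config()].
#' @return Named numeric vector of per-channel responses (keys as names).
#' @export
channel_response <- function(fluor, optics) {
  ch <- optics$channels
  lo <- ch$centre - ch$bandwidth / 2
  hi <- ch$centre + ch$bandwidth / 2
  ex <- exp(-(ch$laser - fluor$ex_max)^2 / (2 * fluor$ex_sigma^2))
  em <- stats::pnorm((hi - fluor$em_max) / fluor$em_sigma) -
        stats::pnorm((lo - fluor$em_max) / fluor$em_sigma)
  stats::setNames(ex * em, ch$key)
}

#' Default DFM fluorophore panel
#'
#' mTagBFP, sYFP2 and mCherry with Gaussian spectral parameters taken from
#' fpbase reference peaks (sigmas 30 nm).  Brightness is calibrated per
#' fluorophore so that, at `expression_scale = 1`, the median signal in the
#' fluorophore's primary channel equals `primary_median` FI units -- the
#' frozen calibration under which the gating accuracy bounds hold.
#'
#' @param optics Optical configuration used for the brightness calibration.
#' @param primary_median Target median FI in each fluorophore's primary
#'   channel (default 5000).
#' @return Named list of `fluorophore_spec` objects.
#' @export
#' @examples
#' panel <- default_panel()
#' round(channel_response(panel$mCherry, default_optics()), 5)
default_panel <- function(optics = default_optics(), primary_median = 5000) {
  base <- list(
    mTagBFP = fluorophore_spec("mTagBFP", 399, 456),
    sYFP2   = fluorophore_spec("sYFP2",   515, 527),
    mCherry = fluorophore_spec("mCherry", 587, 610))
  lapply(base, function(f) {
    r <- channel_response(f, optics)
    f$brightness <- primary_median / max(r)
    f
  })
}

#' Primary detection channel of each panel fluorophore
#'
#' @param panel List of `fluorophore_spec`.
#' @param optics An [optical_config()].
#' @return Named character vector: fluorophore name -> channel key.
#' @export
primary_channels <- function(panel, optics = default_optics()) {
  vapply(panel, function(f) {
    r <- channel_response(f, optics)
    names(r)[which.max(r)]
  }, character(1))
}
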