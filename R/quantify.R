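#' Sample metadata for absolute quantification
#'
#' Records how a root-wash sample was acquired and harvested.  Exactly one
#' of `analysed_volume_mL` or the pair (`flow_rate_uL_min`,
#' `acquisition_time_min`) must be supplied; the instrument's low-speed /
#' high-sensitivity flow rate is 3.66 uL/min and the standard harvest
#' volume is 25 mL.
#'
#' @param sample_id Sample identifier.
#' @param timepoint Timepoint (hours or days post-inoculation, caller's
#'   convention).
#' @param analysed_volume_mL Volume actually analysed (mL), or `NULL`.
#' @param flow_rate_uL_min Flow rate (uL/min; default 3.66 when rate x
#'   time is used).
#' @param acquisition_time_min Acquisition time (min), or `NULL`.
#' @param harvest_volume_mL Harvest-solution volume (mL, default 25).
#' @param root_mass_g Fresh root mass (g).
#' @param dilution_factor Explicit user dilution (default 1).
#' @param plant Plant identifier (e.g. "pea").
#' @param replicate Replicate identifier.
#' @return An object of class `sample_meta`.
#' @export
#' @examples
#' sample_meta("s1", acquisition_time_min = 10, root_mass_g = 0.5)
sample_meta <- function(sample_id, timepoint = NA,
                        analysed_volume_mL = NULL,
                        flow_rate_uL_min = 3.66,
                        acquisition_time_min = NULL,
                        harvest_volume_mL = 25, root_mass_g = NA,
                        dilution_factor = 1, plant = "pea",
                        replicate = 1L) {
  has_vol <- !is.null(analysed_volume_mL)
  has_rt <- !is.null(acquisition_time_min)
  if (has_vol == has_rt)
    stop_dfm("supply exactly one of analysed_volume_mL or ",
             "acquisition_time_min (with flow_rate_uL_min)")
  if (has_vol && analysed_volume_mL <= 0)
    stop_dfm("analysed volume must be > 0")
  if (has_rt && (flow_rate_uL_min <= 0 || acquisition_time_min <= 0))
    stop_dfm("flow rate and acquisition time must be > 0")
  if (harvest_volume_mL <= 0) stop_dfm("harvest volume must be > 0")
  structure(
    list(sample_id = sample_id, timepoint = timepoint,
         analysed_volume_mL = analysed_volume_mL,
         flow_rate_uL_min = flow_rate_uL_min,
         acquisition_time_min = acquisition_time_min,
         harvest_volume_mL = harvest_volume_mL,
         root_mass_g = root_mass_g, dilution_factor = dilution_factor,
         plant = plant, replicate = replicate),
    class = "sample_meta")
}

.analysed_volume <- function(meta) {
  if (!is.null(meta$analysed_volume_mL)) return(meta$analysed_volume_mL)
  meta$flow_rate_uL_min * meta$acquisition_time_min / 1000
}

#' Events per mL (emL)
#'
#' `emL = count * dilution_factor / analysed_volume_mL`, with the analysed
#' volume derived from flow rate x acquisition time when not given
#' directly.
#'
#' @param count Gated event count (vectorised).
#' @param meta A [sample_meta()].
#' @return Events per mL.
#' @export
#' @examples
#' events_to_emL(366, sample_meta("s", acquisition_time_min = 10))  # 10000
events_to_emL <- function(count, meta) {
  v <- .analysed_volume(meta)
  if (v <= 0) stop_dfm("analysed volume must be > 0")
  count * meta$dilution_factor / v
}

#' Events per g root (egr)
#'
#' `egr = emL * harvest_volume_mL / root_mass_g`.
#'
#' @param emL Events per mL (vectorised).
#' @param meta A [sample_meta()].
#' @return Events per g fresh root.
#' @export
emL_to_egr <- function(emL, meta) {
  if (is.na(meta$root_mass_g) || meta$root_mass_g <= 0)
    stop_dfm("root_mass_g must be > 0")
  emL * meta$harvest_volume_mL / meta$root_mass_g
}

#' Build a tidy abundance table from gated counts
#'
#' One row per combined population with `count`, `emL`, `egr` and sample
#' metadata columns.
#'
#' @param labels A `population_labels` list from [gate_chain()].
#' @param meta A [sample_meta()].
#' @param populations Which combined populations to tabulate.
#' @return Data frame of class `abundance_table`.
#' @export
abundance_table <- function(labels, meta,
                            populations = c("R", "Y", "B", "RY", "RB",
                                            "YB", "Unassigned")) {
  counts <- table(factor(labels$combined[labels$in_singlets],
                         levels = populations))
  emL <- events_to_emL(as.vector(counts), meta)
  data.frame(
    sample_id = meta$sample_id, plant = meta$plant,
    timepoint = meta$timepoint, replicate = meta$replicate,
    population = populations, count = as.vector(counts), emL = emL,
    egr = emL_to_egr(emL, meta),
    stringsAsFactors = FALSE)
}

#' Subtract uninoculated-root background abundances
#'
#' For every (plant, population) the mean background `egr` over the
#' uninoculated replicates (pooled across timepoints) is subtracted from
#' each sample's `egr`; negative results clamp to zero and raise the
#' `below_background` flag.  A sample population with no matching
#' background key is a hard error, never a silent zero.
#'
#' @param samples Abundance data frame with columns `plant`, `population`,
#'   `egr` (from [abundance_table()]).
#' @param background Abundance data frame from uninoculated plants, same
#'   columns.
#' @return `samples` with added `egr_corrected` and `below_background`
#'   columns.
#' @export
subtract_background <- function(samples, background) {
  bg <- stats::aggregate(egr ~ plant + population, data = background,
                         FUN = mean)
  key <- function(d) paste(d$plant, d$population, sep = "\r")
  idx <- match(key(samples), key(bg))
  if (anyNA(idx)) {
    missing <- unique(paste0(samples$plant, "/", samples$population)[is.na(idx)])
    stop_dfm("no background record for: ", paste(missing, collapse = ", "))
  }
  raw <- samples$egr - bg$egr[idx]
  samples$egr_corrected <- pmax(0, raw)
  samples$below_background <- raw < 0
  samples
}

#' Relative abundances within each sample
#'
#' Per sample, corrected abundances over the six combined populations are
#' normalised to fractions summing to 1.  `Unassigned` rows are excluded
#' from the denominator.  An all-zero sample is flagged (`undefined =
#' TRUE`) with `NA` fractions rather than dropped.
#'
#' @param abs_table Abundance data frame with `sample_id`, `population`
#'   and an abundance column.
#' @param value Name of the abundance column (default `"egr_corrected"`,
#'   falling back to `"egr"` when absent).
#' @return `abs_table` with `rel` and `undefined` columns.
#' @export
to_relative <- function(abs_table, value = NULL) {
  value <- value %||%
    (if ("egr_corrected" %in% names(abs_table)) "egr_corrected" else "egr")
  strains <- c("R", "Y", "B", "RY", "RB", "YB")
  keep <- abs_table$population %in% strains
  out <- abs_table
  out$rel <- NA_real_
  out$undefined <- FALSE
  for (sid in unique(out$sample_id)) {
    i <- keep & out$sample_id == sid
    tot <- sum(out[[value]][i])
    if (tot > 0) out$rel[i] <- out[[value]][i] / tot
    else out$undefined[i | (out$sample_id == sid)] <- TRUE
  }
  out
}
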