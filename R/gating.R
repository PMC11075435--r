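#' Gating configuration
#'
#' Holds every gate in the chain Bacteria -> Singlets -> colour populations
#' -> Combined populations.  Colour thresholds default to the published
#' cuts: Red = "561-611/31" above 550 FI, Yellow = "488-528/46" above 500
#' FI, Blue = "405-456/51" above 450 FI; all strict `>`.  Singlets require
#' FSC strictly above 0 and aspect-ratio of SSC strictly above 0.4.
#'
#' @param bacteria_mode "density" (deterministic grid-density gate) or
#'   "polygon" (vertex list in log10 FSC / log10 SSC space).
#' @param density_fraction Fraction of events the density gate retains,
#'   in (0, 1].
#' @param polygon Two-column matrix of vertices (log10 FSC, log10 SSC),
#'   required when `bacteria_mode = "polygon"`.
#' @param singlet_fsc_min FSC threshold, strict `>` (default 0).
#' @param singlet_ar_min Aspect-ratio threshold, strict `>` (default 0.4).
#' @param colour_thresholds Data frame with columns `colour`, `key`,
#'   `threshold`.
#' @param grid_bins Bins per axis for the density gate (default 128).
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(bacteria_mode = c("density", "polygon"),
                          density_fraction = 0.95,
                          polygon = NULL,
                          singlet_fsc_min = 0,
                          singlet_ar_min = 0.4,
                          colour_thresholds = default_colour_thresholds(),
                          grid_bins = 128) {
  bacteria_mode <- match.arg(bacteria_mode)
  if (density_fraction <= 0 || density_fraction > 1)
    stop_dfm("density_fraction must lie in (0, 1]")
  if (bacteria_mode == "polygon" && is.null(polygon))
    stop_dfm("polygon mode requires a vertex matrix")
  stopifnot(all(c("colour", "key", "threshold") %in%
                  names(colour_thresholds)))
  if (any(colour_thresholds$threshold <= 0))
    stop_dfm("colour thresholds must be positive")
  structure(
    list(bacteria_mode = bacteria_mode,
         density_fraction = density_fraction, polygon = polygon,
         singlet_fsc_min = singlet_fsc_min,
         singlet_ar_min = singlet_ar_min,
         colour_thresholds = colour_thresholds, grid_bins = grid_bins),
    class = "gating_config")
}

#' @rdname gating_config
#' @export
default_colour_thresholds <- function() {
  data.frame(
    colour    = c("Red", "Yellow", "Blue"),
    key       = c("561-611/31", "488-528/46", "405-456/51"),
    threshold = c(550, 500, 450),
    stringsAsFactors = FALSE)
}

.check_channels <- function(events, keys) {
  miss <- setdiff(keys, names(events))
  if (length(miss))
    stop_dfm("event table lacks channel(s): ", paste(miss, collapse = ", "))
}

#' Bacteria gate: concentrated-events area in (FSC, SSC)
#'
#' Density mode bins (log10 FSC, log10 SSC) on a `grid_bins` x `grid_bins`
#' grid over the data range, ranks bins by occupancy and retains events in
#' the top-density bins whose cumulative event share first reaches
#' `density_fraction`.  Polygon mode applies a point-in-polygon test in the
#' same log space.  Events with non-positive FSC or SSC cannot be placed in
#' log space and are excluded; their count is recorded in the
#' `n_nonpositive_scatter` attribute (with a warning).
#'
#' @param events An [event_table()].
#' @param cfg A [gating_config()].
#' @return Logical vector `in_bacteria`, one element per event.
#' @export
gate_bacteria <- function(events, cfg = gating_config()) {
  if (nrow(events) == 0) stop_dfm("empty event table")
  ok <- events$fsc > 0 & events$ssc > 0
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(n_bad, " event(s) with non-positive scatter excluded from the ",
            "bacteria gate", call. = FALSE)
  lx <- log10(events$fsc[ok]); ly <- log10(events$ssc[ok])
  in_b <- rep(FALSE, nrow(events))
  if (cfg$bacteria_mode == "polygon") {
    in_b[ok] <- .point_in_polygon(lx, ly, cfg$polygon)
  } else {
    nb <- cfg$grid_bins
    # cut() on the closed data range; single-valued axes collapse to bin 1
    bx <- if (diff(range(lx)) == 0) rep(1L, length(lx)) else
      as.integer(cut(lx, breaks = seq(min(lx), max(lx), length.out = nb + 1),
                     include.lowest = TRUE))
    by <- if (diff(range(ly)) == 0) rep(1L, length(ly)) else
      as.integer(cut(ly, breaks = seq(min(ly), max(ly), length.out = nb + 1),
                     include.lowest = TRUE))
    bin <- (bx - 1L) * nb + by
    tab <- sort(table(bin), decreasing = TRUE)
    keep_n <- which(cumsum(tab) >= cfg$density_fraction * length(bin))[1]
    keep_bins <- as.integer(names(tab)[seq_len(keep_n)])
    in_b[ok] <- bin %in% keep_bins
  }
  structure(in_b, n_nonpositive_scatter = n_bad)
}

# Ray-casting point-in-polygon on open boundaries; vertices as a 2-col
# matrix. Adequate for convex hand-drawn scatter gates.
.point_in_polygon <- function(x, y, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Singlet gate
#'
#' Singlets are bacteria-gated events with FSC strictly above
#' `singlet_fsc_min` and aspect-ratio of SSC strictly above
#' `singlet_ar_min` (default 0.4); aggregates present low aspect-ratios.
#'
#' @param events An [event_table()].
#' @param in_bacteria Logical vector from [gate_bacteria()].
#' @param cfg A [gating_config()].
#' @return Logical vector `in_singlets`.
#' @export
gate_singlets <- function(events, in_bacteria, cfg = gating_config()) {
  in_bacteria & events$fsc > cfg$singlet_fsc_min &
    events$ar_ssc > cfg$singlet_ar_min
}

#' Colour populations: per-channel threshold positivity
#'
#' For each singlet, a colour flag is true iff the intensity in that
#' colour's channel is strictly above its threshold.  Flags are `NA` for
#' non-singlets (colour populations are defined on singlets only).
#'
#' @inheritParams gate_singlets
#' @param in_singlets Logical vector from [gate_singlets()].
#' @return Logical matrix with one column per colour (`Red`, `Yellow`,
#'   `Blue`), `NA` outside singlets.
#' @export
assign_colours <- function(events, in_singlets, cfg = gating_config()) {
  ct <- cfg$colour_thresholds
  .check_channels(events, ct$key)
  out <- matrix(NA, nrow(events), nrow(ct),
                dimnames = list(NULL, ct$colour))
  for (i in seq_len(nrow(ct))) {
    f <- events[[ct$key[i]]] > ct$threshold[i]
    f[!in_singlets] <- NA
    out[, i] <- f
  }
  out
}

#' Combined populations from colour flags
#'
#' The six exclusive DFM classes are defined by presence/absence of the
#' Red, Yellow and Blue populations: R (exclusively Red), Y, B, RY, RB and
#' YB.  All-negative and triple-positive singlets do not belong to any of
#' the six classes and are labelled `Unassigned`; non-singlets are
#' `NotSinglet`.
#'
#' @param colours Logical matrix from [assign_colours()].
#' @return Factor with levels `R, Y, B, RY, RB, YB, Unassigned,
#'   NotSinglet`.
#' @export
assign_combined <- function(colours) {
  lv <- c("R", "Y", "B", "RY", "RB", "YB", "Unassigned", "NotSinglet")
  r <- colours[, "Red"]; y <- colours[, "Yellow"]; b <- colours[, "Blue"]
  lab <- rep("NotSinglet", nrow(colours))
  s <- !is.na(r)
  key <- paste0(ifelse(r[s], "R", ""), ifelse(y[s], "Y", ""),
                ifelse(b[s], "B", ""))
  map <- c(R = "R", Y = "Y", B = "B", RY = "RY", RB = "RB", YB = "YB")
  lab[s] <- ifelse(key %in% names(map), map[key], "Unassigned")
  factor(lab, levels = lv)
}

#' Run the full gating chain
#'
#' Bacteria -> Singlets -> colour populations -> Combined populations, in
#' one call.  Deterministic and idempotent: re-running on the same table
#' and config yields identical labels.
#'
#' @param events An [event_table()].
#' @param cfg A [gating_config()].
#' @return A list of class `population_labels` with elements
#'   `in_bacteria`, `in_singlets`, `colours` (logical matrix) and
#'   `combined` (factor).
#' @export
#' @examples
#' ev <- simulate_events(strain_spec("RY", c("mCherry", "sYFP2")), 2000)
#' lab <- gate_chain(ev)
#' table(lab$combined)
gate_chain <- function(events, cfg = gating_config()) {
  in_b <- gate_bacteria(events, cfg)
  in_s <- gate_singlets(events, in_b, cfg)
  cols <- assign_colours(events, in_s, cfg)
  structure(
    list(in_bacteria = as.logical(in_b), in_singlets = in_s,
         colours = cols, combined = assign_combined(cols)),
    class = "population_labels")
}

#' Score demultiplexing assignments against ground truth
#'
#' Builds the truth-by-assigned confusion matrix over the combined
#' populations (singlets only), the per-class accuracy (fraction of a
#' strain's singlets assigned its own combined label), the per-colour
#' detection fraction for the colours each strain expresses, and the
#' overall accuracy.
#'
#' @param labels A `population_labels` list from [gate_chain()].
#' @param truth Character vector of true strain identifiers (length =
#'   number of events); strain ids are expected to equal their combined
#'   label (e.g. "RY") unless `truth_map` says otherwise.
#' @param truth_map Optional named character vector mapping strain id to
#'   expected combined label.
#' @return A list of class `confusion_summary` with `matrix`,
#'   `per_class_accuracy`, `colour_detection`, `overall_accuracy` and
#'   `n_singlets`.
#' @export
score_assignments <- function(labels, truth, truth_map = NULL) {
  if (length(truth) != length(labels$combined))
    stop_dfm("truth and assignments differ in length")
  s <- labels$in_singlets
  tr <- as.character(truth)[s]
  as_ <- labels$combined[s]
  classes <- c("R", "Y", "B", "RY", "RB", "YB", "Unassigned")
  cm <- table(truth = tr, assigned = factor(as_, levels = classes))
  expected <- if (is.null(truth_map))
    stats::setNames(rownames(cm), rownames(cm)) else truth_map
  per_class <- vapply(rownames(cm), function(st) {
    tot <- sum(cm[st, ])
    if (tot == 0) return(NA_real_)
    cm[st, expected[[st]]] / tot
  }, numeric(1))
  # colour detection: fraction of each strain's singlets positive in each
  # colour population (expected or not; Table-3-style layout)
  col_det <- do.call(rbind, lapply(unique(tr), function(st) {
    m <- labels$colours[s, , drop = FALSE][tr == st, , drop = FALSE]
    colMeans(m)
  }))
  rownames(col_det) <- unique(tr)
  correct <- vapply(seq_along(tr),
                    function(i) as.character(as_[i]) == expected[[tr[i]]],
                    logical(1))
  structure(
    list(matrix = cm, per_class_accuracy = per_class,
         colour_detection = col_det,
         overall_accuracy = mean(correct), n_singlets = sum(s)),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> ", x$n_singlets, " singlets, overall accuracy ",
      sprintf("%.3f", x$overall_accuracy), "\n", sep = "")
  print(x$matrix)
  invisible(x)
}
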