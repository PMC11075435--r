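#' Simulate a root-colonisation time series
#'
#' Generates replicate absolute abundances (egr) per strain and timepoint
#' following logistic colonisation towards a strain-specific carrying
#' capacity, with log-normal between-replicate noise.  Used to exercise
#' the assembly summaries with known dynamics.
#'
#' @param strains Character vector of strain labels.
#' @param timepoints Numeric vector (e.g. days post-inoculation).
#' @param k Named numeric carrying capacities (egr) per strain; recycled.
#' @param rate Colonisation rate (per unit time).
#' @param n0 Initial abundance (egr).
#' @param n_rep Number of replicates per strain x timepoint.
#' @param rep_gsd Geometric SD of replicate noise (>= 1).
#' @param seed Integer seed (default 3841).
#' @return Tidy data frame with columns `sample_id`, `plant`,
#'   `timepoint`, `replicate`, `population`, `egr_corrected` and the
#'   noise-free `truth_mean`.
#' @export
simulate_colonisation <- function(strains = c("R", "Y", "B", "RY", "RB", "YB"),
                                  timepoints = c(1, 3, 5, 7, 14, 21),
                                  k = 1e6, rate = 0.8, n0 = 1e3,
                                  n_rep = 4, rep_gsd = 1.5, seed = 3841) {
  k <- rep_len(k, length(strains))
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_rep),
                        population = strains, timepoint = timepoints,
                        stringsAsFactors = FALSE)
    ki <- k[match(rows$population, strains)]
    mean_ab <- ki * n0 / (n0 + (ki - n0) * exp(-rate * rows$timepoint))
    rows$truth_mean <- mean_ab
    rows$egr_corrected <- mean_ab * rlnorm_mg(nrow(rows), 1, rep_gsd)
    rows$plant <- "pea"
    rows$sample_id <- paste0("t", rows$timepoint, "_rep", rows$replicate)
    rows[c("sample_id", "plant", "timepoint", "replicate", "population",
           "egr_corrected", "truth_mean")]
  })
}

#' Summarise an assembly time series
#'
#' Mean, SD, SEM and replicate count of `egr_corrected` per strain x
#' timepoint; cells with no replicates are absent, not zero-filled.
#'
#' @param table Tidy abundance data frame with columns `population`,
#'   `timepoint`, `egr_corrected` (and optionally `replicate`).
#' @param value Abundance column to summarise (default `egr_corrected`).
#' @return Data frame with `population`, `timepoint`, `mean`, `sd`,
#'   `sem`, `n`.
#' @export
summarise_series <- function(table, value = "egr_corrected") {
  if (nrow(table) == 0) stop_dfm("empty abundance table")
  sp <- split(table, list(table$population, table$timepoint), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    x <- d[[value]]
    n <- length(x)
    s <- if (n > 1) stats::sd(x) else 0
    data.frame(population = d$population[1], timepoint = d$timepoint[1],
               mean = mean(x), sd = s, sem = s / sqrt(n), n = n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$population, out$timepoint), ]
}

#' Pearson correlation between two strains' abundance series
#'
#' Pairs observations at the (replicate, timepoint) level (or, with
#' `pairing = "timepoint_mean"`, at timepoint means) and returns the
#' Pearson coefficient, its square and the two-sided p-value.
#'
#' @param series_a,series_b Tidy abundance data frames for one strain
#'   each, with columns `timepoint`, `replicate` and the value column.
#' @param pairing `"replicate"` (default) or `"timepoint_mean"`.
#' @param value Abundance column (default `egr_corrected`).
#' @return List of class `correlation_result`: `r`, `r2`, `p`, `n`.
#' @export
correlate_strains <- function(series_a, series_b,
                              pairing = c("replicate", "timepoint_mean"),
                              value = "egr_corrected") {
  pairing <- match.arg(pairing)
  if (pairing == "timepoint_mean") {
    a <- stats::aggregate(series_a[[value]],
                          by = list(timepoint = series_a$timepoint), mean)
    b <- stats::aggregate(series_b[[value]],
                          by = list(timepoint = series_b$timepoint), mean)
    m <- merge(a, b, by = "timepoint")
    xa <- m$x.x; xb <- m$x.y
  } else {
    key <- function(d) paste(d$timepoint, d$replicate, sep = "\r")
    m <- match(key(series_a), key(series_b))
    keep <- !is.na(m)
    xa <- series_a[[value]][keep]
    xb <- series_b[[value]][m[keep]]
  }
  if (length(xa) < 3) stop_dfm("need at least 3 paired observations")
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    stop_dfm("zero variance in one of the series")
  ct <- stats::cor.test(xa, xb, method = "pearson")
  structure(list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                 p = ct$p.value, n = length(xa)),
            class = "correlation_result")
}

#' Convenience two-group comparisons on abundances
#'
#' Thin wrappers around [stats::t.test()] and [stats::wilcox.test()] for
#' paired or unpaired comparisons of abundance vectors.  Standard
#' statistics, provided for completeness of the reporting layer.
#'
#' @param x,y Numeric abundance vectors.
#' @param paired Paired comparison?
#' @param method `"wilcoxon"` or `"t"`.
#' @return The underlying `htest` object.
#' @export
compare_abundances <- function(x, y, paired = FALSE,
                               method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (method == "wilcoxon") stats::wilcox.test(x, y, paired = paired)
  else stats::t.test(x, y, paired = paired)
}
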