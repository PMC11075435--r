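#' Draw log-normal deviates parameterised by median and geometric SD
#'
#' Flow-cytometry intensity distributions are conventionally described by a
#' median fluorescence intensity and a geometric standard deviation (GSD);
#' this wraps [stats::rlnorm()] with that parameterisation.
#'
#' @param n Number of deviates.
#' @param median Median of the distribution (must be > 0 unless n-length 0).
#' @param gsd Geometric standard deviation, >= 1. `gsd = 1` gives a point
#'   mass at `median`.
#' @return Numeric vector of length `n`.
#' @keywords internal
rlnorm_mg <- function(n, median, gsd) {
  stopifnot(gsd >= 1)
  if (median == 0) return(rep(0, n))
  if (gsd == 1) return(rep(median, n))
  stats::rlnorm(n, meanlog = log(median), sdlog = log(gsd))
}

#' Upper-tail probability of a median/GSD log-normal
#'
#' @param q Threshold.
#' @param median,gsd Median and geometric SD.
#' @return P(X > q).
#' @keywords internal
plnorm_mg_upper <- function(q, median, gsd) {
  if (gsd == 1) return(as.numeric(q < median))
  stats::pnorm(log(q / median) / log(gsd), lower.tail = FALSE)
}

# Run code under a local RNG state seeded from `seed`, restoring the global
# state afterwards so generators never perturb user RNG streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dfm <- function(...) stop(..., call. = FALSE)
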