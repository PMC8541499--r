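#' Block-averaging error estimate for a correlated series
#'
#' Flyvbjerg-Petersen blocking: the series is repeatedly pair-averaged;
#' at each level the naive standard error of the mean is computed together
#' with its own statistical uncertainty. For a correlated series the naive
#' error grows with block size until blocks are longer than the correlation
#' time, where the curve plateaus; the plateau value is the error estimate.
#'
#' Plateau detection: among levels retaining at least `min_blocks` blocks
#' (the next level too), levels whose error differs from the next level's
#' by no more than its own uncertainty band are flat; the plateau extends
#' from the first to the largest flat level, and the reported error is the
#' inverse-variance-weighted mean of the level errors across the plateau
#' (weighting reduces the estimator noise of any single deep level). If no
#' level qualifies the estimate is flagged unconverged and the deepest
#' usable level is reported.
#'
#' @param series A [scalar_series()] (or plain numeric vector) of at least
#'   32 values.
#' @param min_blocks Minimum number of blocks for a level to be usable.
#' @return Object of class `block_average`: list with `mean` (plain
#'   average), `error` (plateau standard error of the mean, same units),
#'   `converged` (logical), `level` (chosen blocking level), and
#'   `block_curve` (data.frame: level, block_size, n_blocks, se, se_err).
#' @export
block_average_error <- function(series, min_blocks = 32) {
  x <- if (inherits(series, "scalar_series")) series$values else as.numeric(series)
  n <- length(x)
  if (n < 32) stop("block averaging needs at least 32 values")
  curve <- list()
  lev <- 0L
  xk <- x
  while (length(xk) >= 2) {
    nk <- length(xk)
    se <- stats::sd(xk) / sqrt(nk)
    curve[[lev + 1L]] <- data.frame(
      level = lev, block_size = 2^lev, n_blocks = nk,
      se = se, se_err = se / sqrt(2 * (nk - 1))
    )
    if (nk %% 2 == 1) xk <- xk[-nk]
    xk <- (xk[seq(1, length(xk), 2)] + xk[seq(2, length(xk), 2)]) / 2
    lev <- lev + 1L
  }
  curve <- do.call(rbind, curve)

  usable <- which(curve$n_blocks >= min_blocks)
  if (length(usable) < 5) {
    warning("series too short for 5 blocking levels; naive standard error ",
            "reported, flagged unconverged")
    return(structure(list(mean = mean(x), error = curve$se[1],
                          converged = FALSE, level = 0L,
                          block_curve = curve),
                     class = "block_average"))
  }
  # Levels whose successor is also usable.
  cand <- usable[usable + 1 <= max(usable)]
  ok <- abs(curve$se[cand] - curve$se[cand + 1]) <= curve$se_err[cand]
  if (any(ok)) {
    plateau <- min(cand[ok]):max(cand[ok])
    w <- 1 / curve$se_err[plateau]^2
    # a zero-uncertainty level (constant series) is exact
    err <- if (any(!is.finite(w))) curve$se[plateau][!is.finite(w)][1]
           else sum(w * curve$se[plateau]) / sum(w)
    pick <- max(cand[ok])
    converged <- TRUE
  } else {
    pick <- max(usable)
    err <- curve$se[pick]
    converged <- FALSE
    warning("block error estimate did not plateau; deepest level reported")
  }
  structure(list(mean = mean(x), error = err,
                 converged = converged, level = curve$level[pick],
                 block_curve = curve),
            class = "block_average")
}

#' @export
print.block_average <- function(x, ...) {
  cat(sprintf("block average: %.6g +/- %.3g (level %d%s)\n", x$mean, x$error,
              x$level, if (x$converged) "" else ", UNCONVERGED"))
  invisible(x)
}

#' Normalised autocorrelation function of a series
#'
#' @param series A [scalar_series()] or numeric vector.
#' @param max_lag Largest lag (frames); must be smaller than the series
#'   length.
#' @return Numeric vector of correlations at lags `0..max_lag` (1 at lag
#'   0).
#' @export
autocorrelation <- function(series, max_lag) {
  x <- if (inherits(series, "scalar_series")) series$values else as.numeric(series)
  stopifnot(max_lag < length(x))
  as.vector(stats::acf(x, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)
}

#' Gaussian kernel density estimate of a series
#'
#' Bandwidth defaults to Scott's factor, `sd(x) * n^(-1/5)`. The grid
#' spans the data range extended by four bandwidths on each side so that
#' the trapezoidal integral of the density is 1 to within 1e-3 even for
#' edge-heavy samples.
#'
#' @param series A [scalar_series()] or numeric vector with at least two
#'   distinct values.
#' @param bandwidth Kernel standard deviation (same units as the data);
#'   `NULL` for Scott's factor.
#' @param n_grid Number of grid points.
#' @return Object of class `kde_estimate`: list with `grid`, `density`,
#'   `bandwidth`.
#' @export
kde_distribution <- function(series, bandwidth = NULL, n_grid = 512) {
  x <- if (inherits(series, "scalar_series")) series$values else as.numeric(series)
  if (length(unique(x)) < 2)
    stop("degenerate distribution: fewer than 2 distinct values")
  if (is.null(bandwidth)) bandwidth <- stats::sd(x) * length(x)^(-1 / 5)
  stopifnot(bandwidth > 0)
  d <- stats::density(x, bw = bandwidth, kernel = "gaussian", n = n_grid,
                      from = min(x) - 4 * bandwidth,
                      to = max(x) + 4 * bandwidth)
  structure(list(grid = d$x, density = d$y, bandwidth = bandwidth),
            class = "kde_estimate")
}
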