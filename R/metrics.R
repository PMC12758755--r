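#' Waveform agreement metrics
#'
#' Root-mean-square error, relative RMSE and the Pearson correlation between
#' a predicted and a measured gait waveform sampled on the same grid.
#' \code{rrmse} normalises by the range of the \emph{measured} series and
#' reports percent; \code{pearson_rho} is the centred cross-product over the
#' product of root centred sums of squares.
#'
#' @param predicted Numeric vector of model values.
#' @param measured Numeric vector of measured values, same length.
#' @return \code{rmse}: RMSE in the native units of the series.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))
#' pearson_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
rmse <- function(predicted, measured) {
  check_metric_args(predicted, measured)
  sqrt(mean((predicted - measured)^2))
}

#' @return \code{rrmse}: RMSE as a percentage of the measured range.
#' @rdname rmse
#' @export
rrmse <- function(predicted, measured) {
  check_metric_args(predicted, measured)
  rng <- max(measured) - min(measured)
  if (rng <= 0)
    stop("rRMSE is undefined for a constant measured series (zero range)")
  100 * rmse(predicted, measured) / rng
}

#' @return \code{pearson_rho}: correlation coefficient in [-1, 1].
#' @rdname rmse
#' @export
pearson_rho <- function(predicted, measured) {
  check_metric_args(predicted, measured)
  dp <- predicted - mean(predicted)
  dm <- measured - mean(measured)
  den <- sqrt(sum(dp^2)) * sqrt(sum(dm^2))
  if (den <= 0)
    stop("Pearson correlation is undefined for a constant series")
  sum(dp * dm) / den
}

check_metric_args <- function(predicted, measured) {
  stopifnot(is.numeric(predicted), is.numeric(measured))
  if (length(predicted) != length(measured))
    stop("`predicted` and `measured` must have the same length")
  if (length(predicted) == 0L) stop("empty series")
  if (anyNA(predicted) || anyNA(measured)) stop("series contain NA")
  invisible(TRUE)
}

#' Metrics report over matched signal sets
#'
#' Applies \code{\link{rmse}}, \code{\link{rrmse}} and
#' \code{\link{pearson_rho}} column-by-column to two data frames holding the
#' same signals (matched by column name; non-numeric and time/percent columns
#' are skipped). Columns whose measured series is constant get \code{NA}
#' rRMSE and correlation rather than an error. Per-sample absolute error
#' series are attached as the \code{"abs_error"} attribute for downstream
#' waveform-level statistics.
#'
#' @param predicted,measured Data frames with identical signal columns and
#'   equal row counts.
#' @return Data frame: \code{signal}, \code{rmse}, \code{rrmse_percent},
#'   \code{pearson_rho}, \code{n}.
#' @export
metrics_report <- function(predicted, measured) {
  stopifnot(is.data.frame(predicted), is.data.frame(measured),
            nrow(predicted) == nrow(measured))
  skip <- c("time", "percent", "percent_gait", "phase", "s")
  sig <- intersect(names(predicted), names(measured))
  sig <- sig[!sig %in% skip]
  sig <- sig[vapply(sig, function(nm) is.numeric(predicted[[nm]]), logical(1))]
  rows <- lapply(sig, function(nm) {
    p <- predicted[[nm]]; m <- measured[[nm]]
    ok <- !(is.na(p) | is.na(m))
    p <- p[ok]; m <- m[ok]
    if (length(p) == 0L)
      return(data.frame(signal = nm, rmse = NA_real_,
                        rrmse_percent = NA_real_, pearson_rho = NA_real_,
                        n = 0L))
    rng <- max(m) - min(m)
    data.frame(signal = nm,
               rmse = rmse(p, m),
               rrmse_percent = if (rng > 0) rrmse(p, m) else NA_real_,
               pearson_rho = if (rng > 0 && stats::sd(p) > 0)
                 pearson_rho(p, m) else NA_real_,
               n = length(p))
  })
  out <- do.call(rbind, rows)
  attr(out, "abs_error") <- lapply(stats::setNames(sig, sig), function(nm)
    abs(predicted[[nm]] - measured[[nm]]))
  out
}
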