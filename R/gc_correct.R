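#' Fit the GC-versus-coverage correction curve
#'
#' Models expected fragment count as a smooth function of bin GC fraction
#' with robustified LOWESS (locally weighted linear regression with
#' bisquare reweighting), evaluated on a fixed GC grid. The curve is later
#' used to scale each bin by the expected coverage of bins with the same GC
#' content.
#'
#' @param bins bin data.frame with `gc`, `mappable_bases` and a
#'   `count_<sample>` column.
#' @param sample `"normal"` or `"tumor"`.
#' @param smoothing_fraction LOWESS span in (0, 1\] (default 0.3).
#' @param robust_iterations bisquare reweighting iterations (default 3).
#' @param grid_size number of evaluation points across the observed GC
#'   range.
#' @return Object of class `gc_curve`: list with `gc` (grid), `fitted`
#'   (expected count at each grid point), `span`, `sample`.
#' @export
fit_gc_curve <- function(bins, sample = c("normal", "tumor"),
                         smoothing_fraction = 0.3, robust_iterations = 3,
                         grid_size = 201) {
  sample <- match.arg(sample)
  cnt <- bins[[paste0("count_", sample)]]
  ok <- is.finite(bins$gc) & is.finite(cnt) & bins$mappable_bases > 0
  gc <- bins$gc[ok]
  cnt <- cnt[ok]
  if (length(gc) < 2) {
    stop("fit_gc_curve needs at least 2 usable bins", call. = FALSE)
  }
  if (length(unique(gc)) == 1L) {
    curve <- list(gc = unique(gc), fitted = mean(cnt),
                  span = smoothing_fraction, sample = sample)
    class(curve) <- "gc_curve"
    return(curve)
  }
  fit <- lowess(gc, cnt, f = smoothing_fraction, iter = robust_iterations)
  grid <- seq(min(gc), max(gc), length.out = grid_size)
  fitted <- approx(fit$x, fit$y, xout = grid, rule = 2, ties = mean)$y
  curve <- list(gc = grid, fitted = fitted, span = smoothing_fraction,
                sample = sample)
  class(curve) <- "gc_curve"
  curve
}

#' Evaluate a GC correction curve
#'
#' Linear interpolation on the fitted grid; GC values outside the observed
#' range take the nearest end value.
#'
#' @param object a `gc_curve`.
#' @param gc GC fractions to evaluate at.
#' @param ... unused.
#' @return Expected counts at `gc`.
#' @export
predict.gc_curve <- function(object, gc, ...) {
  if (length(object$gc) == 1L) {
    return(rep(object$fitted, length(gc)))
  }
  approx(object$gc, object$fitted, xout = gc, rule = 2)$y
}

#' Scale bin counts by the expected coverage at their GC
#'
#' Fills `ratio_<sample> = count / curve(gc)`. Bins with no mappable
#' bases, missing counts, or non-positive expected coverage get a missing
#' ratio (they are excluded from segmentation downstream, not imputed).
#'
#' @param bins bin data.frame.
#' @param curve `gc_curve` fitted on the same sample.
#' @param sample `"normal"` or `"tumor"`; defaults to the curve's sample.
#' @return `bins` with the `ratio_<sample>` column added.
#' @export
normalize_coverage <- function(bins, curve, sample = curve$sample) {
  cnt <- bins[[paste0("count_", sample)]]
  expected <- predict(curve, bins$gc)
  ratio <- cnt / expected
  bad <- !is.finite(ratio) | expected <= 0 | bins$mappable_bases == 0 |
    !is.finite(cnt)
  ratio[bad] <- NA_real_
  bins[[paste0("ratio_", sample)]] <- ratio
  bins
}
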