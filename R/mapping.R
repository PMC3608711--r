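#' Per-pixel emphysema deviation map
#'
#' Converts a parameter map and a cutoff into a parametric map of disease
#' deviation: the signed deviation toward the emphysematous signal
#' characteristic (`param - cutoff` when greater values indicate disease,
#' `cutoff - param` otherwise) divided by the control-group interquartile
#' range of the parameter, clipped to [0, 1]. Deviations toward the
#' healthy side map to 0, so only emphysema-like tissue is color-coded,
#' and pixels outside the segmentation mask are 0.
#'
#' @param param_map matrix of parameter values (T, V or S).
#' @param mask logical segmentation mask.
#' @param cutoff operating cutoff, e.g. from [optimal_cutoff()] or
#'   [cutoff_preset()].
#' @param orientation `"greater_is_diseased"` or `"less_is_diseased"`.
#' @param control_iqr positive scalar: q3 - q1 of the parameter over
#'   control-group pixels (from the current run or a preset).
#' @param parameter label (`"T"`, `"V"`, `"S"`) carried in the result.
#' @return an object of class `deviation_map`: `values` in [0, 1],
#'   `parameter`, `cutoff`, `orientation`, `control_iqr`.
#' @export
#' @examples
#' dm <- deviation_map(matrix(4.9), matrix(TRUE), 7.00,
#'                     "less_is_diseased", 7.2)
#' dm$values  # (7.00 - 4.9) / 7.2 = 0.292
deviation_map <- function(param_map, mask, cutoff,
                          orientation = c("greater_is_diseased",
                                          "less_is_diseased"),
                          control_iqr, parameter = NA_character_) {
  orientation <- match.arg(orientation)
  if (!is.finite(control_iqr) || control_iqr <= 0)
    stopf("control IQR must be positive (got %g)", control_iqr)
  mask <- matrix(as.logical(mask), nrow(param_map), ncol(param_map))
  dev <- if (orientation == "greater_is_diseased") param_map - cutoff
         else cutoff - param_map
  vals <- pmin(pmax(dev / control_iqr, 0), 1)
  vals[!mask | !is.finite(vals)] <- 0
  structure(
    list(values = vals, parameter = parameter, cutoff = cutoff,
         orientation = orientation, control_iqr = control_iqr),
    class = "deviation_map")
}

#' Render a color-coded emphysema overlay
#'
#' Superimposes a deviation map onto the grayscale transmission image: the
#' background is the min-max windowed transmission (1st-99th percentile by
#' default), and pixels with positive deviation are alpha-blended with a
#' yellow-to-red ramp, alpha proportional to the deviation with a
#' visibility floor. Deterministic for fixed inputs.
#'
#' @param T_map transmission matrix (grayscale background).
#' @param deviation a [deviation_map()].
#' @param colormap colors interpolated from no to full deviation.
#' @param alpha_floor minimum blend weight for any colored pixel.
#' @param window grayscale windowing percentiles (low, high).
#' @return an `h x w x 3` RGB array in [0, 1].
#' @export
render_overlay <- function(T_map, deviation,
                           colormap = c("#FFFF00", "#FF0000"),
                           alpha_floor = 0.35,
                           window = c(0.01, 0.99)) {
  stopifnot(inherits(deviation, "deviation_map"))
  v <- deviation$values
  if (!identical(dim(T_map), dim(v)))
    stopf("transmission map and deviation map have different shapes")
  lim <- stats::quantile(T_map[is.finite(T_map)], window, names = FALSE)
  gray <- pmin(pmax((T_map - lim[1]) / max(lim[2] - lim[1],
                                           .Machine$double.eps), 0), 1)
  ramp <- grDevices::colorRamp(colormap)
  col <- ramp(as.numeric(v)) / 255
  alpha <- ifelse(v > 0, pmax(alpha_floor, v), 0)
  h <- nrow(v); w <- ncol(v)
  out <- array(0, c(h, w, 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * gray + alpha * matrix(col[, ch], h, w)
  out
}
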