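#' Dark-field threshold between background and lung signal
#'
#' Locates the border between the background mode (V near 1: water,
#' formalin, container) and the lung peak at low V on a histogram of the
#' dark-field map — the automated counterpart of choosing the valley on the
#' dark-field histogram by eye. Default method `"valley"`: histogram the
#' valid V values into `n_bins` equal bins, smooth the counts with a
#' moving average of `smooth_width` bins, locate the two highest local
#' maxima and return the center of the lowest bin strictly between them.
#' If fewer than two modes are found the method falls back to Otsu's
#' between-class-variance criterion on the same histogram (with a
#' warning), unless `otsu_fallback = FALSE`, in which case it errors.
#'
#' @param V_map dark-field matrix (or vector).
#' @param valid_mask logical mask of usable pixels (default: all finite).
#' @param method `"valley"`, `"otsu"` or `"manual"`.
#' @param n_bins histogram bins over the observed V range.
#' @param smooth_width moving-average width, bins.
#' @param min_separation smallest distance, in bins, between the two modes
#'   (guards against reading noise wiggles on one peak as two modes).
#' @param min_mode_mass smallest fraction of all pixels that must lie on
#'   the secondary-mode side of the valley for the histogram to count as
#'   bimodal (guards against tail spikes of a unimodal histogram).
#' @param max_valley_ratio largest smoothed count at the valley, as a
#'   fraction of the primary-peak count, still accepted as a genuine
#'   between-mode valley (guards against shoulder wiggles on one peak).
#' @param otsu_fallback allow falling back to Otsu when `valley` finds
#'   fewer than two modes.
#' @param manual_value threshold to return when `method = "manual"`.
#' @return the scalar dark-field threshold.
#' @export
darkfield_threshold <- function(V_map, valid_mask = NULL,
                                method = c("valley", "otsu", "manual"),
                                n_bins = 256, smooth_width = 5,
                                min_separation = 32,
                                min_mode_mass = 0.02,
                                max_valley_ratio = 0.4,
                                otsu_fallback = TRUE,
                                manual_value = NULL) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(manual_value)) stopf("manual method requires manual_value")
    return(manual_value)
  }
  v <- as.numeric(V_map)
  if (!is.null(valid_mask)) v <- v[as.logical(valid_mask)]
  v <- v[is.finite(v)]
  if (length(v) < 100)
    stopf("need at least 100 valid pixels to estimate a threshold (got %d)",
          length(v))
  rng <- range(v)
  if (diff(rng) == 0)
    stopf("dark-field histogram is degenerate (all values equal %g)", rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  # moving average with edge replication so end bins stay comparable
  half <- smooth_width %/% 2
  padded <- c(rep(counts[1], half), counts, rep(counts[n_bins], half))
  sm <- stats::filter(padded, rep(1 / smooth_width, smooth_width),
                      sides = 2)
  sm <- as.numeric(sm)[half + seq_len(n_bins)]

  if (method == "valley") {
    i <- 2:(n_bins - 1)
    # strict rise on the left picks one representative bin per plateau
    is_peak <- c(FALSE, sm[i] > sm[i - 1] & sm[i] >= sm[i + 1], FALSE)
    peaks <- which(is_peak)
    if (length(peaks) >= 2) {
      primary <- peaks[which.max(sm[peaks])]
      far <- peaks[abs(peaks - primary) >= min_separation]
      if (length(far) >= 1) {
        secondary <- far[which.max(sm[far])]
        top2 <- sort(c(primary, secondary))
        between <- (top2[1] + 1):(top2[2] - 1)
        valley <- between[which.min(sm[between])]
        side <- if (secondary < primary) seq_len(valley - 1)
                else valley:n_bins
        if (sum(counts[side]) / length(v) >= min_mode_mass &&
            sm[valley] <= max_valley_ratio * sm[primary])
          return(centers[valley])
      }
    }
    if (!otsu_fallback)
      stopf("dark-field histogram is unimodal and Otsu fallback is disabled")
    warnf("fewer than two dark-field modes found; falling back to Otsu")
  }
  centers[otsu_bin(counts)]
}

# Otsu's criterion on precomputed histogram counts; returns the bin index
# maximizing between-class variance (threshold at that bin's center).
otsu_bin <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  idx <- seq_along(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * idx)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  bcv <- (mu_t * w0 - mu)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  which.max(bcv)
}

#' Segment lung tissue on the dark-field channel
#'
#' Lung parenchyma scatters strongly, so its relative visibility is LOW;
#' the mask is `valid & V < threshold`. Connected components smaller than
#' `min_component` pixels are removed (this also drops most of the trachea
#' and main-bronchi remnants). The same mask is applied to every channel
#' downstream, so per-pixel T, V and S vectors stay aligned.
#'
#' @param triplet a `projection_triplet`.
#' @param threshold dark-field threshold, e.g. from
#'   [darkfield_threshold()].
#' @param min_component smallest connected component (8-neighborhood) kept,
#'   pixels.
#' @param method label recorded in the result (how the threshold was
#'   obtained).
#' @return an object of class `segmentation_mask` with fields `mask`,
#'   `threshold`, `method`, `pixel_count`.
#' @export
segment_lung <- function(triplet, threshold, min_component = 20,
                         method = "valley") {
  stopifnot(inherits(triplet, "projection_triplet"))
  mask <- triplet$valid_mask & triplet$V_map < threshold
  if (!any(mask))
    stopf(paste("empty lung mask at threshold %g; review the threshold",
                "(dark-field range %g..%g)"),
          threshold, min(triplet$V_map, na.rm = TRUE),
          max(triplet$V_map, na.rm = TRUE))
  if (min_component > 1) {
    lab <- EBImage::bwlabel(mask * 1L)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_component)
    if (length(drop)) mask[lab %in% drop] <- FALSE
    if (!any(mask))
      stopf("all components smaller than %d pixels; review the threshold",
            min_component)
  }
  structure(
    list(mask = mask, threshold = threshold, method = method,
         pixel_count = sum(mask)),
    class = "segmentation_mask")
}
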