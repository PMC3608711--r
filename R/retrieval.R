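#' Retrieve transmission, differential-phase and dark-field maps
#'
#' Fourier analysis of the phase-stepping curves. Per pixel, the stepping
#' curve `I_k` over one grating period is decomposed into its mean `a0`,
#' first-harmonic amplitude `a1 = |(2/N) sum_k I_k exp(-2 pi i f_k)|` and
#' first-harmonic phase. The three contrast channels are then
#' \deqn{T = a0^s / a0^r, \quad V = (a1^s/a0^s) / (a1^r/a0^r), \quad
#'       \Delta\phi = \mathrm{wrap}(\phi^s - \phi^r).}
#' For noiseless single-harmonic curves sampled uniformly over one period
#' this is exact. Pixels whose reference mean or amplitude falls below
#' `validity_floor` times the respective frame-wide median are flagged
#' invalid (dead/dark detector regions).
#'
#' @param sample,reference [step_scan()] objects sharing shape and step
#'   fractions.
#' @param validity_floor fraction of the median reference `a0`/`a1` below
#'   which a pixel is invalid.
#' @return an object of class `projection_triplet` with `T_map`,
#'   `dphi_map` (radians in (-pi, pi]), `V_map`, `valid_mask` and metadata.
#' @export
#' @examples
#' fr <- (0:15) / 16
#' mk <- function(a, v, ph) vapply(fr, function(f)
#'   matrix(a * (1 + v * cos(2 * pi * f + ph)), 2, 2), matrix(0, 2, 2))
#' ref <- step_scan(mk(100, 0.3, 0), fr, is_reference = TRUE)
#' smp <- step_scan(mk(80, 0.15, 0.5), fr)
#' tri <- retrieve_signals(smp, ref)
#' c(tri$T_map[1], tri$V_map[1], tri$dphi_map[1])  # 0.8, 0.5, 0.5
retrieve_signals <- function(sample, reference, validity_floor = 0.01) {
  stopifnot(inherits(sample, "step_scan"), inherits(reference, "step_scan"))
  if (!identical(dim(sample$frames), dim(reference$frames)))
    stopf("sample and reference scans have different shapes")
  if (!isTRUE(all.equal(sample$step_fractions, reference$step_fractions)))
    stopf("sample and reference scans have different step fractions")
  d <- dim(sample$frames); h <- d[1]; w <- d[2]; N <- d[3]
  fr <- sample$step_fractions

  comp <- function(frames) {
    m <- matrix(frames, h * w, N)
    a0 <- rowMeans(m)
    cc <- (m %*% exp(-2i * pi * fr)) * (2 / N)
    list(a0 = a0, a1 = Mod(cc)[, 1], phi = Arg(cc)[, 1])
  }
  s <- comp(sample$frames)
  r <- comp(reference$frames)

  if (all(reference$frames == 0)) {
    warnf("all-zero reference scan: every pixel flagged invalid")
    valid <- rep(FALSE, h * w)
  } else {
    valid <- r$a0 >= validity_floor * stats::median(r$a0) &
             r$a1 >= validity_floor * stats::median(r$a1)
  }
  T_v <- s$a0 / r$a0
  V_v <- (s$a1 / s$a0) / (r$a1 / r$a0)
  d_v <- wrap_angle(s$phi - r$phi)
  valid <- valid & is.finite(T_v) & is.finite(V_v) & is.finite(d_v)

  structure(
    list(T_map = matrix(T_v, h, w),
         dphi_map = matrix(d_v, h, w),
         V_map = matrix(V_v, h, w),
         valid_mask = matrix(valid, h, w),
         specimen_id = sample$specimen_id,
         projection_index = sample$projection_index,
         validity_floor = validity_floor,
         water_normalizers = NULL),
    class = "projection_triplet")
}

#' Normalize a projection triplet against the water bath
#'
#' Divides the transmission and dark-field maps by their medians over a
#' water ROI, so that water reads T = 1 and V = 1. Idempotent; records the
#' normalizers in the triplet metadata.
#'
#' @param triplet a `projection_triplet`.
#' @param water_roi logical matrix marking water-bath pixels.
#' @return the normalized `projection_triplet`.
#' @export
normalize_to_water <- function(triplet, water_roi) {
  stopifnot(inherits(triplet, "projection_triplet"))
  roi <- water_roi & triplet$valid_mask
  if (!any(roi))
    stopf("water ROI is empty or fully invalid; cannot normalize")
  tn <- stats::median(triplet$T_map[roi])
  vn <- stats::median(triplet$V_map[roi])
  if (!is.finite(tn) || !is.finite(vn) || tn <= 0 || vn <= 0)
    stopf("water ROI yields non-positive normalizers (T = %g, V = %g)",
          tn, vn)
  triplet$T_map <- triplet$T_map / tn
  triplet$V_map <- triplet$V_map / vn
  triplet$water_normalizers <- c(T = tn, V = vn)
  triplet
}
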