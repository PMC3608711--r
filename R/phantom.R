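#' Parameters for the synthetic lung phantom cohort
#'
#' Bundles and validates everything the generator needs: cohort layout
#' (specimens per group, projections per specimen), acquisition geometry
#' (frame size, phase steps per grating period), interferometer reference
#' properties (visibility, flux), the container background log-offset (the
#' true value of the correction factor c), and the per-group calibration
#' quartiles of transmission-relative-to-water and of normalized scatter.
#'
#' The default quartiles are the per-pixel group statistics of ex-vivo
#' elastase-emphysema vs control mouse lungs: transmission 1.11 (1.07-1.17)
#' vs 1.06 (1.04-1.10) and normalized scatter 4.9 (4.1-5.8) vs 10.8
#' (7.5-14.7). The dark-field medians are not a parameter: with independent
#' draws of the log-transmission excess u and the scatter density s, the
#' group medians of V = exp(-s*u) come out at ~0.66 in both groups by
#' construction, matching the observed dark-field signal.
#'
#' @param image_height,image_width frame size in pixels.
#' @param n_steps phase steps over one grating period (>= 3).
#' @param n_projections projections acquired per specimen.
#' @param n_per_group specimens per group.
#' @param group_T_quantiles named list (`emphysema`, `control`) of (q1,
#'   median, q3) of transmission relative to water over lung pixels.
#' @param group_S_quantiles named list of (q1, median, q3) of normalized
#'   scatter over lung pixels.
#' @param container_log_offset true log-ratio of container-background to
#'   water transmission (the simulated value of c).
#' @param reference_visibility stepping-curve visibility of the empty
#'   interferometer, in (0, 1].
#' @param reference_flux mean counts per pixel per frame in the reference.
#' @param noise_model `"poisson"` or `"none"`.
#' @param smooth_sigma spatial correlation length of the lung texture
#'   fields, pixels (cosmetic; marginals are imposed exactly).
#' @param seed master integer seed for the cohort.
#' @return an object of class `phantom_params`.
#' @export
#' @examples
#' p <- phantom_params(image_height = 64, image_width = 64)
#' p$group_T_quantiles$emphysema
phantom_params <- function(image_height = 128,
                           image_width = 128,
                           n_steps = 16,
                           n_projections = 11,
                           n_per_group = 3,
                           group_T_quantiles = list(
                             emphysema = c(1.07, 1.11, 1.17),
                             control   = c(1.04, 1.06, 1.10)
                           ),
                           group_S_quantiles = list(
                             emphysema = c(4.1, 4.9, 5.8),
                             control   = c(7.5, 10.8, 14.7)
                           ),
                           container_log_offset = 0.02,
                           reference_visibility = 0.3,
                           reference_flux = 1000,
                           noise_model = c("poisson", "none"),
                           smooth_sigma = 3,
                           seed = 0L) {
  noise_model <- match.arg(noise_model)
  p <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_steps = as.integer(n_steps),
    n_projections = as.integer(n_projections),
    n_per_group = as.integer(n_per_group),
    group_T_quantiles = group_T_quantiles,
    group_S_quantiles = group_S_quantiles,
    container_log_offset = container_log_offset,
    reference_visibility = reference_visibility,
    reference_flux = reference_flux,
    noise_model = noise_model,
    smooth_sigma = smooth_sigma,
    seed = as.integer(seed)
  )
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$image_height < 16 || p$image_width < 16)
    stopf("image dimensions must be at least 16x16")
  if (p$n_steps < 3)
    stopf("n_steps must be >= 3 (three-parameter sinusoid recovery)")
  if (p$n_projections < 1 || p$n_per_group < 1)
    stopf("n_projections and n_per_group must be >= 1")
  for (nm in c("emphysema", "control")) {
    for (blk in c("group_T_quantiles", "group_S_quantiles")) {
      q <- p[[blk]][[nm]]
      if (is.null(q) || length(q) != 3)
        stopf("%s$%s must be a (q1, median, q3) triple", blk, nm)
      if (any(q <= 0) || any(diff(q) < 0))
        stopf("%s$%s must be positive and non-decreasing", blk, nm)
    }
    if (log(p$group_T_quantiles[[nm]][2]) <= p$container_log_offset)
      stopf("median T for group '%s' must exceed exp(container_log_offset)",
            nm)
  }
  if (p$reference_visibility <= 0 || p$reference_visibility > 1)
    stopf("reference_visibility must lie in (0, 1]")
  if (p$reference_flux <= 0) stopf("reference_flux must be positive")
  invisible(p)
}

#' Specimen identifiers of a phantom cohort
#'
#' @param params a [phantom_params()] object.
#' @return character vector, emphysema specimens (`E1`, `E2`, ...) first,
#'   then controls (`C1`, ...).
#' @export
cohort_specimens <- function(params) {
  c(paste0("E", seq_len(params$n_per_group)),
    paste0("C", seq_len(params$n_per_group)))
}

#' Group label of a specimen id (`E*` = emphysema, `C*` = control)
#' @param specimen_id character vector of specimen identifiers.
#' @return character vector of group labels.
#' @export
specimen_group <- function(specimen_id) {
  ifelse(startsWith(specimen_id, "E"), "emphysema", "control")
}

# Geometry of one projection: two elliptical lung lobes (rotated in-plane
# with the projection angle) inside an elliptical formalin-filled container,
# which sits in a water bath filling the rest of the frame. ROI bands for
# the formalin background and the surrounding water are carved out of the
# respective regions, away from the lung.
phantom_geometry <- function(h, w, projection_index, n_projections) {
  yy <- matrix(seq(-1, 1, length.out = h), h, w)
  xx <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  # in-plane rotation stands in for the rotation about the tomographic axis
  theta <- (projection_index - (n_projections + 1) / 2) * pi / 45
  xr <- cos(theta) * xx - sin(theta) * yy
  yr <- sin(theta) * xx + cos(theta) * yy
  lobe <- function(cx) ((xr - cx) / 0.20)^2 + (yr / 0.40)^2 <= 1
  lung <- lobe(-0.32) | lobe(0.32)
  rc <- sqrt((xx / 0.82)^2 + (yy / 0.82)^2)   # container-normalized radius
  container <- rc <= 1
  formalin <- container & !lung & rc >= 0.80 & rc <= 0.96
  water <- rc >= 1.10 & rc <= 1.50
  list(lung_mask = lung, container_mask = container,
       formalin_roi = formalin, water_roi = water)
}

#' Generate the ground truth of one phantom projection
#'
#' Builds the projection geometry and draws the two per-pixel lung fields:
#' the log-transmission excess `u = ln T - c` and the normalized scatter
#' density `s` (so the true dark-field is `V = exp(-s*u)`). Each field is a
#' Gaussian-copula texture: a smooth correlated Gaussian field supplies the
#' spatial ranks, and the marginal distribution is imposed exactly through a
#' split-log-normal quantile function whose quartiles equal the configured
#' group quartiles (for u, the elementwise `ln(q) - c` of the transmission
#' quartiles). u and s are drawn independently.
#'
#' Deterministic: the RNG substream is derived from `params$seed` and the
#' two identifiers, so the same call always returns the identical phantom.
#'
#' @param params a [phantom_params()] object.
#' @param specimen_id specimen identifier; group is its prefix (`E`/`C`)
#'   unless `group` is given.
#' @param projection_index 1-based projection number.
#' @param group optional explicit group label.
#' @return an object of class `phantom_truth` with fields `u_map`, `s_map`,
#'   `lung_mask`, `container_mask`, `formalin_roi`, `water_roi`,
#'   `group_label`, `specimen_id`, `projection_index`.
#' @export
#' @examples
#' p <- phantom_params(image_height = 64, image_width = 64)
#' tr <- make_lung_phantom(p, "E1", 1)
#' median(exp(tr$u_map[tr$lung_mask] + p$container_log_offset))  # ~ 1.11
make_lung_phantom <- function(params, specimen_id, projection_index,
                              group = NULL) {
  validate_phantom_params(params)
  if (is.null(group)) group <- specimen_group(specimen_id)
  if (!group %in% c("emphysema", "control"))
    stopf("specimen_id '%s' does not map to a group", specimen_id)
  h <- params$image_height; w <- params$image_width
  geo <- phantom_geometry(h, w, projection_index, params$n_projections)
  if (!any(geo$lung_mask) || !any(geo$formalin_roi) || !any(geo$water_roi))
    stopf("degenerate geometry: empty lung/formalin/water region")

  qT <- params$group_T_quantiles[[group]]
  qS <- params$group_S_quantiles[[group]]
  c0 <- params$container_log_offset
  qu <- log(qT) - c0
  if (any(qu <= 0))
    stopf("group '%s' transmission quartiles give non-positive u", group)

  seed <- substream_seed(params$seed, "phantom", specimen_id,
                         projection_index)
  u_map <- matrix(0, h, w)
  s_map <- matrix(0, h, w)
  n_lung <- sum(geo$lung_mask)
  withr_seed(seed, {
    zu <- gaussian_field(h, w, params$smooth_sigma)
    zs <- gaussian_field(h, w, params$smooth_sigma)
    pu <- (rank(zu[geo$lung_mask]) - 0.5) / n_lung
    ps <- (rank(zs[geo$lung_mask]) - 0.5) / n_lung
    u_map[geo$lung_mask] <- qsplitlnorm(pu, qu[1], qu[2], qu[3])
    s_map[geo$lung_mask] <- qsplitlnorm(ps, qS[1], qS[2], qS[3])
  })

  structure(
    list(u_map = u_map, s_map = s_map,
         lung_mask = geo$lung_mask, container_mask = geo$container_mask,
         formalin_roi = geo$formalin_roi, water_roi = geo$water_roi,
         group_label = group, specimen_id = specimen_id,
         projection_index = as.integer(projection_index)),
    class = "phantom_truth")
}

# evaluate expr under a temporary RNG seed, restoring state afterwards
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' True transmission and dark-field maps of a phantom
#'
#' Closed-form forward signals: `T = exp(u + c)` on lung pixels, `exp(c)`
#' on container background, 1 in the water bath; `V = exp(-s*u)` on lung
#' pixels and 1 elsewhere.
#'
#' @param truth a `phantom_truth`.
#' @param params the matching [phantom_params()].
#' @return list with matrices `T_map` and `V_map`.
#' @export
true_signal_maps <- function(truth, params) {
  c0 <- params$container_log_offset
  T_map <- matrix(1, nrow(truth$u_map), ncol(truth$u_map))
  T_map[truth$container_mask] <- exp(c0)
  T_map[truth$lung_mask] <- exp(truth$u_map[truth$lung_mask] + c0)
  V_map <- exp(-truth$s_map * truth$u_map)
  list(T_map = T_map, V_map = V_map)
}

#' Forward-project a phantom into sample and reference stepping scans
#'
#' Simulates the phase-stepping acquisition. Per pixel the reference curve
#' is `I_k = I0 (1 + V0 cos(2 pi f_k + phi0))` and the sample curve is
#' `I_k = I0 T (1 + V0 V cos(2 pi f_k + phi0 + dphi))` with T and V from
#' [true_signal_maps()]. The differential phase is carried but set to zero
#' (the phase channel is retrieved downstream yet never analyzed). Poisson
#' noise is applied per frame when `noise_model = "poisson"`.
#'
#' @param truth a `phantom_truth`.
#' @param params the matching [phantom_params()].
#' @param phi0 global reference phase offset, radians.
#' @return list with `sample` and `reference`, both [step_scan()] objects.
#' @export
forward_project <- function(truth, params, phi0 = 0) {
  validate_phantom_params(params)
  if (!identical(dim(truth$u_map),
                 c(params$image_height, params$image_width)))
    stopf("truth and params disagree on image shape")
  N <- params$n_steps
  fr <- (seq_len(N) - 1) / N
  sig <- true_signal_maps(truth, params)
  I0 <- params$reference_flux
  V0 <- params$reference_visibility
  h <- nrow(sig$T_map); w <- ncol(sig$T_map)

  ref <- array(0, c(h, w, N))
  smp <- array(0, c(h, w, N))
  for (k in seq_len(N)) {
    mod_k <- cos(2 * pi * fr[k] + phi0)
    ref[, , k] <- I0 * (1 + V0 * mod_k)
    smp[, , k] <- I0 * sig$T_map * (1 + V0 * sig$V_map * mod_k)
  }
  if (params$noise_model == "poisson") {
    seed <- substream_seed(params$seed, "forward", truth$specimen_id,
                           truth$projection_index)
    withr_seed(seed, {
      ref[] <- stats::rpois(length(ref), ref)
      smp[] <- stats::rpois(length(smp), smp)
    })
  }
  mk <- function(frames, is_ref) step_scan(
    frames, step_fractions = fr, is_reference = is_ref,
    specimen_id = truth$specimen_id,
    projection_index = truth$projection_index)
  list(sample = mk(smp, FALSE), reference = mk(ref, TRUE))
}

#' Construct a phase-stepping scan object
#'
#' @param frames numeric array `h x w x n_steps` of non-negative counts.
#' @param step_fractions grating-period fractions in `[0, 1)`, strictly
#'   increasing, one per frame.
#' @param is_reference logical, sample-free acquisition?
#' @param specimen_id,projection_index acquisition metadata.
#' @return an object of class `step_scan`.
#' @export
step_scan <- function(frames, step_fractions, is_reference = FALSE,
                      specimen_id = NA_character_,
                      projection_index = NA_integer_) {
  if (length(dim(frames)) != 3)
    stopf("frames must be an h x w x n_steps array")
  n <- dim(frames)[3]
  if (length(step_fractions) != n)
    stopf("number of frames (%d) != number of step fractions (%d)",
          n, length(step_fractions))
  if (any(diff(step_fractions) <= 0) || any(step_fractions < 0) ||
      any(step_fractions >= 1))
    stopf("step_fractions must be strictly increasing within [0, 1)")
  if (any(frames < 0)) stopf("frames must be non-negative")
  structure(
    list(frames = frames, step_fractions = step_fractions,
         is_reference = isTRUE(is_reference),
         n_steps = n, specimen_id = specimen_id,
         projection_index = as.integer(projection_index)),
    class = "step_scan")
}

#' Generate a full phantom cohort
#'
#' Iterates over all specimens and projections, producing for each a
#' `phantom_truth` plus a sample/reference pair of stepping scans. To keep
#' memory bounded the raw stacks are not accumulated: supply `handler` to
#' consume each acquisition as it is produced (only its return value is
#' kept), or `out_dir` to stream TIFF/JSON files to disk. With neither, the
#' full list is returned (sensible only for small configurations).
#'
#' @param params a [phantom_params()] object.
#' @param handler optional `function(truth, sample, reference)`; its return
#'   values are collected and returned.
#' @param out_dir optional directory; scans and truth maps are written via
#'   [write_stepscan()] / [write_map_tiff()] and a manifest is returned.
#' @return list of handler results, a file manifest, or a list of
#'   `list(truth, sample, reference)` records.
#' @export
#' @examples
#' p <- phantom_params(image_height = 32, image_width = 32,
#'                     n_per_group = 1, n_projections = 1,
#'                     noise_model = "none")
#' cohort <- generate_cohort(p)
#' length(cohort)  # 2 specimens x 1 projection
generate_cohort <- function(params, handler = NULL, out_dir = NULL) {
  validate_phantom_params(params)
  specs <- cohort_specimens(params)
  out <- list()
  for (sp in specs) {
    for (pj in seq_len(params$n_projections)) {
      truth <- make_lung_phantom(params, sp, pj)
      fp <- forward_project(truth, params)
      key <- sprintf("%s_p%02d", sp, pj)
      if (!is.null(handler)) {
        out[[key]] <- handler(truth, fp$sample, fp$reference)
      } else if (!is.null(out_dir)) {
        out[[key]] <- write_acquisition(truth, fp$sample, fp$reference,
                                        out_dir, key)
      } else {
        out[[key]] <- list(truth = truth, sample = fp$sample,
                           reference = fp$reference)
      }
    }
  }
  out
}
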