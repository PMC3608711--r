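# File formats: multi-frame 32-bit TIFF for stepping scans and float maps
# (stored as fixed point in [0,1]; the sidecar/metadata records the scale),
# JSON sidecars for acquisition metadata, PNG for overlays.

SCAN_SCALE <- 2^16  # counts / SCAN_SCALE fits comfortably in [0, 1]

#' Write a stepping scan as multi-frame TIFF plus JSON sidecar
#'
#' Frame k of the TIFF is phase step k, stored as 32-bit samples scaled by
#' a factor recorded in the sidecar. Integer count frames (the usual case:
#' Poisson or noiseless integer flux) are marked `quantized = "counts"` so
#' the reader recovers them bit-exactly.
#'
#' @param scan a [step_scan()].
#' @param path output TIFF path; sidecar goes to `<path>.json`.
#' @return invisibly, the two file paths.
#' @export
write_stepscan <- function(scan, path) {
  stopifnot(inherits(scan, "step_scan"))
  mx <- max(scan$frames)
  scale <- if (mx <= SCAN_SCALE) SCAN_SCALE else 2^ceiling(log2(mx))
  frames <- lapply(seq_len(scan$n_steps),
                   function(k) scan$frames[, , k] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- list(
    n_steps = scan$n_steps,
    step_fractions = scan$step_fractions,
    is_reference = scan$is_reference,
    specimen_id = scan$specimen_id,
    projection_index = scan$projection_index,
    scale = scale,
    quantized = if (all(scan$frames == round(scan$frames))) "counts"
                else "none")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tiff = path, json = sidecar))
}

#' Read a stepping scan written by [write_stepscan()]
#'
#' Also accepts a foreign multi-frame TIFF without sidecar when `steps` is
#' given: uniform step fractions over one period are synthesized.
#'
#' @param path TIFF path.
#' @param sidecar sidecar path (default `<path>.json`); ignored when
#'   absent and `steps` is supplied.
#' @param steps frame count for sidecar-less files.
#' @return a [step_scan()].
#' @export
read_stepscan <- function(path, sidecar = paste0(path, ".json"),
                          steps = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  n <- length(frames)
  arr <- array(unlist(frames), c(dim(frames[[1]]), n))
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (meta$n_steps != n)
      stopf("sidecar declares %d steps but file has %d frames",
            meta$n_steps, n)
    arr <- arr * meta$scale
    if (identical(meta$quantized, "counts")) arr <- round(arr)
    step_scan(arr, meta$step_fractions,
              is_reference = isTRUE(meta$is_reference),
              specimen_id = meta$specimen_id,
              projection_index = meta$projection_index)
  } else {
    if (is.null(steps))
      stopf("no sidecar at '%s'; supply steps= for foreign TIFFs", sidecar)
    if (steps != n)
      stopf("steps = %d requested but file has %d frames", steps, n)
    step_scan(arr * SCAN_SCALE, (seq_len(n) - 1) / n)
  }
}

#' Write a float map (T, V, S, truth field) as 32-bit TIFF
#'
#' Values are scaled into [0, 1] by a per-file power-of-two factor written
#' into a sibling `.json` file; [read_map_tiff()] undoes the scaling.
#' Precision is ~1e-9 of the scale (32-bit fixed point).
#'
#' @param map numeric matrix (finite values; NAs stored as 0).
#' @param path output TIFF path.
#' @return invisibly, the TIFF path.
#' @export
write_map_tiff <- function(map, path) {
  m <- map
  m[!is.finite(m)] <- 0
  if (min(m) < 0) stopf("map contains negative values; not representable")
  mx <- max(m, 1e-12)
  scale <- 2^ceiling(log2(mx))
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a float map written by [write_map_tiff()]
#' @param path TIFF path.
#' @return numeric matrix.
#' @export
read_map_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tiff::readTIFF(path) * meta$scale
}

# write one acquisition (truth + scan pair) under out_dir with prefix key
write_acquisition <- function(truth, sample, reference, out_dir, key) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_s <- file.path(out_dir, paste0(key, "_sample.tif"))
  p_r <- file.path(out_dir, paste0(key, "_reference.tif"))
  write_stepscan(sample, p_s)
  write_stepscan(reference, p_r)
  p_u <- file.path(out_dir, paste0(key, "_truth_u.tif"))
  p_v <- file.path(out_dir, paste0(key, "_truth_s.tif"))
  write_map_tiff(truth$u_map, p_u)
  write_map_tiff(truth$s_map, p_v)
  meta <- list(specimen_id = truth$specimen_id,
               projection_index = truth$projection_index,
               group_label = truth$group_label)
  p_m <- file.path(out_dir, paste0(key, "_truth.json"))
  jsonlite::write_json(meta, p_m, auto_unbox = TRUE)
  c(sample = p_s, reference = p_r, truth_u = p_u, truth_s = p_v,
    truth_meta = p_m)
}
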