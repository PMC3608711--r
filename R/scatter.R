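#' Estimate the container background correction factor c
#'
#' Transmission is normalized against the water bath, but the true
#' background of the specimen is the formalin inside the plastic container,
#' which transmits slightly more than the surrounding water. The correction
#' is the log-ratio of the two ROI means:
#' `c = ln(mean T over formalin ROI / mean T over water ROI)`.
#'
#' @param T_map transmission matrix (water-normalized).
#' @param formalin_roi,water_roi disjoint logical ROI masks.
#' @param valid_mask optional validity mask intersected with both ROIs.
#' @return the scalar correction factor.
#' @export
#' @examples
#' Tm <- matrix(1, 4, 4); Tm[1:2, ] <- 1.0202
#' f <- matrix(FALSE, 4, 4); f[1:2, ] <- TRUE
#' estimate_correction(Tm, f, !f)  # 0.02
estimate_correction <- function(T_map, formalin_roi, water_roi,
                                valid_mask = NULL) {
  if (is.null(valid_mask)) valid_mask <- is.finite(T_map)
  f <- formalin_roi & valid_mask
  w <- water_roi & valid_mask
  if (!any(f)) stopf("formalin ROI is empty")
  if (!any(w)) stopf("water ROI is empty")
  mf <- mean(T_map[f]); mw <- mean(T_map[w])
  if (!is.finite(mf) || mf <= 0)
    stopf("formalin ROI has non-positive mean transmission (%g)", mf)
  if (!is.finite(mw) || mw <= 0)
    stopf("water ROI has non-positive mean transmission (%g)", mw)
  log(mf / mw)
}

#' Compute the normalized-scatter map S
#'
#' The thickness-invariant statistic
#' \deqn{S = \frac{-\ln V}{\ln T - c}}
#' i.e. the tissue's small-angle scatter normalized against its
#' background-corrected transmission. Both log-signals grow linearly with
#' path length, so their ratio depends only on the tissue's scattering
#' density, not on how much of it the beam traverses. S is evaluated on
#' `mask` where `ln T - c > eps`; pixels failing that floor are flagged
#' undefined and excluded from downstream statistics (their count is
#' reported).
#'
#' @param T_map,V_map water-normalized transmission and dark-field
#'   matrices (or equal-length vectors).
#' @param c_factor background correction factor, e.g. from
#'   [estimate_correction()].
#' @param mask logical analysis mask (typically the lung segmentation).
#' @param eps floor on the denominator `ln T - c`.
#' @param specimen_id,projection_index,group_label metadata carried along.
#' @return an object of class `scatter_result`: `S_map`, `c_used`,
#'   `defined_mask`, `n_undefined`, per-pixel vectors `T`, `V`, `S` over
#'   the defined mask, and metadata.
#' @export
#' @examples
#' r <- normalized_scatter(1.11, 0.66, 0.02, TRUE)
#' r$S  # ~ 4.93
normalized_scatter <- function(T_map, V_map, c_factor, mask,
                               eps = 1e-4,
                               specimen_id = NA_character_,
                               projection_index = NA_integer_,
                               group_label = NA_character_) {
  T_map <- as.matrix(T_map); V_map <- as.matrix(V_map)
  mask <- matrix(as.logical(mask), nrow(T_map), ncol(T_map))
  if (!is.finite(c_factor)) stopf("correction factor must be finite")
  if (!any(mask)) stopf("analysis mask is empty")
  denom <- log(T_map) - c_factor
  defined <- mask & is.finite(denom) & denom > eps &
    is.finite(V_map) & V_map > 0
  S_map <- matrix(NA_real_, nrow(T_map), ncol(T_map))
  S_map[defined] <- -log(V_map[defined]) / denom[defined]
  structure(
    list(S_map = S_map, c_used = c_factor, defined_mask = defined,
         n_undefined = sum(mask) - sum(defined),
         T = T_map[defined], V = V_map[defined], S = S_map[defined],
         specimen_id = specimen_id,
         projection_index = as.integer(projection_index),
         group_label = group_label),
    class = "scatter_result")
}

#' Group summaries with Mann-Whitney comparisons
#'
#' Summarizes transmission, dark-field and normalized scatter between the
#' emphysema and control groups. `level = "per_pixel"` pools every defined
#' pixel of every projection of every specimen in a group;
#' `level = "per_individual"` first reduces each specimen to the median of
#' its pooled pixels over all its projections, so each specimen contributes
#' one value. Medians and quartiles use linear interpolation; groups are
#' compared per parameter with a two-sided Mann-Whitney U test.
#'
#' Note the per-pixel test treats pixels as independent observations
#' (within-specimen spatial correlation is ignored), which is how pooled
#' per-pixel p-values in this design are conventionally reported.
#'
#' @param results list of `scatter_result` objects with group labels.
#' @param level `"per_pixel"` or `"per_individual"`.
#' @return a `data.frame` (class `group_summary`) with one row per group
#'   and parameter: `level, parameter, group, n, q1, median, q3, p_value`.
#' @export
summarize_groups <- function(results,
                             level = c("per_pixel", "per_individual")) {
  level <- match.arg(level)
  stopifnot(length(results) >= 2)
  groups <- vapply(results, function(r) r$group_label, character(1))
  if (!all(c("emphysema", "control") %in% groups))
    stopf("need at least one specimen per group")

  pooled <- function(grp, par) {
    vals <- lapply(results[groups == grp], function(r) r[[par]])
    if (level == "per_pixel") {
      unlist(vals, use.names = FALSE)
    } else {
      ids <- vapply(results[groups == grp], function(r) r$specimen_id,
                    character(1))
      vapply(split(vals, ids),
             function(v) stats::median(unlist(v, use.names = FALSE)),
             numeric(1))
    }
  }

  rows <- list()
  for (par in c("T", "V", "S")) {
    e <- pooled("emphysema", par)
    ctl <- pooled("control", par)
    if (length(e) == 0 || length(ctl) == 0)
      stopf("group with zero defined pixels for parameter %s", par)
    p <- suppressWarnings(
      stats::wilcox.test(e, ctl, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
    for (grp in c("emphysema", "control")) {
      x <- if (grp == "emphysema") e else ctl
      q <- quartiles(x)
      rows[[length(rows) + 1]] <- data.frame(
        level = level, parameter = par, group = grp, n = length(x),
        q1 = q[["q1"]], median = q[["median"]], q3 = q[["q3"]],
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}
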