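#' Empirical ROC curve
#'
#' Standard empirical receiver-operating-characteristic with tie handling
#' (one operating point per unique score, plus a `+Inf` sentinel). Scores
#' are first oriented so that larger values indicate disease
#' (`orientation = "less_is_diseased"` negates them); at threshold `t` a
#' unit is called diseased when its oriented score is `>= t`. The AUC is
#' the trapezoidal area, which for the empirical curve equals the
#' tie-corrected, rescaled Mann-Whitney U statistic.
#'
#' Orientations used in this pipeline: transmission
#' `greater_is_diseased` (emphysematous tissue is less dense), normalized
#' scatter `less_is_diseased` (destroyed alveolar walls scatter less per
#' unit thickness), dark-field `greater_is_diseased` by convention
#' (configurable; its discrimination is near chance by design).
#'
#' @param scores numeric scores, one per unit (pixel or individual).
#' @param labels logical (or coercible) disease labels, `TRUE` = diseased.
#' @param orientation `"greater_is_diseased"` or `"less_is_diseased"`.
#' @return an object of class `roc_curve`: `thresholds` (on the oriented
#'   scale), `sensitivity`, `specificity`, `auc`, `orientation`, `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' rc <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
#' rc$auc  # 0.75
roc_curve <- function(scores, labels,
                      orientation = c("greater_is_diseased",
                                      "less_is_diseased")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stopf("both classes must be present (n_pos = %d, n_neg = %d)",
          n_pos, n_neg)
  x <- if (orientation == "greater_is_diseased") scores else -scores
  pos <- sort(x[labels]); neg <- sort(x[!labels])
  thr <- c(sort(unique(x)), Inf)
  # at threshold t: sensitivity = P(pos >= t), specificity = P(neg < t)
  sens <- (n_pos - findInterval(thr, pos, left.open = TRUE)) / n_pos
  spec <- findInterval(thr, neg, left.open = TRUE) / n_neg
  fpr <- 1 - spec
  auc <- sum(-diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, orientation = orientation,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_curve")
}

# midrank structural components of the AUC (Sun & Xu fast DeLong form):
# v10[i] = mean_j psi(X_i, Y_j), v01[j] = mean_i psi(X_i, Y_j) with
# psi = 1, 1/2, 0 for X > Y, X = Y, X < Y.
auc_components <- function(x, labels) {
  m <- as.numeric(sum(labels)); n <- as.numeric(sum(!labels))
  r_all <- rank(x, ties.method = "average")
  r_pos <- rank(x[labels], ties.method = "average")
  r_neg <- rank(x[!labels], ties.method = "average")
  v10 <- (r_all[labels] - r_pos) / n
  v01 <- 1 - (r_all[!labels] - r_neg) / m
  auc <- (sum(r_all[labels]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same units using the
#' asymptotic variance-covariance of the AUC structural components
#' (DeLong's paired test, computed with midranks). The test statistic
#' `z = (auc_a - auc_b) / se` is referred to the standard normal; the
#' p-value is two-sided.
#'
#' @param scores_a,scores_b paired marker scores on identical units.
#' @param labels logical disease labels.
#' @param orientation_a,orientation_b per-marker score orientation (see
#'   [roc_curve()]).
#' @return an object of class `delong_result`: `auc_a`, `auc_b`, `cov`
#'   (2x2 covariance matrix of the AUCs), `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           orientation_a = "greater_is_diseased",
                           orientation_b = "greater_is_diseased") {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stopf("scores_a, scores_b and labels must be paired (equal length)")
  if (sum(labels) == 0 || sum(!labels) == 0)
    stopf("both classes must be present")
  xa <- if (orientation_a == "greater_is_diseased") scores_a else -scores_a
  xb <- if (orientation_b == "greater_is_diseased") scores_b else -scores_b
  a <- auc_components(xa, labels)
  b <- auc_components(xb, labels)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  covm <- s10 / a$m + s01 / a$n
  var_diff <- covm[1, 1] + covm[2, 2] - 2 * covm[1, 2]
  d <- a$auc - b$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (d != 0)
      warnf("degenerate DeLong variance (all components equal); p set to 1")
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
    if (p == 0) p <- .Machine$double.xmin  # keep p in (0, 1]
  }
  structure(
    list(auc_a = a$auc, auc_b = b$auc, cov = covm, z = z, p_value = p),
    class = "delong_result")
}

#' Operating cutoff from a ROC curve
#'
#' Default criterion `"youden"` maximizes J = sensitivity + specificity
#' - 1; ties are broken toward higher specificity. The returned cutoff is
#' placed halfway between the selected threshold and the next lower unique
#' score (for separated classes this is the midpoint of the gap), and is
#' reported on the original score scale of the marker.
#'
#' The printed per-pixel cutoffs of the reference ex-vivo dataset are
#' available as presets via [cutoff_preset()] (transmission 1.087,
#' dark-field 0.715, normalized scatter 7.00).
#'
#' @param curve a [roc_curve()].
#' @param criterion only `"youden"` currently.
#' @return scalar cutoff on the original score scale.
#' @export
optimal_cutoff <- function(curve, criterion = c("youden")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.max(curve$specificity[best])]  # ties: higher spec
  thr <- curve$thresholds
  t_hi <- thr[pick]
  t_lo <- if (pick > 1) thr[pick - 1] else
    t_hi - (if (length(thr) > 2) thr[2] - thr[1] else 1)
  if (!is.finite(t_hi)) {  # +Inf sentinel selected: everything negative
    t_hi <- t_lo + (t_lo - thr[max(1, pick - 2)])
  }
  cut <- (t_lo + t_hi) / 2
  if (curve$orientation == "less_is_diseased") -cut else cut
}

#' Sensitivity at a fixed specificity
#'
#' Reads the sensitivity at the smallest threshold whose specificity
#' reaches `spec_level` (a conservative, interpolation-free convention);
#' `interpolate = TRUE` instead interpolates linearly in specificity
#' between the two bracketing operating points.
#'
#' @param curve a [roc_curve()].
#' @param spec_level target specificity in (0, 1).
#' @param interpolate use linear interpolation between operating points.
#' @return scalar sensitivity.
#' @export
sensitivity_at_specificity <- function(curve, spec_level,
                                       interpolate = FALSE) {
  stopifnot(inherits(curve, "roc_curve"),
            spec_level > 0, spec_level < 1)
  i <- which(curve$specificity >= spec_level)[1]  # thresholds ascending
  if (!interpolate || i == 1 ||
      curve$specificity[i] == spec_level) return(curve$sensitivity[i])
  s0 <- curve$specificity[i - 1]; s1 <- curve$specificity[i]
  w <- (spec_level - s0) / (s1 - s0)
  (1 - w) * curve$sensitivity[i - 1] + w * curve$sensitivity[i]
}

#' Published per-pixel cutoff and control-IQR presets
#'
#' Cutoffs that maximized per-pixel discrimination in the reference
#' ex-vivo mouse dataset (`"table1"`), and the control-group per-pixel
#' interquartile ranges used to normalize parametric maps (`"control_iqr"`).
#' These are real-data constants for use in the mapping stage; the phantom
#' pipeline can also derive both quantities from its own run.
#'
#' @param what `"table1"` (cutoffs) or `"control_iqr"`.
#' @param parameter `"T"`, `"V"` or `"S"`.
#' @return scalar preset value.
#' @export
#' @examples
#' cutoff_preset("table1", "S")  # 7.00
cutoff_preset <- function(what = c("table1", "control_iqr"),
                          parameter = c("T", "V", "S")) {
  what <- match.arg(what)
  parameter <- match.arg(parameter)
  presets <- list(
    table1 = c(T = 1.087, V = 0.715, S = 7.00),
    control_iqr = c(T = 0.06, V = 0.37, S = 7.2)
  )
  unname(presets[[what]][parameter])
}
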