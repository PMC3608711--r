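#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages. The `phantom` block takes any
#' [phantom_params()] argument; the remaining blocks hold stage knobs:
#' retrieval validity floor; segmentation method, per-projection vs global
#' thresholding and minimum component size; the denominator floor of the
#' scatter statistic; ROC orientations and cutoff criterion; mapping cutoff
#' source (`"from_roc"` or `"table1"`), IQR source (`"from_run"` or
#' `"preset"`), colormap and which projection of each specimen to render.
#'
#' @param seed master seed propagated to every stochastic stage.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 0L) {
  structure(list(
    phantom = list(),
    retrieval = list(validity_floor = 0.01),
    segmentation = list(method = "valley", global_threshold = FALSE,
                        min_component = 20, manual_value = NULL),
    statistic = list(eps = 1e-4),
    roc = list(orientations = c(T = "greater_is_diseased",
                                V = "greater_is_diseased",
                                S = "less_is_diseased"),
               cutoff_criterion = "youden"),
    mapping = list(cutoff_source = "from_roc", iqr_source = "from_run",
                   colormap = c("#FFFF00", "#FF0000"), alpha_floor = 0.35,
                   projection = "middle"),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror [default_config()]; missing blocks keep their defaults.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), usr)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full phantom-to-maps analysis pipeline
#'
#' Executes, in order: phantom cohort simulation, phase-stepping signal
#' retrieval with water normalization, dark-field lung segmentation,
#' background-correction estimation and normalized-scatter computation,
#' group summaries with Mann-Whitney tests, per-pixel (and, with at least
#' two specimens per group, per-individual) ROC analysis with paired
#' DeLong comparisons, cutoff selection, and IQR-normalized parametric
#' emphysema maps. Identical configuration and seed give an identical
#' report and identical output files.
#'
#' @param config a `run_config` from [default_config()] or
#'   [load_config()].
#' @param out_dir optional output directory; when given, summary CSVs, the
#'   JSON report, deviation-map TIFFs and overlay PNGs are written and a
#'   checksum manifest is included in the report.
#' @return a `run_report` list: parameters used, correction factors,
#'   segmentation thresholds, group summaries, AUC/DeLong tables, cutoffs,
#'   control IQRs, sensitivities at 75% specificity, deviation-map AUCs
#'   against ground truth, undefined-pixel counts and (with `out_dir`) the
#'   file manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  t0 <- Sys.time()
  cfg <- config
  params <- do.call(phantom_params,
                    utils::modifyList(cfg$phantom, list(seed = cfg$seed)))

  # --- stages 0-1: simulate, retrieve, water-normalize (streamed) -------
  acq <- generate_cohort(params, handler = function(truth, smp, ref) {
    tri <- retrieve_signals(smp, ref,
                            validity_floor = cfg$retrieval$validity_floor)
    tri <- normalize_to_water(tri, truth$water_roi)
    list(triplet = tri,
         lung_mask = truth$lung_mask, formalin_roi = truth$formalin_roi,
         water_roi = truth$water_roi,
         group = truth$group_label, specimen = truth$specimen_id,
         projection = truth$projection_index,
         c_proj = estimate_correction(tri$T_map, truth$formalin_roi,
                                      truth$water_roi, tri$valid_mask))
  })

  specs <- cohort_specimens(params)
  spec_of <- vapply(acq, function(a) a$specimen, character(1))

  # --- stage 2: per-specimen correction factor --------------------------
  c_by_specimen <- vapply(specs, function(sp)
    mean(vapply(acq[spec_of == sp], function(a) a$c_proj, numeric(1))),
    numeric(1))
  c_mean <- mean(c_by_specimen)

  # --- stage 3: segmentation --------------------------------------------
  seg_cfg <- cfg$segmentation
  global_thr <- NULL
  if (isTRUE(seg_cfg$global_threshold)) {
    v_all <- unlist(lapply(acq, function(a)
      a$triplet$V_map[a$triplet$valid_mask]), use.names = FALSE)
    global_thr <- darkfield_threshold(v_all, method = seg_cfg$method,
                                      manual_value = seg_cfg$manual_value)
  }
  for (k in seq_along(acq)) {
    thr <- if (!is.null(global_thr)) global_thr else
      darkfield_threshold(acq[[k]]$triplet$V_map,
                          acq[[k]]$triplet$valid_mask,
                          method = seg_cfg$method,
                          manual_value = seg_cfg$manual_value)
    acq[[k]]$seg <- segment_lung(acq[[k]]$triplet, thr,
                                 min_component = seg_cfg$min_component,
                                 method = seg_cfg$method)
  }
  thresholds <- vapply(acq, function(a) a$seg$threshold, numeric(1))

  # --- stage 4: normalized scatter --------------------------------------
  scatter <- lapply(acq, function(a)
    normalized_scatter(a$triplet$T_map, a$triplet$V_map,
                       c_by_specimen[[a$specimen]], a$seg$mask,
                       eps = cfg$statistic$eps,
                       specimen_id = a$specimen,
                       projection_index = a$projection,
                       group_label = a$group))
  n_undefined <- sum(vapply(scatter, function(s) s$n_undefined, numeric(1)))

  summary_px <- summarize_groups(scatter, "per_pixel")
  summary_ind <- summarize_groups(scatter, "per_individual")

  # parameter recovery against ground truth: medians of the retrieved
  # channels pooled over the phantoms' true lung pixels per group (the
  # segmentation-independent check that retrieval + normalization recover
  # the generator's calibration)
  recovery <- {
    rows <- list()
    for (grp in c("emphysema", "control")) {
      sel <- which(vapply(acq, function(a) a$group, character(1)) == grp)
      tv <- lapply(acq[sel], function(a) {
        m <- a$lung_mask & a$triplet$valid_mask
        den <- log(a$triplet$T_map) - c_by_specimen[[a$specimen]]
        d <- m & is.finite(den) & den > cfg$statistic$eps
        list(T = a$triplet$T_map[m], V = a$triplet$V_map[m],
             S = -log(a$triplet$V_map[d]) / den[d])
      })
      for (par in c("T", "V", "S")) {
        x <- unlist(lapply(tv, `[[`, par), use.names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          group = grp, parameter = par, median = stats::median(x),
          n = length(x), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  }

  # --- stage 5: ROC / DeLong --------------------------------------------
  ori <- cfg$roc$orientations
  pool <- function(par) unlist(lapply(scatter, function(s) s[[par]]),
                               use.names = FALSE)
  px <- list(T = pool("T"), V = pool("V"), S = pool("S"))
  labels_px <- unlist(lapply(scatter, function(s)
    rep(s$group_label == "emphysema", length(s$S))), use.names = FALSE)

  roc_px <- lapply(c(T = "T", V = "V", S = "S"), function(p)
    roc_curve(px[[p]], labels_px, ori[[p]]))

  delong_px <- list(
    S_vs_T = delong_compare(px$S, px$T, labels_px, ori[["S"]], ori[["T"]]),
    S_vs_V = delong_compare(px$S, px$V, labels_px, ori[["S"]], ori[["V"]]),
    T_vs_V = delong_compare(px$T, px$V, labels_px, ori[["T"]], ori[["V"]]))

  roc_ind <- NULL
  warnings_out <- character(0)
  if (params$n_per_group >= 2) {
    ind_scores <- lapply(c(T = "T", V = "V", S = "S"), function(p)
      vapply(specs, function(sp) stats::median(unlist(
        lapply(scatter[spec_of == sp], function(s) s[[p]]),
        use.names = FALSE)), numeric(1)))
    labels_ind <- specimen_group(specs) == "emphysema"
    roc_ind <- lapply(c(T = "T", V = "V", S = "S"), function(p)
      roc_curve(ind_scores[[p]], labels_ind, ori[[p]]))
    warnings_out <- c(warnings_out, sprintf(
      paste("per-individual AUC with %d vs %d specimens lies on the grid",
            "{0, 1/%d, ...}; interpret with care"),
      params$n_per_group, params$n_per_group, params$n_per_group^2))
  } else {
    warnf("per-individual ROC skipped: needs >= 2 specimens per group")
    warnings_out <- c(warnings_out, "per-individual ROC skipped (n < 2)")
  }

  sens75 <- vapply(roc_px, sensitivity_at_specificity,
                   numeric(1), spec_level = 0.75)

  # --- stage 6: cutoffs, control IQRs, parametric maps ------------------
  map_cfg <- cfg$mapping
  cutoffs <- if (identical(map_cfg$cutoff_source, "table1")) {
    c(T = cutoff_preset("table1", "T"), V = cutoff_preset("table1", "V"),
      S = cutoff_preset("table1", "S"))
  } else {
    vapply(roc_px, optimal_cutoff, numeric(1),
           criterion = cfg$roc$cutoff_criterion)
  }
  control_iqr <- if (identical(map_cfg$iqr_source, "preset")) {
    c(T = cutoff_preset("control_iqr", "T"),
      V = cutoff_preset("control_iqr", "V"),
      S = cutoff_preset("control_iqr", "S"))
  } else {
    ctl <- summary_px[summary_px$group == "control", ]
    stats::setNames(ctl$q3 - ctl$q1, ctl$parameter)[c("T", "V", "S")]
  }

  # deviation-map discrimination vs ground truth, pooled over all pixels
  dev_vec <- function(p) {
    d <- if (ori[[p]] == "greater_is_diseased") px[[p]] - cutoffs[[p]]
         else cutoffs[[p]] - px[[p]]
    pmin(pmax(d / control_iqr[[p]], 0), 1)
  }
  map_auc <- vapply(c(T = "T", V = "V", S = "S"), function(p)
    roc_curve(dev_vec(p), labels_px, "greater_is_diseased")$auc,
    numeric(1))

  # rendered maps: one projection per specimen, all three parameters
  proj_pick <- if (identical(map_cfg$projection, "middle"))
    (params$n_projections + 1) %/% 2 else as.integer(map_cfg$projection)
  maps <- list()
  map_bg <- list()
  for (sp in specs) {
    k <- which(spec_of == sp &
                 vapply(acq, function(a) a$projection, integer(1)) ==
                 proj_pick)[1]
    a <- acq[[k]]; sc <- scatter[[k]]
    pmaps <- list(T = a$triplet$T_map, V = a$triplet$V_map, S = sc$S_map)
    for (p in c("T", "V", "S")) {
      msk <- if (p == "S") sc$defined_mask else a$seg$mask
      nm <- paste(sp, p, sep = "_")
      maps[[nm]] <- deviation_map(
        pmaps[[p]], msk, cutoffs[[p]], ori[[p]], control_iqr[[p]],
        parameter = p)
      map_bg[[nm]] <- a$triplet$T_map
    }
  }

  report <- list(
    generated = list(n_specimens = length(specs),
                     n_projections = length(acq),
                     image = c(params$image_height, params$image_width),
                     n_steps = params$n_steps, seed = cfg$seed,
                     noise_model = params$noise_model),
    c_by_specimen = as.list(c_by_specimen),
    c_mean = c_mean,
    segmentation = list(method = seg_cfg$method,
                        global = isTRUE(seg_cfg$global_threshold),
                        thresholds = stats::setNames(thresholds, names(acq))),
    summary_per_pixel = summary_px,
    summary_per_individual = summary_ind,
    recovery = recovery,
    auc = list(
      per_pixel = vapply(roc_px, function(r) r$auc, numeric(1)),
      per_individual = if (!is.null(roc_ind))
        vapply(roc_ind, function(r) r$auc, numeric(1)) else NULL),
    delong_per_pixel = lapply(delong_px, function(d)
      list(auc_a = d$auc_a, auc_b = d$auc_b, z = d$z, p_value = d$p_value)),
    cutoffs = as.list(cutoffs),
    control_iqr = as.list(control_iqr),
    sensitivity_at_75_specificity = as.list(sens75),
    map_auc_vs_truth = as.list(map_auc),
    n_undefined_pixels = n_undefined,
    warnings = warnings_out,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  report$roc_per_pixel <- roc_px
  report$deviation_maps <- maps

  if (!is.null(out_dir)) {
    report$manifest <- write_report_files(report, map_bg, out_dir, map_cfg)
  }
  class(report) <- "run_report"
  report
}

# write CSV/JSON/TIFF/PNG outputs; returns manifest with md5 checksums
write_report_files <- function(report, map_bg, out_dir, map_cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(p) { paths[[length(paths) + 1]] <<- p; p }

  summ <- rbind(report$summary_per_pixel, report$summary_per_individual)
  utils::write.csv(summ, w(file.path(out_dir, "group_summary.csv")),
                   row.names = FALSE)

  auc_df <- data.frame(
    level = "per_pixel", parameter = names(report$auc$per_pixel),
    auc = unname(report$auc$per_pixel), stringsAsFactors = FALSE)
  if (!is.null(report$auc$per_individual))
    auc_df <- rbind(auc_df, data.frame(
      level = "per_individual", parameter = names(report$auc$per_individual),
      auc = unname(report$auc$per_individual), stringsAsFactors = FALSE))
  utils::write.csv(auc_df, w(file.path(out_dir, "auc_table.csv")),
                   row.names = FALSE)

  for (p in names(report$roc_per_pixel)) {
    rc <- report$roc_per_pixel[[p]]
    utils::write.csv(
      data.frame(threshold = rc$thresholds, sensitivity = rc$sensitivity,
                 specificity = rc$specificity),
      w(file.path(out_dir, sprintf("roc_points_%s.csv", p))),
      row.names = FALSE)
  }

  for (nm in names(report$deviation_maps)) {
    dm <- report$deviation_maps[[nm]]
    write_map_tiff(dm$values,
                   w(file.path(out_dir, sprintf("devmap_%s.tif", nm))))
    rgb <- render_overlay(map_bg[[nm]], dm,
                          colormap = map_cfg$colormap,
                          alpha_floor = map_cfg$alpha_floor)
    png::writePNG(rgb, w(file.path(out_dir, sprintf("overlay_%s.png", nm))))
  }

  # runtime excluded: the JSON must be byte-identical across reruns
  core <- report[setdiff(names(report),
                         c("roc_per_pixel", "deviation_maps", "manifest",
                           "runtime_s"))]
  jp <- w(file.path(out_dir, "report.json"))
  jsonlite::write_json(core, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)

  paths <- unlist(paths)
  # map sidecars written alongside dev-map TIFFs
  extra <- paste0(grep("devmap_.*\\.tif$", paths, value = TRUE), ".json")
  manifest <- data.frame(
    file = basename(c(paths, extra)),
    md5 = unname(tools::md5sum(c(paths, extra))),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
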