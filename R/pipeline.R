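# End-to-end pipeline orchestration and configuration handling.

#' Pipeline configuration
#'
#' Collects every stage's tunables with the project defaults: threshold
#' (NULL = Otsu), morphological closing radius, indicator smoothing,
#' cutting-plane optimizer settings, feature-curve settings, SIFT
#' scale-space settings, the Canny constants (sigma 1.2, thresholds
#' 0.3/0.7), the ratio-test threshold 0.75, the px calibration and the
#' overlay options.
#'
#' @param threshold Segmentation threshold (`NULL` for Otsu).
#' @param morph_radius Closing radius (voxels).
#' @param smooth_sigma Indicator smoothing (voxels) before iso-extraction.
#' @param optimize An [optimize_config()].
#' @param grow A [grow_config()].
#' @param feature_percentile,feature_measure Feature-point selection.
#' @param sift A [scale_space_config()].
#' @param canny_sigma,canny_low,canny_high Canny constants.
#' @param tau_ratio SIFT ratio-test threshold.
#' @param calib_mm_per_px Pixel calibration for registration.
#' @param overlay An [overlay_spec()].
#' @param seed Global seed for stochastic components.
#' @export
pipeline_config <- function(threshold = NULL, morph_radius = 1,
                            smooth_sigma = 1, optimize = optimize_config(),
                            grow = grow_config(), feature_percentile = 95,
                            feature_measure = "max_principal",
                            sift = scale_space_config(), canny_sigma = 1.2,
                            canny_low = 0.3, canny_high = 0.7,
                            tau_ratio = 0.75, calib_mm_per_px = 0.1,
                            overlay = overlay_spec(), seed = 1L) {
  list(threshold = threshold, morph_radius = morph_radius,
       smooth_sigma = smooth_sigma, optimize = optimize, grow = grow,
       feature_percentile = feature_percentile,
       feature_measure = feature_measure, sift = sift,
       canny_sigma = canny_sigma, canny_low = canny_low,
       canny_high = canny_high, tau_ratio = tau_ratio,
       calib_mm_per_px = calib_mm_per_px, overlay = overlay,
       seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected; sub-configuration lists are merged
#' over the defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (nm in names(raw)) {
    if (is.list(defaults[[nm]]) && is.list(raw[[nm]])) {
      sub_unknown <- setdiff(names(raw[[nm]]), names(defaults[[nm]]))
      if (length(sub_unknown) > 0)
        stop("unknown keys under ", nm, ": ",
             paste(sub_unknown, collapse = ", "))
      defaults[[nm]] <- modifyList(defaults[[nm]], raw[[nm]])
    } else {
      defaults[[nm]] <- raw[[nm]]
    }
  }
  defaults
}

#' Run the full navigation pipeline
#'
#' Stages: surface reconstruction, sagittal-plane optimization, medial
#' resection, feature-curve extraction, BH-grid construction, and - when
#' frames are supplied - frame registration and overlay rendering. Every
#' stage writes its artifact into `out_dir` and is recorded in
#' `manifest.json` (with the config echo and MD5 hashes); a stage failure
#' halts the run with a stage-tagged error.
#'
#' @param volume A [volume_image()] or NIfTI path.
#' @param landmarks Landmark list (see [read_landmarks()]) or JSON path;
#'   must contain `anterior_notch`, `posterior_notch`, and for resection a
#'   `lateral_marker` (and optionally `medial_point`, `transverse_normal`,
#'   `roof_polyline`).
#' @param frames Optional list of frame matrices or PNG paths.
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest (invisibly): per-stage artifact paths and hashes.
#' @export
run_pipeline <- function(volume, landmarks, frames = NULL,
                         cfg = pipeline_config(), out_dir = tempfile("cnav")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("condylenav")),
                   config = cfg, stages = list())
  t_all <- Sys.time()
  self <- environment()  # stage expressions assign results here
  stage <- function(name, expr) {
    t0 <- Sys.time()
    value <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- c(value,
      list(seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    invisible(NULL)
  }

  if (is.character(volume)) volume <- read_volume(volume)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  if (is.null(landmarks$anterior_notch) || is.null(landmarks$posterior_notch))
    stop("stage 'sagittal-plane' failed: missing notch landmarks",
         call. = FALSE)

  mesh <- NULL
  stage("reconstruct", {
    mask <- segment_volume(volume, cfg$threshold)
    mask <- refine_mask(mask, cfg$morph_radius)
    self$mesh <- extract_surface(mask, volume$spacing, volume$origin,
                             cfg$smooth_sigma)
    p <- file.path(out_dir, "femur.ply")
    write_ply(mesh, p)
    list(path = p, n_vertices = nrow(mesh$vertices))
  })

  opt <- NULL
  stage("optimize-plane", {
    init <- initial_sagittal_plane(landmarks$anterior_notch,
                                   landmarks$posterior_notch,
                                   landmarks$transverse_normal %||% c(0, 0, 1),
                                   landmarks$medial_point)
    self$opt <- optimize_cutting_plane(mesh, init, cfg$optimize)
    p <- file.path(out_dir, "plane.json")
    jsonlite::write_json(list(normal = opt$plane$normal,
                              offset = opt$plane$offset,
                              objective = opt$objective[
                                c("mean_eccentricity", "focal_dispersion",
                                  "objective")]),
                         p, auto_unbox = TRUE, digits = NA)
    list(path = p, objective = opt$objective$objective)
  })

  lateral <- NULL
  stage("resect", {
    if (is.null(landmarks$lateral_marker))
      stop("missing lateral_marker landmark")
    self$lateral <- resect_medial(mesh, opt$plane, landmarks$lateral_marker)
    p <- file.path(out_dir, "lateral.ply")
    write_ply(lateral, p)
    list(path = p, n_vertices = nrow(lateral$vertices))
  })

  curves <- NULL
  stage("features", {
    self$curves <- extract_clr(lateral, opt$plane,
                           superior_limit = landmarks$posterior_notch,
                           percentile = cfg$feature_percentile,
                           measure = cfg$feature_measure, cfg = cfg$grow)
    p <- file.path(out_dir, "curves.json")
    write_curves_json(curves, p)
    list(path = p, n_curves = length(curves),
         labels = vapply(curves, function(s) s$label, character(1)))
  })

  grid <- NULL
  proj <- NULL
  stage("grid", {
    axis <- opt$plane$normal  # epicondylar axis: perpendicular to the plane
    roof <- landmarks$roof_polyline %||%
      rbind(as.numeric(landmarks$posterior_notch),
            as.numeric(landmarks$anterior_notch))
    self$proj <- lateral_projection(lateral, axis)
    B <- blumensaat_line(proj, rbind3(roof))
    self$grid <- build_grid(proj, B)
    p <- file.path(out_dir, "grid.json")
    write_grid_json(grid, p)
    list(path = p, L_D = grid$L_D, L_H = grid$L_H)
  })

  if (!is.null(frames)) {
    frames <- lapply(frames, function(f)
      if (is.character(f)) read_image(f) else as_gray(f))
    clr <- Filter(function(s) s$label == "CLR", curves)
    model_curves <- lapply(clr, function(s) proj$project(s$points))
    # add the lateral-silhouette boundary: the registration needs more
    # structure than the CLR arc alone
    hull <- grDevices::chull(proj$points2d)
    model_curves <- c(model_curves,
                      list(proj$points2d[c(hull, hull[1]), , drop = FALSE]))
    reg <- NULL
    stage("register", {
      self$reg <- register_frame(frames[[1]], model_curves,
                             calib = cfg$calib_mm_per_px,
                             tau = cfg$tau_ratio)
      p <- file.path(out_dir, "transform.json")
      write_registration_json(reg, p)
      if (reg$status != "ok") stop("registration failed: ",
                                   reg$diagnostics$reason)
      list(path = p, rmse_mm = reg$rmse_mm, n_matches = reg$n_matches)
    })
    stage("overlay", {
      tr <- track_frames(frames, model_curves, calib = cfg$calib_mm_per_px,
                         init_f = reg$transform)
      paths <- character(0)
      for (i in seq_along(frames)) {
        if (is.null(tr$transforms[[i]])) next
        pg <- project_grid(grid, tr$transforms[[i]], cfg$calib_mm_per_px,
                           boundary_curves = model_curves)
        img <- render_overlay(frames[[i]], pg, cfg$overlay)
        p <- file.path(out_dir, sprintf("overlay_%03d.png", i))
        write_image(img, p)
        paths <- c(paths, p)
      }
      logp <- file.path(out_dir, "tracking_log.json")
      jsonlite::write_json(tr$log, logp, auto_unbox = TRUE, digits = NA)
      list(path = logp, frames = paths,
           n_ok = sum(tr$log$status == "ok"))
    })
  }

  manifest$seconds_total <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  artifact_paths <- unlist(lapply(manifest$stages, function(s) s$path))
  manifest$hashes <- as.list(tools::md5sum(artifact_paths))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
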