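#' Run the full simulate-localize-quality-resolution-render-register pipeline
#'
#' Executes the configured stages in order, writing every artifact class to
#' the output directory together with a manifest (parameters, seeds and md5
#' hashes of all outputs). Identical config and seed give identical
#' manifests. A stage failure aborts with the failing stage named; partial
#' outputs are retained on disk.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   named list. Recognized top-level keys: `seed`, `output_dir`,
#'   `simulate`, `localize`, `quality`, `resolution`, `render`, `register`.
#'   Unknown keys are a validation error before anything runs. See the demo
#'   config shipped at
#'   `system.file("extdata", "demo_config.yaml", package = "smlmpipe")`.
#' @param output_dir Overrides the config's output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  allowed <- c("seed", "output_dir", "simulate", "localize", "quality",
               "resolution", "render", "register")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop_smlm(sprintf("run_pipeline: unknown config key '%s' (allowed: %s)",
                      unknown[1], paste(allowed, collapse = ", ")))
  }
  if (is.null(cfg$seed)) stop_smlm("run_pipeline: config must set a seed")
  seed <- as.integer(cfg$seed)
  out <- output_dir %||% cfg$output_dir %||% "smlmpipe_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  add <- function(p) artifacts <<- c(artifacts, p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_smlm(sprintf("run_pipeline: stage '%s' failed: %s", name,
                        conditionMessage(e)))
    })
  }

  sim <- cfg$simulate %||% list()
  fov <- as.numeric(sim$field_of_view %||% c(4000, 4000))
  cam <- do.call(camera_model, sim$camera %||% list())
  psf <- do.call(psf_model, sim$psf %||% list())
  sw <- do.call(switching_params, sim$switching %||% list())
  n_fr <- sim$n_frames %||% 100

  env <- new.env()
  stage("simulate", {
    st <- sim$structure %||% list(kind = "membrane_pair")
    env$emitters <- generate_structure(st$kind %||% "membrane_pair",
                                       st$params %||% list(), fov, seed)
    env$schedule <- simulate_switching(env$emitters, sw, n_fr, cam, seed + 1L)
    env$movie <- render_movie(env$schedule, psf, cam,
                              background = sim$background %||% 2,
                              noise = TRUE, seed = seed + 2L)
    write_movie(env$movie, file.path(out, "movie.tif"))
    add(file.path(out, c("movie.tif", "movie.tif.yaml")))
    env$gt <- write_ground_truth(env$schedule, cam, file.path(out, "ground_truth.csv"))
    add(file.path(out, "ground_truth.csv"))
    emc <- sim$em %||% list()
    env$true_transform <- similarity_transform(
      scale = emc$scale %||% 0.05, angle_deg = emc$rotation_deg %||% 0,
      translation = as.numeric(emc$translation %||% c(0, 0)))
    env$em <- synthesize_em_image(env$emitters, env$true_transform,
                                  size = as.integer(emc$size %||% c(256, 256)),
                                  noise_level = emc$noise_level %||% 0.02,
                                  seed = seed + 3L)
    tiff::writeTIFF(env$em$image, file.path(out, "em.tif"))
    add(file.path(out, "em.tif"))
  })

  stage("localize", {
    settings <- do.call(localize_settings, cfg$localize %||% list())
    env$locs <- localize_movie(env$movie, psf, settings)
    write_localizations(env$locs, file.path(out, "localizations.csv"))
    add(file.path(out, "localizations.csv"))
    if (!is.null(attr(env$locs, "unmerged"))) {
      # per-frame records before burst merging; adjacent-frame accuracy
      # estimation and per-frame detection-rate statistics use these
      write_localizations(attr(env$locs, "unmerged"),
                          file.path(out, "localizations_unmerged.csv"))
      add(file.path(out, "localizations_unmerged.csv"))
    }
  })

  stage("quality", {
    q <- cfg$quality %||% list()
    radius <- q$search_radius %||% 200
    env$nena <- estimate_accuracy_nena(env$locs, radius)
    jsonlite::write_json(glance(env$nena), file.path(out, "accuracy.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    add(file.path(out, "accuracy.json"))
    if (!is.null(q$n_epochs) && q$n_epochs >= 2) {
      tr <- accuracy_trend(env$locs, q$n_epochs, radius)
      utils::write.csv(as.data.frame(tr), file.path(out, "accuracy_trend.csv"),
                       row.names = FALSE)
      add(file.path(out, "accuracy_trend.csv"))
    }
  })

  stage("resolution", {
    r <- cfg$resolution %||% list()
    env$densres <- estimate_resolution(env$locs, env$nena$sigma_loc,
                                       K = r$K %||% 20)
    utils::write.csv(as.data.frame(env$densres),
                     file.path(out, "resolution.csv"), row.names = FALSE)
    jsonlite::write_json(glance(env$densres),
                         file.path(out, "resolution_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    add(file.path(out, c("resolution.csv", "resolution_summary.json")))
  })

  stage("render", {
    rs <- do.call(render_settings, cfg$render %||% list())
    env$sr <- render_sr_image(env$locs, env$densres, rs)
    paths <- write_sr_image(env$sr, file.path(out, "sr"))
    add(paths)
    wf <- render_widefield_reference(env$locs, out_pixel_nm = rs$out_pixel_nm)
    tiff::writeTIFF(wf / max(max(wf), 1e-12), file.path(out, "widefield.tif"),
                    bits.per.sample = 16)
    add(file.path(out, "widefield.tif"))
  })

  stage("register", {
    rg <- cfg$register %||% list()
    # control points: well-spread ground-truth emitters seen in both frames
    n_cp <- min(rg$n_points %||% 6, nrow(env$emitters))
    idx <- unique(round(seq(1, nrow(env$emitters), length.out = n_cp)))
    src <- cbind(env$emitters$x_nm[idx], env$emitters$y_nm[idx])
    dst <- transform_xy(src, env$true_transform)
    cp <- tibble(smlm_x_nm = src[, 1], smlm_y_nm = src[, 2],
                 em_x_px = dst[, 1], em_y_px = dst[, 2])
    write_control_points(cp, file.path(out, "control_points.csv"))
    env$transform <- estimate_transform(cp, rg$kind %||% "similarity")
    write_transform(env$transform, file.path(out, "transform.json"))
    add(file.path(out, c("control_points.csv", "transform.json")))
    ov <- make_overlay(env$sr$rgb, env$em$image, env$transform,
                       alpha = rg$alpha %||% 0.5,
                       sr_pixel_nm = attr(env$sr, "pixel_nm"))
    if (requireNamespace("png", quietly = TRUE)) {
      png::writePNG(ov, file.path(out, "overlay.png"))
      add(file.path(out, "overlay.png"))
    }
  })

  manifest <- list(
    config = cfg, seed = seed,
    package_version = as.character(utils::packageVersion("smlmpipe")),
    artifacts = lapply(setNames(nm = basename(artifacts)), function(a) {
      list(md5 = unname(tools::md5sum(file.path(out, a))))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
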