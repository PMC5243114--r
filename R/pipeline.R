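#' Default pipeline configuration
#'
#' One configuration list drives the whole demo pipeline: geometry,
#' simulation parameters, analysis windows/bins, segmentation and surface
#' reconstruction settings.  Serializable to YAML and back without loss
#' ([read_run_config()] / [write_run_config()]).
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    geometry = list(center = c(0, 0, 0), outer_semiaxes = c(50, 40, 40),
                    shell_thickness = 12),
    sim = list(n0 = 250L, t0 = 18, t1 = 30, dt = 1 / 12,
               division_rate_nonsensory = 0.07,
               division_rate_sensory = 0.03,
               delam_prob = 0.25, delam_front_speed = 0.125,
               diff_onset_rate = 0.6, noise_xyz = 0.15,
               delam_domain = "neurogenic"),
    analysis = list(window = c(18, 30), intervals = c(18, 20, 22, 24, 30),
                    k_hysteresis = 3L, density_radius = 20, t_ref = 30,
                    density_t = 24),
    segmentation = list(enabled = TRUE, wa = 1, wc = 1, sigma = 0.5, K = 300,
                        iso = 0.55, cell_radius = 14, img_size = 64L),
    reconstruction = list(enabled = TRUE, n_points = 300L, noise = 0.5,
                          subdiv = 3L, wa = 1, wc = 0.05, dt = 0.5,
                          n_steps = 500L))
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return `read_run_config` returns the list; `write_run_config` the path,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(status = "ok", value = expr),
                  error = function(e) list(status = "failed",
                                           error = conditionMessage(e)))
  report$stages[[name]] <- res[setdiff(names(res), "value")]
  report$values[[name]] <- res$value
  report
}

#' Run the full synthetic-to-report pipeline
#'
#' simulate -> lineage forest -> delamination/differentiation analytics ->
#' spatial statistics -> single-cell segmentation -> vesicle surface
#' reconstruction, writing the result tables and a JSON report into
#' `out_dir`.  A failed stage is recorded in the report and the pipeline
#' continues where dependencies allow.  With a fixed seed the run is fully
#' deterministic ([pipeline_checksums()] digests the outputs).
#'
#' @param config configuration list ([default_run_config()]) or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return the report list, invisibly; files in `out_dir`: `tracks.csv`,
#'   `delaminations.csv`, `division_behavior.csv`, `sister_delays.csv`,
#'   `density.csv`, `nn_summary.csv`, `report.json`, `config.yaml`,
#'   `run.log`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("oticmap_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logit <- function(...) log_lines <<- c(log_lines, paste0(...))
  report <- list(package_version = as.character(utils::packageVersion("oticmap")),
                 config = config, seeds = list(), stages = list(),
                 values = list())
  seed_of <- function(stage, off) {
    s <- ((config$seed %% 1000003L) * 1009L + off) %% .Machine$integer.max
    report$seeds[[stage]] <<- s
    s
  }

  geom <- vesicle_geometry(config$geometry$center,
                           config$geometry$outer_semiaxes,
                           config$geometry$shell_thickness)
  sp <- do.call(sim_params, c(config$sim, list(seed = seed_of("simulate", 1L))))
  logit("simulate: n0=", sp$n0, " window=[", sp$t0, ",", sp$t1, "] seed=",
        sp$seed)

  sim <- NULL
  report <- run_stage(report, "simulate", {
    sim <- simulate_epithelium(geom, sp)
    write_tracks(sim$tracks, file.path(out_dir, "tracks.csv"))
    list(n_tracks = length(unique(sim$tracks$cell_id)),
         n_rows = nrow(sim$tracks))
  })

  forest <- NULL; events <- NULL
  report <- run_stage(report, "lineage", {
    forest <- build_forest(sim$tracks)
    list(n_founders = length(forest$founders),
         n_divisions = nrow(forest$divisions),
         n_terminal = sum(forest$info$terminal))
  })

  an <- config$analysis
  report <- run_stage(report, "delamination", {
    events <- detect_delamination(forest, geom, an$k_hysteresis, an$intervals)
    utils::write.csv(events, file.path(out_dir, "delaminations.csv"),
                     row.names = FALSE)
    frac <- delaminated_fraction(forest, events, an$window[1],
                                 min(an$window[1] + 4, an$window[2]), geom)
    list(n_events = nrow(events),
         interval_counts = as.list(table(events$interval_class)),
         delaminated_fraction_4h = frac$fraction)
  })

  report <- run_stage(report, "division_behavior", {
    cb <- classify_division_behavior(forest, events, an$window)
    utils::write.csv(cb$classes, file.path(out_dir, "division_behavior.csv"),
                     row.names = FALSE)
    sd <- sister_delay(forest, events)
    utils::write.csv(sd, file.path(out_dir, "sister_delays.csv"),
                     row.names = FALSE)
    list(counts = as.list(cb$counts),
         n_sister_pairs = nrow(sd),
         n_long_delay = sum(sd$long_delay, na.rm = TRUE))
  })

  report <- run_stage(report, "correspondence", {
    if (nrow(events) < 5) stop("fewer than 5 delamination events")
    sag <- do.call(rbind, lapply(events$cell_id, function(id) {
      d <- forest$tracks[[as.character(id)]]
      d[nrow(d), c("cell_id", "x_um", "y_um", "z_um")]
    }))
    rAP <- positional_correspondence(events, sag, "AP",
                                     seed = seed_of("correspondence", 2L))
    rML <- positional_correspondence(events, sag, "ML",
                                     seed = report$seeds$correspondence)
    list(rho_AP = rAP$rho, p_AP = rAP$p_perm,
         rho_ML = rML$rho, p_ML = rML$p_perm, n = rAP$n)
  })

  report <- run_stage(report, "differentiation", {
    dev <- detect_differentiation(forest)
    viol <- postmitotic_check(forest, dev)
    list(n_events = nrow(dev), n_AM = sum(dev$patch == "AM"),
         n_PM = sum(dev$patch == "PM"), postmitotic_violations = nrow(viol))
  })

  report <- run_stage(report, "spatialstats", {
    td <- an$density_t
    frame <- sim$tracks[abs(sim$tracks$t_hpf - snap_time(td, sp$t0, sp$dt)) < 1e-9, ]
    dens <- local_density(frame, r = an$density_radius)
    utils::write.csv(cbind(t_hpf = td, dens), file.path(out_dir, "density.csv"),
                     row.names = FALSE)
    nn <- nn_distance(frame)
    nn$t_hpf <- td
    utils::write.csv(summarize_nn(nn), file.path(out_dir, "nn_summary.csv"),
                     row.names = FALSE)
    list(n_cells = nrow(frame),
         median_density = stats::median(dens$density),
         median_nn = stats::median(nn$nn_dist))
  })

  if (isTRUE(config$segmentation$enabled)) {
    report <- run_stage(report, "segmentation", {
      sg <- config$segmentation
      n <- sg$img_size
      ctr <- rbind(c(n / 2, n / 2, n / 2))
      colnames(ctr) <- c("x_um", "y_um", "z_um")
      ri <- render_images(ctr, geom = NULL, voxel_size = 1, psf_sigma = 0.8,
                          dim = rep(n, 3), origin = c(0, 0, 0),
                          cell_radius = sg$cell_radius)
      seeds <- sweep(rbind(c(0, 0, 0), c(-4, 0, 0), c(4, 0, 0)), 2, ctr[1, ], "+")
      seg <- segment_cell(ri$membranes, seeds, radius = sg$cell_radius * 0.6,
                          params = gsubsurf_params(wa = sg$wa, wc = sg$wc,
                                                   eps = 1, dt = 0.5,
                                                   tol = 1e-6, max_iter = 500),
                          sigma = sg$sigma, K = sg$K, iso = sg$iso)
      truth_mask <- ri$masks > 0
      jac <- sum(seg$mask & truth_mask) / sum(seg$mask | truth_mask)
      list(jaccard = jac,
           volume_voxel_um3 = seg$volume_voxel_um3,
           volume_mesh_um3 = seg$volume_mesh_um3,
           volume_true_um3 = sum(truth_mask),
           iterations = seg$evolution$iterations)
    })
  }

  if (isTRUE(config$reconstruction$enabled)) {
    report <- run_stage(report, "reconstruction", {
      rc <- config$reconstruction
      pin <- sample_surface_points(geom, "inner", rc$n_points, rc$noise,
                                   seed = seed_of("reconstruction", 3L))
      pout <- sample_surface_points(geom, "outer", rc$n_points, rc$noise,
                                    seed = report$seeds$reconstruction + 1L)
      mp <- mesh_evolve_params(wa = rc$wa, wc = rc$wc, dt = rc$dt,
                               n_steps = rc$n_steps)
      vv <- vesicle_volumes(pin, pout, params = mp, subdiv = rc$subdiv)
      write_mesh(vv$meshes$outer, file.path(out_dir, "outer_wall.ply"))
      write_mesh(vv$meshes$inner, file.path(out_dir, "inner_wall.ply"))
      list(outer_enclosed_um3 = vv$outer_enclosed,
           inner_enclosed_um3 = vv$inner_enclosed,
           shell_um3 = vv$shell)
    })
  }

  report$log <- NULL
  write_run_config(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(report[c("package_version", "config", "seeds",
                                "stages", "values")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logit("done: ", sum(vapply(report$stages, function(s) s$status == "ok",
                             logical(1))), "/", length(report$stages),
        " stages ok")
  writeLines(c(paste("oticmap pipeline", format(Sys.time())), log_lines),
             file.path(out_dir, "run.log"))
  invisible(report)
}

#' Checksums of a pipeline output directory
#'
#' MD5 digests of every output file except the (timestamped) log, for
#' verifying that fixed-seed runs are identical.
#'
#' @param dir pipeline output directory.
#' @return named character vector of digests.
#' @export
pipeline_checksums <- function(dir) {
  files <- setdiff(list.files(dir), "run.log")
  md5 <- tools::md5sum(file.path(dir, files))
  names(md5) <- files
  md5
}
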