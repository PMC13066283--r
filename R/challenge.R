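#' Simulate a complete scan from a phantom scene
#'
#' Scales the ground-truth activity so that the total expected true counts
#' hit `counts_target`, builds the multiplicative/additive factors, predicts
#' the expected data and draws one Poisson realisation.
#'
#' @param scene a `phantom_scene`.
#' @param geom a `projector_geometry` (default: [default_geometry()]).
#' @param counts_target total expected true counts.
#' @param seed seed for the Poisson draw.
#' @param scatter_fraction,efficiency,virtual_bins see [make_factors()].
#' @return List with `activity` (count-scaled truth), `factors`, `ybar`,
#'   `y`, `scale`, `geom`.
#' @export
simulate_scan <- function(scene, geom = default_geometry(scene$activity),
                          counts_target = 1e6, seed = 1L,
                          scatter_fraction = 0.1, efficiency = 1,
                          virtual_bins = NULL) {
  att <- forward_project(scene$mu, geom)
  mv <- efficiency * exp(-att$values)
  if (!is.null(virtual_bins)) mv[virtual_bins] <- 0
  trues_raw <- forward_project(scene$activity, geom)$values
  tot <- sum(mv * trues_raw)
  if (tot <= 0) stop("scene produces no expected counts")
  scale <- counts_target / tot
  activity <- with_values(scene$activity, scene$activity$values * scale)
  factors <- make_factors(scene, geom, activity = activity,
                          efficiency = efficiency,
                          scatter_fraction = scatter_fraction,
                          virtual_bins = virtual_bins)
  ybar <- predict_counts(activity, geom, factors)
  y <- sample_counts(ybar, seed = seed)
  list(activity = activity, factors = factors, ybar = ybar, y = y,
       scale = scale, geom = geom)
}

#' Score a solver trace against a reference image
#'
#' Builds the metric trace and extracts the joint pass time plus one pass
#' time per metric (for per-metric ranking).
#' @param st a `solver_trace` with recorded images.
#' @param r reference image.
#' @param vois a [voi_set()].
#' @param th a [thresholds()].
#' @return List with `metrics` (a [metric_trace()]), `overall` (joint
#'   [pass_time()]) and `per_metric` (named list of pass times).
#' @export
score_trace <- function(st, r, vois, th = thresholds()) {
  mt <- metric_trace(st, r, vois, th)
  per <- lapply(metric_columns(mt), function(mc) pass_time(mt, th, mc))
  names(per) <- metric_columns(mt)
  list(metrics = mt, overall = pass_time(mt, th, "all"), per_metric = per)
}

challenge_thresholds <- function(cfg) {
  thresholds(whole_rmse = cfg$whole_rmse,
             background_rmse = cfg$background_rmse,
             voi_aem = cfg$voi_aem, persistence = cfg$persistence,
             time_cap = cfg$time_cap)
}

challenge_scene <- function(cfg) {
  generate_phantom(cfg$phantom, dims = c(cfg$size, cfg$size),
                   voxel_size = cfg$voxel_size, contrast = cfg$contrast,
                   seed = derive_seed(cfg$seed, "phantom"))
}

challenge_geometry <- function(cfg, scene) {
  g <- default_geometry(scene$activity, n_views = cfg$n_views)
  if (g$n_views %% cfg$n_subsets != 0L)
    stop("n_subsets (", cfg$n_subsets, ") must divide n_views (",
         g$n_views, ")")
  g
}

run_one_challenger <- function(algo, run, sim, prep, cfg, object_mask) {
  seed <- derive_seed(cfg$seed, paste0(algo, "-run-", run))
  sched <- if (algo == "svrg")
    step_schedule(cfg$svrg_alpha0, cfg$svrg_eta)
  else step_schedule(cfg$alpha0, cfg$eta)
  scfg <- solver_config(schedule = sched,
                        delta = prep$delta, n_subsets = cfg$n_subsets,
                        max_updates = cfg$challenger_max_updates,
                        seed = seed, time_mode = cfg$timing,
                        record_images = TRUE)
  switch(algo,
    bsrem = bsrem(sim$y, sim$geom, sim$factors, prep$p, scfg,
                  x0 = prep$x_osem, object_mask = object_mask),
    svrg = svrg_solver(sim$y, sim$geom, sim$factors, prep$p, scfg,
                       x0 = prep$x_osem, object_mask = object_mask,
                       warmup_epochs = cfg$svrg_warmup_epochs),
    osem = {
      # OSEM as a challenger: wrap the multiplicative iteration in a trace
      scheme <- make_subsets(sim$geom$n_views, cfg$n_subsets)
      clock <- make_clock(cfg$timing)
      rows <- new_trace(); images <- list()
      x <- prep$x_osem
      sens <- sensitivity_images(sim$geom, sim$factors, scheme,
                                 x$dims, x$voxel_size)
      for (k in seq_len(cfg$challenger_max_updates)) {
        s <- ((k - 1L) %% cfg$n_subsets) + 1L
        x <- osem_subset_update(x, s, scheme, sim$y, sim$geom, sim$factors,
                                sens$per_subset[[s]])
        ob <- pl_objective(x, sim$y, sim$geom, sim$factors, prep$p)
        rows$update <- c(rows$update, k)
        rows$time_s <- c(rows$time_s, clock(k))
        rows$loglik <- c(rows$loglik, ob$loglik)
        rows$prior <- c(rows$prior, ob$prior)
        rows$total <- c(rows$total, ob$total)
        images[[k]] <- x
      }
      solver_trace(rows, x, images, algorithm = "osem")
    },
    stop("unknown algorithm: ", algo))
}

#' Run the full challenge pipeline
#'
#' Simulates a phantom dataset, computes the converged BSREM reference,
#' runs every configured challenger algorithm `runs` times, scores each run
#' against the reference with the three-threshold / persistence protocol,
#' and ranks the algorithms per metric from the median pass times. When
#' `out_dir` is given, writes the dataset (Interfile-lite), the resolved
#' config, per-run trace and metric CSVs, final images, the pass-time table
#' and the leaderboard CSV, plus a timestamped log.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional output directory.
#' @return List with `scene`, `sim`, `reference` (the
#'   [reconstruct_reference()] result), `traces`, `scores`, `times`
#'   (pass-time table) and `ranking` (a `rank_table`).
#' @export
run_challenge <- function(cfg = run_config(), out_dir = NULL) {
  validate_config(cfg)
  logf <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "petrec.log")
  } else nullfile()
  log_line(logf, "challenge start: phantom=", cfg$phantom,
           " size=", cfg$size, " seed=", cfg$seed)

  scene <- challenge_scene(cfg)
  geom <- challenge_geometry(cfg, scene)
  sim <- simulate_scan(scene, geom, counts_target = cfg$counts_target,
                       seed = derive_seed(cfg$seed, "counts"),
                       scatter_fraction = cfg$scatter_fraction,
                       efficiency = cfg$efficiency)
  object_mask <- scene$vois$object_mask
  th <- challenge_thresholds(cfg)
  log_line(logf, "simulated ", sum(sim$y$values), " counts over ",
           length(sim$y$values), " bins")

  scheme <- make_subsets(geom$n_views, cfg$n_subsets)
  x_osem <- osem(sim$y, geom, sim$factors, scheme,
                 n_epochs = cfg$osem_epochs, object_mask = object_mask)
  p <- prior_params(cfg$beta, cfg$gamma,
                    epsilon = epsilon_from_osem(x_osem, cfg$epsilon_rel),
                    kappa = kappa_from_osem(x_osem, sim$y, geom, sim$factors))
  delta <- delta_from_osem(x_osem, cfg$delta_rel)

  ref_cfg <- solver_config(schedule = step_schedule(cfg$alpha0, cfg$eta),
                           delta = delta, n_subsets = cfg$n_subsets,
                           max_updates = cfg$reference_max_updates,
                           restart = TRUE,
                           seed = derive_seed(cfg$seed, "reference"),
                           time_mode = cfg$timing, record_images = FALSE)
  ref <- reconstruct_reference(sim$y, geom, sim$factors, p, ref_cfg,
                               object_mask = object_mask, x_osem = x_osem)
  log_line(logf, "reference done after ", nrow(ref$trace$trace),
           " updates; converged=", ref$converged)

  prep <- list(x_osem = x_osem, p = ref$p, delta = delta)
  traces <- list(); scores <- list()
  times <- NULL
  ds <- paste0(cfg$phantom, "_", cfg$size)
  for (algo in cfg$algorithms) {
    for (run in seq_len(cfg$runs)) {
      st <- run_one_challenger(algo, run, sim, prep, cfg, object_mask)
      sc <- score_trace(st, ref$reference, scene$vois, th)
      key <- paste0(algo, "_run", run)
      traces[[key]] <- st
      scores[[key]] <- sc
      for (mc in names(sc$per_metric)) {
        pt <- sc$per_metric[[mc]]
        times <- rbind(times, data.frame(
          dataset = ds, metric = mc, algorithm = algo, run = run,
          time = pt$time, censored = pt$censored))
      }
      log_line(logf, key, ": overall pass ",
               if (sc$overall$censored) "censored" else
                 sprintf("at t=%.3f (update %d)", sc$overall$time,
                         sc$overall$update))
    }
  }
  ranking <- rank_algorithms(times, time_cap = cfg$time_cap)

  if (!is.null(out_dir)) {
    write_challenge_outputs(out_dir, cfg, scene, sim, ref, traces, scores,
                            times, ranking)
    log_line(logf, "outputs written to ", out_dir)
  }
  list(scene = scene, sim = sim, reference = ref, traces = traces,
       scores = scores, times = times, ranking = ranking, config = cfg)
}

write_challenge_outputs <- function(out_dir, cfg, scene, sim, ref, traces,
                                    scores, times, ranking) {
  write_config(cfg, file.path(out_dir, "config.yaml"))
  data_dir <- file.path(out_dir, "dataset")
  write_scene(scene, data_dir)
  write_image(sim$activity, file.path(data_dir, "activity_scaled"))
  write_projdata(sim$y, file.path(data_dir, "counts"))
  write_projdata(sim$factors$m, file.path(data_dir, "mult_factors"))
  write_projdata(sim$factors$a, file.path(data_dir, "additive"))
  write_image(ref$x_osem, file.path(out_dir, "osem"))
  write_image(ref$reference, file.path(out_dir, "reference"))
  utils::write.csv(ref$trace$trace, file.path(out_dir, "reference_trace.csv"),
                   row.names = FALSE)
  for (key in names(traces)) {
    utils::write.csv(traces[[key]]$trace,
                     file.path(out_dir, paste0("trace_", key, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(scores[[key]]$metrics),
                     file.path(out_dir, paste0("metrics_", key, ".csv")),
                     row.names = FALSE)
    write_image(traces[[key]]$final,
                file.path(out_dir, paste0("final_", key)))
  }
  utils::write.csv(times, file.path(out_dir, "pass_times.csv"),
                   row.names = FALSE)
  utils::write.csv(ranking$cells, file.path(out_dir, "rank_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(ranking$summary, file.path(out_dir, "leaderboard.csv"),
                   row.names = FALSE)
  lb <- utils::capture.output(print(ranking))
  writeLines(lb, file.path(out_dir, "leaderboard.txt"))
  invisible(out_dir)
}
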