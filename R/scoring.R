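#' Convergence thresholds and protocol constants
#'
#' Defaults follow the evaluation protocol: normalised whole-object RMSE
#' below 0.01, normalised background RMSE below 0.01, every per-VOI
#' absolute error of the mean (AEM) below 0.005, all holding for 10
#' consecutive updates, within a configurable run-time cap.
#'
#' @param whole_rmse,background_rmse,voi_aem positive thresholds on the
#'   normalised metrics.
#' @param persistence number of consecutive passing updates required.
#' @param time_cap censoring time in clock units (seconds under wall-clock
#'   timing; update counts under the deterministic pseudo-clock).
#' @return An object of class `thresholds`.
#' @export
thresholds <- function(whole_rmse = 0.01, background_rmse = 0.01,
                       voi_aem = 0.005, persistence = 10L, time_cap = 3600) {
  if (any(c(whole_rmse, background_rmse, voi_aem, time_cap) <= 0))
    stop("thresholds and time_cap must be > 0")
  if (persistence < 1L) stop("persistence must be >= 1")
  structure(list(whole_rmse = whole_rmse, background_rmse = background_rmse,
                 voi_aem = voi_aem, persistence = as.integer(persistence),
                 time_cap = time_cap), class = "thresholds")
}

#' Root mean squared error over a region
#' @param x,r `image_volume`s on the same grid.
#' @param region nonempty logical mask.
#' @return sqrt(mean((x - r)^2)) over the region.
#' @export
rmse <- function(x, r, region) {
  stopifnot_same_grid(x, r)
  region <- as_mask(region)
  if (!any(region)) stop("empty region")
  sqrt(mean((x$values[region] - r$values[region])^2))
}

#' Mean of an image over a region
#' @param x an `image_volume`.
#' @param region nonempty logical mask.
#' @return Arithmetic mean of the region's voxels.
#' @export
mean_in <- function(x, region) {
  region <- as_mask(region)
  if (!any(region)) stop("empty region")
  mean(x$values[region])
}

#' Evaluate the three convergence criteria for one image
#'
#' All metrics are normalised by the reference background mean MEAN(r; B):
#' whole = RMSE(x; r; W) / MEAN(r; B), background = RMSE(x; r; B) /
#' MEAN(r; B), and per target VOI AEM_i = |MEAN(x; R_i) - MEAN(r; R_i)| /
#' MEAN(r; B). The image passes when whole and background are below their
#' thresholds and every AEM is below the VOI threshold.
#'
#' @param x candidate image.
#' @param r converged reference image.
#' @param vois a [voi_set()].
#' @param th a [thresholds()].
#' @return List with `values` (named numeric: `whole`, `background`,
#'   `aem_<voi>`...), `pass_each` (named logical) and `pass`.
#' @export
evaluate_criteria <- function(x, r, vois, th = thresholds()) {
  norm <- mean_in(r, vois$background)
  if (norm <= 0) stop("reference background mean must be positive")
  vals <- c(whole = rmse(x, r, vois$whole_eroded) / norm,
            background = rmse(x, r, vois$background) / norm)
  pass <- c(whole = unname(vals["whole"] < th$whole_rmse),
            background = unname(vals["background"] < th$background_rmse))
  for (nm in names(vois$targets)) {
    aem <- abs(mean_in(x, vois$targets[[nm]]) -
               mean_in(r, vois$targets[[nm]])) / norm
    vals[[paste0("aem_", nm)]] <- aem
    pass[[paste0("aem_", nm)]] <- aem < th$voi_aem
  }
  list(values = vals, pass_each = pass, pass = all(pass), norm = norm)
}

#' Build a metric trace from per-update iterates
#'
#' Applies [evaluate_criteria()] to each recorded iterate of a solver trace.
#' @param st a `solver_trace` with recorded images.
#' @param r reference image.
#' @param vois a [voi_set()].
#' @param th a [thresholds()].
#' @param stride evaluate every `stride`-th update (default 1).
#' @return A data.frame of class `metric_trace` with columns `update`,
#'   `time_s`, `whole`, `background`, `aem_*`; the normaliser MEAN(r; B) is
#'   attached as attribute `norm`.
#' @export
metric_trace <- function(st, r, vois, th = thresholds(), stride = 1L) {
  if (is.null(st$images) || !length(st$images))
    stop("solver trace has no recorded images; run with record_images = TRUE")
  idx <- seq(1L, nrow(st$trace), by = as.integer(stride))
  rows <- lapply(idx, function(i) {
    ev <- evaluate_criteria(st$images[[st$trace$update[i]]], r, vois, th)
    c(update = st$trace$update[i], time_s = st$trace$time_s[i], ev$values)
  })
  df <- as.data.frame(do.call(rbind, rows))
  attr(df, "norm") <- mean_in(r, vois$background)
  class(df) <- c("metric_trace", class(df))
  df
}

metric_columns <- function(mt) setdiff(names(mt), c("update", "time_s"))

# logical pass vector for one metric column (or all jointly)
pass_flags <- function(mt, th, metric = "all") {
  cols <- metric_columns(mt)
  thr_for <- function(cl) {
    if (cl == "whole") th$whole_rmse
    else if (cl == "background") th$background_rmse
    else th$voi_aem
  }
  if (identical(metric, "all")) {
    ok <- rep(TRUE, nrow(mt))
    for (cl in cols) ok <- ok & (mt[[cl]] < thr_for(cl))
    ok
  } else {
    if (!metric %in% cols) stop("unknown metric: ", metric)
    mt[[metric]] < thr_for(metric)
  }
}

#' Pass time of a metric trace
#'
#' The recorded pass time is the timestamp of the FIRST update of the first
#' run of `persistence` consecutive passing updates that completes within
#' the time cap; if no such run exists the observation is censored at the
#' cap.
#'
#' @param mt a [metric_trace()].
#' @param th a [thresholds()].
#' @param metric `"all"` for the joint stopping rule, or one metric column
#'   (`"whole"`, `"background"`, `"aem_<voi>"`) for per-metric ranking.
#' @return List with `time` (pass time, or the cap when censored),
#'   `censored` and `update` (first passing update, NA when censored).
#' @export
pass_time <- function(mt, th = thresholds(), metric = "all") {
  ok <- pass_flags(mt, th, metric) & mt$time_s <= th$time_cap
  n <- length(ok)
  P <- th$persistence
  if (n >= P) {
    run <- cumsum(ok)
    for (u in seq_len(n - P + 1L)) {
      if (all(ok[u:(u + P - 1L)]))
        return(list(time = mt$time_s[u], censored = FALSE,
                    update = mt$update[u]))
    }
  }
  list(time = th$time_cap, censored = TRUE, update = NA_integer_)
}

#' Rank algorithms from pass times
#'
#' For every (dataset, metric) cell, takes the median pass time over runs
#' (censored runs count at the time cap), then ranks algorithms from worst
#' (rank 1, slowest) to best (rank N, fastest). Cells whose majority of runs
#' is censored rank strictly worse than every uncensored cell; ties share
#' the average of the tied rank positions. The overall score per algorithm
#' is its mean rank over all cells, reported with its standard error.
#'
#' @param times data.frame with columns `dataset`, `metric`, `algorithm`,
#'   `run`, `time`, `censored`.
#' @param time_cap the censoring cap used when medianing censored runs.
#' @return List of class `rank_table` with `cells` (per-cell medians and
#'   ranks) and `summary` (per-algorithm mean rank and standard error,
#'   sorted best first).
#' @export
rank_algorithms <- function(times, time_cap = 3600) {
  need <- c("dataset", "metric", "algorithm", "run", "time", "censored")
  if (!all(need %in% names(times))) stop("times must have columns: ",
                                         paste(need, collapse = ", "))
  algos <- sort(unique(times$algorithm))
  cells <- unique(times[c("dataset", "metric")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- times[times$dataset == cells$dataset[i] &
                  times$metric == cells$metric[i], ]
    if (!setequal(unique(cell$algorithm), algos))
      stop("inconsistent algorithm sets across cells")
    med <- vapply(algos, function(a) {
      rr <- cell[cell$algorithm == a, ]
      stats::median(ifelse(rr$censored, time_cap, pmin(rr$time, time_cap)))
    }, numeric(1))
    cen <- vapply(algos, function(a) {
      rr <- cell[cell$algorithm == a, ]
      mean(rr$censored) > 0.5
    }, logical(1))
    key <- ifelse(cen, Inf, med)
    rk <- rank(-key, ties.method = "average")  # slowest -> rank 1
    out[[i]] <- data.frame(dataset = cells$dataset[i],
                           metric = cells$metric[i], algorithm = algos,
                           median_time = med, censored = cen, rank = rk,
                           row.names = NULL)
  }
  cells_df <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(algos, function(a) {
    r <- cells_df$rank[cells_df$algorithm == a]
    data.frame(algorithm = a, mean_rank = mean(r),
               se_rank = stats::sd(r) / sqrt(length(r)), n_cells = length(r))
  }))
  summ <- summ[order(-summ$mean_rank), ]
  rownames(summ) <- NULL
  structure(list(cells = cells_df, summary = summ), class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("Leaderboard (higher mean rank is better):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
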