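# Shared fixtures: small random acquisition instances built in code.

# random acquisition model instance on an nx x nx grid
tiny_instance <- function(nx = 8, n_views = 6, seed = 1, voxel = 1,
                          abar = 0.3, virtual = integer()) {
  set.seed(seed)
  geom <- projector_geometry(n_views, nx + 1L, voxel)
  x <- image_volume(matrix(runif(nx * nx, 0.5, 2), nx, nx), voxel)
  nb <- (nx + 1L) * n_views
  mv <- array(runif(nb, 0.5, 1), c(nx + 1L, n_views))
  mv[virtual] <- 0
  m <- proj_data(mv, geom)
  a <- proj_data(array(abar, c(nx + 1L, n_views)), geom)
  factors <- acq_factors(m, a)
  ybar <- predict_counts(x, geom, factors)
  y <- sample_counts(ybar, seed + 100)
  list(geom = geom, x = x, factors = factors, ybar = ybar, y = y)
}

# central finite differences of a scalar function of an image
fd_gradient <- function(fn, x, h) {
  g <- array(0, dim = x$dims)
  for (i in seq_along(g)) {
    xp <- x; xp$values[i] <- xp$values[i] + h
    xm <- x; xm$values[i] <- xm$values[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

# brute-force box erosion oracle: voxelwise min over the 3x3 neighbourhood
erode_oracle <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) FALSE else mask[ii, jj]
      if (!v) ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}

# projected gradient ascent with backtracking line search: the independent
# optimiser oracle for the penalised-likelihood maximum
pg_oracle <- function(y, geom, factors, p, x0, object_mask,
                      max_iter = 4000, stall_limit = 25) {
  obj <- function(z) pl_objective(z, y, geom, factors, p)$total
  x <- project_C(x0, object_mask)
  f <- obj(x)
  step <- 1e-2
  stall <- 0
  for (it in seq_len(max_iter)) {
    g <- pl_grad(x, y, geom, factors, p)
    fn <- -Inf
    repeat {
      xn <- project_C(with_values(x, x$values + step * g$values), object_mask)
      fn <- obj(xn)
      if (fn >= f - 1e-12 * abs(f) || step < 1e-18) break
      step <- step / 2
    }
    if (fn > f) {
      stall <- if (fn - f < 1e-12 * abs(f)) stall + 1 else 0
      x <- xn; f <- fn; step <- step * 1.3
    } else stall <- stall + 1
    if (stall > stall_limit) break
  }
  list(x = x, value = f, iterations = it)
}

# wrap a fixed image as a 20-update solver trace (self-scoring fixture)
solver_trace_selfscore <- function(img, n = 20) {
  rows <- list(update = seq_len(n), time_s = as.numeric(seq_len(n)),
               loglik = rep(NA_real_, n), prior = rep(NA_real_, n),
               total = rep(NA_real_, n))
  petrec:::solver_trace(rows, img, images = rep(list(img), n),
                        algorithm = "fixed")
}

# synthetic metric trace with prescribed pass pattern support
random_metric_trace <- function(n, n_voi = 2, seed = 1, scale = 0.02) {
  set.seed(seed)
  df <- data.frame(update = seq_len(n), time_s = cumsum(runif(n, 0.5, 1.5)))
  df$whole <- stats::rexp(n, rate = 1 / scale)
  df$background <- stats::rexp(n, rate = 1 / scale)
  for (k in seq_len(n_voi))
    df[[paste0("aem_voi", k)]] <- stats::rexp(n, rate = 2 / scale)
  class(df) <- c("metric_trace", class(df))
  df
}

# brute-force pass-time oracle: literal scan over all starting updates
pass_time_oracle <- function(mt, th, metric = "all") {
  thr_of <- function(cl) {
    if (cl == "whole") th$whole_rmse
    else if (cl == "background") th$background_rmse
    else th$voi_aem
  }
  cols <- if (identical(metric, "all"))
    setdiff(names(mt), c("update", "time_s")) else metric
  ok <- rep(TRUE, nrow(mt))
  for (cl in cols) ok <- ok & (mt[[cl]] < thr_of(cl))
  ok <- ok & mt$time_s <= th$time_cap
  P <- th$persistence
  n <- length(ok)
  if (n >= P) for (u in 1:(n - P + 1)) {
    run_ok <- TRUE
    for (v in u:(u + P - 1)) if (!ok[v]) { run_ok <- FALSE; break }
    if (run_ok) return(list(time = mt$time_s[u], censored = FALSE))
  }
  list(time = th$time_cap, censored = TRUE)
}

# brute-force ranking oracle following the stated rules literally
rank_oracle <- function(times, time_cap) {
  algos <- sort(unique(times$algorithm))
  cells <- unique(times[c("dataset", "metric")])
  rows <- NULL
  for (i in seq_len(nrow(cells))) {
    cc <- times[times$dataset == cells$dataset[i] &
                times$metric == cells$metric[i], ]
    med <- sapply(algos, function(a) {
      rr <- cc[cc$algorithm == a, ]
      stats::median(ifelse(rr$censored, time_cap, pmin(rr$time, time_cap)))
    })
    cen <- sapply(algos, function(a) mean(cc$censored[cc$algorithm == a]) > 0.5)
    key <- ifelse(cen, Inf, med)
    # slowest -> rank 1; ties share averaged positions
    ord_rank <- rank(-key, ties.method = "average")
    rows <- rbind(rows, data.frame(dataset = cells$dataset[i],
                                   metric = cells$metric[i],
                                   algorithm = algos, rank = ord_rank))
  }
  agg <- sapply(algos, function(a) mean(rows$rank[rows$algorithm == a]))
  list(cells = rows, mean_rank = agg)
}
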