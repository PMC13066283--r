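make_img <- function(v, vox = 1) image_volume(v, vox)

test_that("rmse and region means follow their definitions", {
  x <- make_img(matrix(c(0, 2, 5, 1), 2, 2))
  r <- make_img(matrix(c(2, 2, 5, 3), 2, 2))
  all4 <- array(TRUE, c(2, 2))
  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(rmse(x, r, two), sqrt(4 / 2))
  expect_equal(rmse(x, x, all4), 0)
  expect_error(rmse(x, r, array(FALSE, c(2, 2))), "empty")
  expect_equal(mean_in(x, all4), 2)
  expect_equal(mean_in(x, two), 1)
  single <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(mean_in(x, single), 5)
})

test_that("criteria normalise by the reference background mean", {
  sc <- generate_phantom("nema_like", dims = c(32, 32), contrast = 4,
                         seed = 4)
  r <- sc$activity
  ev <- evaluate_criteria(r, r, sc$vois)
  expect_true(ev$pass)
  expect_true(all(ev$values == 0))
  # scaling both images leaves the normalised values unchanged
  x <- with_values(r, r$values * (1 + 0.004 * (r$values > 2)))
  e1 <- evaluate_criteria(x, r, sc$vois)
  lam <- 37.5
  e2 <- evaluate_criteria(with_values(x, lam * x$values),
                          with_values(r, lam * r$values), sc$vois)
  expect_equal(e1$values, e2$values, tolerance = 1e-12)
})

test_that("a 0.006-background-mean bump on one VOI fails only its AEM", {
  sc <- generate_phantom("nema_like", dims = c(32, 32), contrast = 4,
                         seed = 4)
  r <- sc$activity
  normB <- mean_in(r, sc$vois$background)
  voi <- sc$vois$targets[[2]]
  x <- with_values(r, r$values + 0.006 * normB * voi)
  ev <- evaluate_criteria(x, r, sc$vois, thresholds())
  expect_false(ev$pass)
  expect_equal(unname(ev$values["aem_insert_2"]), 0.006, tolerance = 1e-12)
  expect_false(ev$pass_each[["aem_insert_2"]])
  expect_true(ev$pass_each[["background"]])
})

test_that("pass_time agrees with the brute-force scan oracle", {
  th <- thresholds(persistence = 10, time_cap = 50)
  for (seed in 1:100) {
    mt <- random_metric_trace(n = 40, n_voi = 2, seed = seed)
    got <- pass_time(mt, th)
    want <- pass_time_oracle(mt, th)
    expect_equal(got$time, want$time)
    expect_equal(got$censored, want$censored)
    for (mc in c("whole", "aem_voi1")) {
      g2 <- pass_time(mt, th, mc)
      w2 <- pass_time_oracle(mt, th, mc)
      expect_equal(g2$time, w2$time)
      expect_equal(g2$censored, w2$censored)
    }
  }
})

test_that("pass_time handles the canonical edge patterns", {
  th <- thresholds(persistence = 10, time_cap = 1e6)
  base <- random_metric_trace(n = 30, n_voi = 1, seed = 1)
  # force values: pass from update 5 onward
  for (cl in c("whole", "background", "aem_voi1")) base[[cl]] <- 1
  pass_rows <- 5:30
  for (cl in c("whole", "background", "aem_voi1")) base[[cl]][pass_rows] <- 0
  pt <- pass_time(base, th)
  expect_false(pt$censored)
  expect_equal(pt$update, 5)
  expect_equal(pt$time, base$time_s[5])
  # exactly persistence - 1 consecutive passes, never again: censored
  for (cl in c("whole", "background", "aem_voi1")) {
    base[[cl]] <- 1
    base[[cl]][3:11] <- 0          # 9 < 10 consecutive
  }
  pt2 <- pass_time(base, th)
  expect_true(pt2$censored)
  expect_equal(pt2$time, th$time_cap)
  # passing from the first update
  for (cl in c("whole", "background", "aem_voi1")) base[[cl]] <- 0
  pt3 <- pass_time(base, th)
  expect_equal(pt3$update, 1)
  expect_equal(pt3$time, base$time_s[1])
})

test_that("loosening thresholds never delays the pass time", {
  th1 <- thresholds(persistence = 8, time_cap = 100)
  th2 <- thresholds(whole_rmse = 0.02, background_rmse = 0.02,
                    voi_aem = 0.01, persistence = 8, time_cap = 100)
  for (seed in 1:30) {
    mt <- random_metric_trace(n = 40, n_voi = 2, seed = seed + 500)
    t1 <- pass_time(mt, th1)$time
    t2 <- pass_time(mt, th2)$time
    expect_lte(t2, t1)
  }
})

test_that("ranking follows median-of-runs, worst-first, tie-averaged rules", {
  tab <- data.frame(
    dataset = "d1", metric = "whole",
    algorithm = rep(c("a", "b"), each = 1),
    run = 1L, time = c(10, 20), censored = FALSE)
  rk <- rank_algorithms(tab, time_cap = 100)
  expect_equal(rk$cells$rank[rk$cells$algorithm == "a"], 2)
  expect_equal(rk$cells$rank[rk$cells$algorithm == "b"], 1)
  # all tied: everyone gets (1 + N) / 2
  tab$time <- 15
  rk2 <- rank_algorithms(tab, time_cap = 100)
  expect_true(all(rk2$cells$rank == 1.5))
  # an always-censored algorithm ranks 1 everywhere
  tab3 <- data.frame(
    dataset = rep(c("d1", "d2"), each = 6),
    metric = "whole",
    algorithm = rep(rep(c("a", "b", "c"), each = 2), 2),
    run = rep(1:2, 6),
    time = 10, censored = FALSE)
  tab3$censored[tab3$algorithm == "c"] <- TRUE
  tab3$time[tab3$algorithm == "c"] <- 100
  rk3 <- rank_algorithms(tab3, time_cap = 100)
  expect_true(all(rk3$cells$rank[rk3$cells$algorithm == "c"] == 1))
  summ <- rk3$summary
  expect_equal(summ$mean_rank[summ$algorithm == "c"], 1)
})

test_that("ranking matches the brute-force oracle on random tables", {
  set.seed(77)
  for (rep in 1:60) {
    n_alg <- sample(2:5, 1)
    n_ds <- sample(1:3, 1)
    algos <- paste0("alg", seq_len(n_alg))
    tab <- expand.grid(dataset = paste0("d", seq_len(n_ds)),
                       metric = c("whole", "background"),
                       algorithm = algos, run = 1:3,
                       stringsAsFactors = FALSE)
    tab$time <- round(runif(nrow(tab), 1, 30))   # rounding induces ties
    tab$censored <- runif(nrow(tab)) < 0.2
    rk <- rank_algorithms(tab, time_cap = 30)
    orc <- rank_oracle(tab, time_cap = 30)
    merged <- merge(rk$cells, orc$cells,
                    by = c("dataset", "metric", "algorithm"))
    expect_equal(merged$rank.x, merged$rank.y)
    expect_equal(rk$summary$mean_rank[order(rk$summary$algorithm)],
                 unname(orc$mean_rank[sort(names(orc$mean_rank))]))
  }
})

test_that("ranking is equivariant under relabelling and monotone times", {
  set.seed(91)
  tab <- expand.grid(dataset = "d", metric = c("m1", "m2"),
                     algorithm = c("a", "b", "c"), run = 1:3,
                     stringsAsFactors = FALSE)
  tab$time <- runif(nrow(tab), 1, 40)
  tab$censored <- runif(nrow(tab)) < 0.15
  rk <- rank_algorithms(tab, time_cap = 50)
  # relabel
  map <- c(a = "zz", b = "yy", c = "xx")
  tab2 <- tab
  tab2$algorithm <- unname(map[tab2$algorithm])
  rk2 <- rank_algorithms(tab2, time_cap = 50)
  for (al in names(map)) {
    expect_equal(rk$summary$mean_rank[rk$summary$algorithm == al],
                 rk2$summary$mean_rank[rk2$summary$algorithm == map[[al]]])
  }
  # strictly monotone transform of times (cap transformed consistently)
  tab3 <- tab
  tab3$time <- tab$time^2
  rk3 <- rank_algorithms(tab3, time_cap = 50^2)
  expect_equal(rk$cells$rank, rk3$cells$rank)
})

test_that("metric traces expose per-update criteria for solver runs", {
  sc <- generate_phantom("constant_disc", dims = c(16, 16), voxel_size = 2,
                         contrast = 3, seed = 12)
  geom <- projector_geometry(8, 17, 2)
  sim <- simulate_scan(sc, geom, counts_target = 2e4, seed = 13)
  sch <- make_subsets(8, 4)
  mask <- sc$vois$object_mask
  xo <- osem(sim$y, geom, sim$factors, sch, n_epochs = 1, object_mask = mask)
  p <- prior_params(0.5, 2, epsilon_from_osem(xo),
                    kappa_from_osem(xo, sim$y, geom, sim$factors))
  cfg <- solver_config(delta = delta_from_osem(xo), n_subsets = 4,
                       max_updates = 25)
  st <- bsrem(sim$y, geom, sim$factors, p, cfg, x0 = xo, object_mask = mask)
  mt <- metric_trace(st, st$final, sc$vois)
  expect_equal(nrow(mt), 25)
  expect_true(all(is.finite(as.matrix(mt))))
  # final update scored against itself is exactly zero on every metric
  last <- as.numeric(mt[25, petrec:::metric_columns(mt)])
  expect_true(all(last == 0))
})
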