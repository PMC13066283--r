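test_that("constraint projection clips, masks, and is idempotent", {
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  x <- image_volume(matrix(c(-3, 2, 5, -1), 2, 2), 1)
  px <- project_C(x, mask)
  expect_equal(px$values, matrix(c(0, 2, 0, 0), 2, 2))
  expect_equal(project_C(px, mask)$values, px$values)
  expect_equal(project_C(x)$values, matrix(c(0, 2, 5, 0), 2, 2))
})

test_that("step schedule relaxes per epoch and stays positive", {
  s <- step_schedule(2, 0.5)
  a <- petrec:::schedule_alpha(s, 1:12, n_subsets = 4)
  expect_equal(a[1:4], rep(2, 4))
  expect_equal(a[5:8], rep(2 / 1.5, 4))
  expect_true(all(diff(a) <= 0))
  expect_true(all(a > 0))
  expect_equal(petrec:::schedule_alpha(step_schedule(1, 0), 1000, 4), 1)
})

test_that("MLEM fixed point: data-fitting start does not move", {
  inst <- tiny_instance(nx = 8, n_views = 6, seed = 41)
  sch <- make_subsets(6, 1)
  yfit <- predict_counts(inst$x, inst$geom, inst$factors)
  x1 <- osem(yfit, inst$geom, inst$factors, sch, n_epochs = 1, x0 = inst$x)
  expect_equal(x1$values, inst$x$values, tolerance = 1e-12)
})

test_that("MLEM never decreases the log-likelihood", {
  sc <- generate_phantom("constant_disc", dims = c(16, 16), voxel_size = 2,
                         contrast = 3, seed = 2)
  sim <- simulate_scan(sc, counts_target = 2e4, seed = 4)
  sch <- make_subsets(sim$geom$n_views, 1)
  x <- osem(sim$y, sim$geom, sim$factors, sch, n_epochs = 0,
            object_mask = sc$vois$object_mask)
  prev <- loglik(sim$y, predict_counts(x, sim$geom, sim$factors), sim$factors)
  for (it in 1:60) {
    x <- osem(sim$y, sim$geom, sim$factors, sch, n_epochs = 1, x0 = x)
    cur <- loglik(sim$y, predict_counts(x, sim$geom, sim$factors),
                  sim$factors)
    expect_gte(cur - prev, -1e-12 * abs(prev))
    prev <- cur
  }
})

test_that("near-identity model: MLEM converges towards the data", {
  # single view, one ray per voxel row makes A nearly diagonal
  geom <- projector_geometry(1, 8, 1)
  set.seed(3)
  x_true <- image_volume(matrix(runif(8, 1, 4), 8, 1), 1)
  m <- proj_data(array(1, c(8, 1)), geom)
  a <- proj_data(array(1e-9, c(8, 1)), geom)
  f <- acq_factors(m, a)
  y <- predict_counts(x_true, geom, f)    # noise-free data
  sch <- make_subsets(1, 1)
  x <- osem(y, geom, f, sch, n_epochs = 200,
            x0 = image_volume(matrix(1, 8, 1), 1))
  yhat <- predict_counts(x, geom, f)
  expect_lt(max(abs(yhat$values - y$values)) / max(y$values), 1e-6)
})

test_that("solver iterates stay in the constraint set and finite", {
  sc <- generate_phantom("nema_like", dims = c(16, 16), voxel_size = 4,
                         contrast = 4, seed = 2)
  geom <- projector_geometry(8, 17, 4)
  sim <- simulate_scan(sc, geom, counts_target = 5e4, seed = 11)
  mask <- sc$vois$object_mask
  sch <- make_subsets(8, 4)
  xo <- osem(sim$y, geom, sim$factors, sch, n_epochs = 2, object_mask = mask)
  p <- prior_params(0.5, 2, epsilon_from_osem(xo),
                    kappa_from_osem(xo, sim$y, geom, sim$factors))
  cfg <- solver_config(delta = delta_from_osem(xo), n_subsets = 4,
                       max_updates = 60, seed = 3)
  for (solver in list(bsrem, svrg_solver)) {
    st <- solver(sim$y, geom, sim$factors, p, cfg, x0 = xo,
                 object_mask = mask)
    for (im in st$images) {
      expect_true(all(is.finite(im$values)))
      expect_true(all(im$values >= 0))
      expect_true(all(im$values[!mask] == 0))
    }
    expect_true(all(is.finite(st$trace$total)))
    expect_identical(st$trace$update, 1:60)
    expect_true(all(diff(st$trace$time_s) >= 0))
  }
})

test_that("small constant step on the concave objective never descends", {
  inst <- tiny_instance(nx = 8, n_views = 6, seed = 43)
  sch <- make_subsets(6, 1)
  xo <- osem(inst$y, inst$geom, inst$factors, sch, n_epochs = 2,
             x0 = with_values(inst$x, 1))
  p <- prior_params(1e-8, 2, epsilon = 1e-3)  # beta -> 0: pure likelihood
  cfg <- solver_config(schedule = step_schedule(0.05, 0), delta = 1e-6,
                       n_subsets = 1, max_updates = 100)
  st <- bsrem(inst$y, inst$geom, inst$factors, p, cfg, x0 = xo)
  expect_true(all(diff(st$trace$total) >= -1e-9 * abs(st$trace$total[-1])))
})

test_that("svrg with per-update snapshots is exactly preconditioned GD", {
  inst <- tiny_instance(nx = 8, n_views = 6, seed = 47)
  sch <- make_subsets(6, 2)
  xo <- osem(inst$y, inst$geom, inst$factors, sch, n_epochs = 1,
             x0 = with_values(inst$x, 1))
  p <- prior_params(0.3, 2, epsilon = 1e-3)
  cfg <- solver_config(schedule = step_schedule(0.1, 0), delta = 1e-6,
                       n_subsets = 2, max_updates = 20, seed = 5)
  sv <- svrg_solver(inst$y, inst$geom, inst$factors, p, cfg, x0 = xo,
                    snapshot_period = 1L)
  # preconditioned full-gradient ascent reference trajectory
  sens <- sensitivity_images(inst$geom, inst$factors, sch, c(8, 8), 1)
  S <- sens$average$values
  x <- project_C(xo)
  for (k in 1:20) {
    g <- pl_grad(x, inst$y, inst$geom, inst$factors, p)
    stepv <- array(0, dim = x$dims)
    live <- S > 0
    stepv[live] <- 0.1 * (x$values[live] + 1e-6) / S[live] * g$values[live]
    x <- project_C(with_values(x, x$values + stepv))
  }
  expect_equal(sv$final$values, x$values, tolerance = 1e-14)
})

test_that("svrg runs are bit-identical given the seed", {
  inst <- tiny_instance(nx = 8, n_views = 6, seed = 53)
  sch <- make_subsets(6, 3)
  xo <- osem(inst$y, inst$geom, inst$factors, sch, n_epochs = 1,
             x0 = with_values(inst$x, 1))
  p <- prior_params(0.3, 2, epsilon = 1e-3)
  cfg <- solver_config(schedule = step_schedule(0.05, 0.05), delta = 1e-6,
                       n_subsets = 3, max_updates = 30, seed = 17)
  a <- svrg_solver(inst$y, inst$geom, inst$factors, p, cfg, x0 = xo)
  b <- svrg_solver(inst$y, inst$geom, inst$factors, p, cfg, x0 = xo)
  expect_identical(a$final$values, b$final$values)
  expect_identical(a$trace, b$trace)
})

test_that("bsrem and svrg share the optimum on a tiny instance", {
  sc <- generate_phantom("constant_disc", dims = c(16, 16), voxel_size = 2,
                         contrast = 3, seed = 6)
  geom <- projector_geometry(8, 17, 2)
  sim <- simulate_scan(sc, geom, counts_target = 3e4, seed = 21)
  mask <- sc$vois$object_mask
  sch <- make_subsets(8, 4)
  xo <- osem(sim$y, geom, sim$factors, sch, n_epochs = 2, object_mask = mask)
  p <- prior_params(0.5, 2, epsilon_from_osem(xo),
                    kappa_from_osem(xo, sim$y, geom, sim$factors))
  d <- delta_from_osem(xo)
  cfgb <- solver_config(schedule = step_schedule(1, 0.2), delta = d,
                        n_subsets = 4, max_updates = 2500,
                        record_images = FALSE, objective_every = 2500L)
  stb <- bsrem(sim$y, geom, sim$factors, p, cfgb, x0 = xo,
               object_mask = mask)
  cfgs <- solver_config(schedule = step_schedule(0.1, 0.02), delta = d,
                        n_subsets = 4, max_updates = 2500, seed = 2,
                        record_images = FALSE, objective_every = 2500L)
  sts <- svrg_solver(sim$y, geom, sim$factors, p, cfgs, x0 = xo,
                     object_mask = mask, warmup_epochs = 50L)
  psi_b <- stb$trace$total[2500]
  psi_s <- sts$trace$total[2500]
  expect_lt(abs(psi_b - psi_s) / abs(psi_b), 1e-5)
})

test_that("reference reconstruction is deterministic and self-consistent", {
  sc <- generate_phantom("constant_disc", dims = c(16, 16), voxel_size = 2,
                         contrast = 3, seed = 9)
  geom <- projector_geometry(8, 17, 2)
  sim <- simulate_scan(sc, geom, counts_target = 3e4, seed = 31)
  mask <- sc$vois$object_mask
  p0 <- prior_params(0.5, 2)
  cfg <- solver_config(schedule = step_schedule(1, 0.2), n_subsets = 4,
                       max_updates = 1200, record_images = FALSE)
  r1 <- reconstruct_reference(sim$y, geom, sim$factors, p0, cfg,
                              object_mask = mask)
  r2 <- reconstruct_reference(sim$y, geom, sim$factors, p0, cfg,
                              object_mask = mask)
  expect_identical(r1$reference$values, r2$reference$values)
  # the reference scored against itself passes immediately with zeros
  ev <- evaluate_criteria(r1$reference, r1$reference, sc$vois)
  expect_true(ev$pass)
  expect_true(all(ev$values == 0))
})

test_that("strong smoothing on noise-free constant-disc data flattens r", {
  sc <- generate_phantom("constant_disc", dims = c(16, 16), voxel_size = 2,
                         contrast = 2, seed = 3)
  geom <- projector_geometry(8, 17, 2)
  att <- forward_project(sc$mu, geom)
  m <- proj_data(exp(-att$values), geom)
  a <- proj_data(array(0.5, dim(m$values)), geom)
  f <- acq_factors(m, a)
  y <- predict_counts(sc$activity, geom, f)   # noise-free data
  mask <- sc$vois$object_mask
  # kappa = object indicator keeps the penalty inside the object, so the
  # constant disc is exactly prior-compatible and a large beta must
  # reproduce its fitted constant
  kap <- image_volume(array(as.numeric(mask), dim(mask)), c(2, 2))
  p0 <- prior_params(beta = 50, gamma = 2, epsilon = 2e-4, kappa = kap)
  cfg <- solver_config(schedule = step_schedule(1, 0.2), n_subsets = 4,
                       max_updates = 3000, record_images = FALSE)
  ref <- reconstruct_reference(y, geom, f, p0, cfg, object_mask = mask)
  expect_true(ref$converged)
  inside <- ref$reference$values[mask]
  fit <- mean(inside)
  expect_lt(sqrt(mean((inside - fit)^2)), 1e-3 * fit)
  expect_equal(fit, 2, tolerance = 1e-6)
})
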