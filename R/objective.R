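#' Prior parameters for the smoothed relative difference penalty
#'
#' The penalty on an image x is
#' R(x) = 1/2 * sum_i sum_{j in N_i} w_ij k_i k_j (x_i - x_j)^2 /
#'        (x_i + x_j + gamma * |x_i - x_j| + epsilon),
#' with N_i the 8 (2D) or 26 (3D) nearest neighbours, w_ij the in-plane
#' ("horizontal") voxel pitch divided by the Euclidean distance between
#' voxels i and j (so the direct in-plane weight is exactly 1), and k the
#' voxelwise kappa weight image. gamma controls edge preservation (larger
#' gamma penalises large differences less); epsilon > 0 makes the penalty
#' twice differentiable at equal neighbours.
#'
#' @param beta regularisation strength multiplying the penalty in the
#'   objective; must be > 0.
#' @param gamma edge-preservation parameter, >= 0 (default 2).
#' @param epsilon smoothing constant, > 0; see [epsilon_from_osem()].
#' @param kappa `image_volume` of nonnegative voxel weights, or `NULL` for
#'   uniform weights of 1; see [kappa_from_osem()].
#' @return An object of class `prior_params`.
#' @export
prior_params <- function(beta, gamma = 2, epsilon = 1e-9, kappa = NULL) {
  if (beta <= 0) stop("beta must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (!is.null(kappa)) {
    if (!is_image_volume(kappa)) stop("kappa must be an image_volume")
    if (any(kappa$values < 0)) stop("kappa must be nonnegative")
  }
  structure(list(beta = beta, gamma = gamma, epsilon = epsilon, kappa = kappa),
            class = "prior_params")
}

# All nonzero offsets in {-1,0,1}^nd with their weights: w = in-plane pitch
# of the first axis divided by the Euclidean inter-voxel distance.
neighbour_offsets <- function(nd, voxel_size) {
  g <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  dist <- sqrt(colSums((t(g) * voxel_size[seq_len(nd)])^2))
  list(offsets = g, weights = voxel_size[1] / dist)
}

# Index slices pairing voxel i with neighbour j = i + offset.
offset_slices <- function(dims, off) {
  ii <- jj <- vector("list", length(dims))
  for (k in seq_along(dims)) {
    o <- off[k]
    lo <- max(1L, 1L - o); hi <- min(dims[k], dims[k] - o)
    if (lo > hi) return(NULL)
    ii[[k]] <- seq.int(lo, hi)
    jj[[k]] <- ii[[k]] + o
  }
  list(i = ii, j = jj)
}

sub_array <- function(a, idx) do.call(`[`, c(list(a), idx, list(drop = FALSE)))

#' Smoothed relative difference penalty value
#' @param x nonnegative `image_volume`.
#' @param p a [prior_params()].
#' @return Scalar penalty R(x) >= 0; zero for any constant image.
#' @export
rdp_value <- function(x, p) {
  rdp_eval(x, p, want_grad = FALSE)$value
}

#' Gradient of the smoothed relative difference penalty
#' @inheritParams rdp_value
#' @return An `image_volume` holding dR/dx.
#' @export
rdp_grad <- function(x, p) {
  with_values(x, rdp_eval(x, p, want_grad = TRUE)$grad)
}

rdp_eval <- function(x, p, want_grad = FALSE) {
  if (any(x$values < 0)) stop("rdp requires a nonnegative image")
  xv <- x$values
  kv <- if (is.null(p$kappa)) array(1, dim = x$dims) else p$kappa$values
  if (!identical(dim(kv), x$dims)) stop("kappa grid must match the image")
  nb <- neighbour_offsets(length(x$dims), x$voxel_size)
  total <- 0
  grad <- if (want_grad) array(0, dim = x$dims)
  for (r in seq_len(nrow(nb$offsets))) {
    sl <- offset_slices(x$dims, nb$offsets[r, ])
    if (is.null(sl)) next
    xi <- sub_array(xv, sl$i); xj <- sub_array(xv, sl$j)
    ki <- sub_array(kv, sl$i); kj <- sub_array(kv, sl$j)
    d <- xi - xj
    s <- xi + xj + p$gamma * abs(d) + p$epsilon
    w <- nb$weights[r]
    total <- total + w * sum(ki * kj * d^2 / s)
    if (want_grad) {
      dphi <- (2 * d * s - d^2 * (1 + p$gamma * sign(d))) / s^2
      g <- array(0, dim = x$dims)
      g[matrix_index(sl$i, x$dims)] <- w * ki * kj * dphi
      grad <- grad + g
    }
  }
  list(value = total / 2, grad = grad)
}

#' Poisson log-likelihood (up to image-independent terms)
#'
#' L(y; ybar) = sum_k y_k log(ybar_k) - ybar_k over live bins. Virtual
#' crystal bins (m_k = 0) contribute exactly zero; live bins with y_k = 0
#' contribute -ybar_k.
#' @param y observed counts (`proj_data`, nonnegative integers).
#' @param ybar expected data from [predict_counts()].
#' @param factors the `acq_factors` defining which bins are live.
#' @return Scalar log-likelihood.
#' @export
loglik <- function(y, ybar, factors) {
  yv <- y$values; bv <- ybar$values
  live <- factors$m$values > 0
  if (any(live & yv > 0 & bv <= 0))
    stop("ybar = 0 at a live bin with observed counts; a must be > 0 there")
  term <- numeric(length(yv))
  pos <- live & bv > 0
  term[pos] <- yv[pos] * log(bv[pos]) - bv[pos]
  sum(term)
}

#' Gradient of the log-likelihood with respect to the image
#'
#' Equals the adjoint projector applied to m * (y / ybar - 1), with virtual
#' crystal bins excluded.
#' @param x current image (`image_volume`).
#' @param y observed counts.
#' @param geom projector geometry.
#' @param factors acquisition factors.
#' @return An `image_volume`.
#' @export
loglik_grad <- function(x, y, geom, factors) {
  ybar <- predict_counts(x, geom, factors)
  g <- loglik_grad_bins(y, ybar, factors)
  back_project(proj_data(g, geom), geom, x$dims, x$voxel_size)
}

# bin-space gradient factor m * (y/ybar - 1), zero on dead bins
loglik_grad_bins <- function(y, ybar, factors) {
  mv <- factors$m$values; yv <- y$values; bv <- ybar$values
  live <- mv > 0
  if (any(live & yv > 0 & bv <= 0))
    stop("ybar = 0 at a live bin with observed counts")
  g <- numeric(length(yv))
  pos <- live & bv > 0
  g[pos] <- mv[pos] * (yv[pos] / bv[pos] - 1)
  g[live & bv <= 0] <- 0
  array(g, dim = dim(yv))
}

#' Kappa weight image from an initial OSEM reconstruction
#'
#' kappa_i = sqrt(-[H 1]_i) with H the Hessian of the log-likelihood at the
#' OSEM image: kappa = sqrt(A' (m^2 y / ybar^2 * A 1)), virtual bins
#' excluded, clamped at zero against round-off.
#' @param x_osem nonnegative OSEM image.
#' @param y observed counts.
#' @param geom projector geometry.
#' @param factors acquisition factors.
#' @return An `image_volume` of nonnegative weights.
#' @export
kappa_from_osem <- function(x_osem, y, geom, factors) {
  ybar <- predict_counts(x_osem, geom, factors)
  mv <- factors$m$values; yv <- y$values; bv <- ybar$values
  live <- mv > 0
  if (any(live & yv > 0 & bv <= 0)) stop("ybar = 0 at a live bin")
  wbin <- numeric(length(yv))
  pos <- live & bv > 0
  wbin[pos] <- mv[pos]^2 * yv[pos] / bv[pos]^2
  ones <- with_values(x_osem, 1)
  a1 <- forward_project(ones, geom)$values
  rs <- back_project(proj_data(array(wbin * a1, dim = dim(yv)), geom),
                     geom, x_osem$dims, x_osem$voxel_size)
  with_values(x_osem, sqrt(pmax(rs$values, 0)))
}

#' Smoothing constant from an initial OSEM reconstruction
#'
#' epsilon = rel * max(x_osem); the default rel = 1e-4 keeps the penalty
#' effectively scale-matched to the reconstruction.
#' @param x_osem OSEM image with a positive maximum.
#' @param rel relative factor > 0.
#' @return Scalar epsilon > 0.
#' @export
epsilon_from_osem <- function(x_osem, rel = 1e-4) {
  if (rel <= 0) stop("rel must be > 0")
  mx <- max(x_osem$values)
  if (mx <= 0) stop("OSEM image has no positive values")
  rel * mx
}

#' Penalised-likelihood objective
#'
#' Psi(x; y) = L(y; ybar(x)) - beta * R(x), the quantity every solver in the
#' package ascends.
#' @inheritParams loglik_grad
#' @param p a [prior_params()].
#' @return List with `loglik`, `prior` and `total`.
#' @export
pl_objective <- function(x, y, geom, factors, p) {
  ybar <- predict_counts(x, geom, factors)
  L <- loglik(y, ybar, factors)
  R <- rdp_value(x, p)
  list(loglik = L, prior = R, total = L - p$beta * R)
}

#' Gradient of the penalised-likelihood objective
#' @inheritParams pl_objective
#' @return An `image_volume` holding the gradient of Psi.
#' @export
pl_grad <- function(x, y, geom, factors, p) {
  gl <- loglik_grad(x, y, geom, factors)
  gr <- rdp_grad(x, p)
  with_values(x, gl$values - p$beta * gr$values)
}

#' Upscaled subset gradient of the objective
#'
#' n_subsets * grad L_s(x) - beta * grad R(x), where L_s uses only the
#' subset's views; the average over all subsets equals the full gradient of
#' Psi exactly.
#' @param x current image.
#' @param subset_index 1-based subset index.
#' @param scheme a [make_subsets()] scheme.
#' @inheritParams pl_objective
#' @return An `image_volume`.
#' @export
subset_grad <- function(x, subset_index, scheme, y, geom, factors, p) {
  if (subset_index < 1L || subset_index > scheme$n_subsets)
    stop("invalid subset index")
  ybar <- predict_counts(x, geom, factors)
  g <- loglik_grad_bins(y, ybar, factors)
  g[!subset_bin_mask(geom, scheme$subsets[[subset_index]])] <- 0
  gl <- back_project(proj_data(g, geom), geom, x$dims, x$voxel_size)
  gr <- rdp_grad(x, p)
  with_values(x, scheme$n_subsets * gl$values - p$beta * gr$values)
}
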