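#' Volume-of-interest mask set
#'
#' Bundles the binary masks the convergence-metric protocol needs: the object
#' support mask M (defining the constraint set: voxels outside M are pinned at
#' zero), the marginally eroded whole-object VOI W, the uniform background VOI
#' B used to normalise all metrics, and the named target VOIs R_i (hot
#' spheres, matter regions, ...).
#'
#' @param object_mask,whole_eroded,background logical arrays sharing the
#'   phantom grid.
#' @param targets named list of logical arrays, pairwise disjoint, each a
#'   subset of `object_mask`.
#' @return An object of class `voi_set`.
#' @export
voi_set <- function(object_mask, whole_eroded, background, targets = list()) {
  object_mask <- as_mask(object_mask)
  whole_eroded <- as_mask(whole_eroded)
  background <- as_mask(background)
  targets <- lapply(targets, as_mask)
  d <- dim(object_mask)
  for (m in c(list(whole_eroded, background), targets))
    if (!identical(dim(m), d)) stop("all VOI masks must share dimensions")
  if (any(whole_eroded & !object_mask))
    stop("whole_eroded must be a subset of object_mask")
  if (any(background & !whole_eroded))
    stop("background must be a subset of whole_eroded")
  if (!any(background)) stop("background VOI must be nonempty")
  if (length(targets)) {
    if (is.null(names(targets)) || any(!nzchar(names(targets))))
      stop("targets must be named")
    acc <- array(0L, d)
    for (tm in targets) {
      if (any(tm & !object_mask)) stop("each target must lie inside object_mask")
      acc <- acc + tm
    }
    if (any(acc > 1L)) stop("target VOIs must be pairwise disjoint")
  }
  structure(list(object_mask = object_mask, whole_eroded = whole_eroded,
                 background = background, targets = targets),
            class = "voi_set")
}

as_mask <- function(m) {
  if (is_image_volume(m)) m <- m$values
  storage.mode(m) <- "logical"
  m
}

#' Binary erosion with the full box structuring element
#'
#' Erodes a binary mask with the 3x3 (2D) or 3x3x3 (3D) box: a voxel survives
#' one iteration only if its entire box neighbourhood (with voxels beyond the
#' image border counting as background) is inside the mask. Used to build the
#' marginally eroded whole-object VOI.
#'
#' @param mask logical 2D/3D array (or an `image_volume` of 0/1).
#' @param iterations number of erosion passes; 0 returns the mask unchanged.
#' @return Logical array of the same dimensions.
#' @examples
#' erode_mask(array(TRUE, c(3, 3)), 1)  # only the centre survives
#' @export
erode_mask <- function(mask, iterations = 1L) {
  mask <- as_mask(mask)
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  nd <- length(dim(mask))
  shifts <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  for (it in seq_len(iterations)) {
    out <- mask
    for (r in seq_len(nrow(shifts)))
      out <- out & shift_mask(mask, shifts[r, ])
    mask <- out
  }
  mask
}

# Shift a logical array by an integer offset per axis, filling with FALSE.
shift_mask <- function(mask, offset) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    o <- offset[k]
    src[[k]] <- seq_len(d[k]) - o
    keep <- src[[k]] >= 1 & src[[k]] <= d[k]
    src[[k]] <- src[[k]][keep]
    dst[[k]] <- seq_len(d[k])[keep]
    if (!length(src[[k]])) return(out)
  }
  out[matrix_index(dst, d)] <- mask[matrix_index(src, d)]
  out
}

matrix_index <- function(axes, d) {
  g <- as.matrix(expand.grid(axes))
  colnames(g) <- NULL
  g
}

#' Generate a synthetic phantom scene
#'
#' Builds a ground-truth activity image, a water-like attenuation map and the
#' full VOI set that the convergence-metric protocol expects. Three phantom
#' families are available:
#' \describe{
#'   \item{`nema_like`}{a warm elliptical background at activity 1.0 with four
#'     hot disc inserts at activity `contrast`, emulating an image-quality
#'     phantom with hot spheres; one target VOI per insert.}
#'   \item{`hoffman_like`}{an ellipse filled with interleaved high/low bands
#'     (activity `contrast` and 1.0), emulating grey/white matter structure;
#'     one target VOI in a high band and one in a low band.}
#'   \item{`constant_disc`}{a uniform disc at activity `contrast`; the
#'     simplest scene, mostly useful for solver sanity checks.}
#' }
#' Insert sizes and positions are deterministic fractions of the grid; the
#' seed only jitters insert positions by at most one voxel, so VOIs are
#' reproducible. The background VOI is carved well inside the uniform warm
#' region, at least two voxels from any insert and from the object boundary.
#'
#' @param kind one of `"nema_like"`, `"hoffman_like"`, `"constant_disc"`.
#' @param dims grid extents, 2D `c(nx, ny)` or 3D; every axis must be >= 16.
#' @param voxel_size voxel pitch in mm per axis.
#' @param contrast activity of the hot regions relative to the warm
#'   background at 1.0; must be > 0.
#' @param seed integer seed controlling the (at most one voxel) insert jitter.
#' @param erosion_iters erosion passes applied to the object mask to form the
#'   whole-object VOI W ("marginal" erosion defaults to 1 pass).
#' @param mu_water linear attenuation coefficient of the phantom material,
#'   1/mm (default 0.0096, water at 511 keV).
#' @return A `phantom_scene`: list with `activity` and `mu` (`image_volume`),
#'   `vois` (`voi_set`) and `meta`.
#' @examples
#' sc <- generate_phantom("nema_like", dims = c(64, 64), contrast = 4)
#' names(sc$vois$targets)
#' @export
generate_phantom <- function(kind = c("nema_like", "hoffman_like", "constant_disc"),
                             dims = c(64L, 64L), voxel_size = 3,
                             contrast = 4, seed = 1L,
                             erosion_iters = 1L, mu_water = 0.0096) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  if (length(dims) < 2L || length(dims) > 3L) stop("dims must be 2D or 3D")
  if (any(dims < 16L)) stop("grid too small: every axis must be >= 16")
  if (contrast <= 0) stop("contrast must be > 0")
  voxel_size <- rep(as.numeric(voxel_size), length.out = length(dims))

  sc <- switch(kind,
    nema_like = phantom_nema(dims, voxel_size, contrast, seed),
    hoffman_like = phantom_hoffman(dims, voxel_size, contrast, seed),
    constant_disc = phantom_disc(dims, voxel_size, contrast, seed))

  whole <- erode_mask(sc$object, erosion_iters)
  # keep the background VOI inside the eroded whole-object VOI
  background <- sc$background & whole
  if (!any(background)) stop("grid too small to place the background VOI")
  vois <- voi_set(sc$object, whole, background, sc$targets)

  activity <- image_volume(sc$activity, voxel_size)
  mu <- image_volume(ifelse(sc$object, mu_water, 0), voxel_size)
  structure(list(activity = activity, mu = mu, vois = vois,
                 meta = list(kind = kind, seed = as.integer(seed),
                             contrast = contrast,
                             erosion_iters = as.integer(erosion_iters))),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene %s %s, contrast %.3g, %d target VOI(s), seed %d>\n",
              x$meta$kind, paste(x$activity$dims, collapse = "x"),
              x$meta$contrast, length(x$vois$targets), x$meta$seed))
  invisible(x)
}

# Normalised coordinate arrays (mm from grid centre), broadcast per axis.
coord_arrays <- function(dims, voxel_size) {
  ax <- grid_axes(dims, voxel_size)
  lapply(seq_along(dims), function(k) {
    perm <- rep(1, length(dims)); perm[k] <- dims[k]
    array(rep(ax[[k]], each = prod(dims[seq_len(k - 1)])), dim = dims)
  })
}

ellipse_mask <- function(dims, voxel_size, semi) {
  co <- coord_arrays(dims, voxel_size)
  acc <- 0
  for (k in seq_along(co)) acc <- acc + (co[[k]] / semi[k])^2
  acc <= 1
}

disc_mask <- function(dims, voxel_size, centre, radius, axes = seq_along(dims)) {
  co <- coord_arrays(dims, voxel_size)
  acc <- 0
  for (k in axes) acc <- acc + (co[[k]] - centre[k])^2
  acc <= radius^2
}

phantom_nema <- function(dims, voxel_size, contrast, seed) {
  half <- dims * voxel_size / 2
  h <- min(half[1:2])
  semi <- c(0.85 * half[1], 0.75 * half[2])
  if (length(dims) == 3L) semi <- c(semi, 0.8 * half[3])
  object <- ellipse_mask(dims, voxel_size, semi)
  activity <- ifelse(object, 1.0, 0.0)

  ring_r <- 0.45 * h
  radii <- c(0.10, 0.13, 0.16, 0.19) * h
  angles <- (c(45, 135, 225, 315)) * pi / 180
  set.seed(as.integer(seed) %% .Machine$integer.max)
  jitter <- matrix(sample(-1:1, 8, replace = TRUE), ncol = 2) *
    rep(voxel_size[1:2], each = 4)

  targets <- list()
  for (i in seq_along(radii)) {
    ctr <- c(ring_r * cos(angles[i]) + jitter[i, 1],
             ring_r * sin(angles[i]) + jitter[i, 2])
    if (length(dims) == 3L) ctr <- c(ctr, 0)
    m <- disc_mask(dims, voxel_size, ctr, radii[i], axes = 1:2) & object
    if (!any(m)) stop("grid too small to place inserts")
    activity[m] <- contrast
    targets[[paste0("insert_", i)]] <- m
  }
  for (i in seq_along(targets))        # guard against jitter-induced overlap
    for (j in seq_len(i - 1L))
      targets[[i]] <- targets[[i]] & !targets[[j]]

  insert_any <- Reduce(`|`, targets)
  rb <- max(voxel_size[1], ring_r - max(radii) - 2 * max(voxel_size[1:2]))
  centre <- disc_mask(dims, voxel_size, rep(0, length(dims)), rb)
  # keep >=2 voxels clear of inserts, relaxing on very coarse grids
  for (clear in 2:0) {
    background <- centre & !grow_mask(insert_any, clear)
    if (any(background)) break
  }
  list(object = object, activity = activity, background = background,
       targets = targets)
}

phantom_hoffman <- function(dims, voxel_size, contrast, seed) {
  half <- dims * voxel_size / 2
  semi <- c(0.85 * half[1], 0.8 * half[2])
  if (length(dims) == 3L) semi <- c(semi, 0.8 * half[3])
  object <- ellipse_mask(dims, voxel_size, semi)

  hb <- max(3L, as.integer(round(dims[2] / 8)))   # band height, voxels
  set.seed(as.integer(seed) %% .Machine$integer.max)
  shift <- sample(0:(hb - 1L), 1L)                # <=1-band deterministic shift
  j <- slice.index(array(0, dims), 2L)
  band <- ((j - 1L + shift) %/% hb)
  high <- band %% 2L == 0L
  activity <- ifelse(object, ifelse(high, contrast, 1.0), 0.0)

  interior <- erode_mask(object, 2L)
  band_core <- (j - 1L + shift) %% hb %in% seq.int(1L, hb - 2L)
  centre_disc <- disc_mask(dims, voxel_size, rep(0, length(dims)),
                           0.45 * min(half[1:2]), axes = 1:2)
  bands_present <- sort(unique(band[interior & band_core & centre_disc]))
  lows <- bands_present[bands_present %% 2L == 1L]
  highs <- bands_present[bands_present %% 2L == 0L]
  if (length(lows) < 2L || length(highs) < 1L)
    stop("grid too small to place inserts")
  pick_mid <- function(v) v[ceiling(length(v) / 2)]
  sel <- function(b) interior & band_core & centre_disc & band == b
  background <- sel(pick_mid(lows))
  targets <- list(low_band = sel(lows[length(lows)]),
                  high_band = sel(pick_mid(highs)))
  targets$low_band <- targets$low_band & !background
  if (!any(targets$low_band)) targets$low_band <- NULL
  list(object = object, activity = activity, background = background,
       targets = targets)
}

phantom_disc <- function(dims, voxel_size, contrast, seed) {
  half <- dims * voxel_size / 2
  h <- min(half[1:2])
  object <- disc_mask(dims, voxel_size, rep(0, length(dims)), 0.7 * h,
                      axes = 1:2)
  activity <- ifelse(object, contrast, 0.0)
  background <- disc_mask(dims, voxel_size, rep(0, length(dims)), 0.3 * h,
                          axes = 1:2)
  off <- c(0.45 * h, 0)
  if (length(dims) == 3L) off <- c(off, 0)
  target <- disc_mask(dims, voxel_size, off, 0.12 * h, axes = 1:2) & object
  list(object = object, activity = activity, background = background,
       targets = list(centre_offset = target & !background))
}

# Dilation (box) by n passes; used to keep the background VOI clear of inserts.
grow_mask <- function(mask, iterations = 1L) {
  !erode_mask(!mask, iterations)
}
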