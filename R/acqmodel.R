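#' Parallel-beam projector geometry
#'
#' Describes the binned sinogram geometry: `n_views` evenly spaced view
#' angles over [0, pi), `n_radial` radial bins with `radial_spacing` mm pitch
#' centred on the scanner axis, and (for 3D volumes) `n_planes` axial planes
#' projected independently. The projector is a 2D parallel-beam line-integral
#' operator with exact voxel-intersection lengths; in 3D the same in-plane
#' operator is applied slice by slice.
#'
#' @param n_views number of view angles (>= 1).
#' @param n_radial number of radial bins (>= 1).
#' @param radial_spacing radial bin pitch in mm.
#' @param n_planes number of axial planes, or `NULL` for 2D.
#' @return An object of class `projector_geometry`.
#' @export
projector_geometry <- function(n_views, n_radial, radial_spacing = 1,
                               n_planes = NULL) {
  n_views <- as.integer(n_views); n_radial <- as.integer(n_radial)
  if (n_views < 1L || n_radial < 1L) stop("n_views and n_radial must be >= 1")
  if (radial_spacing <= 0) stop("radial_spacing must be > 0")
  angles <- (seq_len(n_views) - 1L) * pi / n_views
  structure(list(n_views = n_views, n_radial = n_radial,
                 radial_spacing = as.numeric(radial_spacing),
                 n_planes = if (!is.null(n_planes)) as.integer(n_planes),
                 angles = angles),
            class = "projector_geometry")
}

#' Default geometry covering an image grid
#'
#' Chooses a sinogram geometry whose radial bins span the image field of view
#' at the in-plane voxel pitch, with roughly one view per image column.
#' @param img an `image_volume` (or integer dims with `voxel_size`).
#' @param n_views optional view count override.
#' @param voxel_size used when `img` is a dims vector.
#' @return A `projector_geometry`.
#' @export
default_geometry <- function(img, n_views = NULL, voxel_size = 1) {
  if (is_image_volume(img)) {
    dims <- img$dims; voxel_size <- img$voxel_size
  } else {
    dims <- as.integer(img)
    voxel_size <- rep(voxel_size, length.out = length(dims))
  }
  nx <- dims[1]
  if (is.null(n_views)) n_views <- max(16L, nx)
  projector_geometry(n_views = n_views, n_radial = nx + 1L,
                     radial_spacing = voxel_size[1],
                     n_planes = if (length(dims) == 3L) dims[3])
}

#' Binned projection data
#'
#' Sinogram-shaped values (counts, expectations or multiplicative factors)
#' over a [projector_geometry()]: an array of dim (n_radial, n_views) or
#' (n_radial, n_views, n_planes).
#' @param values numeric array matching the geometry.
#' @param geom the `projector_geometry`.
#' @return An object of class `proj_data`.
#' @export
proj_data <- function(values, geom) {
  d <- proj_dims(geom)
  values <- array(as.numeric(values), dim = d)
  if (!all(is.finite(values))) stop("projection values must be finite")
  structure(list(values = values, geom = geom), class = "proj_data")
}

proj_dims <- function(geom) {
  d <- c(geom$n_radial, geom$n_views)
  if (!is.null(geom$n_planes)) d <- c(d, geom$n_planes)
  d
}

#' @export
print.proj_data <- function(x, ...) {
  cat(sprintf("<proj_data %s, range [%.4g, %.4g]>\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

# ---- system matrix -------------------------------------------------------

.proj_cache <- new.env(parent = emptyenv())

geom_key <- function(geom, dims, voxel_size) {
  paste(geom$n_views, geom$n_radial, signif(geom$radial_spacing, 12),
        paste(dims[1:2], collapse = "x"),
        paste(signif(voxel_size[1:2], 12), collapse = "x"), sep = "|")
}

#' In-plane system matrix of the line-integral operator
#'
#' Assembles (and caches per geometry/grid pair) the sparse matrix A whose
#' entry (k, i) is the exact intersection length in mm of ray k with voxel i,
#' computed by Siddon-style parametric ray tracing. Back-projection uses the
#' transpose of this same matrix, so the projector/adjoint pair is matched to
#' machine precision by construction.
#'
#' @param geom a `projector_geometry`.
#' @param dims image grid dims (only the first two axes are used).
#' @param voxel_size voxel pitch in mm.
#' @return A `Matrix::dgCMatrix` of dim (n_radial * n_views, nx * ny).
#' @export
system_matrix <- function(geom, dims, voxel_size) {
  voxel_size <- rep(voxel_size, length.out = length(dims))
  key <- geom_key(geom, dims, voxel_size)
  hit <- .proj_cache[[key]]
  if (!is.null(hit)) return(hit)
  A <- build_system_matrix(geom, dims[1:2], voxel_size[1:2])
  .proj_cache[[key]] <- A
  A
}

build_system_matrix <- function(geom, dims, voxel_size) {
  nx <- dims[1]; ny <- dims[2]
  dx <- voxel_size[1]; dy <- voxel_size[2]
  xb <- (0:nx - nx / 2) * dx        # voxel boundary planes
  yb <- (0:ny - ny / 2) * dy
  offs <- (seq_len(geom$n_radial) - (geom$n_radial + 1) / 2) *
    geom$radial_spacing
  tiny <- 1e-12

  ii <- jj <- vv <- vector("list", geom$n_views * geom$n_radial)
  slot <- 0L
  for (v in seq_len(geom$n_views)) {
    th <- geom$angles[v]
    u <- c(cos(th), sin(th))        # radial offset direction
    w <- c(-sin(th), cos(th))       # ray direction, unit length
    for (r in seq_len(geom$n_radial)) {
      slot <- slot + 1L
      p0 <- offs[r] * u
      # parametric range inside the grid bounding box
      tlo <- -Inf; thi <- Inf; ok <- TRUE
      for (ax in 1:2) {
        b <- if (ax == 1) xb else yb
        if (abs(w[ax]) < tiny) {
          if (p0[ax] <= b[1] || p0[ax] >= b[length(b)]) { ok <- FALSE; break }
        } else {
          t1 <- (b[1] - p0[ax]) / w[ax]
          t2 <- (b[length(b)] - p0[ax]) / w[ax]
          tlo <- max(tlo, min(t1, t2)); thi <- min(thi, max(t1, t2))
        }
      }
      if (!ok || tlo >= thi - tiny) next
      tt <- c(tlo, thi)
      for (ax in 1:2) {
        if (abs(w[ax]) >= tiny) {
          b <- if (ax == 1) xb else yb
          tc <- (b - p0[ax]) / w[ax]
          tt <- c(tt, tc[tc > tlo + tiny & tc < thi - tiny])
        }
      }
      tt <- sort(tt)
      len <- diff(tt)
      keep <- len > tiny
      if (!any(keep)) next
      tm <- (tt[-length(tt)] + tt[-1])[keep] / 2
      ix <- floor((p0[1] + tm * w[1] - xb[1]) / dx) + 1
      iy <- floor((p0[2] + tm * w[2] - yb[1]) / dy) + 1
      good <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
      if (!any(good)) next
      bin <- (v - 1L) * geom$n_radial + r
      ii[[slot]] <- rep.int(bin, sum(good))
      jj[[slot]] <- (iy[good] - 1) * nx + ix[good]
      vv[[slot]] <- len[keep][good]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(geom$n_radial * geom$n_views, nx * ny))
}

# ---- forward / adjoint ---------------------------------------------------

#' Forward-project an image into sinogram space
#'
#' Applies the line-integral operator A: bin k receives (approximately) the
#' integral of the image along ray k, in activity * mm. 3D volumes are
#' projected plane by plane.
#' @param x an `image_volume`.
#' @param geom a `projector_geometry` compatible with `x`.
#' @return A `proj_data`.
#' @export
forward_project <- function(x, geom) {
  check_geom_image(geom, x)
  A <- system_matrix(geom, x$dims, x$voxel_size)
  if (length(x$dims) == 2L) {
    g <- as.numeric(A %*% as.vector(x$values))
  } else {
    g <- vapply(seq_len(x$dims[3]), function(p)
      as.numeric(A %*% as.vector(x$values[, , p])),
      numeric(geom$n_radial * geom$n_views))
  }
  proj_data(g, geom)
}

#' Back-project sinogram data into image space
#'
#' Applies the exact adjoint (matrix transpose) of [forward_project()], so
#' that `<Ax, g> == <x, A'g>` holds to machine precision for all x, g.
#' @param g a `proj_data`.
#' @param geom the matching geometry.
#' @param dims,voxel_size the target image grid.
#' @return An `image_volume`.
#' @export
back_project <- function(g, geom, dims, voxel_size = 1) {
  if (!identical(dim(g$values), proj_dims(geom)))
    stop("dimension mismatch between projection data and geometry")
  voxel_size <- rep(voxel_size, length.out = length(dims))
  A <- system_matrix(geom, dims, voxel_size)
  if (length(dims) == 2L) {
    x <- as.numeric(Matrix::crossprod(A, as.vector(g$values)))
  } else {
    x <- vapply(seq_len(dims[3]), function(p)
      as.numeric(Matrix::crossprod(A, as.vector(g$values[, , p]))),
      numeric(prod(dims[1:2])))
  }
  image_volume(array(x, dim = dims), voxel_size)
}

check_geom_image <- function(geom, x) {
  nd <- length(x$dims)
  if (is.null(geom$n_planes)) {
    if (nd != 2L) stop("dimension mismatch: 2D geometry needs a 2D image")
  } else if (nd != 3L || x$dims[3] != geom$n_planes)
    stop("dimension mismatch: geometry expects ", geom$n_planes, " planes")
  invisible(TRUE)
}

# ---- acquisition factors and forward model -------------------------------

#' Multiplicative and additive acquisition factors
#'
#' Bundles the bin-wise multiplicative factors m (detection efficiency times
#' attenuation) and the additive background a (randoms + scatter estimate,
#' pre-corrected by m). Bins with m = 0 are "virtual crystal" bins whose data
#' are structurally zero; everywhere m > 0 the background a must be strictly
#' positive.
#' @param m,a `proj_data` objects on the same geometry.
#' @return An object of class `acq_factors`.
#' @export
acq_factors <- function(m, a) {
  if (!identical(dim(m$values), dim(a$values)))
    stop("m and a must share dimensions")
  if (any(m$values < 0)) stop("m must be nonnegative")
  if (any(a$values[m$values > 0] <= 0))
    stop("a must be strictly positive wherever m > 0")
  structure(list(m = m, a = a), class = "acq_factors")
}

#' Build acquisition factors from a phantom scene
#'
#' m = efficiency * exp(-integral of mu along the ray); a is a constant,
#' strictly positive background set to `scatter_fraction` times the mean
#' line integral of the (scaled) activity over live bins.
#' @param scene a `phantom_scene` (its `mu` map sets the attenuation).
#' @param geom a `projector_geometry`.
#' @param activity the (possibly count-scaled) activity image.
#' @param efficiency scalar detector efficiency.
#' @param scatter_fraction background level as a fraction of mean trues.
#' @param virtual_bins optional integer indices of bins forced to m = 0.
#' @return An `acq_factors`.
#' @export
make_factors <- function(scene, geom, activity = scene$activity,
                         efficiency = 1, scatter_fraction = 0.1,
                         virtual_bins = NULL) {
  att <- forward_project(scene$mu, geom)
  mv <- efficiency * exp(-att$values)
  if (!is.null(virtual_bins)) mv[virtual_bins] <- 0
  trues <- forward_project(activity, geom)$values
  live <- mv > 0
  abar <- scatter_fraction * mean(trues[live])
  if (!is.finite(abar) || abar <= 0) abar <- 1e-6
  acq_factors(proj_data(mv, geom),
              proj_data(array(abar, dim = dim(mv)), geom))
}

#' Expected data for an image under the affine Poisson model
#'
#' ybar_k = m_k * ((Ax)_k + a_k); exactly zero at virtual-crystal bins
#' (m_k = 0) and strictly positive everywhere else.
#' @param x nonnegative `image_volume`.
#' @param geom a `projector_geometry`.
#' @param factors an `acq_factors`.
#' @return A `proj_data` of expectations.
#' @export
predict_counts <- function(x, geom, factors) {
  if (any(x$values < -1e-12)) stop("negative activity in predict_counts")
  ax <- forward_project(x, geom)
  yb <- factors$m$values * (ax$values + factors$a$values)
  yb[factors$m$values == 0] <- 0
  proj_data(yb, geom)
}

#' Draw Poisson counts from expected data
#' @param ybar nonnegative `proj_data` of expectations.
#' @param seed integer seed (draws are deterministic given the seed).
#' @return A `proj_data` of integer counts.
#' @export
sample_counts <- function(ybar, seed = 1L) {
  if (any(ybar$values < 0)) stop("negative means")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  proj_data(stats::rpois(length(ybar$values), ybar$values), ybar$geom)
}

# ---- subsets and sensitivity ---------------------------------------------

#' Partition views into interleaved angular subsets
#'
#' Subset j contains the views congruent to j modulo `n_subsets`, giving each
#' subset maximally spread angular coverage.
#' @param n_views total view count.
#' @param n_subsets number of subsets; must divide `n_views`.
#' @return An object of class `subset_scheme`: list with `subsets` (a list of
#'   1-based view-index vectors) and `n_subsets`.
#' @export
make_subsets <- function(n_views, n_subsets) {
  n_views <- as.integer(n_views); n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1L || n_subsets > n_views) stop("need 1 <= n_subsets <= n_views")
  if (n_views %% n_subsets != 0L) stop("n_subsets must divide n_views")
  subsets <- lapply(seq_len(n_subsets), function(j)
    seq.int(j, n_views, by = n_subsets))
  structure(list(subsets = subsets, n_subsets = n_subsets,
                 n_views = n_views), class = "subset_scheme")
}

# logical mask over sinogram bins selecting a subset's views
subset_bin_mask <- function(geom, views) {
  m <- array(FALSE, proj_dims(geom))
  if (is.null(geom$n_planes)) m[, views] <- TRUE else m[, views, ] <- TRUE
  m
}

#' Per-subset and average sensitivity images
#'
#' The sensitivity image of subset s is the adjoint of the subset projector
#' applied to the subset's multiplicative factors, A_s' m_s; S is their
#' arithmetic mean over subsets and is the denominator of the EM-style
#' preconditioner used by the solvers.
#' @param geom a `projector_geometry`.
#' @param factors an `acq_factors`.
#' @param scheme a `subset_scheme`.
#' @param dims,voxel_size the image grid.
#' @return List with `per_subset` (list of `image_volume`) and `average`.
#' @export
sensitivity_images <- function(geom, factors, scheme, dims, voxel_size = 1) {
  per <- lapply(scheme$subsets, function(views) {
    mv <- factors$m$values
    mv[!subset_bin_mask(geom, views)] <- 0
    back_project(proj_data(mv, geom), geom, dims, voxel_size)
  })
  avg <- Reduce(`+`, lapply(per, function(im) im$values)) / scheme$n_subsets
  list(per_subset = per,
       average = image_volume(array(avg, dim = per[[1]]$dims),
                              per[[1]]$voxel_size))
}
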