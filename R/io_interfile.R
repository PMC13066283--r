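# Interfile-lite: a documented, fixed subset of Interfile keys. Images use a
# .hv text header plus a .v raw payload; projection data use .hs/.s with
# extra geometry keys. Unknown keys are tolerated with a warning.

il_number_format <- function(values) "float"

il_write_header <- function(path, keys) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("!INTERFILE :=", con)
  for (nm in names(keys))
    writeLines(sprintf("%s := %s", nm, as.character(keys[[nm]])), con)
  writeLines("!END OF INTERFILE :=", con)
}

il_parse_header <- function(path, known) {
  lines <- readLines(path, warn = FALSE)
  keys <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || !grepl(":=", ln, fixed = TRUE)) next
    parts <- strsplit(ln, ":=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- if (length(parts) > 1) trimws(paste(parts[-1], collapse = ":=")) else ""
    if (key %in% c("!INTERFILE", "!END OF INTERFILE")) next
    if (!(key %in% known))
      warning("ignoring unknown Interfile key: ", key, call. = FALSE)
    keys[[key]] <- val
  }
  keys
}

il_require <- function(keys, nm) {
  if (is.null(keys[[nm]])) stop("missing Interfile key: ", nm)
  keys[[nm]]
}

il_payload_write <- function(path, values, bytes, endian) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = bytes, endian = endian)
}

il_payload_read <- function(path, n, format, bytes, endian, offset = 0) {
  expected <- offset + n * bytes
  actual <- file.info(path)$size
  if (is.na(actual) || actual != expected)
    stop(sprintf("payload size mismatch: header declares %d bytes, file has %s",
                 expected, format(actual)))
  con <- file(path, open = "rb")
  on.exit(close(con))
  if (offset > 0) seek(con, offset)
  what <- switch(format,
                 float = numeric(),
                 `signed integer` = integer(),
                 stop("unsupported number format: ", format))
  readBin(con, what, n = n, size = bytes, endian = endian)
}

endian_word <- function(e) if (e == "little") "LITTLEENDIAN" else "BIGENDIAN"
word_endian <- function(w) {
  w <- toupper(w)
  if (w == "LITTLEENDIAN") "little"
  else if (w == "BIGENDIAN") "big"
  else stop("unsupported byte order: ", w)
}

#' Write an image volume as an Interfile-lite header/raw pair
#'
#' Writes `<path>.hv` (text header) and `<path>.v` (raw payload). Values are
#' stored as 8-byte floats by default, so a write/read round trip is
#' bit-identical.
#' @param img an `image_volume`.
#' @param path output path without extension (or ending in `.hv`).
#' @param endian `"little"` (default) or `"big"`.
#' @return The header path, invisibly.
#' @export
write_image <- function(img, path, endian = c("little", "big")) {
  endian <- match.arg(endian)
  path <- sub("\\.hv$", "", path)
  data_file <- paste0(basename(path), ".v")
  keys <- list(`name of data file` = data_file,
               `!imaging modality` = "PT",
               `!number format` = "float",
               `!number of bytes per pixel` = 8,
               `imagedata byte order` = endian_word(endian),
               `number of dimensions` = length(img$dims),
               `data offset in bytes` = 0)
  for (k in seq_along(img$dims)) {
    keys[[sprintf("!matrix size [%d]", k)]] <- img$dims[k]
    keys[[sprintf("scaling factor (mm/pixel) [%d]", k)]] <-
      format(img$voxel_size[k], digits = 17)
  }
  il_write_header(paste0(path, ".hv"), keys)
  il_payload_write(paste0(path, ".v"), img$values, 8L, endian)
  invisible(paste0(path, ".hv"))
}

image_known_keys <- function(nd_max = 3) {
  c("name of data file", "!imaging modality", "!number format",
    "!number of bytes per pixel", "imagedata byte order",
    "number of dimensions", "data offset in bytes",
    sprintf("!matrix size [%d]", 1:nd_max),
    sprintf("scaling factor (mm/pixel) [%d]", 1:nd_max))
}

#' Read an Interfile-lite image
#' @param path path to the `.hv` header.
#' @return An `image_volume`.
#' @export
read_image <- function(path) {
  keys <- il_parse_header(path, image_known_keys())
  nd <- as.integer(il_require(keys, "number of dimensions"))
  dims <- vapply(1:nd, function(k)
    as.integer(il_require(keys, sprintf("!matrix size [%d]", k))), integer(1))
  vox <- vapply(1:nd, function(k)
    as.numeric(il_require(keys, sprintf("scaling factor (mm/pixel) [%d]", k))),
    numeric(1))
  fmt <- il_require(keys, "!number format")
  bytes <- as.integer(il_require(keys, "!number of bytes per pixel"))
  if (!bytes %in% c(4L, 8L)) stop("unsupported bytes per pixel: ", bytes)
  endian <- word_endian(il_require(keys, "imagedata byte order"))
  offset <- as.numeric(keys[["data offset in bytes"]] %||% 0)
  data_file <- file.path(dirname(path), il_require(keys, "name of data file"))
  vals <- il_payload_read(data_file, prod(dims), fmt, bytes, endian, offset)
  image_volume(array(vals, dim = dims), vox)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write projection data as an Interfile-lite header/raw pair
#'
#' Writes `<path>.hs` / `<path>.s` with the sinogram geometry recorded in
#' the header (number of views, radial bins, radial spacing, planes).
#' @param pd a `proj_data`.
#' @param path output path without extension (or ending in `.hs`).
#' @param endian byte order.
#' @return The header path, invisibly.
#' @export
write_projdata <- function(pd, path, endian = c("little", "big")) {
  endian <- match.arg(endian)
  path <- sub("\\.hs$", "", path)
  d <- dim(pd$values)
  keys <- list(`name of data file` = paste0(basename(path), ".s"),
               `!imaging modality` = "PT",
               `!number format` = "float",
               `!number of bytes per pixel` = 8,
               `imagedata byte order` = endian_word(endian),
               `number of dimensions` = length(d),
               `data offset in bytes` = 0,
               `number of views` = pd$geom$n_views,
               `number of radial bins` = pd$geom$n_radial,
               `radial bin spacing (mm)` =
                 format(pd$geom$radial_spacing, digits = 17))
  if (!is.null(pd$geom$n_planes))
    keys[["number of planes"]] <- pd$geom$n_planes
  for (k in seq_along(d))
    keys[[sprintf("!matrix size [%d]", k)]] <- d[k]
  il_write_header(paste0(path, ".hs"), keys)
  il_payload_write(paste0(path, ".s"), pd$values, 8L, endian)
  invisible(paste0(path, ".hs"))
}

proj_known_keys <- function() {
  c(image_known_keys(), "number of views", "number of radial bins",
    "radial bin spacing (mm)", "number of planes")
}

#' Read Interfile-lite projection data
#' @param path path to the `.hs` header.
#' @param counts if `TRUE`, warn when the payload is not integral (count
#'   data are expected to be whole numbers).
#' @return A `proj_data`.
#' @export
read_projdata <- function(path, counts = FALSE) {
  keys <- il_parse_header(path, proj_known_keys())
  nd <- as.integer(il_require(keys, "number of dimensions"))
  dims <- vapply(1:nd, function(k)
    as.integer(il_require(keys, sprintf("!matrix size [%d]", k))), integer(1))
  n_views <- as.integer(il_require(keys, "number of views"))
  n_radial <- as.integer(il_require(keys, "number of radial bins"))
  spacing <- as.numeric(il_require(keys, "radial bin spacing (mm)"))
  n_planes <- if (!is.null(keys[["number of planes"]]))
    as.integer(keys[["number of planes"]])
  geom <- projector_geometry(n_views, n_radial, spacing, n_planes)
  if (!identical(dims, proj_dims(geom)))
    stop("geometry mismatch between header matrix sizes and geometry keys")
  fmt <- il_require(keys, "!number format")
  bytes <- as.integer(il_require(keys, "!number of bytes per pixel"))
  endian <- word_endian(il_require(keys, "imagedata byte order"))
  offset <- as.numeric(keys[["data offset in bytes"]] %||% 0)
  data_file <- file.path(dirname(path), il_require(keys, "name of data file"))
  vals <- il_payload_read(data_file, prod(dims), fmt, bytes, endian, offset)
  if (counts && any(vals != round(vals)))
    warning("count data expected integral values; payload has fractions",
            call. = FALSE)
  proj_data(array(vals, dim = dims), geom)
}

#' Export a phantom scene to a dataset directory
#'
#' Writes the activity and attenuation images plus one Interfile-lite mask
#' image per VOI (object, whole eroded, background, and each target).
#' @param scene a `phantom_scene`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(scene$activity, file.path(dir, "activity"))
  write_image(scene$mu, file.path(dir, "mu"))
  vs <- scene$activity$voxel_size
  wm <- function(mask, nm)
    write_image(image_volume(array(as.numeric(mask), dim = dim(mask)), vs),
                file.path(dir, nm))
  wm(scene$vois$object_mask, "voi_object")
  wm(scene$vois$whole_eroded, "voi_whole_eroded")
  wm(scene$vois$background, "voi_background")
  for (nm in names(scene$vois$targets))
    wm(scene$vois$targets[[nm]], paste0("voi_", nm))
  invisible(dir)
}

#' Read a VOI set back from a dataset directory written by [write_scene()]
#' @param dir the dataset directory.
#' @return A [voi_set()].
#' @export
read_vois <- function(dir) {
  rd <- function(nm) read_image(file.path(dir, paste0(nm, ".hv")))$values > 0.5
  files <- list.files(dir, pattern = "^voi_.*\\.hv$")
  std <- c("voi_object.hv", "voi_whole_eroded.hv", "voi_background.hv")
  targets <- setdiff(files, std)
  tl <- lapply(targets, function(f) rd(sub("\\.hv$", "", f)))
  names(tl) <- sub("^voi_(.*)\\.hv$", "\\1", targets)
  voi_set(rd("voi_object"), rd("voi_whole_eroded"), rd("voi_background"), tl)
}
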