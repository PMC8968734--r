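fileExt <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

ioError <- function(path, why)
  stop(sprintf("format error reading '%s': %s", path, why), call. = FALSE)

#' Read / write 2D intensity grids
#'
#' Supported formats, chosen by extension: NIfTI (`.nii`, `.nii.gz`; stored
#' as double, lossless round-trip), TIFF (`.tif`, `.tiff`; 32-bit float),
#' and PNG (`.png`; documented 8-bit quantization of `[0, 1]` intensities).
#' Unknown extensions and unreadable files raise errors; images containing
#' non-finite pixels are refused with the offending coordinate named.
#'
#' @param path file path; the extension selects the format.
#' @param image numeric matrix to write.
#' @return `readImageGrid` returns a numeric matrix; `writeImageGrid`
#'   returns `path` invisibly.
#' @export
readImageGrid <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path),
                               call. = FALSE)
  ext <- fileExt(path)
  img <- switch(ext,
    "nii" = , "nii.gz" = tryCatch({
      v <- RNifti::readNifti(path)
      a <- as.array(v)
      if (length(dim(a)) > 2) a <- a[, , 1]
      matrix(as.numeric(a), dim(a)[1], dim(a)[2])
    }, error = function(e) ioError(path, conditionMessage(e))),
    "png" = tryCatch({
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a
    }, error = function(e) ioError(path, conditionMessage(e))),
    "tif" = , "tiff" = tryCatch({
      a <- tiff::readTIFF(path)
      if (is.list(a)) a <- a[[1]]
      if (length(dim(a)) == 3) a <- a[, , 1]
      a
    }, error = function(e) ioError(path, conditionMessage(e))),
    stop(sprintf("unsupported format '.%s'", ext), call. = FALSE))
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' @rdname readImageGrid
#' @export
writeImageGrid <- function(image, path) {
  stopIfNotMatrix(image)
  ext <- fileExt(path)
  switch(ext,
    "nii" = , "nii.gz" = RNifti::writeNifti(
      RNifti::asNifti(array(image, dim = dim(image)), datatype = "double"),
      path),
    "png" = {
      clipped <- pmin(pmax(image, 0), 1)
      png::writePNG(clipped, path)
    },
    "tif" = , "tiff" = tiff::writeTIFF(
      matrix(as.numeric(image), nrow(image)), path, bits.per.sample = 32L),
    stop(sprintf("unsupported format '.%s'", ext), call. = FALSE))
  invisible(path)
}

#' Read / write integer label maps
#'
#' Label maps (tissue codes 0..3) round-trip exactly: PNG stores code k as
#' gray value k/255 (8-bit), NIfTI stores integers.
#'
#' @param path file path (`.png`, `.nii`, `.nii.gz`).
#' @param labels integer matrix of tissue codes.
#' @return `readLabelMap` returns an integer matrix; `writeLabelMap` returns
#'   `path` invisibly.
#' @export
readLabelMap <- function(path) {
  ext <- fileExt(path)
  m <- if (ext == "png") round(readImageGrid(path) * 255)
       else readImageGrid(path)
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}

#' @rdname readLabelMap
#' @export
writeLabelMap <- function(labels, path) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ext <- fileExt(path)
  if (ext == "png") {
    if (any(labels < 0 | labels > 255))
      stop("PNG label maps support codes 0..255", call. = FALSE)
    png::writePNG(labels / 255, path)
  } else {
    writeImageGrid(matrix(as.numeric(labels), nrow(labels)), path)
  }
  invisible(path)
}

#' Read / write image time series
#'
#' Multi-page TIFF (`.tif`) stores one 32-bit-float page per frame; NIfTI
#' (`.nii`, `.nii.gz`) stores an H x W x frames volume of doubles.
#'
#' @param path file path.
#' @param frames list of numeric matrices sharing one dimension.
#' @return `readSeries` returns a list of matrices; `writeSeries` returns
#'   `path` invisibly.
#' @export
readSeries <- function(path) {
  ext <- fileExt(path)
  switch(ext,
    "tif" = , "tiff" = tryCatch({
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, function(a) {
        if (length(dim(a)) == 3) a <- a[, , 1]
        matrix(as.numeric(a), nrow(a), ncol(a))
      })
    }, error = function(e) ioError(path, conditionMessage(e))),
    "nii" = , "nii.gz" = tryCatch({
      a <- as.array(RNifti::readNifti(path))
      if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
      lapply(seq_len(dim(a)[3]), function(k)
        matrix(as.numeric(a[, , k]), dim(a)[1], dim(a)[2]))
    }, error = function(e) ioError(path, conditionMessage(e))),
    stop(sprintf("unsupported series format '.%s'", ext), call. = FALSE))
}

#' @rdname readSeries
#' @export
writeSeries <- function(frames, path) {
  if (is(frames, "MotionSeries")) frames <- frames@frames
  ext <- fileExt(path)
  switch(ext,
    "tif" = , "tiff" = tiff::writeTIFF(frames, path, bits.per.sample = 32L),
    "nii" = , "nii.gz" = {
      a <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
      RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), path)
    },
    stop(sprintf("unsupported series format '.%s'", ext), call. = FALSE))
  invisible(path)
}

#' Read / write rigid transforms as JSON
#'
#' Transforms serialize as an array of objects
#' `{frame, tx, ty, angle_deg, center_row, center_col}` with 0-based frame
#' indices and (row, col) coordinates.
#'
#' @param path JSON file path.
#' @param transforms list of [RigidTransform2D-class] objects.
#' @return `readTransforms` returns a list of [RigidTransform2D-class];
#'   `writeTransforms` returns `path` invisibly.
#' @export
writeTransforms <- function(transforms, path) {
  df <- data.frame(
    frame = seq_along(transforms) - 1L,
    tx = vapply(transforms, function(t) t@tx, numeric(1)),
    ty = vapply(transforms, function(t) t@ty, numeric(1)),
    angle_deg = vapply(transforms, function(t) t@angle, numeric(1)),
    center_row = vapply(transforms, function(t) t@center[1], numeric(1)),
    center_col = vapply(transforms, function(t) t@center[2], numeric(1)))
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' @rdname writeTransforms
#' @export
readTransforms <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(df)), function(i)
    rigidTransform(df$tx[i], df$ty[i], df$angle_deg[i],
                   c(df$center_row[i], df$center_col[i])))
}

#' Full resolved run configuration
#'
#' Collects every tunable default of the toolkit (Chan-Vese weights, texture
#' window and orientations, kernel width and cost, training-set size, block
#' matching and boosting constants, seeds) into a single flat list that
#' round-trips losslessly through a YAML config file.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class `"RunConfig"`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    gamma1 = 0.3, gamma2 = 0.7, alpha = 0.2, beta = 0,
    heaviside_eps = 1, time_step = 1, max_iters = 500L, stop_tol = 1e-5,
    window = 7L, d = 1L, thetas = c(0, 45, 90, 135), n_levels = 16L,
    log_base = 2, symmetric = FALSE,
    sigma = 0.5, c = 1000, n_train = 1500L,
    block = 4L, search_radius = 5L, phi_coeff = 0.5,
    m_threshold = 5, tau = 1e-3, neighborhood_radius = 5,
    n_iters = 100L, iter_step = 10L, descent_rate = 0.45,
    edge_quant_coeff = 0.62,
    noise_fraction = 0.02, bias_fraction = 0.30,
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop(sprintf("unknown config keys: %s",
                                  paste(bad, collapse = ", ")),
                          call. = FALSE)
    cfg[names(over)] <- over
  }
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param config a `"RunConfig"` list.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- runConfig()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    tmpl <- base[[nm]]
    if (is.integer(tmpl)) v <- as.integer(v)
    else if (is.numeric(tmpl)) v <- as.numeric(v)
    else if (is.logical(tmpl)) v <- as.logical(v)
    base[[nm]] <- v
  }
  base
}
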