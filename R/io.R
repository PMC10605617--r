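# File I/O: multi-page TIFF frame stacks, NIfTI volumes, CSV tables,
# YAML configs. Tabular floating point is written with 6 significant
# digits and a fixed column order so identical runs give identical files.

#' Write a frame stack as a multi-page TIFF (plus a YAML sidecar)
#'
#' Intensities are clamped to `[0, 1]` and stored as 32-bit float, one
#' page per frame. Physical calibration (pixel size, frame rate, kind)
#' goes to `<path>.yaml` since baseline TIFF tags cannot carry it.
#'
#' @param stack a [FrameStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  fr <- frames(stack)
  pages <- lapply(seq_len(dim(fr)[3L]),
                  function(f) pmin(pmax(fr[, , f], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size_mm = pixelSize(stack),
                        frame_rate_hz = frameRate(stack),
                        kind = stackKind(stack)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame stack written by [writeFrameStack()]
#'
#' @param path TIFF path; calibration is read from `<path>.yaml` unless
#'   given explicitly.
#' @param pixelSize,frameRate,kind calibration overrides.
#' @return A [FrameStack-class].
#' @export
readFrameStack <- function(path, pixelSize = NULL, frameRate = NULL,
                           kind = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  px <- pixelSize %||% meta$pixel_size_mm
  fps <- frameRate %||% meta$frame_rate_hz
  knd <- kind %||% meta$kind %||% "contrast"
  if (is.null(px) || is.null(fps))
    stop("pixel size and frame rate must come from the sidecar or arguments")
  arr <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  FrameStack(arr, px, fps, knd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 3D volume (or mask/radius field) as NIfTI
#'
#' @param x a [Volume3D-class], [RadiusMap-class] or plain 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSizeUm voxel size when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path, voxelSizeUm = 26.5) {
  if (is(x, "Volume3D")) {
    arr <- volumeData(x); vs <- voxelSize(x)
  } else if (is(x, "RadiusMap")) {
    arr <- radiusField(x); vs <- voxelSize(x)
  } else {
    arr <- x; vs <- voxelSizeUm
  }
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vs / 1000, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @return A [Volume3D-class] (voxel size taken from the header, mm
#'   converted to µm).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1L] * 1000
  Volume3D(array(as.numeric(img), dim = dim(img)), vs)
}

# fixed-format CSV writer: 6 significant digits, no row names
writeTable <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read tracks as CSV
#'
#' Column order `track_id, frame, x_mm, z_mm`, positions in mm with 6
#' significant digits.
#'
#' @param trackset a [TrackSet-class].
#' @param path CSV path.
#' @return `path` (write) or a [TrackSet-class] (read).
#' @export
writeTracksCsv <- function(trackset, path) {
  writeTable(tracks(trackset)[, c("track_id", "frame", "x_mm", "z_mm")], path)
}

#' @param frameRate frame rate (Hz) to attach on read.
#' @rdname writeTracksCsv
#' @export
readTracksCsv <- function(path, frameRate) {
  TrackSet(utils::read.csv(path), frameRate)
}

#' Write / read detections as CSV
#'
#' @param detections data.frame (`frame`, `x_mm`, `z_mm`, ...).
#' @param path CSV path.
#' @return `path` (write) or a data.frame (read).
#' @export
writeDetectionsCsv <- function(detections, path) writeTable(detections, path)

#' @rdname writeDetectionsCsv
#' @export
readDetectionsCsv <- function(path) utils::read.csv(path)

#' Read or write a pipeline configuration
#'
#' Configurations are plain named lists serialized to YAML; reading back
#' a written config reproduces it exactly, and every pipeline run writes
#' its resolved config (with an md5 content hash) next to its outputs.
#'
#' @param config named list.
#' @param path YAML path.
#' @return `path` (write) or the configuration list (read).
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)

# md5 of the YAML serialization of a config list
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Render an SRUS image to PNG with color-wheel direction encoding
#'
#' Track-filled pixels are colored by flow direction (angle mapped to
#' hue around the color wheel), background is black, and a small color
#' wheel legend is inset in the bottom-right corner. Direction encoding
#' is rendering-only; no quantification uses it.
#'
#' @param img an [SRUSImage-class].
#' @param path output PNG path.
#' @param legend draw the color-wheel inset (default TRUE).
#' @return `path`, invisibly.
#' @export
writeSrusPng <- function(img, path, legend = TRUE) {
  ras <- trackRaster(img)
  dir <- directionMap(img)
  nz <- nrow(ras); nx <- ncol(ras)
  rgb <- array(0, dim = c(nz, nx, 3L))
  if (any(ras)) {
    hue <- (dir[ras] / (2 * pi)) %% 1
    cols <- grDevices::hsv(hue, s = 1, v = 1)
    cm <- grDevices::col2rgb(cols) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[ras] <- cm[ch, ]
      rgb[, , ch] <- plane
    }
  }
  if (legend) {
    rad <- max(8L, round(min(nz, nx) * 0.06))
    ci <- nz - rad - 2L; cj <- nx - rad - 2L
    for (di in -rad:rad) for (dj in -rad:rad) {
      rr <- sqrt(di^2 + dj^2)
      if (rr > rad) next
      hue <- (atan2(di, dj) / (2 * pi)) %% 1
      cm <- grDevices::col2rgb(grDevices::hsv(hue, min(1, rr / rad), 1)) / 255
      rgb[ci + di, cj + dj, ] <- cm
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
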