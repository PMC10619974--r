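# Serialization: spatiotemporal blocks and trajectory sets in R's native
# serialization (a portable self-describing container), images as 32-bit
# float TIFF with 8-bit dB-compressed PNG previews, localizations as CSV,
# metrics as JSON.

#' Write / read a spatiotemporal block
#'
#' The container stores the data array together with its attributes
#' (`pixel_pitch`, `frame_rate`, `kind`).
#'
#' @param block an `st_block`.
#' @param path file path (`.rds`).
#' @return `write_block` returns `path` invisibly; `read_block` the block.
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "st_block"))
  saveRDS(block, path)
  invisible(path)
}

#' @rdname write_block
#' @export
read_block <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "st_block"))
  x
}

#' Export an intensity image as 32-bit float TIFF
#'
#' @param image numeric matrix (`power_doppler_image`, `ulm_image`,
#'   `cspd_image` or plain matrix).
#' @param path output path.
#' @param normalize scale to `[0, 1]` before writing.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, normalize = TRUE) {
  m <- image_matrix(image)
  if (normalize && max(m) > 0) m <- m / max(m)
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Export a dB-compressed 8-bit PNG preview
#'
#' Display-only log compression (see [log_compress()]); quantitative work
#' stays on the linear scale.
#'
#' @param image intensity image.
#' @param path output path.
#' @param dynamic_range dB span (default 70).
#' @return `path`, invisibly.
#' @export
write_png_preview <- function(image, path, dynamic_range = 70) {
  m <- log_compress(image_matrix(image), dynamic_range)
  grDevices::png(path, width = ncol(m), height = nrow(m))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

image_matrix <- function(image) {
  if (inherits(image, "power_doppler_image")) return(image$intensity)
  if (inherits(image, "cspd_image")) return(image$intensity)
  if (inherits(image, "ulm_image")) {
    return(if (!is.null(image$intensity)) image$intensity else image$counts)
  }
  stopifnot(is.matrix(image))
  image
}

#' Write localizations as CSV
#'
#' Columns: `frame`, `x_mm`, `z_mm`, `amplitude`.
#'
#' @param locs a `localization_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations_csv <- function(locs, path) {
  stopifnot(inherits(locs, "localization_set"))
  ev <- locs$events
  utils::write.csv(data.frame(frame = ev$frame, x_mm = ev$x, z_mm = ev$z,
                              amplitude = ev$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Save / load a fitted CS-PD model
#'
#' The checkpoint is self-describing: it stores the architecture spec, the
#' parameters, the normalization state and the training history.
#'
#' @param object a fitted [cspd()] model.
#' @param path file path (`.rds`).
#' @return `save_cspd` returns `path` invisibly; `load_cspd` the model.
#' @export
save_cspd <- function(object, path) {
  stopifnot(inherits(object, "cspd"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_cspd
#' @export
load_cspd <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "cspd"))
  x
}
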