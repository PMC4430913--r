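## File I/O: PNG images, keypoint CSVs, the volume container and a PLY
## point-cloud export of tracked models.

#' Read a grayscale image
#'
#' Reads PNG (8/16-bit); RGB images are converted by luminance
#' (0.299 R + 0.587 G + 0.114 B). Values are returned on the 0..255
#' scale as a numeric matrix `[row, col]`.
#'
#' @param path PNG file path.
#' @return numeric matrix.
#' @export
read_gray_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a * 255
}

#' Write a grayscale image as PNG
#' @param img numeric matrix on the 0..255 scale (clipped).
#' @param path output path.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Write control points as CSV
#' @param pts data.frame with columns `u`, `v`, `role`.
#' @param path output path.
#' @export
write_control_points <- function(pts, path) {
  utils::write.csv(pts, path, row.names = FALSE)
  invisible(path)
}

#' Write model keypoints as CSV
#' @param model an [artery_model()].
#' @param path output path.
#' @export
write_keypoints <- function(model, path) {
  kp <- model$keypoints
  kp$label <- model$label
  utils::write.csv(kp[, c("label", "role", "z", "y", "x")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Save / load the CTA volume container
#'
#' The container stores the raw integer array together with the rescale
#' slope/intercept and voxel spacing, mirroring the metadata a DICOM
#' series carries.
#'
#' @param vol a [cta_volume()].
#' @param path output path (`.rds`).
#' @export
write_cta_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cta_volume"))
  saveRDS(vol, path)
  invisible(path)
}

#' @rdname write_cta_volume
#' @return `read_cta_volume` returns the [cta_volume()].
#' @export
read_cta_volume <- function(path) {
  vol <- readRDS(path)
  cta_volume(vol$raw, vol$slope, vol$intercept, vol$spacing)
}

#' Export an artery model as an ASCII PLY point cloud
#'
#' One vertex per occupied voxel, in physical coordinates
#' (`(x, y, z) * spacing`), replacing interactive 3D rendering.
#'
#' @param model an [artery_model()].
#' @param path output path.
#' @param spacing `(dz, dy, dx)` mm.
#' @export
write_ply <- function(model, path, spacing = c(0.75, 0.4, 0.4)) {
  stopifnot(inherits(model, "artery_model"))
  w <- which(model$M, arr.ind = TRUE)  # (z, y, x)
  xyz <- cbind((w[, 3] - 1) * spacing[3], (w[, 2] - 1) * spacing[2],
               (w[, 1] - 1) * spacing[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(xyz)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(xyz, trim = TRUE), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
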