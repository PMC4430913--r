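## CTA preparation: Hounsfield conversion, anatomical HU regions, the lung
## removal mask and aorta detection on the initial axial slices.

#' Construct a CTA volume container
#'
#' @param raw integer/numeric array `[z, y, x]` of stored voxel values.
#' @param slope,intercept linear rescale parameters from the acquisition
#'   metadata (`HU = raw * slope + intercept`).
#' @param spacing `(dz, dy, dx)` voxel spacing in mm; axial slices are
#'   typically 0.75 mm apart.
#' @return object of class `cta_volume`.
#' @export
cta_volume <- function(raw, slope = 1, intercept = -1024,
                       spacing = c(0.75, 0.4, 0.4)) {
  if (!is.array(raw) || length(dim(raw)) != 3)
    stop("raw must be a 3D array [z, y, x]")
  if (dim(raw)[1] < 3) stop("need at least 3 slices")
  if (is.null(slope) || is.null(intercept))
    stop("missing slope/intercept rescale metadata")
  if (slope == 0) stop("slope must be nonzero")
  structure(list(raw = raw, slope = slope, intercept = intercept,
                 spacing = spacing), class = "cta_volume")
}

#' @export
print.cta_volume <- function(x, ...) {
  d <- dim(x$raw)
  cat(sprintf("<cta_volume> %d slices of %dx%d, slope=%g intercept=%g, spacing=%s mm\n",
              d[1], d[2], d[3], x$slope, x$intercept,
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Convert stored voxel values to Hounsfield units
#'
#' Applies the linear rescale `HU = raw * slope + intercept` elementwise
#' and clips to the working range `[-1100, +1100]`.
#'
#' @param vol a [cta_volume()].
#' @return list of class `hu_volume` with `hu` (numeric array `[z,y,x]`)
#'   and `spacing`.
#' @export
to_hounsfield <- function(vol) {
  stopifnot(inherits(vol, "cta_volume"))
  hu <- vol$raw * vol$slope + vol$intercept
  hu <- clamp(hu, -1100, 1100)
  structure(list(hu = hu, spacing = vol$spacing), class = "hu_volume")
}

#' Classify voxels into the four anatomical HU regions
#'
#' Region 1 (`HU <= -225`) holds air and pulmonary tissue; region 2
#' (`-225 < HU <= +30`) diaphragm/pericardium-type soft tissue; region 3
#' (`+30 < HU <= +390`) myocardium and uncontrasted arteries; region 4
#' (`+390 < HU <= +1000`) contrasted coronary arteries, aorta, ventricles
#' and bone. Values above +1000 are left unclassified (0). The printed
#' clinical bounds overlap at -226/-225; the half-open convention used
#' here makes the regions a strict partition.
#'
#' @param huv an `hu_volume` (or bare numeric array of HU values).
#' @return integer array of region ids in `{0, 1, 2, 3, 4}`.
#' @export
classify_regions <- function(huv) {
  hu <- if (inherits(huv, "hu_volume")) huv$hu else huv
  region <- array(0L, dim(hu))
  region[hu <= -225] <- 1L
  region[hu > -225 & hu <= 30] <- 2L
  region[hu > 30 & hu <= 390] <- 3L
  region[hu > 390 & hu <= 1000] <- 4L
  region
}

#' Build the per-slice lung removal mask
#'
#' For every axial slice the region-1 (air/lung) pixels are binarized and
#' their interior holes -- cross-sections of pulmonary vessels -- are
#' filled; the mask is the complement, so multiplying an image by it
#' removes lung tissue together with the pulmonary vessels embedded in it.
#'
#' @param huv an `hu_volume` (or numeric array of HU values).
#' @return logical array `[z, y, x]`; `TRUE` marks pixels to keep.
#' @export
build_lung_mask <- function(huv) {
  region <- classify_regions(huv)
  d <- dim(region)
  keep <- array(TRUE, d)
  for (z in seq_len(d[1])) {
    lung <- region[z, , ] == 1L
    if (!any(lung)) next
    keep[z, , ] <- !fill_holes(lung)
  }
  keep
}

## Circle Hough transform on a binary slice: votes of boundary pixels over
## ring templates of each candidate radius. Returns the best circle
## (center row/col 1-based, radius, score in 0..1) or NULL.
hough_best_circle <- function(mask, radii, min_score = 0.5) {
  if (!any(mask)) return(NULL)
  er <- mask
  er[-1, ] <- er[-1, ] & mask[-nrow(mask), ]
  er[-nrow(mask), ] <- er[-nrow(mask), ] & mask[-1, ]
  er[, -1] <- er[, -1] & mask[, -ncol(mask)]
  er[, -ncol(mask)] <- er[, -ncol(mask)] & mask[, -1]
  edge <- mask & !er
  ep <- which(edge, arr.ind = TRUE)
  if (nrow(ep) == 0) return(NULL)
  nr <- nrow(mask); nc <- ncol(mask)
  best <- NULL
  for (r in radii) {
    ## ring offsets at radius r
    th <- seq(0, 2 * pi, length.out = max(16L, ceiling(2 * pi * r)))
    offs <- unique(cbind(round(r * cos(th)), round(r * sin(th))))
    acc <- matrix(0L, nr, nc)
    for (k in seq_len(nrow(offs))) {
      cr <- ep[, 1] + offs[k, 1]; cc <- ep[, 2] + offs[k, 2]
      ok <- cr >= 1 & cr <= nr & cc >= 1 & cc <= nc
      if (any(ok)) {
        idx <- cbind(cr[ok], cc[ok])
        acc[idx] <- acc[idx] + 1L
      }
    }
    peak <- which.max(acc)
    score <- acc[peak] / nrow(offs)
    if (score >= min_score && (is.null(best) || score > best$score)) {
      pr <- (peak - 1L) %% nr + 1L
      pc <- (peak - 1L) %/% nr + 1L
      best <- list(row = pr, col = pc, radius = r, score = score)
    }
  }
  best
}

#' Segment the aorta on the initial axial slices
#'
#' Per slice: region-4 binarization, small-object removal, circle
#' detection by a Hough transform over the requested radius range, then
#' residual-noise removal and small-hole filling. Detected discs are
#' accumulated into a 3D occupancy model labeled `"Aorta"`.
#'
#' @param huv an `hu_volume`.
#' @param slices slice indices to scan (default: the initial 10% of the
#'   stack, at least 3 slices).
#' @param radius_range `c(min, max)` circle radius in pixels.
#' @param min_area components smaller than this are treated as noise.
#' @param min_score minimum fraction of the circle perimeter that must
#'   vote for a detection.
#' @return an [artery_model()] with label `"Aorta"`; empty (with a
#'   warning) if no circle is found in any requested slice.
#' @export
segment_aorta <- function(huv, slices = NULL, radius_range = c(8, 25),
                          min_area = 20L, min_score = 0.5) {
  stopifnot(inherits(huv, "hu_volume"))
  d <- dim(huv$hu)
  if (is.null(slices)) slices <- seq_len(max(3L, ceiling(0.1 * d[1])))
  if (any(slices < 1 | slices > d[1])) stop("slices outside volume")
  if (any(radius_range <= 0)) stop("radius_range must be positive")
  region <- classify_regions(huv)
  M <- array(FALSE, d)
  found <- FALSE
  radii <- seq(floor(radius_range[1]), ceiling(radius_range[2]))
  for (z in slices) {
    bin <- region[z, , ] == 4L
    if (!any(bin)) next
    lab <- label_components(bin)
    sizes <- tabulate(lab[lab > 0L])
    keepers <- which(sizes >= min_area)
    bin <- lab %in% keepers & lab > 0L
    dim(bin) <- dim(lab)
    if (!any(bin)) next
    circ <- hough_best_circle(bin, radii, min_score)
    if (is.null(circ)) next
    disc <- matrix(FALSE, d[2], d[3])
    rr <- outer(seq_len(d[2]) - circ$row, rep(1, d[3]))^2 +
      outer(rep(1, d[2]), seq_len(d[3]) - circ$col)^2
    disc[rr <= circ$radius^2] <- TRUE
    slice_mask <- fill_holes(disc & bin)
    M[z, , ] <- slice_mask
    found <- TRUE
  }
  if (!found) warning("no circular object found in the requested slices; empty aorta model")
  keypoints <- data.frame(role = character(0), z = integer(0),
                          y = integer(0), x = integer(0))
  artery_model("Aorta", M, keypoints)
}
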