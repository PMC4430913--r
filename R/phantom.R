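## Synthetic vascular phantoms for both modalities. These provide a fully
## known ground truth (vessel masks, centrelines, keypoints, the stenosis
## voxel and the exact projection geometry) so that every downstream stage
## can be tested without clinical data.

#' Specification of a 2D angiogram phantom
#'
#' @param image_size `c(rows, cols)`.
#' @param tree list of branches; each branch is a list with `poly`
#'   (m x 2 matrix of `(row, col)` vertices, 1-based) and `width`
#'   (vessel width in pixels, `>= 1`).
#' @param vessel_intensity,background_intensity grey levels in 0..255;
#'   vessels must be darker than background, as in clinical angiograms.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return object of class `phantom_spec_2d`.
#' @export
phantom_spec_2d <- function(image_size = c(128L, 128L), tree = list(),
                            vessel_intensity = 60, background_intensity = 200,
                            noise_sd = 0, seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8))
  if (vessel_intensity >= background_intensity)
    stop("vessel_intensity must be below background_intensity (dark vessels)")
  for (b in tree) {
    if (is.null(b$poly) || is.null(b$width) || b$width < 1)
      stop("each branch needs a poly matrix and width >= 1 px")
  }
  structure(list(image_size = as.integer(image_size), tree = tree,
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec_2d")
}

#' Generate a synthetic 2D angiogram with ground truth
#'
#' Draws anti-aliased dark tubes over a noisy bright background. A pixel
#' belongs to the truth vessel mask iff its centre lies within
#' `width / 2` of the branch polyline (Euclidean rule).
#'
#' @param spec a [phantom_spec_2d()].
#' @return list with `image` (numeric matrix, 0..255) and `truth`, a list
#'   holding `vessel_mask`, `centreline_mask`, `label_image` (per-branch),
#'   `branch_points` and `end_points` (`(row, col)` matrices).
#' @export
make_angiogram_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec_2d"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  vessel_mask <- matrix(FALSE, nr, nc)
  centreline <- matrix(FALSE, nr, nc)
  label_img <- matrix(0L, nr, nc)
  ## opacity per pixel: 1 inside a tube, a ramp strictly below 0.5 in the
  ## half-pixel anti-aliasing band outside, so thresholding a noise-free
  ## phantom at the intensity midpoint reproduces vessel_mask exactly
  alpha <- matrix(0, nr, nc)
  for (bi in seq_along(spec$tree)) {
    b <- spec$tree[[bi]]
    poly <- b$poly
    if (any(poly[, 1] < 1 | poly[, 1] > nr | poly[, 2] < 1 | poly[, 2] > nc))
      stop("branch ", bi, " polyline lies outside the image")
    r <- b$width / 2
    d <- polyline_distance(nr, nc, poly, r)
    inside <- d <= r
    vessel_mask <- vessel_mask | inside
    ba <- ifelse(inside, 1, clamp(r + 0.5 - d, 0, 0.499))
    alpha <- pmax(alpha, ba)
    cl <- raster_polyline(poly)
    centreline[cl] <- TRUE
    lab_new <- inside & label_img == 0L
    label_img[lab_new] <- bi
  }
  img <- spec$background_intensity +
    alpha * (spec$vessel_intensity - spec$background_intensity)
  ## keypoints from tree topology: a polyline endpoint lying on another
  ## branch is a branch (bifurcation) point, otherwise an end point
  branch_pts <- NULL; end_pts <- NULL
  for (bi in seq_along(spec$tree)) {
    poly <- spec$tree[[bi]]$poly
    for (pt in list(poly[1, ], poly[nrow(poly), ])) {
      on_other <- FALSE
      for (bj in seq_along(spec$tree)) {
        if (bj == bi) next
        dj <- polyline_distance(nr, nc,
                                spec$tree[[bj]]$poly, 2)[pt[1], pt[2]]
        if (is.finite(dj) && dj <= 1.5) { on_other <- TRUE; break }
      }
      if (on_other) branch_pts <- rbind(branch_pts, pt)
      else end_pts <- rbind(end_pts, pt)
    }
  }
  img <- with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    else img
  })
  img <- clamp(img, 0, 255)
  list(image = img,
       truth = list(vessel_mask = vessel_mask, centreline_mask = centreline,
                    label_image = label_img,
                    branch_points = branch_pts, end_points = end_pts))
}

#' Specification of a 3D CTA phantom
#'
#' The volume emulates the tissue classes seen in cardiac CTA: air
#' background, lung fields, a soft-tissue body, myocardium-range tissue, a
#' contrasted aortic cylinder and contrast-filled coronary tubes (with an
#' optional stenotic narrowing and unlabeled side branches).
#'
#' @param volume_size `c(nz, ny, nx)` voxels.
#' @param tissue_hu named list of HU values for `air`, `lung`, `soft`,
#'   `myocardial`, `contrast`, `aorta`. Contrast/aorta must lie in the
#'   contrasted-artery HU band (+391..+1000); lung in the air band.
#' @param body optional list `(center_yx, radius)`: soft-tissue cylinder
#'   spanning all slices. `NULL` for none.
#' @param lungs optional list of lung cylinders `(center_yx, radius,
#'   slices)`.
#' @param aorta optional list `(center_yx, radius, slices)` for the aortic
#'   cylinder.
#' @param artery_curves named list (names = labels, e.g. `"LAD"`); each a
#'   list with `points` (m x 3 matrix of `(x, y, z)` voxel coordinates,
#'   0-based) and `radius` (voxels; scalar or per-vertex).
#' @param stenosis optional list `(label, position, radius)`: narrow the
#'   labeled tube to `radius` around fractional arclength `position`
#'   (0..1); the narrowed radius must be below the parent radius.
#' @param branch_spec list of unlabeled side-branch tubes, same fields as
#'   an artery curve plus an implicit termination at the end of `points`.
#' @param noise_sd HU noise sd.
#' @param slope,intercept rescale pair used to encode raw values
#'   (`raw = (HU - intercept) / slope`).
#' @param spacing `(dz, dy, dx)` mm.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec_3d`.
#' @export
phantom_spec_3d <- function(volume_size = c(64L, 64L, 64L),
                            tissue_hu = list(air = -1000, lung = -800,
                                             soft = -60, myocardial = 200,
                                             contrast = 450, aorta = 500),
                            body = NULL, lungs = list(), aorta = NULL,
                            artery_curves = list(), stenosis = NULL,
                            branch_spec = list(), noise_sd = 0,
                            slope = 1, intercept = -1024,
                            spacing = c(0.75, 0.4, 0.4), seed = 1L) {
  stopifnot(length(volume_size) == 3, all(volume_size >= 4), slope != 0)
  for (nm in c("contrast", "aorta"))
    if (tissue_hu[[nm]] < 391 || tissue_hu[[nm]] > 1000)
      stop(nm, " HU must lie in the contrasted band [+391, +1000]")
  if (tissue_hu$lung > -225)
    stop("lung HU must lie in the air band (<= -225)")
  if (!is.null(stenosis)) {
    parent <- artery_curves[[stenosis$label]]
    if (is.null(parent)) stop("stenosis label not among artery_curves")
    if (stenosis$radius >= min(parent$radius))
      stop("stenotic radius must be below the parent radius")
  }
  structure(list(volume_size = as.integer(volume_size), tissue_hu = tissue_hu,
                 body = body, lungs = lungs, aorta = aorta,
                 artery_curves = artery_curves, stenosis = stenosis,
                 branch_spec = branch_spec, noise_sd = noise_sd,
                 slope = slope, intercept = intercept, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec_3d")
}

## Rasterize a tube: voxels whose centre is within radius of the 3D
## polyline, clipped to the curve's z-range (flat axial end caps, so a
## tube spanning slices z0..z1 occupies exactly those slices).
## `points` are 0-based (x, y, z); returns logical [z, y, x].
rasterize_tube <- function(dim_zyx, points, radius) {
  zclip <- range(points[, 3])
  nz <- dim_zyx[1]; ny <- dim_zyx[2]; nx <- dim_zyx[3]
  vox <- array(FALSE, dim_zyx)
  radius <- rep_len(radius, nrow(points))
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    r0 <- radius[i]; r1 <- radius[i + 1L]
    rmax <- max(r0, r1)
    xs <- max(1L, floor(min(a[1], b[1]) - rmax)):min(nx, ceiling(max(a[1], b[1]) + rmax) + 1L)
    ys <- max(1L, floor(min(a[2], b[2]) - rmax)):min(ny, ceiling(max(a[2], b[2]) + rmax) + 1L)
    zs <- max(1L, floor(min(a[3], b[3]) - rmax)):min(nz, ceiling(max(a[3], b[3]) + rmax) + 1L)
    ## voxel index k corresponds to coordinate k-1
    gx <- xs - 1; gy <- ys - 1; gz <- zs - 1
    ab <- b - a; len2 <- sum(ab^2)
    px <- array(rep(gx, each = length(gz) * length(gy)),
                c(length(gz), length(gy), length(gx)))
    py <- array(rep(rep(gy, each = length(gz)), times = length(gx)),
                c(length(gz), length(gy), length(gx)))
    pz <- array(rep(gz, times = length(gy) * length(gx)),
                c(length(gz), length(gy), length(gx)))
    if (len2 == 0) {
      t <- 0
      dist2 <- (px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2
      rr <- r0
    } else {
      t <- clamp(((px - a[1]) * ab[1] + (py - a[2]) * ab[2] +
                    (pz - a[3]) * ab[3]) / len2, 0, 1)
      dist2 <- (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
        (pz - (a[3] + t * ab[3]))^2
      rr <- r0 + t * (r1 - r0)
    }
    inside <- dist2 <= rr^2 & pz >= zclip[1] - 1e-9 & pz <= zclip[2] + 1e-9
    vox[zs, ys, xs] <- vox[zs, ys, xs] | inside
  }
  vox
}

## Cumulative arclength parametrisation of a 3D polyline.
polyline_arclength <- function(points) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

## Point at fractional arclength s (0..1) along a polyline.
polyline_point_at <- function(points, s) {
  arc <- polyline_arclength(points)
  target <- s * arc[length(arc)]
  i <- max(which(arc <= target + 1e-12))
  if (i >= nrow(points)) return(points[nrow(points), ])
  t <- (target - arc[i]) / (arc[i + 1] - arc[i])
  points[i, ] + t * (points[i + 1, ] - points[i, ])
}

## Resample a polyline with per-vertex radii honouring a stenosis: radius
## dips to sten$radius inside a window of +-2*parent_radius arclength
## around the stenosis position.
stenotic_radii <- function(points, base_radius, sten) {
  arc <- polyline_arclength(points)
  total <- arc[length(arc)]
  ## densify so the narrowing is well sampled
  n <- max(64L, nrow(points) * 8L)
  s <- seq(0, 1, length.out = n)
  dense <- t(vapply(s, function(si) polyline_point_at(points, si),
                    numeric(3)))
  r <- rep(base_radius, n)
  half <- max(2 * base_radius, 2) / total  # half-window in fractional arc
  w <- abs(s - sten$position) <= half
  r[w] <- sten$radius
  list(points = dense, radius = r)
}

#' Generate a synthetic CTA volume with ground truth
#'
#' Raw voxel values encode HU through the inverse rescale relation
#' `raw = (HU - intercept) / slope`. Artery voxels take the contrast HU
#' value; truth masks follow the tube rasterization rule exactly.
#'
#' @param spec a [phantom_spec_3d()].
#' @return list with `volume` (a `cta_volume`: `raw` int array `[z,y,x]`,
#'   `slope`, `intercept`, `spacing`) and `truth` (per-label masks,
#'   keypoints, `stenosis_voxel` 1-based `(z, y, x)`, aorta/lung masks and
#'   `branch_masks` for the unlabeled side branches).
#' @export
make_cta_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec_3d"))
  dzyx <- spec$volume_size
  nz <- dzyx[1]; ny <- dzyx[2]; nx <- dzyx[3]
  hu <- array(spec$tissue_hu$air, dzyx)
  circle_xy <- function(center_yx, radius) {
    outer(seq_len(ny) - 1 - center_yx[1], rep(1, nx))^2 +
      outer(rep(1, ny), seq_len(nx) - 1 - center_yx[2])^2 <= radius^2
  }
  if (!is.null(spec$body)) {
    disk <- circle_xy(spec$body$center_yx, spec$body$radius)
    for (z in seq_len(nz)) hu[z, , ][disk] <- spec$tissue_hu$soft
  }
  for (lg in spec$lungs) {
    disk <- circle_xy(lg$center_yx, lg$radius)
    for (z in lg$slices) hu[z, , ][disk] <- spec$tissue_hu$lung
  }
  my <- if (is.null(spec$body)) NULL else spec$body$myocardium
  if (!is.null(my)) {
    ## optional myocardial cylinder nested in the body
    disk <- circle_xy(my$center_yx, my$radius)
    for (z in my$slices) hu[z, , ][disk] <- spec$tissue_hu$myocardial
  }
  aorta_mask <- array(FALSE, dzyx)
  if (!is.null(spec$aorta)) {
    disk <- circle_xy(spec$aorta$center_yx, spec$aorta$radius)
    for (z in spec$aorta$slices) aorta_mask[z, , ][disk] <- TRUE
    hu[aorta_mask] <- spec$tissue_hu$aorta
  }
  ## unlabeled side branches first (distractors), then labeled arteries
  branch_masks <- list()
  for (bi in seq_along(spec$branch_spec)) {
    b <- spec$branch_spec[[bi]]
    bm <- rasterize_tube(dzyx, b$points, b$radius)
    branch_masks[[bi]] <- bm
    hu[bm] <- spec$tissue_hu$contrast
  }
  label_masks <- list()
  keypoints <- list()
  for (nm in names(spec$artery_curves)) {
    cv <- spec$artery_curves[[nm]]
    pts <- cv$points; rad <- cv$radius
    if (!is.null(spec$stenosis) && identical(spec$stenosis$label, nm)) {
      sr <- stenotic_radii(pts, rad[1], spec$stenosis)
      pts <- sr$points; rad <- sr$radius
    }
    m <- rasterize_tube(dzyx, pts, rad)
    label_masks[[nm]] <- m
    hu[m] <- spec$tissue_hu$contrast
    ## keypoints: slice centroids at the first and last occupied slice
    zs <- which(apply(m, 1, any))
    cen <- function(z) {
      w <- which(m[z, , ], arr.ind = TRUE)
      c(z = z, y = round(mean(w[, 1])), x = round(mean(w[, 2])))
    }
    keypoints[[nm]] <- data.frame(
      role = c("start", "end"),
      rbind(cen(zs[1]), cen(zs[length(zs)])))
  }
  ## refuse ambiguous truth: two labels claiming one voxel
  if (length(label_masks) > 1) {
    nms <- names(label_masks)
    for (i in seq_along(nms)[-1]) for (j in seq_len(i - 1)) {
      if (any(label_masks[[nms[i]]] & label_masks[[nms[j]]]))
        stop("artery labels ", nms[j], " and ", nms[i],
             " overlap at a voxel; ambiguous truth")
    }
  }
  stenosis_voxel <- NULL
  if (!is.null(spec$stenosis)) {
    p <- polyline_point_at(spec$artery_curves[[spec$stenosis$label]]$points,
                           spec$stenosis$position)
    stenosis_voxel <- c(z = unname(round(p[3])) + 1L,
                        y = unname(round(p[2])) + 1L,
                        x = unname(round(p[1])) + 1L)
  }
  hu <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) hu + array(stats::rnorm(length(hu), 0,
                                                   spec$noise_sd), dzyx)
    else hu
  })
  raw <- round((hu - spec$intercept) / spec$slope)
  volume <- cta_volume(raw, spec$slope, spec$intercept, spec$spacing)
  list(volume = volume,
       truth = list(label_masks = label_masks, keypoints = keypoints,
                    stenosis_voxel = stenosis_voxel,
                    aorta_mask = aorta_mask, branch_masks = branch_masks,
                    volume_size = dzyx, view_to_image = NULL))
}

#' Project a 3D phantom to a synthetic angiogram
#'
#' Rotates the union of the truth artery (and side-branch) masks by the
#' given view angles about the volume centre, projects orthographically
#' along the viewing axis and renders dark vessels on a bright background.
#' The exact projection geometry (`view_to_image`) is recorded so that a
#' paired registration test knows the true mapping.
#'
#' @param truth the `truth` element of [make_cta_phantom()].
#' @param angles a [view_angles()].
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param labels which truth labels to draw (default all labeled arteries
#'   plus side branches).
#' @param vessel_intensity,background_intensity grey levels (dark on
#'   bright).
#' @param seed RNG seed for the noise.
#' @return list with `image`, `truth2d` (projected vessel mask and the
#'   pixel sets per source), and `view_to_image` (angles + canvas
#'   offsets).
#' @export
project_phantom <- function(truth, angles, noise_sd = 0, labels = NULL,
                            vessel_intensity = 60,
                            background_intensity = 200, seed = 1L) {
  stopifnot(inherits(angles, "view_angles"))
  dzyx <- truth$volume_size
  if (is.null(labels)) labels <- names(truth$label_masks)
  acc <- array(FALSE, dzyx)
  for (nm in labels) acc <- acc | truth$label_masks[[nm]]
  for (bm in truth$branch_masks) acc <- acc | bm
  geom <- projection_geometry(dzyx, angles)
  pix <- project_voxels(which(acc), dzyx, geom)
  nr <- geom$nrow; nc <- geom$ncol
  img <- matrix(background_intensity, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(pix$row, pix$col)] <- TRUE
  img[mask] <- vessel_intensity
  img <- with_seed(seed, {
    if (noise_sd > 0) img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    else img
  })
  img <- clamp(img, 0, 255)
  sten_uv <- NULL
  if (!is.null(truth$stenosis_voxel)) {
    sv <- truth$stenosis_voxel
    uvd <- project_points(cbind(sv["x"] - 1, sv["y"] - 1, sv["z"] - 1), geom)
    ## in the angiogram's own pixel frame (canvas origin at (0, 0))
    sten_uv <- c(u = uvd[1, 1] - geom$u0, v = uvd[1, 2] - geom$v0)
  }
  list(image = img,
       truth2d = list(vessel_mask = mask, stenosis_uv = sten_uv),
       view_to_image = geom)
}
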