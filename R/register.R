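## 2D/3D registration: rotate + orthographically project the tracked 3D
## artery, fit a landmark-normalized affine transform between the two
## modalities' control points, warp the angiogram artery into the
## projection plane, localize the marked stenosis on the CTA artery by
## the centreline length ratio, and back-project it to the 3D volume.

#' View angles for the CTA rotation
#'
#' Rotations are applied about the volume centre in x, then y, then z
#' order, right-handed, in degrees.
#'
#' @param thx,thy,thz rotation angles in degrees.
#' @return object of class `view_angles`.
#' @export
view_angles <- function(thx = 0, thy = 0, thz = 0) {
  stopifnot(is.finite(thx), is.finite(thy), is.finite(thz))
  structure(list(thx = thx, thy = thy, thz = thz), class = "view_angles")
}

rotation_matrix <- function(angles) {
  r <- function(a) a * pi / 180
  cx <- cos(r(angles$thx)); sx <- sin(r(angles$thx))
  cy <- cos(r(angles$thy)); sy <- sin(r(angles$thy))
  cz <- cos(r(angles$thz)); sz <- sin(r(angles$thz))
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

## Shared projection geometry for a volume of dim [nz, ny, nx]: rotation
## about the volume centre, orthographic projection along the rotated z
## axis, and a canvas covering the projected volume bounding box (so a
## projected model and a projected phantom share one pixel frame).
projection_geometry <- function(dim_zyx, angles) {
  nz <- dim_zyx[1]; ny <- dim_zyx[2]; nx <- dim_zyx[3]
  R <- rotation_matrix(angles)
  center <- c((nx - 1) / 2, (ny - 1) / 2, (nz - 1) / 2)
  corners <- as.matrix(expand.grid(x = c(0, nx - 1), y = c(0, ny - 1),
                                   z = c(0, nz - 1)))
  rot <- sweep(corners, 2, center) %*% t(R)
  rot <- sweep(rot, 2, center, "+")
  u0 <- floor(min(rot[, 1])); u1 <- ceiling(max(rot[, 1]))
  v0 <- floor(min(rot[, 2])); v1 <- ceiling(max(rot[, 2]))
  list(R = R, center = center, angles = angles, dim_zyx = dim_zyx,
       u0 = u0, v0 = v0, nrow = v1 - v0 + 1L, ncol = u1 - u0 + 1L)
}

## Project 0-based (x, y, z) coordinate rows; returns (u, v, depth).
project_points <- function(xyz, geom) {
  rot <- sweep(as.matrix(xyz), 2, geom$center) %*% t(geom$R)
  rot <- sweep(rot, 2, geom$center, "+")
  cbind(u = round(rot[, 1]), v = round(rot[, 2]), depth = rot[, 3])
}

## Project linear voxel indices of a [z,y,x] array; returns data.frame of
## canvas (row, col), depth and source voxel indices, one entry per pixel
## keeping the viewer-nearest (smallest depth) voxel.
project_voxels <- function(vox_idx, dim_zyx, geom) {
  if (length(vox_idx) == 0) stop("empty model: nothing to project")
  aidx <- arrayInd(vox_idx, dim_zyx)   # (z, y, x)
  xyz <- cbind(aidx[, 3] - 1, aidx[, 2] - 1, aidx[, 1] - 1)
  uvd <- project_points(xyz, geom)
  row <- uvd[, 2] - geom$v0 + 1L
  col <- uvd[, 1] - geom$u0 + 1L
  ord <- order(uvd[, 3])               # nearest first
  pixkey <- row + (col - 1L) * geom$nrow
  first <- ord[!duplicated(pixkey[ord])]
  data.frame(row = row[first], col = col[first], depth = uvd[first, 3],
             z = aidx[first, 1], y = aidx[first, 2], x = aidx[first, 3])
}

#' Rotate an artery model and project it to the image plane
#'
#' Voxel centres are rotated by the view angles about the volume centre
#' and projected orthographically along the viewing axis to pixel
#' coordinates `(u, v) = (round(x'), round(y'))`. When several voxels
#' land on one pixel the viewer-nearest voxel provides the pixel's
#' provenance. Keypoints are projected identically, preserving roles and
#' order, into the candidate control points `P_C`.
#'
#' @param model an [artery_model()].
#' @param angles a [view_angles()].
#' @param geom optional precomputed projection geometry (to share a
#'   canvas across projections).
#' @return object of class `projected_artery`: `mask` (logical canvas),
#'   `back_z`, `back_y`, `back_x` (provenance voxel indices, NA off the
#'   artery), `points` (data.frame `u`, `v`, `role`), `u0`, `v0` (pixel
#'   coordinate of canvas element [1,1]), `geom`.
#' @export
rotate_and_project <- function(model, angles, geom = NULL) {
  stopifnot(inherits(model, "artery_model"))
  if (!any(model$M)) stop("empty model: nothing to project")
  if (is.null(geom)) geom <- projection_geometry(dim(model$M), angles)
  pix <- project_voxels(which(model$M), dim(model$M), geom)
  mask <- matrix(FALSE, geom$nrow, geom$ncol)
  back_z <- back_y <- back_x <- matrix(NA_integer_, geom$nrow, geom$ncol)
  ok <- pix$row >= 1 & pix$row <= geom$nrow & pix$col >= 1 & pix$col <= geom$ncol
  idx <- cbind(pix$row[ok], pix$col[ok])
  mask[idx] <- TRUE
  back_z[idx] <- pix$z[ok]; back_y[idx] <- pix$y[ok]; back_x[idx] <- pix$x[ok]
  pts <- NULL
  if (nrow(model$keypoints) > 0) {
    kp <- model$keypoints
    uvd <- project_points(cbind(kp$x - 1, kp$y - 1, kp$z - 1), geom)
    pts <- data.frame(u = uvd[, 1], v = uvd[, 2], role = kp$role)
  }
  structure(list(mask = mask, back_z = back_z, back_y = back_y,
                 back_x = back_x, points = pts,
                 u0 = geom$u0, v0 = geom$v0, geom = geom,
                 label = model$label),
            class = "projected_artery")
}

#' Normalize control points to zero centroid and RMS distance sqrt(2)
#'
#' Translates the point set so its centroid sits at the origin and
#' scales it so the root-mean-square distance from the origin equals
#' `sqrt(2)` (`S = sqrt(2n) / sqrt(sum ||C_i - c||^2)`). The companion
#' 3x3 matrix `N` maps normalized coordinates back to raw coordinates
#' under the row-vector convention `[u v 1] %*% N`.
#'
#' @param pts n x 2 matrix (or data.frame) of `(u, v)` coordinates,
#'   `n >= 3`.
#' @return list with `normalized` (n x 2 matrix), `centroid`, `scale`
#'   (S), and `N`.
#' @export
normalize_points <- function(pts) {
  pts <- as.matrix(pts[, 1:2])
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 control points")
  cen <- colMeans(pts)
  ct <- sweep(pts, 2, cen)
  ss <- sum(ct^2)
  if (ss < 1e-20) stop("zero spread: scale factor undefined")
  S <- sqrt(2 * n) / sqrt(ss)
  N <- matrix(c(1 / S, 0, 0,
                0, 1 / S, 0,
                cen[1], cen[2], 1), 3, 3, byrow = TRUE)
  list(normalized = ct * S, centroid = cen, scale = S, N = N)
}

#' Estimate the de-normalized affine transform from correspondences
#'
#' Both point sets are normalized; the normalized affine is solved from
#' `[C~ 1] %*% T~' = C~'` (exact inverse at n = 3, least squares for
#' n > 3) and de-normalized as `T = N^-1 %*% T~ %*% N'`. Under the
#' row-vector convention the result maps raw source-frame (projected
#' CTA) coordinates to raw destination-frame (angiogram) coordinates:
#' `[u v 1] %*% T`.
#'
#' @param src n x 2 matrix of source control points (from `P_C`).
#' @param dst n x 2 matrix of corresponding destination points (from
#'   `P_A`); `n >= 3`, source points not collinear.
#' @return 3 x 3 affine matrix of class `affine2d` (last column
#'   `(0, 0, 1)`).
#' @export
estimate_affine <- function(src, dst) {
  src <- as.matrix(src[, 1:2]); dst <- as.matrix(dst[, 1:2])
  if (nrow(src) != nrow(dst)) stop("correspondence sets differ in size")
  if (nrow(src) < 3) stop("need at least 3 correspondences")
  ns <- normalize_points(src)
  nd <- normalize_points(dst)
  A <- cbind(ns$normalized, 1)
  rk <- qr(A)$rank
  if (rk < 3) stop("collinear source points: affine transform is singular")
  Tp <- qr.solve(A, nd$normalized)   # 3 x 2
  Tt <- cbind(Tp, c(0, 0, 1))
  Tm <- solve(ns$N) %*% Tt %*% nd$N
  structure(Tm, class = c("affine2d", "matrix"))
}

#' Apply an affine transform to points
#' @param pts n x 2 matrix of `(u, v)` points.
#' @param T a 3 x 3 `affine2d` matrix (row-vector convention).
#' @return n x 2 matrix of transformed points.
#' @export
apply_affine <- function(pts, T) {
  pts <- as.matrix(pts)
  if (is.null(dim(pts)) || ncol(pts) != 2) pts <- matrix(pts, ncol = 2)
  out <- cbind(pts, 1) %*% unclass(T)
  out[, 1:2, drop = FALSE]
}

#' Register the angiogram artery onto the projected CTA plane
#'
#' The angiogram mask is resampled into the projection (CTA-frame)
#' canvas by inverse warping: each output pixel `p` takes the angiogram
#' value at `[p 1] %*% T` (nearest neighbour). The result holds both
#' arteries as separate channels of one plane.
#'
#' @param angio_mask logical matrix: the labeled angiogram artery
#'   (pixel `(u, v) = (col-1, row-1)`).
#' @param proj a [rotate_and_project()] result.
#' @param T the `affine2d` from [estimate_affine()] (CTA frame to
#'   angiogram frame).
#' @return object of class `registered_plane`: `angio` and `cta`
#'   (logical canvases), `u0`, `v0`, `T`.
#' @export
register_artery <- function(angio_mask, proj, T) {
  assert_mask(angio_mask, "angio_mask")
  stopifnot(inherits(proj, "projected_artery"))
  det2 <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  if (abs(det2) < 1e-12) stop("non-invertible transform")
  nr <- nrow(proj$mask); nc <- ncol(proj$mask)
  ## raw (u, v) of every canvas pixel
  u <- rep(seq_len(nc) - 1L + proj$u0, each = nr)
  v <- rep(seq_len(nr) - 1L + proj$v0, times = nc)
  uv <- apply_affine(cbind(u, v), T)
  cc <- round(uv[, 1]) + 1L
  rr <- round(uv[, 2]) + 1L
  ok <- rr >= 1 & rr <= nrow(angio_mask) & cc >= 1 & cc <= ncol(angio_mask)
  warped <- matrix(FALSE, nr, nc)
  warped[ok] <- angio_mask[cbind(rr[ok], cc[ok])]
  structure(list(angio = warped, cta = proj$mask,
                 u0 = proj$u0, v0 = proj$v0, T = T),
            class = "registered_plane")
}

## nearest TRUE pixel of `mask` to canvas point (row, col); NULL if none
nearest_mask_pixel <- function(mask, row, col) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  dd <- (w[, 1] - row)^2 + (w[, 2] - col)^2
  i <- which.min(dd)
  list(row = unname(w[i, 1]), col = unname(w[i, 2]),
       dist = sqrt(unname(dd[i])))
}

#' Localize the marked stenosis on the CTA artery
#'
#' The stenosis marked on the angiogram is mapped into the registration
#' plane through the inverse transform. If it lands within `tol_px` of
#' the CTA artery it is snapped to the nearest CTA artery pixel.
#' Otherwise both channels are thinned, the intersection points of the
#' two centrelines are found, the bracketing pair `p_k` / `p_l` around
#' the stenosis is taken, the geodesic lengths `l1'`, `l2'` (angiogram
#' centreline) and `L` (CTA centreline) are measured, the proportional
#' lengths `l1 = l1' L / (l1' + l2')` and `l2 = l2' L / (l1' + l2')`
#' are computed (so `l1 + l2 = L`), and the stenosis is placed `l1`
#' along the CTA centreline from `p_k`.
#'
#' @param ireg a [register_artery()] result.
#' @param stenosis_uv `(u, v)` of the marked stenosis in the angiogram
#'   frame.
#' @param T the transform used for the registration.
#' @param tol_px snap tolerance in pixels (default 2).
#' @return object of class `stenosis_localization`: the mapped point,
#'   the snapped CTA pixel (canvas row/col and raw `(u, v)`), the
#'   lengths `l1p`, `l2p`, `L`, `l1`, `l2` (NA when the direct
#'   intersection branch was used) and the method used.
#' @export
localize_stenosis <- function(ireg, stenosis_uv, T, tol_px = 2) {
  stopifnot(inherits(ireg, "registered_plane"))
  sm <- apply_affine(matrix(stenosis_uv[1:2], 1), solve(unclass(T)))
  srow <- sm[1, 2] - ireg$v0 + 1
  scol <- sm[1, 1] - ireg$u0 + 1
  near_a <- nearest_mask_pixel(ireg$angio, srow, scol)
  if (is.null(near_a) || near_a$dist > max(tol_px, 2))
    stop("stenosis point does not lie on the registered angiogram artery")
  near_c <- nearest_mask_pixel(ireg$cta, srow, scol)
  if (is.null(near_c)) stop("empty CTA artery channel")
  if (near_c$dist <= tol_px) {
    ## on the CTA artery: snap onto its centreline (the localization is
    ## reported on the vessel axis, as in the ratio branch)
    skel_c0 <- thin_mask(ireg$cta)
    near_s <- nearest_mask_pixel(skel_c0, srow, scol)
    if (!is.null(near_s)) near_c <- near_s
    loc <- list(stenosis_uv = stenosis_uv, mapped = c(sm[1, 1], sm[1, 2]),
                row = near_c$row, col = near_c$col,
                uv = c(near_c$col - 1 + ireg$u0, near_c$row - 1 + ireg$v0),
                l1p = NA_real_, l2p = NA_real_, L = NA_real_,
                l1 = NA_real_, l2 = NA_real_, method = "intersection")
    class(loc) <- "stenosis_localization"
    return(loc)
  }
  ## ratio method on the thinned channels
  skel_a <- thin_mask(ireg$angio)
  skel_c <- thin_mask(ireg$cta)
  inter <- skel_a & dilate_disc(skel_c, 1.5)
  if (!any(inter))
    stop("the two centrelines do not intersect; refine the control points")
  ilab <- label_components(inter)
  k <- max(ilab)
  if (k < 2)
    stop("fewer than two centreline intersection points; refine the control points")
  icen <- t(vapply(seq_len(k), function(i) {
    w <- which(ilab == i, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  pix_a <- mask_which(skel_a)
  ## snap stenosis and intersections to the angiogram centreline
  snap_to <- function(pix, row, col) {
    dd <- (pix[, 1] - row)^2 + (pix[, 2] - col)^2
    which.min(dd)
  }
  s_id <- snap_to(pix_a, srow, scol)
  g_a <- skeleton_geodesic(pix_a, s_id)
  int_ids <- vapply(seq_len(k), function(i)
    snap_to(pix_a, icen[i, 1], icen[i, 2]), integer(1))
  dists <- g_a$dist[int_ids]
  fin <- which(is.finite(dists))
  if (length(fin) < 2)
    stop("fewer than two intersection points reachable along the centreline")
  ## bracketing pair: nearest intersection, then the nearest one on the
  ## other side (the geodesic between them passes through the stenosis)
  ordf <- fin[order(dists[fin])]
  pk_i <- ordf[1]
  pl_i <- NA_integer_
  for (cand in ordf[-1]) {
    g_k <- skeleton_geodesic(pix_a, int_ids[pk_i])
    d_kl <- g_k$dist[int_ids[cand]]
    if (is.finite(d_kl) &&
        abs(d_kl - (dists[pk_i] + dists[cand])) <= 2.5) {
      pl_i <- cand; break
    }
  }
  if (is.na(pl_i)) pl_i <- ordf[2]
  l1p <- dists[pk_i]; l2p <- dists[pl_i]
  ## CTA centreline lengths between the snapped intersection points
  pix_c <- mask_which(skel_c)
  pk_c <- snap_to(pix_c, icen[pk_i, 1], icen[pk_i, 2])
  pl_c <- snap_to(pix_c, icen[pl_i, 1], icen[pl_i, 2])
  g_c <- skeleton_geodesic(pix_c, pk_c)
  L <- g_c$dist[pl_c]
  if (!is.finite(L))
    stop("CTA centreline is disconnected between the intersection points")
  prop <- stenosis_lengths(l1p, l2p, L)
  path <- geodesic_path(g_c$prev, pl_c)
  ## walk l1 from p_k along the CTA centreline
  acc <- g_c$dist[path]
  j <- which.min(abs(acc - prop$l1))
  loc <- list(stenosis_uv = stenosis_uv, mapped = c(sm[1, 1], sm[1, 2]),
              row = unname(pix_c[path[j], 1]),
              col = unname(pix_c[path[j], 2]),
              uv = unname(c(pix_c[path[j], 2] - 1 + ireg$u0,
                            pix_c[path[j], 1] - 1 + ireg$v0)),
              l1p = l1p, l2p = l2p, L = L, l1 = prop$l1, l2 = prop$l2,
              method = "ratio")
  class(loc) <- "stenosis_localization"
  loc
}

#' Proportional stenosis lengths on the CTA centreline
#'
#' Splits the CTA centreline length `L` between the bracketing
#' intersection points in the proportion of the angiogram-side lengths:
#' `l1 = l1' L / (l1' + l2')`, `l2 = l2' L / (l1' + l2')`, so that
#' `l1 + l2 = L` exactly.
#'
#' @param l1p,l2p angiogram centreline lengths from the stenosis to the
#'   bracketing points (`l1'`, `l2'`).
#' @param L CTA centreline length between the bracketing points.
#' @return list with `l1` and `l2`.
#' @export
stenosis_lengths <- function(l1p, l2p, L) {
  if (l1p < 0 || l2p < 0 || L < 0) stop("lengths must be non-negative")
  if (l1p + l2p == 0) stop("degenerate bracketing: l1' + l2' = 0")
  list(l1 = l1p * L / (l1p + l2p), l2 = l2p * L / (l1p + l2p))
}

#' Back-project a located stenosis pixel to the 3D volume
#'
#' Looks up the provenance voxel recorded during projection at the
#' located CTA pixel (searching a small neighbourhood when the exact
#' pixel carries none) and reports voxel indices and physical
#' coordinates.
#'
#' @param loc a [localize_stenosis()] result.
#' @param proj the [rotate_and_project()] result the localization refers
#'   to.
#' @param spacing `(dz, dy, dx)` mm.
#' @param snap_radius maximum pixel radius searched for provenance.
#' @return list with `voxel` (`(z, y, x)` 1-based indices) and `mm`
#'   (`(x, y, z)` physical coordinates).
#' @export
back_project <- function(loc, proj, spacing = c(0.75, 0.4, 0.4),
                         snap_radius = 2) {
  stopifnot(inherits(loc, "stenosis_localization"),
            inherits(proj, "projected_artery"))
  has_prov <- !is.na(proj$back_z)
  r0 <- loc$row; c0 <- loc$col
  if (r0 < 1 || r0 > nrow(has_prov) || c0 < 1 || c0 > ncol(has_prov) ||
      !has_prov[r0, c0]) {
    near <- nearest_mask_pixel(has_prov, r0, c0)
    if (is.null(near) || near$dist > snap_radius)
      stop("no provenance within the snap radius at the located pixel")
    r0 <- near$row; c0 <- near$col
  }
  vox <- c(z = proj$back_z[r0, c0], y = proj$back_y[r0, c0],
           x = proj$back_x[r0, c0])
  mm <- c(x = (vox[["x"]] - 1) * spacing[3],
          y = (vox[["y"]] - 1) * spacing[2],
          z = (vox[["z"]] - 1) * spacing[1])
  list(voxel = vox, mm = mm)
}
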