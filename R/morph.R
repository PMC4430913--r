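## Binary-morphology helpers shared by the angiogram and CTA modules.
## EBImage provides hole filling, distance maps and structuring-element
## dilation; 8-connected labeling and Zhang-Suen thinning are implemented
## here because the installed stack only labels 4-connected components and
## offers no 2D skeletonization.

#' Label 8-connected components of a binary mask
#'
#' Components are numbered 1..K in raster order of their first pixel;
#' background is 0. Diagonal contact joins components (8-connectivity),
#' matching the neighbourhood convention used for centreline analysis.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  ## 2x upsample; bridge diagonal pairs so 4-connected labeling of the
  ## upsampled image equals 8-connected labeling of the original.
  up <- matrix(0L, 2L * nr, 2L * nc)
  ri <- rep(seq_len(nr), times = nc)
  ci <- rep(seq_len(nc), each = nr)
  on <- which(mask)
  for (dr in c(0L, 1L)) for (dc in c(0L, 1L))
    up[cbind(2L * ri[on] - 1L + dr, 2L * ci[on] - 1L + dc)] <- 1L
  ## diagonal pair (i,j)-(i+1,j+1): bridge at (2i, 2j+1)
  d1 <- mask[-nr, -nc] & mask[-1, -1]
  if (any(d1)) {
    w <- which(d1, arr.ind = TRUE)
    up[cbind(2L * w[, 1], 2L * w[, 2] + 1L)] <- 1L
  }
  ## anti-diagonal pair (i,j)-(i+1,j-1): bridge at (2i+1, 2j-1)
  d2 <- mask[-nr, -1] & mask[-1, -nc]
  if (any(d2)) {
    w <- which(d2, arr.ind = TRUE)  # (i, j-1) index space
    up[cbind(2L * w[, 1] + 1L, 2L * w[, 2] + 1L)] <- 1L
  }
  lab_up <- EBImage::bwlabel(up)
  lab <- matrix(0L, nr, nc)
  lab[on] <- as.integer(lab_up[cbind(2L * ri[on] - 1L, 2L * ci[on] - 1L)])
  ## renumber consecutively in raster order of first occurrence
  ids <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Fill interior holes of a binary mask
#' @param mask logical matrix.
#' @return logical matrix with background regions not connected to the
#'   border filled in.
#' @export
fill_holes <- function(mask) {
  assert_mask(mask)
  storage <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  matrix(EBImage::fillHull(storage) > 0, nrow(mask), ncol(mask))
}

#' Euclidean distance to the nearest background pixel
#'
#' Foreground pixels receive their Euclidean distance to the closest
#' `FALSE` pixel; background pixels receive 0.
#' @param mask logical matrix.
#' @return numeric matrix.
#' @export
distance_to_background <- function(mask) {
  assert_mask(mask)
  if (!any(!mask)) stop("mask has no background pixels")
  matrix(EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask))),
         nrow(mask), ncol(mask))
}

## Distance from every pixel to the nearest TRUE pixel of `targets`.
distance_to_targets <- function(targets) {
  if (!any(targets)) return(matrix(Inf, nrow(targets), ncol(targets)))
  inv <- !targets
  matrix(EBImage::distmap(matrix(as.numeric(inv), nrow(inv), ncol(inv))),
         nrow(inv), ncol(inv))
}

#' Dilate a binary mask with a disc structuring element
#' @param mask logical matrix.
#' @param radius disc radius in pixels (`>= 0`; 0 returns the input).
#' @return logical matrix.
#' @export
dilate_disc <- function(mask, radius) {
  assert_mask(mask)
  if (radius <= 0) return(mask)
  size <- 2L * as.integer(ceiling(radius)) + 1L
  brush <- make_disc(size, radius)
  matrix(EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                         brush) > 0, nrow(mask), ncol(mask))
}

## Disc brush by the pixel-centre-within-radius rule (consistent with the
## phantom rasterizer).
make_disc <- function(size, radius) {
  c0 <- (size + 1) / 2
  idx <- seq_len(size)
  outer(idx, idx, function(r, c) (r - c0)^2 + (c - c0)^2 <= radius^2) * 1
}

## Count of TRUE pixels in each 3x3 neighbourhood (centre included),
## zero-padded at the border: convolution with a 3x3 kernel of ones.
neighbor_count_3x3 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + pad[dr + seq_len(nr), dc + seq_len(nc)]
  out
}

## Number of FALSE -> TRUE transitions around the 8-neighbourhood circle
## of every pixel. A true branch point of a 1-px skeleton has >= 3; a
## diagonal staircase pixel (which can reach a 3x3 ones-count of 4) has 2.
transition_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  ## clockwise from north
  nb <- list(shift(mask, -1L, 0L), shift(mask, -1L, 1L),
             shift(mask, 0L, 1L), shift(mask, 1L, 1L),
             shift(mask, 1L, 0L), shift(mask, 1L, -1L),
             shift(mask, 0L, -1L), shift(mask, -1L, -1L))
  tc <- matrix(0L, nr, nc)
  for (k in seq_len(8)) {
    nxt <- if (k == 8L) 1L else k + 1L
    tc <- tc + (!nb[[k]] & nb[[nxt]])
  }
  tc
}

#' Morphological thinning (Zhang-Suen)
#'
#' Iteratively peels a binary mask down to an 8-connected, 1-pixel-wide
#' skeleton while preserving connectivity and line ends.
#'
#' @param mask logical matrix.
#' @return logical matrix containing the skeleton.
#' @export
thin_mask <- function(mask) {
  assert_mask(mask)
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      ## neighbours clockwise from north: P2..P9
      p2 <- shift(m, -1L,  0L); p3 <- shift(m, -1L,  1L)
      p4 <- shift(m,  0L,  1L); p5 <- shift(m,  1L,  1L)
      p6 <- shift(m,  1L,  0L); p7 <- shift(m,  1L, -1L)
      p8 <- shift(m,  0L, -1L); p9 <- shift(m, -1L, -1L)
      bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      an <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
            (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- m & bn >= 2 & bn <= 6 & an == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bn >= 2 & bn <= 6 & an == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

## Coordinates (row, col) of TRUE pixels.
mask_which <- function(mask) which(mask, arr.ind = TRUE)

## --- skeleton graph utilities ------------------------------------------

## Geodesic distances along an 8-connected skeleton from a source pixel.
## Axial steps cost 1, diagonal steps sqrt(2) (discrete arc length).
## Returns list(dist, prev) over skeleton pixel ids; `pix` is the
## (row, col) matrix of skeleton pixels; source is a row index into pix.
skeleton_geodesic <- function(pix, source) {
  n <- nrow(pix)
  if (n == 0L) stop("empty skeleton")
  key <- paste(pix[, 1], pix[, 2])
  id_of <- structure(seq_len(n), names = key)
  ## adjacency lists
  adj <- vector("list", n); wts <- vector("list", n)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  step_w <- sqrt(offs[, 1]^2 + offs[, 2]^2)
  for (k in seq_len(8)) {
    nb <- paste(pix[, 1] + offs[k, 1], pix[, 2] + offs[k, 2])
    hit <- id_of[nb]
    ok <- !is.na(hit)
    if (any(ok)) {
      src <- which(ok)
      for (ii in seq_along(src)) {
        i <- src[ii]
        adj[[i]] <- c(adj[[i]], hit[ok][ii])
        wts[[i]] <- c(wts[[i]], step_w[k])
      }
    }
  }
  dist <- rep(Inf, n); prev <- rep(NA_integer_, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nbrs <- adj[[u]]
    if (is.null(nbrs)) next
    alt <- dist[u] + wts[[u]]
    upd <- alt < dist[nbrs]
    if (any(upd)) {
      dist[nbrs[upd]] <- alt[upd]
      prev[nbrs[upd]] <- u
    }
  }
  list(dist = dist, prev = prev)
}

## Reconstruct path of pixel ids from source to target using `prev`.
geodesic_path <- function(prev, target) {
  path <- integer(0)
  u <- target
  while (!is.na(u)) { path <- c(u, path); u <- prev[u] }
  path
}

## --- rasterization helpers ---------------------------------------------

## 1-px raster of the segment (r0,c0)-(r1,c1), inclusive (Bresenham-like
## by dense parameter sampling; exact for our test geometries).
raster_segment <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1)
  t <- seq(0, 1, length.out = n + 1)
  cbind(round(r0 + t * (r1 - r0)), round(c0 + t * (c1 - c0)))
}

## 1-px raster of a polyline given as an m x 2 matrix of (row, col).
raster_polyline <- function(poly) {
  out <- NULL
  for (i in seq_len(nrow(poly) - 1L))
    out <- rbind(out, raster_segment(poly[i, 1], poly[i, 2],
                                     poly[i + 1, 1], poly[i + 1, 2]))
  unique(out)
}

## Distance from every pixel centre of an nr x nc grid to a polyline
## ((row, col) vertices), computed per segment over a bounding window.
polyline_distance <- function(nr, nc, poly, max_r) {
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    rlo <- max(1L, floor(min(a[1], b[1]) - max_r - 1))
    rhi <- min(nr, ceiling(max(a[1], b[1]) + max_r + 1))
    clo <- max(1L, floor(min(a[2], b[2]) - max_r - 1))
    chi <- min(nc, ceiling(max(a[2], b[2]) + max_r + 1))
    if (rlo > rhi || clo > chi) next
    rs <- rlo:rhi; cs <- clo:chi
    pr <- matrix(rs, length(rs), length(cs))
    pc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      seg_d <- sqrt((pr - a[1])^2 + (pc - a[2])^2)
    } else {
      t <- clamp(((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2, 0, 1)
      seg_d <- sqrt((pr - (a[1] + t * ab[1]))^2 + (pc - (a[2] + t * ab[2]))^2)
    }
    d[rs, cs] <- pmin(d[rs, cs], seg_d)
  }
  d
}
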