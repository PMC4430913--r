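## Centreline extraction, detachment, labeling, and construction of the
## labeled artery with its candidate control points.

#' Extract centrelines and keypoints from an artery mask
#'
#' The mask is thinned to a minimally connected stroke; counting each
#' skeleton pixel's 3x3 neighbourhood (centre included, a convolution
#' with a 3x3 kernel of ones) classifies end pixels (count == 2) and
#' branch pixels (count >= 4).
#'
#' @param mask logical matrix (non-empty segmentation).
#' @return list of class `centerline_set`: `skeleton` (logical),
#'   `neighbor_counts` (integer), `keypoints` (data.frame `u`, `v`,
#'   `role`; 0-based pixel coordinates), `labels` (integer matrix, filled
#'   by [detach_and_label()]), and the source `mask`.
#' @export
extract_centerlines <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("empty mask: nothing to thin")
  skeleton <- thin_mask(mask)
  counts <- neighbor_count_3x3(skeleton)
  ends <- skeleton & counts == 2
  ## a 3x3 ones-count of 4 alone also fires on diagonal staircase pixels;
  ## requiring >= 3 circular transitions keeps only true junctions
  branches <- skeleton & counts >= 4 & transition_count(skeleton) >= 3
  ## adjacent branch pixels at one junction collapse to a single
  ## representative (the member nearest the cluster centroid)
  branch_pts <- NULL
  if (any(branches)) {
    clab <- label_components(dilate_disc(branches, 1.5))
    ids <- sort(unique(clab[branches]))
    branch_pts <- t(vapply(ids, function(id) {
      w <- which(branches & clab == id, arr.ind = TRUE)
      cen <- colMeans(w)
      w[which.min((w[, 1] - cen[1])^2 + (w[, 2] - cen[2])^2), ]
    }, numeric(2)))
  }
  kp <- rbind(
    if (any(ends)) {
      w <- which(ends, arr.ind = TRUE)
      data.frame(u = w[, 2] - 1L, v = w[, 1] - 1L, role = "end")
    },
    if (!is.null(branch_pts))
      data.frame(u = branch_pts[, 2] - 1L, v = branch_pts[, 1] - 1L,
                 role = "bifurcation"))
  if (is.null(kp))
    kp <- data.frame(u = integer(0), v = integer(0), role = character(0))
  rownames(kp) <- NULL
  structure(list(skeleton = skeleton, neighbor_counts = counts,
                 keypoints = kp, labels = matrix(0L, nrow(mask), ncol(mask)),
                 mask = mask),
            class = "centerline_set")
}

#' Detach centrelines at branch points and label them
#'
#' Branch pixels are removed; in addition every skeleton pixel that lies
#' closer (Euclidean distance transform) to a branch point than to the
#' nearest non-vessel pixel is cleared, so the detachment cuts cleanly
#' through the junction. Components shorter than `min_len` pixels are
#' discarded and the survivors are labeled `1..K` (8-connected).
#'
#' @param cs a `centerline_set` from [extract_centerlines()].
#' @param min_len minimum component pixel count to keep (`>= 1`).
#' @return the `centerline_set` with `labels` filled and `detached`
#'   (logical matrix) added.
#' @export
detach_and_label <- function(cs, min_len = 10L) {
  stopifnot(inherits(cs, "centerline_set"))
  if (min_len < 1) stop("min_len must be >= 1")
  skel <- cs$skeleton
  bp <- cs$keypoints[cs$keypoints$role == "bifurcation", , drop = FALSE]
  detached <- skel
  if (nrow(bp) > 0) {
    bp_mask <- matrix(FALSE, nrow(skel), ncol(skel))
    bp_mask[cbind(bp$v + 1L, bp$u + 1L)] <- TRUE
    detached[bp_mask] <- FALSE
    d_branch <- distance_to_targets(bp_mask)
    d_bg <- distance_to_background(cs$mask)
    ## ties removed too, so diagonal contact across a junction is cut
    detached[detached & d_branch <= d_bg] <- FALSE
  }
  lab <- label_components(detached)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_len)
    lab[!(lab %in% keep)] <- 0L
    ids <- unique(lab[lab > 0L])
    lab[lab > 0L] <- match(lab[lab > 0L], ids)
  }
  cs$labels <- lab
  cs$detached <- detached & lab > 0L
  cs
}

#' Build the labeled artery mask and its candidate control points
#'
#' The selected centreline labels are united into the selection image;
#' the mask radius `r` is the maximum distance-to-background of the
#' segmentation over the selected centreline pixels; the artery mask is
#' the selection dilated by a disc of radius `r`, intersected with the
#' segmentation. Candidate control points are the keypoints falling
#' inside the artery mask, ordered along the centreline from the start
#' (the endpoint with the larger local vessel radius; proximal vessels
#' are wider) to the end.
#'
#' @param selected_labels integer vector of centreline label ids.
#' @param cs a labeled `centerline_set` (after [detach_and_label()]).
#' @param seg logical matrix: the artery segmentation the centrelines
#'   came from.
#' @return list with `artery_mask` (logical matrix), `control_points`
#'   (data.frame `u`, `v`, `role`, ordered start to end) and `radius`.
#' @export
label_artery <- function(selected_labels, cs, seg) {
  stopifnot(inherits(cs, "centerline_set"))
  assert_mask(seg)
  if (length(selected_labels) == 0) stop("selected_labels must be nonempty")
  present <- setdiff(unique(selected_labels), cs$labels)
  if (length(present) > 0)
    stop("unknown centreline label id(s): ", paste(present, collapse = ", "))
  sel <- matrix(cs$labels %in% selected_labels, nrow(seg), ncol(seg))
  d_bg <- distance_to_background(seg)
  r <- max(d_bg[sel])
  artery <- dilate_disc(sel, r) & seg
  kp <- cs$keypoints
  inside <- artery[cbind(kp$v + 1L, kp$u + 1L)]
  pts <- kp[inside, , drop = FALSE]
  if (nrow(pts) == 0)
    stop("no keypoints fall inside the selected artery; re-select labels")
  ## a junction between wide vessels can yield two nearby triple points;
  ## same-role points closer than the mask radius merge to one
  if (nrow(pts) > 1) {
    pr <- max(2, r)
    keep <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(pts) - 1)) {
      if (!keep[i]) next
      for (j in seq.int(i + 1, nrow(pts))) {
        if (keep[j] && pts$role[i] == pts$role[j] &&
            (pts$u[i] - pts$u[j])^2 + (pts$v[i] - pts$v[j])^2 <= pr^2)
          keep[j] <- FALSE
      }
    }
    pts <- pts[keep, , drop = FALSE]
  }
  ## order along the centreline: geodesic distance from the start point
  skel_sel <- cs$skeleton & artery
  pix <- mask_which(skel_sel)
  ends <- pts[pts$role == "end", , drop = FALSE]
  if (nrow(ends) > 0) {
    widths <- d_bg[cbind(ends$v + 1L, ends$u + 1L)]
    ## widest endpoint is the ostium side; topmost on ties
    ord <- order(-widths, ends$v)
    start_uv <- c(ends$u[ord[1]], ends$v[ord[1]])
  } else {
    start_uv <- c(pts$u[1], pts$v[1])
  }
  src <- which(pix[, 1] == start_uv[2] + 1L & pix[, 2] == start_uv[1] + 1L)
  if (length(src) == 1L && nrow(pix) > 1) {
    g <- skeleton_geodesic(pix, src)
    ## nearest skeleton pixel distance for each control point
    dist_of <- vapply(seq_len(nrow(pts)), function(i) {
      dd <- (pix[, 1] - (pts$v[i] + 1L))^2 + (pix[, 2] - (pts$u[i] + 1L))^2
      j <- which.min(dd)
      g$dist[j]
    }, numeric(1))
    pts <- pts[order(dist_of), , drop = FALSE]
  }
  ## the first endpoint in path order is the start
  pts$role[pts$role == "end"] <- "end"
  first_end <- which(pts$role == "end")[1]
  if (!is.na(first_end) && first_end == 1L) pts$role[1] <- "start"
  rownames(pts) <- NULL
  list(artery_mask = artery, control_points = pts, radius = r)
}
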