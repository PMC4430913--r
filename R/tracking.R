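## Intersection Tracking: slice-to-slice propagation of a coronary artery
## cross-section by region overlap, with bifurcation resolution (the
## terminating branch is a sub-artery and is removed; a branch that
## bifurcates again is the main artery), preservation of long terminal
## branches for the RCA (R-PDA / R-PLB), and a backtracking window that
## bridges slices where the cross-section momentarily vanishes.

#' Construct a labeled 3D artery model
#'
#' @param label artery label (`"LM"`, `"LAD"`, `"LCX"`, `"RCA"`,
#'   `"Aorta"`, ...).
#' @param M logical occupancy array `[z, y, x]`.
#' @param keypoints data.frame with columns `role` (`start`,
#'   `bifurcation`, `end`), `z`, `y`, `x` (1-based voxel indices).
#' @param gaps integer vector of slices bridged by backtracking (empty
#'   `M` rows between start and end).
#' @return object of class `artery_model`.
#' @export
artery_model <- function(label, M, keypoints,
                         gaps = integer(0)) {
  stopifnot(is.array(M), length(dim(M)) == 3, is.logical(M))
  structure(list(label = label, M = M, keypoints = keypoints, gaps = gaps),
            class = "artery_model")
}

#' @export
print.artery_model <- function(x, ...) {
  zs <- which(apply(x$M, 1, any))
  cat(sprintf("<artery_model %s> %d voxels over slices %s..%s; %d keypoint(s)\n",
              x$label, sum(x$M),
              if (length(zs)) min(zs) else NA, if (length(zs)) max(zs) else NA,
              nrow(x$keypoints)))
  invisible(x)
}

#' Define a tracking seed
#' @param z slice index (1-based, from the top of the stack).
#' @param row,col pixel position inside that slice (1-based).
#' @param label artery label the seed belongs to.
#' @return object of class `tracking_seed`.
#' @export
tracking_seed <- function(z, row, col, label = "LM") {
  structure(list(z = as.integer(z), row = as.integer(row),
                 col = as.integer(col), label = label),
            class = "tracking_seed")
}

## centroid of a logical slice mask, as c(y, x) (1-based, rounded)
mask_centroid <- function(m) {
  w <- which(m, arr.ind = TRUE)
  c(y = round(mean(w[, 1])), x = round(mean(w[, 2])))
}

## the 8-connected component of `mask` containing (row, col), or NULL
component_containing <- function(mask, row, col) {
  if (!mask[row, col]) return(NULL)
  lab <- label_components(mask)
  id <- lab[row, col]
  out <- lab == id
  dim(out) <- dim(mask)
  out
}

## list of component masks of `mask` overlapping the reference region
components_overlapping <- function(mask, ref) {
  if (!any(mask & ref)) return(list())
  lab <- label_components(mask)
  ids <- sort(unique(lab[ref & lab > 0L]))
  lapply(ids, function(id) {
    out <- lab == id; dim(out) <- dim(mask); out
  })
}

#' Detect a bifurcation inside a single cross-section region
#'
#' The region is thinned; a skeleton pixel whose 3x3 neighbourhood count
#' (centre included) reaches 4 marks a branch locus. When one is found
#' the region is split at the locus: the skeleton is cut around the
#' branch pixels and every region pixel is assigned to its nearest
#' skeleton stroke.
#'
#' @param H logical matrix: one 8-connected region.
#' @return list with `flag` (logical) and `branch_regions` (list of
#'   logical masks partitioning `H`; empty when `flag` is `FALSE`).
#' @export
detect_bifurcation <- function(H) {
  assert_mask(H)
  if (!any(H)) stop("empty region")
  lab <- label_components(H)
  if (max(lab) != 1L) stop("region must be a single 8-connected component")
  skel <- thin_mask(H)
  counts <- neighbor_count_3x3(skel)
  bp <- skel & counts >= 4 & transition_count(skel) >= 3
  if (!any(bp)) return(list(flag = FALSE, branch_regions = list()))
  ## cut the skeleton at the branch locus (branch pixels + their 8-ring)
  cut <- skel & !dilate_disc(bp, 1.5)
  strokes <- label_components(cut)
  ns <- max(strokes)
  if (ns < 2L) return(list(flag = FALSE, branch_regions = list()))
  ## assign every H pixel to the nearest stroke
  dmaps <- lapply(seq_len(ns), function(i) {
    m <- strokes == i; dim(m) <- dim(H); distance_to_targets(m)
  })
  hw <- which(H)
  dmat <- vapply(dmaps, function(d) d[hw], numeric(length(hw)))
  assign_id <- max.col(-dmat, ties.method = "first")
  regions <- lapply(seq_len(ns), function(i) {
    m <- matrix(FALSE, nrow(H), ncol(H))
    m[hw[assign_id == i]] <- TRUE
    m
  })
  regions <- regions[vapply(regions, any, logical(1))]
  list(flag = TRUE, branch_regions = regions)
}

## does any component of `slice_mask` overlap `region`?
has_continuation <- function(slice_mask, region) any(slice_mask & region)

#' Track a coronary artery through binarized slices
#'
#' Starting from a seed on a segmented component, the component is
#' followed top to bottom by region intersection with each next slice.
#' At a bifurcation the branches are tracked in parallel (logically;
#' executed branch by branch) and resolved by two rules: a branch that
#' reaches its end first is a sub-artery and is removed; a branch that
#' bifurcates again before the other ends is the main artery. For the
#' RCA, terminating branches tracked over at least `preserve_len` slices
#' are preserved and merged (R-PDA / R-PLB). When the intersection with
#' the next slice is empty, a backtracking window (the region dilated by
#' `dilate_px`, looked ahead up to `lookahead` slices) is searched before
#' the end of the artery is declared. In-slice bifurcations (a Y-shaped
#' cross-section) are accepted only if at least two sub-regions continue
#' into the next slice; spurious ones are ignored.
#'
#' The start centroid, every accepted bifurcation slice and the end
#' centroid are recorded as keypoints.
#'
#' @param binarized logical array `[z, y, x]` of per-slice segmented
#'   vessel candidates.
#' @param seed a [tracking_seed()].
#' @param preserve_len minimum tracked slice count for a terminating
#'   branch to be preserved (applies when `preserve_terminal`).
#' @param dilate_px,lookahead backtracking window parameters.
#' @param stop_at_bifurcation stop at the first bifurcation (used for the
#'   LM, which by definition ends where LAD and LCX begin).
#' @param preserve_terminal keep long terminating branches (default: only
#'   for label `"RCA"`).
#' @return an [artery_model()]; the attribute `"last_region"` holds the
#'   final tracked cross-section (used for seed derivation).
#' @export
track_artery <- function(binarized, seed, preserve_len = 15L,
                         dilate_px = 3, lookahead = 3L,
                         stop_at_bifurcation = FALSE,
                         preserve_terminal = identical(seed$label, "RCA")) {
  stopifnot(is.array(binarized), length(dim(binarized)) == 3,
            inherits(seed, "tracking_seed"))
  d <- dim(binarized)
  nz <- d[1]
  if (seed$z < 1 || seed$z > nz) stop("seed slice outside volume")
  H0 <- component_containing(binarized[seed$z, , ], seed$row, seed$col)
  if (is.null(H0))
    stop("seed does not lie on a segmented component of its slice")
  M <- array(FALSE, d)
  keypoints <- data.frame(role = character(0), z = integer(0),
                          y = integer(0), x = integer(0))
  gaps <- integer(0)
  add_kp <- function(kp, role, z, cen)
    rbind(kp, data.frame(role = role, z = z, y = cen["y"], x = cen["x"],
                         row.names = NULL))

  ## Track one branch starting with region H at slice z. Returns a
  ## segment: slices (list of z -> mask), keypoints (bifurcation/end),
  ## end_z, deepest (deepest slice reached incl. kept descendants),
  ## first_bif_z, gaps, stopped_at_bif (+ last region for seed use).
  track_branch <- function(H, z) {
    seg <- list(slices = list(), kp = keypoints[0, ], end_z = z,
                first_bif_z = Inf, gaps = integer(0), last = H,
                stopped_at_bif = FALSE)
    seg$slices[[as.character(z)]] <- H
    zi <- z
    repeat {
      if (zi >= nz) {
        seg$kp <- add_kp(seg$kp, "end", zi, mask_centroid(H))
        seg$end_z <- zi; seg$last <- H
        return(seg)
      }
      zn <- zi + 1L
      comps <- components_overlapping(binarized[zn, , ], H)
      if (length(comps) == 0L) {
        ## backtracking window before declaring the end
        Hd <- dilate_disc(H, dilate_px)
        hit_z <- NA_integer_; hit <- NULL
        hi <- min(zi + lookahead, nz)
        if (hi >= zn) for (zj in seq.int(zn, hi)) {  # forward only
          cc <- components_overlapping(binarized[zj, , ], Hd)
          if (length(cc) > 0L) { hit_z <- zj; hit <- cc; break }
        }
        if (is.na(hit_z)) {
          seg$kp <- add_kp(seg$kp, "end", zi, mask_centroid(H))
          seg$end_z <- zi; seg$last <- H
          return(seg)
        }
        if (hit_z > zn) seg$gaps <- c(seg$gaps, seq.int(zn, hit_z - 1L))
        comps <- hit
        zn <- hit_z
      }
      if (length(comps) == 1L) {
        C <- comps[[1]]
        ## in-slice Y-junction check (step-6 style thinning test)
        db <- detect_bifurcation(C)
        accepted <- FALSE
        if (db$flag && zn < nz) {
          cont <- vapply(db$branch_regions,
                         function(b) has_continuation(binarized[zn + 1L, , ], b),
                         logical(1))
          if (sum(cont) >= 2L) {
            accepted <- TRUE
            branches <- db$branch_regions[cont]
            bif_cen <- mask_centroid(C)
            seg$kp <- add_kp(seg$kp, "bifurcation", zn, bif_cen)
            seg$first_bif_z <- min(seg$first_bif_z, zn)
            if (stop_at_bifurcation) {
              seg$kp <- add_kp(seg$kp, "end", zn, bif_cen)
              seg$end_z <- zn; seg$last <- C
              seg$slices[[as.character(zn)]] <- C
              seg$stopped_at_bif <- TRUE
              return(seg)
            }
            seg <- resolve_bifurcation(seg, branches, zn, in_slice = TRUE)
            return(seg)
          }
        }
        if (!accepted) {
          seg$slices[[as.character(zn)]] <- C
          H <- C; zi <- zn; seg$end_z <- zn; seg$last <- C
        }
      } else {
        ## the region splits across slices: a bifurcation
        bif_cen <- mask_centroid(H)
        seg$kp <- add_kp(seg$kp, "bifurcation", zi, bif_cen)
        seg$first_bif_z <- min(seg$first_bif_z, zi)
        if (stop_at_bifurcation) {
          seg$kp <- add_kp(seg$kp, "end", zi, bif_cen)
          seg$end_z <- zi
          seg$stopped_at_bif <- TRUE
          return(seg)
        }
        seg <- resolve_bifurcation(seg, comps, zn, in_slice = FALSE)
        return(seg)
      }
    }
  }

  ## Track every branch to completion and keep the one reaching deepest
  ## (the terminating branch ends first and is removed; a branch that
  ## bifurcates again keeps going and wins). Preserved terminal branches
  ## are merged for the RCA.
  resolve_bifurcation <- function(seg, branches, zn, in_slice) {
    subs <- lapply(branches, function(b) track_branch(b, zn))
    depth <- vapply(subs, function(s) s$end_z, numeric(1))
    volume <- vapply(subs, function(s)
      sum(vapply(s$slices, sum, numeric(1))), numeric(1))
    main_i <- order(-depth, -volume)[1]
    for (i in seq_along(subs)) {
      s <- subs[[i]]
      if (i == main_i) {
        seg$slices <- c(seg$slices, s$slices)
        seg$kp <- rbind(seg$kp, s$kp)
        seg$end_z <- s$end_z
        seg$first_bif_z <- min(seg$first_bif_z, s$first_bif_z)
        seg$gaps <- c(seg$gaps, s$gaps)
        seg$last <- s$last
        seg$stopped_at_bif <- s$stopped_at_bif
      } else if (preserve_terminal &&
                 (s$end_z - zn + 1L) >= preserve_len) {
        ## long terminating branch: an R-PDA / R-PLB type main part
        seg$slices <- c(seg$slices, s$slices)
        seg$kp <- rbind(seg$kp, s$kp)
        seg$gaps <- c(seg$gaps, s$gaps)
      }
    }
    seg
  }

  start_cen <- mask_centroid(H0)
  seg <- track_branch(H0, seed$z)
  keypoints <- rbind(
    data.frame(role = "start", z = seed$z, y = start_cen["y"],
               x = start_cen["x"], row.names = NULL),
    seg$kp)
  for (k in seq_along(seg$slices)) {
    zi <- as.integer(names(seg$slices)[k])
    M[zi, , ] <- M[zi, , ] | seg$slices[[k]]
  }
  keypoints <- keypoints[order(keypoints$z,
                               match(keypoints$role,
                                     c("start", "bifurcation", "end"))), ]
  rownames(keypoints) <- NULL
  model <- artery_model(seed$label, M, keypoints, gaps = sort(unique(seg$gaps)))
  attr(model, "last_region") <- seg$last
  attr(model, "stopped_at_bifurcation") <- seg$stopped_at_bif
  model
}

#' Derive LAD and LCX seeds from a tracked LM
#'
#' The LM ends where it first bifurcates; the two branch regions present
#' just below that slice become the LAD and LCX seeds. By default the
#' leftmost region in the image (smaller column) is assigned to the LAD;
#' the assignment is reported in the result.
#'
#' @param lm an [artery_model()] for the LM containing at least one
#'   bifurcation keypoint (track with `stop_at_bifurcation = TRUE`).
#' @param binarized the binarized slice array used for tracking.
#' @param leftmost_label which label the leftmost branch receives
#'   (default `"LAD"`).
#' @return list with elements `LAD` and `LCX` (each a
#'   [tracking_seed()]) and `assignment` (a description string).
#' @export
derive_lad_lcx_seeds <- function(lm, binarized, leftmost_label = "LAD") {
  stopifnot(inherits(lm, "artery_model"))
  bif <- lm$keypoints[lm$keypoints$role == "bifurcation", , drop = FALSE]
  if (nrow(bif) == 0) stop("LM model has no bifurcation keypoint")
  zb <- min(bif$z)
  last_region <- attr(lm, "last_region")
  if (is.null(last_region)) last_region <- lm$M[zb, , ]
  d <- dim(binarized)
  regions <- NULL; z_seed <- NULL
  ## the daughters may first appear a slice or two below the bifurcation
  ## (same window the tracker's backtracking uses)
  ref <- dilate_disc(last_region, 2)
  for (zj in seq.int(min(zb + 1L, d[1]), min(zb + 3L, d[1]))) {
    comps <- components_overlapping(binarized[zj, , ], ref)
    if (length(comps) >= 2L) { regions <- comps; z_seed <- zj; break }
  }
  if (is.null(regions)) {
    ## branches still connected at the bifurcation slice: split in-slice
    db <- detect_bifurcation(last_region)
    if (db$flag && length(db$branch_regions) >= 2L) {
      regions <- db$branch_regions; z_seed <- zb
    }
  }
  if (is.null(regions))
    stop("no branch regions found below the LM bifurcation")
  if (length(regions) > 2L) {
    cens <- t(vapply(regions, mask_centroid, numeric(2)))
    stop("ambiguous three-way split at slice ", z_seed, "; candidate regions at (y,x): ",
         paste(sprintf("(%d,%d)", cens[, 1], cens[, 2]), collapse = ", "))
  }
  cens <- t(vapply(regions, mask_centroid, numeric(2)))
  ord <- order(cens[, 2])  # by column: leftmost first
  other_label <- if (identical(leftmost_label, "LAD")) "LCX" else "LAD"
  seeds <- list(
    tracking_seed(z_seed, cens[ord[1], 1], cens[ord[1], 2], leftmost_label),
    tracking_seed(z_seed, cens[ord[2], 1], cens[ord[2], 2], other_label))
  names(seeds) <- c(leftmost_label, other_label)
  list(LAD = seeds[["LAD"]], LCX = seeds[["LCX"]],
       assignment = paste0("leftmost-in-image = ", leftmost_label))
}

#' Binarize vesselness slices for tracking
#'
#' Applies [frangi_enhance()] per slice under the lung-removal mask and
#' thresholds the vesselness map.
#'
#' @param huv an `hu_volume`.
#' @param threshold vesselness cut (default 0.15).
#' @param scales,phi1,phi2,polarity passed to [frangi_enhance()].
#' @param lung_mask optional precomputed keep-mask from
#'   [build_lung_mask()].
#' @return logical array `[z, y, x]`.
#' @export
binarize_vesselness <- function(huv, threshold = 0.15, scales = 1:4,
                                phi1 = 0.75, phi2 = 25,
                                polarity = "bright_vessels",
                                lung_mask = NULL) {
  stopifnot(inherits(huv, "hu_volume"))
  d <- dim(huv$hu)
  if (is.null(lung_mask)) lung_mask <- build_lung_mask(huv)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) {
    sl <- huv$hu[z, , ] * lung_mask[z, , ]
    vs <- frangi_enhance(sl, scales = scales, phi1 = phi1, phi2 = phi2,
                         polarity = polarity)
    out[z, , ] <- vs$v > threshold
  }
  out
}

#' Binarize by contrasted-artery HU region
#'
#' The simple alternative to vesselness binarization: region-4 voxels
#' (contrast-filled structures) under the lung mask, per slice.
#'
#' @param huv an `hu_volume`.
#' @param exclude optional logical array of voxels to remove first (e.g.
#'   the aorta model, so tracking does not leak into it).
#' @return logical array `[z, y, x]`.
#' @export
binarize_region4 <- function(huv, exclude = NULL) {
  region <- classify_regions(huv)
  out <- region == 4L
  if (!is.null(exclude)) out <- out & !exclude
  out
}
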