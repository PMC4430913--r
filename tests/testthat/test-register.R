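test_that("identity projection maps a voxel to its (x, y) pixel", {
  M <- array(FALSE, c(16, 16, 16)); M[8, 6, 4] <- TRUE  # z=8 y=6 x=4
  am <- artery_model("LAD", M, data.frame(role = "start", z = 8, y = 6, x = 4))
  pr <- rotate_and_project(am, view_angles(0, 0, 0))
  w <- which(pr$mask, arr.ind = TRUE)
  expect_equal(nrow(w), 1)
  expect_equal(unname(w[1, 2]) - 1 + pr$u0, 3)   # u = x - 1
  expect_equal(unname(w[1, 1]) - 1 + pr$v0, 5)   # v = y - 1
  expect_equal(unname(c(pr$back_z[w], pr$back_y[w], pr$back_x[w])),
               c(8, 6, 4))
  expect_equal(pr$points$u, 3)
  expect_error(rotate_and_project(
    artery_model("X", array(FALSE, c(4, 4, 4)),
                 data.frame(role = character(0), z = integer(0),
                            y = integer(0), x = integer(0))),
    view_angles(0, 0, 0)), "empty")
})

test_that("projection matches a brute-force voxel rotation oracle", {
  ## ~200-voxel tube under a generic rotation
  sp <- vertical_tube_spec(z0 = 8, z1 = 28, y0 = 16, x0 = 20, radius = 1.6,
                           size = c(36L, 36L, 36L))
  ph <- make_cta_phantom(sp)
  am <- artery_model("LAD", ph$truth$label_masks$LAD,
                     data.frame(role = character(0), z = integer(0),
                                y = integer(0), x = integer(0)))
  ang <- view_angles(30, 15, -20)
  pr <- rotate_and_project(am, ang)
  w <- which(am$M, arr.ind = TRUE)
  xyz <- cbind(w[, 3] - 1, w[, 2] - 1, w[, 1] - 1)
  r <- function(a) a * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r(30)), -sin(r(30)), 0, sin(r(30)), cos(r(30))), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(r(15)), 0, sin(r(15)), 0, 1, 0, -sin(r(15)), 0, cos(r(15))), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(r(-20)), -sin(r(-20)), 0, sin(r(-20)), cos(r(-20)), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  cen <- rep(35 / 2, 3)
  rot <- t(Rz %*% Ry %*% Rx %*% (t(xyz) - cen) + cen)
  oracle <- unique(cbind(round(rot[, 2]), round(rot[, 1])))  # (v, u)
  got <- which(pr$mask, arr.ind = TRUE)
  got_uv <- cbind(got[, 1] - 1 + pr$v0, got[, 2] - 1 + pr$u0)
  expect_setequal(paste(oracle[, 1], oracle[, 2]),
                  paste(got_uv[, 1], got_uv[, 2]))
})

test_that("normalization matches hand arithmetic and its invariants", {
  np <- normalize_points(rbind(c(0, 0), c(2, 0), c(0, 2)))
  expect_equal(np$centroid, c(2 / 3, 2 / 3))
  expect_equal(np$scale, 3 * sqrt(2) / 4, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(np$normalized))), 1e-9)
  expect_equal(sqrt(mean(rowSums(np$normalized^2))), sqrt(2),
               tolerance = 1e-9)
  ## fixed point: already centred with RMS sqrt(2)
  p0 <- rbind(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  np0 <- normalize_points(p0)
  expect_equal(np0$scale, 1, tolerance = 1e-12)
  expect_equal(np0$normalized, p0, ignore_attr = TRUE)
  ## translation invariance
  pts <- rbind(c(3, 1), c(7, 2), c(5, 9), c(0, 4))
  expect_equal(normalize_points(pts)$normalized,
               normalize_points(sweep(pts, 2, c(-12.5, 40), "+"))$normalized,
               tolerance = 1e-12)
  ## N maps normalized coordinates back to raw ones
  npt <- normalize_points(pts)
  back <- cbind(npt$normalized, 1) %*% npt$N
  expect_equal(back[, 1:2], pts, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(normalize_points(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(normalize_points(rbind(c(2, 2), c(2, 2), c(2, 2))),
               "spread")
})

test_that("normalization RMS invariant holds for arbitrary point sets", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(3:12, 1)
      pts <- matrix(runif(2 * n, -50, 400), n, 2)
      if (abs(max(dist(pts))) < 1e-6) next
      np <- normalize_points(pts)
      expect_lt(abs(sqrt(mean(rowSums(np$normalized^2))) - sqrt(2)), 1e-9)
      expect_lt(max(abs(colMeans(np$normalized))), 1e-9)
    }
  })
})

test_that("affine estimation recovers exact and perturbed transforms", {
  ## identity
  C <- rbind(c(0, 0), c(10, 0), c(0, 10))
  expect_equal(unclass(estimate_affine(C, C)), diag(3), tolerance = 1e-9)
  ## pure translation
  T2 <- estimate_affine(C, sweep(C, 2, c(5, 7), "+"))
  expect_equal(unclass(T2)[3, 1:2], c(5, 7), tolerance = 1e-9)
  expect_equal(unclass(T2)[1:2, 1:2], diag(2), tolerance = 1e-9)
  ## random exact recovery at n = 3, equal to the un-normalized solve
  withr::with_seed(11, {
    for (i in 1:20) {
      Tm <- rbind(cbind(matrix(rnorm(4, 0, 0.8), 2, 2) + diag(2), 0),
                  c(rnorm(2, 0, 30), 1))
      C <- matrix(runif(6, 0, 100), 3, 2)
      if (abs(det(cbind(C, 1))) < 1) next
      Cp <- (cbind(C, 1) %*% Tm)[, 1:2]
      Tr <- estimate_affine(C, Cp)
      expect_lt(max(abs(unclass(Tr) - Tm)), 1e-6)
      ## independent oracle: direct solve without normalization
      Td <- solve(cbind(C, 1), Cp)
      expect_lt(max(abs(unclass(Tr)[, 1:2] - Td)), 1e-6)
      resid <- cbind(C, 1) %*% unclass(Tr) - cbind(Cp, 1)
      expect_lt(max(abs(resid)), 1e-6)
    }
  })
  expect_error(estimate_affine(rbind(c(0, 0), c(1, 1), c(2, 2)),
                               rbind(c(0, 0), c(1, 0), c(2, 1))),
               "collinear")
  expect_error(estimate_affine(C[1:2, ], C[1:2, ]), "at least 3")
})

test_that("jittered overdetermined fits recover the transform closely", {
  withr::with_seed(3, {
    for (i in 1:10) {
      Tm <- rbind(cbind(matrix(rnorm(4, 0, 0.4), 2, 2) + diag(2), 0),
                  c(rnorm(2, 0, 20), 1))
      C <- matrix(runif(20, 0, 200), 10, 2)
      Cp <- (cbind(C, 1) %*% Tm)[, 1:2] +
        matrix(rnorm(20, 0, 0.5), 10, 2)
      Tr <- estimate_affine(C, Cp)
      expect_lt(max(abs(unclass(Tr)[1:2, 1:2] - Tm[1:2, 1:2])), 0.05)
    }
  })
})

test_that("identity registration reproduces the angiogram mask", {
  sp <- vertical_tube_spec(z0 = 6, z1 = 26, y0 = 16, x0 = 16, radius = 2,
                           size = c(32L, 32L, 32L))
  ph <- make_cta_phantom(sp)
  am <- artery_model("LAD", ph$truth$label_masks$LAD,
                     data.frame(role = "start", z = 6, y = 16, x = 16))
  pr <- rotate_and_project(am, view_angles(-90, 0, 0))
  ## an angiogram mask equal to the projection canvas, identity transform
  ## shifted by the canvas origin
  Tid <- structure(rbind(c(1, 0, 0), c(0, 1, 0),
                         c(-pr$u0, -pr$v0, 1)),
                   class = c("affine2d", "matrix"))
  ireg <- register_artery(pr$mask, pr, Tid)
  expect_identical(ireg$angio, pr$mask)
  expect_error(register_artery(pr$mask, pr, structure(
    rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
    class = c("affine2d", "matrix"))), "invertible")
})

test_that("control points coincide in the registered plane", {
  ## fitted transform sends each source control point onto its target
  ph <- make_cta_phantom(branching_spec())
  ang <- view_angles(-90, 0, 10)
  pp <- project_phantom(ph$truth, ang)
  huv <- to_hounsfield(ph$volume)
  bin <- binarize_region4(huv)
  kp <- ph$truth$keypoints$LAD
  model <- track_artery(bin, tracking_seed(kp$z[1], kp$y[1], kp$x[1], "LAD"))
  proj <- rotate_and_project(model, ang)
  seg <- segment_main_arteries(denoise_dwt(pp$image), min_length = 20)
  cs <- detach_and_label(extract_centerlines(seg), min_len = 8)
  support <- dilate_disc(proj$mask, 2)
  sel <- Filter(function(id) mean(support[cs$labels == id]) > 0.5,
                seq_len(max(cs$labels)))
  la <- label_artery(unlist(sel), cs, seg)
  pairing <- pair_control_points(la$control_points, proj$points)
  expect_lt(max(pairing$residuals), 5)
  mapped <- apply_affine(as.matrix(pairing$src[, 1:2]), pairing$T)
  expect_equal(mapped, as.matrix(pairing$dst[, 1:2]),
               tolerance = 5, ignore_attr = TRUE)
  ## a phantom pair with known view registers with high overlap when the
  ## 2D side is the projected truth silhouette itself
  Tid <- structure(rbind(c(1, 0, 0), c(0, 1, 0), c(-proj$u0, -proj$v0, 1)),
                   class = c("affine2d", "matrix"))
  ireg <- register_artery(pp$truth2d$vessel_mask, proj, Tid)
  expect_gte(dice_overlap(ireg$angio, dilate_disc(ireg$cta, 1)), 0.8)
})

test_that("the proportional lengths conserve the CTA centreline length", {
  pr <- stenosis_lengths(3, 1, 8)
  expect_equal(pr$l1, 6)
  expect_equal(pr$l2, 2)
  expect_equal(pr$l1 + pr$l2, 8)
  withr::with_seed(5, {
    for (i in 1:50) {
      l1p <- runif(1, 0, 50); l2p <- runif(1, 0, 50); L <- runif(1, 1, 200)
      pr <- stenosis_lengths(l1p, l2p, L)
      expect_equal(pr$l1 + pr$l2, L, tolerance = 1e-12)
    }
  })
  expect_error(stenosis_lengths(0, 0, 5), "degenerate")
  expect_error(stenosis_lengths(-1, 1, 5), "non-negative")
})

test_that("a stenosis on the CTA artery snaps to its centreline", {
  sp <- vertical_tube_spec(z0 = 6, z1 = 26, y0 = 16, x0 = 16, radius = 2,
                           size = c(32L, 32L, 32L))
  ph <- make_cta_phantom(sp)
  am <- artery_model("LAD", ph$truth$label_masks$LAD,
                     data.frame(role = "start", z = 6, y = 16, x = 16))
  pr <- rotate_and_project(am, view_angles(-90, 0, 0))
  Tid <- structure(rbind(c(1, 0, 0), c(0, 1, 0), c(-pr$u0, -pr$v0, 1)),
                   class = c("affine2d", "matrix"))
  ireg <- register_artery(pr$mask, pr, Tid)
  w <- which(pr$mask, arr.ind = TRUE)
  mid <- w[which.min(abs(w[, 1] - mean(w[, 1]))), ]
  sten_uv <- c(mid[2] - 1, mid[1] - 1)  # angiogram frame = canvas here
  loc <- localize_stenosis(ireg, sten_uv, Tid)
  expect_equal(loc$method, "intersection")
  expect_true(is.na(loc$L))
  ## off-artery marks are rejected
  expect_error(localize_stenosis(ireg, c(0, 0), Tid), "artery")
  ## back projection returns a voxel inside the model
  bp <- back_project(loc, pr, spacing = c(0.75, 0.4, 0.4))
  expect_true(am$M[bp$voxel["z"], bp$voxel["y"], bp$voxel["x"]])
  expect_equal(unname(bp$mm["z"]), unname((bp$voxel["z"] - 1) * 0.75))
})

test_that("the ratio branch localizes a midpoint stenosis symmetrically", {
  ## two overlapping straight centrelines with a lateral offset between
  ## the marked intersections force the ratio branch; symmetric geometry
  ## puts the located pixel at the CTA centreline midpoint
  nr <- 41; nc <- 61
  cta <- matrix(FALSE, nr, nc); cta[21, 6:56] <- TRUE
  ang <- matrix(FALSE, nr, nc)
  ## angiogram artery: same line but bowed away between the crossings
  for (cc in 6:56) {
    off <- if (cc > 16 && cc < 46) 6 else 0
    ang[21 - off, cc] <- TRUE
  }
  ang[15:21, 17] <- TRUE; ang[15:21, 45] <- TRUE  # reconnect at crossings
  proj_stub <- structure(list(mask = cta,
                              back_z = matrix(1L, nr, nc),
                              back_y = matrix(1L, nr, nc),
                              back_x = matrix(1L, nr, nc),
                              points = NULL, u0 = 0, v0 = 0,
                              geom = NULL, label = "LAD"),
                         class = "projected_artery")
  Tid <- structure(diag(3), class = c("affine2d", "matrix"))
  ireg <- register_artery(ang, proj_stub, Tid)
  ## stenosis marked at the bow's midpoint, 6 px off the CTA artery
  loc <- localize_stenosis(ireg, c(30, 14), Tid, tol_px = 2)
  expect_equal(loc$method, "ratio")
  expect_equal(loc$l1 + loc$l2, loc$L, tolerance = 1e-9)
  ## symmetric: located pixel at the CTA centreline midpoint +- 1
  expect_equal(loc$row, 21, tolerance = 1)
  expect_lt(abs(loc$col - 31), 2)
})

test_that("back projection demands provenance near the pixel", {
  M <- array(FALSE, c(8, 8, 8)); M[4, 4, 4] <- TRUE
  am <- artery_model("LAD", M, data.frame(role = "start", z = 4, y = 4, x = 4))
  pr <- rotate_and_project(am, view_angles(0, 0, 0))
  loc <- structure(list(row = nrow(pr$mask), col = ncol(pr$mask),
                        method = "intersection"),
                   class = "stenosis_localization")
  expect_error(back_project(loc, pr, snap_radius = 1), "provenance|snap")
})
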