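test_that("detect_bifurcation distinguishes Y regions from convex ones", {
  ## Y-shaped region: vertical stem splitting into two diagonal arms
  Y <- matrix(FALSE, 24, 24)
  Y[2:12, 11:13] <- TRUE
  for (k in 0:8) {
    Y[12 + k, (9 - k):(11 - k)] <- TRUE
    Y[12 + k, (13 + k):(15 + k)] <- TRUE
  }
  db <- detect_bifurcation(Y)
  expect_true(db$flag)
  expect_gte(length(db$branch_regions), 2)
  ## the regions partition the mask
  un <- Reduce(`|`, db$branch_regions)
  expect_identical(un, Y)
  ## convex disk
  disk <- matrix(FALSE, 15, 15)
  for (r in 1:15) for (c in 1:15)
    if ((r - 8)^2 + (c - 8)^2 <= 25) disk[r, c] <- TRUE
  expect_false(detect_bifurcation(disk)$flag)
  expect_error(detect_bifurcation(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 8, 8); two[2, 2] <- TRUE; two[7, 7] <- TRUE
  expect_error(detect_bifurcation(two), "single")
})

test_that("a straight tube is tracked with start and end centroids", {
  inp <- phantom_tracking_inputs(vertical_tube_spec(z0 = 10, z1 = 40))
  model <- track_artery(inp$bin, inp$seed)
  truth <- inp$phantom$truth$label_masks$LAD
  expect_gte(voxel_recall(model$M, truth), 0.95)
  kp <- model$keypoints
  expect_equal(kp$z[kp$role == "start"], 10)
  expect_equal(kp$z[kp$role == "end"], 40)
  expect_equal(kp$y[kp$role == "start"], 32, tolerance = 1)
  expect_equal(kp$x[kp$role == "end"], 32, tolerance = 1)
  expect_equal(sum(kp$role == "bifurcation"), 0)
  ## start has the smallest slice among keypoints
  expect_equal(min(kp$z), kp$z[kp$role == "start"])
})

test_that("a seed off the segmentation is rejected", {
  inp <- phantom_tracking_inputs(vertical_tube_spec())
  expect_error(track_artery(inp$bin, tracking_seed(15, 2, 2, "LAD")),
               "seed")
})

test_that("terminating side branches are removed, bifurcations recorded", {
  spec <- branching_spec()
  inp <- phantom_tracking_inputs(spec)
  model <- track_artery(inp$bin, inp$seed, preserve_len = 15)
  truth <- inp$phantom$truth$label_masks$LAD
  expect_gte(voxel_recall(model$M, truth), 0.95)
  kp <- model$keypoints
  bifs <- kp$z[kp$role == "bifurcation"]
  expect_equal(length(bifs), 2)
  ## bifurcation slices within +-1 of the truth separation slices
  for (i in 1:2) {
    sep <- truth_separation_slice(inp$bin, truth,
                                  inp$phantom$truth$branch_masks[[i]])
    expect_lte(min(abs(bifs - sep)), 1)
    ## distal branch voxels are excluded from the model
    bm <- inp$phantom$truth$branch_masks[[i]] & !truth
    distal <- array(FALSE, dim(bm)); distal[sep:dim(bm)[1], , ] <- bm[sep:dim(bm)[1], , ]
    expect_equal(sum(model$M & distal), 0)
  }
})

test_that("long terminating branches are preserved for the RCA", {
  spec <- branching_spec(side = FALSE)
  ## one long terminating branch: diverges quickly, then runs deep so
  ## its tracked (post-split) slice count well exceeds preserve_len
  long_side <- cbind(x = 42 + 14 * sin(pi * 0.33) +
                       c(seq(0, 12, length.out = 8),
                         seq(12.5, 16, length.out = 28)),
                     y = c(seq(41, 48, length.out = 8),
                           seq(48.5, 62, length.out = 28)),
                     z = seq(32, 70, length.out = 36))
  spec$branch_spec <- list(list(points = long_side, radius = 2))
  inp <- phantom_tracking_inputs(spec)
  inp$seed$label <- "RCA"
  model_rca <- track_artery(inp$bin, inp$seed, preserve_len = 15,
                            preserve_terminal = TRUE)
  model_lad <- track_artery(inp$bin, inp$seed, preserve_terminal = FALSE)
  bm <- inp$phantom$truth$branch_masks[[1]] &
    !inp$phantom$truth$label_masks$LAD
  sep <- truth_separation_slice(inp$bin, inp$phantom$truth$label_masks$LAD,
                                inp$phantom$truth$branch_masks[[1]])
  distal <- array(FALSE, dim(bm)); distal[sep:dim(bm)[1], , ] <- bm[sep:dim(bm)[1], , ]
  ## preserved under the RCA rule, removed otherwise
  expect_gt(sum(model_rca$M & distal) / sum(distal), 0.8)
  expect_equal(sum(model_lad$M & distal), 0)
})

test_that("a one-slice gap is bridged by backtracking", {
  spec <- branching_spec(side = FALSE)
  inp <- phantom_tracking_inputs(spec)
  gap_z <- 50
  bin2 <- inp$bin; bin2[gap_z, , ] <- FALSE
  model <- track_artery(bin2, inp$seed, lookahead = 3)
  truth <- inp$phantom$truth$label_masks$LAD
  zs_truth <- which(apply(truth, 1, any))
  kp <- model$keypoints
  expect_equal(kp$z[kp$role == "end"], max(zs_truth))
  expect_true(gap_z %in% model$gaps)
  expect_gte(voxel_recall(model$M, truth), 0.95)
  ## without lookahead the tracking stops at the gap
  model0 <- track_artery(bin2, inp$seed, lookahead = 0)
  expect_equal(model0$keypoints$z[model0$keypoints$role == "end"], gap_z - 1)
})

test_that("the retained main path is the longest root-to-leaf path", {
  ## exhaustive oracle over the truth branch graph: candidate leaves are
  ## the main-curve end and each side-branch end; the main path must end
  ## at the deepest leaf
  spec <- branching_spec(rebif = TRUE)
  inp <- phantom_tracking_inputs(spec)
  model <- track_artery(inp$bin, inp$seed)
  leaf_depths <- c(
    main = max(which(apply(inp$phantom$truth$label_masks$LAD, 1, any))),
    vapply(inp$phantom$truth$branch_masks,
           function(b) max(which(apply(b, 1, any))), numeric(1)))
  expect_equal(model$keypoints$z[model$keypoints$role == "end"],
               unname(max(leaf_depths)))
  ## and the deepest leaf is the main curve, so recall stays high
  expect_gte(voxel_recall(model$M, inp$phantom$truth$label_masks$LAD), 0.95)
})

test_that("keypoint slices are ordered start <= bifurcations <= end", {
  spec <- branching_spec(rebif = TRUE)
  inp <- phantom_tracking_inputs(spec)
  model <- track_artery(inp$bin, inp$seed)
  kp <- model$keypoints
  zs <- kp$z[kp$role == "start"]; ze <- kp$z[kp$role == "end"]
  zb <- kp$z[kp$role == "bifurcation"]
  expect_true(all(zb >= zs & zb <= ze))
  ## M nonempty on every slice between start and end except gaps
  occ <- which(apply(model$M, 1, any))
  missing <- setdiff(seq(zs, ze), occ)
  expect_true(all(missing %in% model$gaps))
})

test_that("LM-style tracking stops at the first bifurcation and seeds LAD/LCX", {
  ## LM: short stem splitting into two separated daughters
  stem <- cbind(x = c(48, 48), y = c(30, 38), z = c(10, 24))
  lad <- cbind(x = seq(44, 34, length.out = 30), y = seq(40, 52, length.out = 30),
               z = seq(26, 58, length.out = 30))
  lcx <- cbind(x = seq(53, 62, length.out = 30), y = seq(40, 56, length.out = 30),
               z = seq(26, 58, length.out = 30))
  spec <- phantom_spec_3d(volume_size = c(64L, 96L, 96L),
                          artery_curves = list(LM = list(points = stem, radius = 3),
                                               LAD = list(points = lad, radius = 2.2),
                                               LCX = list(points = lcx, radius = 2.2)),
                          seed = 2)
  ph <- make_cta_phantom(spec)
  bin <- binarize_region4(to_hounsfield(ph$volume))
  kp <- ph$truth$keypoints$LM
  lm <- track_artery(bin, tracking_seed(kp$z[1], kp$y[1], kp$x[1], "LM"),
                     stop_at_bifurcation = TRUE)
  expect_true(any(lm$keypoints$role == "bifurcation"))
  seeds <- derive_lad_lcx_seeds(lm, bin)
  expect_match(seeds$assignment, "leftmost")
  ## each seed lies inside its truth daughter (LAD is leftmost: smaller x)
  sl <- seeds$LAD; sc <- seeds$LCX
  expect_true(ph$truth$label_masks$LAD[sl$z, sl$row, sl$col])
  expect_true(ph$truth$label_masks$LCX[sc$z, sc$row, sc$col])
  ## tracking each daughter from its derived seed recovers it
  mlad <- track_artery(bin, seeds$LAD)
  expect_gte(voxel_recall(mlad$M, ph$truth$label_masks$LAD), 0.9)
})

test_that("seed derivation fails without a bifurcation", {
  inp <- phantom_tracking_inputs(vertical_tube_spec())
  lm <- track_artery(inp$bin, inp$seed, stop_at_bifurcation = TRUE)
  expect_error(derive_lad_lcx_seeds(lm, inp$bin), "no bifurcation")
})

test_that("a three-way split is reported as ambiguous", {
  stem <- cbind(x = c(48, 48), y = c(30, 38), z = c(10, 24))
  d1 <- cbind(x = seq(42, 30, length.out = 20), y = seq(40, 50, length.out = 20),
              z = seq(26, 48, length.out = 20))
  d2 <- cbind(x = seq(54, 66, length.out = 20), y = seq(40, 50, length.out = 20),
              z = seq(26, 48, length.out = 20))
  d3 <- cbind(x = rep(48, 20), y = seq(41, 58, length.out = 20),
              z = seq(26, 48, length.out = 20))
  spec <- phantom_spec_3d(volume_size = c(56L, 96L, 96L),
                          artery_curves = list(LM = list(points = stem, radius = 3),
                                               A = list(points = d1, radius = 2),
                                               B = list(points = d2, radius = 2),
                                               C = list(points = d3, radius = 2)),
                          seed = 2)
  ph <- make_cta_phantom(spec)
  bin <- binarize_region4(to_hounsfield(ph$volume))
  kp <- ph$truth$keypoints$LM
  lm <- track_artery(bin, tracking_seed(kp$z[1], kp$y[1], kp$x[1], "LM"),
                     stop_at_bifurcation = TRUE)
  expect_error(derive_lad_lcx_seeds(lm, bin), "ambiguous|three")
})

test_that("vesselness binarization feeds tracking", {
  sp <- vertical_tube_spec(z0 = 8, z1 = 30, radius = 2.5,
                           size = c(36L, 48L, 48L))
  sp$body <- list(center_yx = c(32, 32), radius = 20)
  inp_truth <- make_cta_phantom(sp)
  huv <- to_hounsfield(inp_truth$volume)
  bin <- binarize_vesselness(huv, threshold = 0.15,
                             polarity = "bright_vessels")
  kp <- inp_truth$truth$keypoints$LAD
  expect_true(bin[kp$z[1], kp$y[1], kp$x[1]])
  model <- track_artery(bin, tracking_seed(kp$z[1], kp$y[1], kp$x[1], "LAD"))
  expect_gte(voxel_recall(model$M, inp_truth$truth$label_masks$LAD), 0.6)
})
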