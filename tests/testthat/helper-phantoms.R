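## Shared fixture builders: all fixtures are generated in code.

## straight 2D tube phantom
tube2d_spec <- function(width = 8, noise_sd = 0, seed = 1L,
                        size = c(128L, 128L)) {
  phantom_spec_2d(
    image_size = size,
    tree = list(list(poly = cbind(c(20, 110), c(30, 100)), width = width)),
    noise_sd = noise_sd, seed = seed)
}

## three-branch 2D tree (widths 4..8)
tree2d_spec <- function(noise_sd = 0, seed = 3L) {
  phantom_spec_2d(
    image_size = c(128L, 128L),
    tree = list(
      list(poly = cbind(c(10, 60, 110), c(64, 60, 50)), width = 7),
      list(poly = cbind(c(60, 100), c(60, 90)), width = 5),
      list(poly = cbind(c(85, 110), c(55, 20)), width = 4)),
    noise_sd = noise_sd, seed = seed)
}

## straight vertical 3D tube (axis along z) at (y0, x0), slices z0..z1
vertical_tube_spec <- function(z0 = 10, z1 = 40, y0 = 32, x0 = 32,
                               radius = 3, size = c(48L, 64L, 64L),
                               seed = 1L) {
  pts <- cbind(x = rep(x0 - 1, 2), y = rep(y0 - 1, 2), z = c(z0 - 1, z1 - 1))
  phantom_spec_3d(volume_size = size,
                  artery_curves = list(LAD = list(points = pts,
                                                  radius = radius)),
                  seed = seed)
}

## main artery + configurable side branches (coordinates 0-based);
## `scale` grows the geometry with the volume (e.g. 4/3 for 128^3)
branching_spec <- function(size = c(96L, 96L, 96L), side = TRUE,
                           rebif = FALSE, stenosis = NULL, seed = 7L,
                           scale = size[1] / 96) {
  tt <- seq(0, 1, length.out = 80)
  main <- cbind(x = 42 + 14 * sin(pi * tt),
                y = seq(30, 66, length.out = 80),
                z = seq(5, 88, length.out = 80))
  branches <- list()
  if (side) {
    branches <- list(
      list(points = cbind(x = main[20, "x"] + seq(0, 16, length.out = 12),
                          y = seq(39, 46, length.out = 12),
                          z = seq(25, 36, length.out = 12)), radius = 2),
      list(points = cbind(x = main[40, "x"] - seq(0, 18, length.out = 12),
                          y = seq(48, 54, length.out = 12),
                          z = seq(45, 56, length.out = 12)), radius = 2))
  }
  if (rebif) {
    reb <- cbind(x = main[53, "x"] + seq(0, 14, length.out = 11),
                 y = seq(55, 60, length.out = 11),
                 z = seq(60, 70, length.out = 11))
    rebA <- cbind(x = reb[11, "x"] + seq(0, 8, length.out = 9),
                  y = seq(60, 64, length.out = 9),
                  z = seq(70, 78, length.out = 9))
    rebB <- cbind(x = reb[11, "x"] - seq(0, 6, length.out = 9),
                  y = seq(60, 70, length.out = 9),
                  z = seq(70, 78, length.out = 9))
    branches <- c(branches, list(list(points = reb, radius = 2),
                                 list(points = rebA, radius = 1.8),
                                 list(points = rebB, radius = 1.8)))
  }
  branches <- lapply(branches, function(b) {
    b$points <- b$points * scale; b
  })
  phantom_spec_3d(volume_size = size,
                  artery_curves = list(LAD = list(points = main * scale,
                                                  radius = 3)),
                  stenosis = stenosis,
                  branch_spec = branches, seed = seed)
}

## tracking inputs from a 3D phantom: region-4 binarization + start seed
phantom_tracking_inputs <- function(spec, label = "LAD") {
  ph <- make_cta_phantom(spec)
  huv <- to_hounsfield(ph$volume)
  bin <- binarize_region4(huv)
  kp <- ph$truth$keypoints[[label]]
  list(phantom = ph, bin = bin,
       seed = tracking_seed(kp$z[1], kp$y[1], kp$x[1], label))
}

## first slice at which a side branch becomes a separate in-plane
## component from the main artery (truth-derived bifurcation slice)
truth_separation_slice <- function(bin, main_mask, branch_mask) {
  bm <- branch_mask & !main_mask
  for (z in seq_len(dim(bin)[1])) {
    if (!any(bm[z, , ])) next
    lab <- label_components(bin[z, , ])
    main_ids <- unique(lab[main_mask[z, , ] & lab > 0])
    br_ids <- unique(lab[bm[z, , ] & lab > 0])
    if (length(br_ids) > 0 && !any(br_ids %in% main_ids)) return(z)
  }
  NA_integer_
}
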