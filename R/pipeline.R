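## Pipeline orchestration: angiogram segmentation -> CTA tracking ->
## registration -> stenosis localization (-> evaluation against phantom
## truth when available), driven by a single config.

#' Pair control points by role, resolving the 2D orientation
#'
#' Builds ordered correspondence sets from the candidate control points
#' of both modalities: the start, the bifurcations in path order and the
#' final end point. Because the 2D start/end assignment is a heuristic
#' (a constant-width vessel gives no radius cue), both orientations of
#' the angiogram sequence are fitted and the one with the smaller mean
#' control-point residual is kept.
#'
#' @param pa data.frame of angiogram control points (`u`, `v`, `role`,
#'   in path order).
#' @param pc data.frame of projected CTA control points (`u`, `v`,
#'   `role`, start first).
#' @return list with `src` (CTA-side points), `dst` (angiogram-side),
#'   `T` (the fitted `affine2d`), `residuals` (per-point px) and
#'   `reversed` (logical).
#' @export
pair_control_points <- function(pa, pc) {
  seq_of <- function(df) {
    st <- df[df$role == "start", , drop = FALSE]
    bi <- df[df$role == "bifurcation", , drop = FALSE]
    en <- df[df$role == "end", , drop = FALSE]
    rbind(st[1, ], bi, en[nrow(en), ])
  }
  a <- seq_of(pa); c <- seq_of(pc)
  a <- a[stats::complete.cases(a[, 1:2]), ]
  c <- c[stats::complete.cases(c[, 1:2]), ]
  n <- min(nrow(a), nrow(c))
  if (n < 3) stop("need at least 3 control points on each side")
  ## trim to equal counts: keep start, the first bifurcations, the end
  trim <- function(df, n) {
    if (nrow(df) == n) return(df)
    rbind(df[1, ], df[2:(n - 1), ], df[nrow(df), ])[seq_len(n), ]
  }
  if (nrow(a) != nrow(c)) {
    keep <- function(df, n) rbind(df[1, ], utils::head(df[-c(1, nrow(df)), , drop = FALSE], n - 2), df[nrow(df), ])
    a <- keep(a, n); c <- keep(c, n)
  }
  fit <- function(dst_pts) {
    T <- estimate_affine(as.matrix(c[, 1:2]), as.matrix(dst_pts[, 1:2]))
    res <- apply_affine(as.matrix(c[, 1:2]), T) - as.matrix(dst_pts[, 1:2])
    list(T = T, res = sqrt(rowSums(res^2)))
  }
  fwd <- fit(a)
  rev_a <- a[rev(seq_len(nrow(a))), ]
  bwd <- fit(rev_a)
  if (mean(bwd$res) < mean(fwd$res)) {
    list(src = c, dst = rev_a, T = bwd$T, residuals = bwd$res,
         reversed = TRUE)
  } else {
    list(src = c, dst = a, T = fwd$T, residuals = fwd$res,
         reversed = FALSE)
  }
}

#' Default pipeline configuration for a phantom study
#'
#' Builds a self-contained config around a coronary-like phantom: a main
#' artery descending through the stack with two terminating side
#' branches, a mid-artery stenosis, and a view roughly perpendicular to
#' the artery course (as an angiographic projection would be).
#'
#' @param seed RNG seed propagated to every stochastic element.
#' @param noise_sd_2d angiogram noise sd (intensity units).
#' @param jitter_px control-point jitter sd applied on the angiogram
#'   side before the affine fit (emulates imprecise marking).
#' @return a config list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 1L, noise_sd_2d = 0,
                                 jitter_px = 0) {
  nzyx <- c(96L, 96L, 96L)
  ## main artery: descends through the stack with the gentle C-shaped
  ## course of a left coronary branch (curvature also conditions the
  ## control-point affine fit, as the bent course does clinically)
  tt <- seq(0, 1, length.out = 80)
  main <- cbind(x = 42 + 14 * sin(pi * tt),
                y = seq(30, 66, length.out = 80),
                z = seq(5, 88, length.out = 80))
  side1 <- cbind(x = main[20, "x"] + seq(0, 16, length.out = 12),
                 y = seq(39, 46, length.out = 12),
                 z = seq(25, 36, length.out = 12))
  side2 <- cbind(x = main[40, "x"] - seq(0, 18, length.out = 12),
                 y = seq(48, 54, length.out = 12),
                 z = seq(45, 56, length.out = 12))
  spec3d <- phantom_spec_3d(
    volume_size = nzyx,
    artery_curves = list(LAD = list(points = main, radius = 3)),
    stenosis = list(label = "LAD", position = 0.5, radius = 1.2),
    branch_spec = list(list(points = side1, radius = 2),
                       list(points = side2, radius = 2)),
    seed = seed)
  list(seed = as.integer(seed),
       phantom3d = spec3d,
       view = list(thx = -90, thy = 0, thz = 10),
       angio_noise_sd = noise_sd_2d,
       stenosis_uv = "truth",
       jitter_px = jitter_px,
       angio = list(min_length = 20L, min_len = 8L),
       labels = "auto",
       seeds = "truth",
       track = list(label = "LAD", binarize = "region4",
                    preserve_len = 15L, dilate_px = 3, lookahead = 3L),
       register = list(correspondences = "by_role", tol_px = 2,
                       snap_radius = 2))
}

#' Run the full two-modality pipeline
#'
#' Executes angiogram segmentation and labeling, CTA tracking,
#' registration and stenosis localization in order, evaluating against
#' phantom ground truth when available, and optionally writing a JSON
#' report plus stage artifacts. Re-running with an identical config and
#' seed reproduces all numeric fields exactly.
#'
#' @param cfg a config list (see [demo_pipeline_config()]); phantom mode
#'   requires `phantom3d` (a [phantom_spec_3d()]) and a `view`; file
#'   mode takes `angio_path` (PNG) and `cta_path` (volume container)
#'   plus explicit `seeds`, `labels`, `correspondences` and
#'   `stenosis_uv`.
#' @param out_dir optional output directory for the report and
#'   artifacts.
#' @return a report list: per-stage summaries, the transform `T`,
#'   control-point residuals, the stenosis voxel and mm coordinates, and
#'   (phantom mode) `truth_distance_voxels`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (is.null(cfg[["seed"]])) stop("config error: missing seed")
  report <- list(config_echo = list(seed = cfg[["seed"]], view = cfg$view),
                 stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  ## a YAML config can request the built-in phantom study by parameters
  if (!is.null(cfg$phantom_demo)) {
    demo <- do.call(demo_pipeline_config, cfg$phantom_demo)
    cfg <- utils::modifyList(demo, cfg[setdiff(names(cfg), "phantom_demo")])
  }

  ## ---- inputs ----------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$phantom3d)) {
    ph <- stage("phantom", make_cta_phantom(cfg$phantom3d))
    vol <- ph$volume; truth <- ph$truth
    view <- view_angles(cfg$view$thx, cfg$view$thy, cfg$view$thz)
    pp <- stage("phantom", project_phantom(
      truth, view, noise_sd = cfg$angio_noise_sd %||% 0,
      seed = cfg[["seed"]]))
    angio_img <- pp$image
    stenosis_uv <- if (identical(cfg$stenosis_uv, "truth"))
      pp$truth2d$stenosis_uv else cfg$stenosis_uv
  } else {
    if (is.null(cfg$angio_path) || is.null(cfg$cta_path))
      stop("config error: need phantom3d or angio_path + cta_path")
    angio_img <- stage("input", read_gray_image(cfg$angio_path))
    vol <- stage("input", read_cta_volume(cfg$cta_path))
    view <- view_angles(cfg$view$thx, cfg$view$thy, cfg$view$thz)
    stenosis_uv <- cfg$stenosis_uv
  }
  if (is.null(stenosis_uv)) stop("config error: missing stenosis_uv")

  ## ---- angiogram stage -------------------------------------------------
  acfg <- cfg$angio %||% list()
  den <- stage("angio", denoise_dwt(angio_img))
  seg <- stage("angio", segment_main_arteries(
    den, min_length = acfg$min_length %||% 30L))
  cs <- stage("angio", detach_and_label(
    extract_centerlines(seg), min_len = acfg$min_len %||% 10L))
  report$stages$angio <- list(segmented_px = sum(seg),
                              n_labels = max(cs$labels))

  ## ---- CTA stage -------------------------------------------------------
  tcfg <- cfg$track %||% list()
  huv <- stage("cta", to_hounsfield(vol))
  bin <- stage("cta", if (identical(tcfg$binarize %||% "region4", "frangi"))
    binarize_vesselness(huv, threshold = tcfg$threshold %||% 0.15)
    else binarize_region4(huv))
  label <- tcfg$label %||% "LAD"
  seed3 <- if (identical(cfg$seeds, "truth")) {
    if (is.null(truth)) stop("config error: seeds = 'truth' without phantom")
    kp <- truth$keypoints[[label]]
    tracking_seed(kp$z[1], kp$y[1], kp$x[1], label)
  } else {
    s <- cfg$seeds[[label]]
    if (is.null(s)) stop("config error: no seed for requested label ", label)
    tracking_seed(s[1], s[2], s[3], label)
  }
  model <- stage("cta", track_artery(
    bin, seed3, preserve_len = tcfg$preserve_len %||% 15L,
    dilate_px = tcfg$dilate_px %||% 3, lookahead = tcfg$lookahead %||% 3L))
  report$stages$cta <- list(voxels = sum(model$M),
                            keypoints = model$keypoints,
                            gaps = model$gaps)

  ## ---- registration stage ----------------------------------------------
  rcfg <- cfg$register %||% list()
  proj <- stage("register", rotate_and_project(model, view))
  ## 2D label selection: config labels, or overlap with the projected model
  sel <- cfg$labels %||% "auto"
  if (identical(sel, "auto")) {
    support <- dilate_disc(proj$mask, 2)
    sel <- integer(0)
    for (id in seq_len(max(cs$labels))) {
      px <- which(cs$labels == id)
      if (length(px) > 0 && mean(support[px]) > 0.5) sel <- c(sel, id)
    }
    if (length(sel) == 0) stop("stage [register]: no 2D centreline overlaps the projected artery")
  }
  la <- stage("register", label_artery(sel, cs, seg))
  pa <- la$control_points
  if (!is.null(cfg$jitter_px) && cfg$jitter_px > 0) {
    pa[, c("u", "v")] <- with_seed(cfg[["seed"]] + 1L,
      pa[, c("u", "v")] +
        matrix(stats::rnorm(2 * nrow(pa), 0, cfg$jitter_px), ncol = 2))
  }
  corr <- rcfg$correspondences %||% "by_role"
  if (identical(corr, "by_role")) {
    pairing <- stage("register", pair_control_points(pa, proj$points))
  } else {
    ## explicit ordered index pairs [[i, j], ...] into P_A / P_C
    idx <- do.call(rbind, corr)
    src <- proj$points[idx[, 2], 1:2]
    dst <- pa[idx[, 1], 1:2]
    T0 <- estimate_affine(as.matrix(src), as.matrix(dst))
    res <- apply_affine(as.matrix(src), T0) - as.matrix(dst)
    pairing <- list(src = proj$points[idx[, 2], ], dst = pa[idx[, 1], ],
                    T = T0, residuals = sqrt(rowSums(res^2)),
                    reversed = FALSE)
  }
  ireg <- stage("register", register_artery(la$artery_mask, proj, pairing$T))
  loc <- stage("register", localize_stenosis(
    ireg, stenosis_uv, pairing$T, tol_px = rcfg$tol_px %||% 2))
  bp <- stage("register", back_project(
    loc, proj, spacing = vol$spacing,
    snap_radius = rcfg$snap_radius %||% 2))
  report$transform <- unclass(pairing$T)
  report$control_point_residuals <- pairing$residuals
  report$stages$register <- list(
    selected_labels = sel, n_control_points = nrow(pairing$dst),
    orientation_reversed = pairing$reversed,
    overlap_dice = dice_overlap(ireg$angio, ireg$cta),
    method = loc$method)
  report$stenosis <- list(marked_uv = as.numeric(stenosis_uv),
                          voxel = bp$voxel, mm = bp$mm)

  ## ---- evaluation against truth ---------------------------------------
  if (!is.null(truth)) {
    tv <- truth$stenosis_voxel
    report$evaluation <- list(
      truth_voxel = tv,
      truth_distance_voxels = sqrt(sum((bp$voxel - tv)^2)),
      tracking_recall = voxel_recall(model$M, truth$label_masks[[label]]))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gray_image(angio_img, file.path(out_dir, "angiogram.png"))
    write_gray_image(seg * 255, file.path(out_dir, "angio_segmentation.png"))
    write_control_points(pa, file.path(out_dir, "control_points_2d.csv"))
    write_keypoints(model, file.path(out_dir, "keypoints_3d.csv"))
    write_ply(model, file.path(out_dir, "artery_model.ply"),
              spacing = vol$spacing)
    overlay <- matrix(0, nrow(ireg$cta), ncol(ireg$cta))
    overlay[ireg$cta] <- 128; overlay[ireg$angio] <- overlay[ireg$angio] + 127
    write_gray_image(overlay, file.path(out_dir, "registration_overlay.png"))
    jsonlite::write_json(
      rapply(report, function(x) if (is.matrix(x)) as.data.frame(x) else x,
             how = "replace"),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  report
}

#' Read a pipeline config from YAML
#' @param path YAML file path.
#' @return config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
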