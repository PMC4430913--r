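#' @title Image and volume conventions
#'
#' @description
#' Throughout the package a 2D grayscale image is a plain numeric matrix
#' indexed `[row, col]` (1-based, origin top-left). Point coordinates on an
#' image are written `(u, v)` with `u = col - 1` and `v = row - 1`, i.e.
#' 0-based, matching the pixel-coordinate convention of the registration
#' equations. A 3D volume is a numeric or logical array with
#' `dim = c(nz, ny, nx)` indexed `[z, y, x]` (slice, row, col; 1-based,
#' slices counted from the top of the stack). Cartesian voxel coordinates
#' are `(x, y, z) = (x_idx - 1, y_idx - 1, z_idx - 1)`.
#'
#' @name stenoreg-conventions
#' @keywords internal
NULL

## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_gray_image <- function(img, min_dim = 2L, what = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix")
  if (any(dim(img) < min_dim))
    stop(what, " must be at least ", min_dim, "x", min_dim)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values")
  invisible(img)
}

assert_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(what, " must be a logical matrix")
  invisible(mask)
}

## Whole-sample mirror reflection of out-of-range indices (edge not repeated).
mirror_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx >= n, period - idx, idx)
  idx + 1L
}

## 1D convolution of `img` along rows (margin = 1) or cols (margin = 2) with
## taps placed at integer `offsets`, mirror boundary. sum(taps) need not be 1.
conv_taps <- function(img, taps, offsets, margin) {
  n <- dim(img)[margin]
  out <- matrix(0, nrow(img), ncol(img))
  for (k in seq_along(taps)) {
    idx <- mirror_index(seq_len(n) + offsets[k], n)
    out <- out + taps[k] * (if (margin == 1L) img[idx, , drop = FALSE]
                            else img[, idx, drop = FALSE])
  }
  out
}

## Separable 2D convolution: taps_r along rows then taps_c along cols.
conv_sep <- function(img, taps_r, offsets_r, taps_c = taps_r,
                     offsets_c = offsets_r) {
  conv_taps(conv_taps(img, taps_r, offsets_r, 1L), taps_c, offsets_c, 2L)
}

## Centered symmetric 1D kernels get offsets -r..r.
centered_offsets <- function(taps) {
  r <- (length(taps) - 1L) / 2L
  if (r != floor(r)) stop("centered kernel must have odd length")
  seq.int(-r, r)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Sample 1D Gaussian and its derivatives on -r..r.
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  list(x = x,
       g = g,
       g1 = -x / sigma^2 * g,
       g2 = (x^2 - sigma^2) / sigma^4 * g)
}
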