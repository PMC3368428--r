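#' Gaussian smoothing of a 2D map
#'
#' Separable Gaussian convolution with reflective boundary handling; the
#' discrete kernel is normalised to unit sum, so constant maps pass through
#' unchanged.  The default usage smooths fMRI parameter maps with sigma =
#' 489 um, the FOV-scale voxel.
#'
#' @param map numeric matrix.
#' @param sigma_um kernel sigma in microns (0 returns the map unchanged).
#' @param pixel_um pixel size of `map` in microns.
#' @return Smoothed matrix.
#' @export
smooth_map <- function(map, sigma_um, pixel_um) {
  if (sigma_um < 0) stop("sigma_um must be >= 0")
  if (sigma_um == 0) return(map)
  sig <- sigma_um / pixel_um
  r <- max(1L, ceiling(4 * sig))
  k <- exp(-((-r):r)^2 / (2 * sig^2))
  k <- k / sum(k)
  pad_reflect <- function(x, r) {
    n <- nrow(x)
    idx <- c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
    x[idx, , drop = FALSE]
  }
  conv_rows <- function(x) {
    xp <- pad_reflect(x, r)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(map))))
}

# Keys bicubic kernel, a = -0.5 (reproduces quadratics exactly)
cubic_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

# 1D resampling matrix mapping n_in samples onto coords (0-based centres)
resample_matrix <- function(coords, n_in, kernel = cubic_kernel) {
  W <- matrix(0, length(coords), n_in)
  for (j in seq_along(coords)) {
    c0 <- coords[j]
    base <- floor(c0)
    taps <- (base - 1):(base + 2)
    w <- kernel(c0 - taps)
    taps <- pmin(pmax(taps, 0), n_in - 1L)   # clamp at edges
    for (i in seq_along(taps))
      W[j, taps[i] + 1L] <- W[j, taps[i] + 1L] + w[i]
  }
  sw <- rowSums(W)
  W / ifelse(sw == 0, 1, sw)
}

#' Cubic subsampling of a map
#'
#' Resamples a map to `round(dim * scale)` using separable Keys bicubic
#' interpolation (output pixel centres mapped back into the input grid).
#' `scale = 1` is the identity up to numerical noise.
#'
#' @param map numeric matrix.
#' @param scale resampling factor in `(0, 1]`.
#' @param method `"cubic"` (default) or `"bilinear"`.
#' @return The resampled matrix.
#' @export
subsample_map <- function(map, scale, method = c("cubic", "bilinear")) {
  method <- match.arg(method)
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  ny <- nrow(map); nx <- ncol(map)
  oy <- round(ny * scale); ox <- round(nx * scale)
  if (oy < 2 || ox < 2) stop("output smaller than 2 pixels")
  cy <- ((seq_len(oy) - 0.5) / scale) - 0.5
  cx <- ((seq_len(ox) - 0.5) / scale) - 0.5
  kern <- if (method == "cubic") cubic_kernel else
    function(x) pmax(0, 1 - abs(x))
  Wy <- resample_matrix(cy, ny, kern)
  Wx <- resample_matrix(cx, nx, kern)
  Wy %*% map %*% t(Wx)
}

# bilinear sample of a matrix at fractional 0-based (y, x); outside -> NA
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  ok <- y >= 0 & y <= ny - 1 & x >= 0 & x <= nx - 1
  y0 <- pmin(pmax(floor(y), 0), ny - 2); x0 <- pmin(pmax(floor(x), 0), nx - 2)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0 + 1, x0 + 1); i10 <- cbind(y0 + 2, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2); i11 <- cbind(y0 + 2, x0 + 2)
  v <- (1 - fy) * (1 - fx) * img[i00] + fy * (1 - fx) * img[i10] +
    (1 - fy) * fx * img[i01] + fy * fx * img[i11]
  v[!ok] <- NA_real_
  v
}

#' Affine template correlation
#'
#' Exhaustive search over uniform scale, rotation and integer translation
#' for the placement of a template within a target map that maximises the
#' zero-mean normalised cross-correlation.  For each (scale, angle) the
#' template is resampled about its centre; pixels falling outside the
#' original support are masked out of the correlation.  The default grids
#' bracket the expected optics-to-fMRI resolution ratio (~0.17).
#'
#' @param template numeric matrix with non-zero variance.
#' @param target numeric matrix, larger than the scaled template.
#' @param scale_grid,angle_grid search grids.
#' @param step_px translation step in pixels (1 = exhaustive).
#' @return An `affine_match` list: `scale`, `angle_deg`, `tx_px`, `ty_px`
#'   (0-based offsets of the warped template within the target),
#'   `correlation`, and the warped template of the best match.
#' @export
match_template <- function(template, target,
                           scale_grid = seq(0.10, 0.25, by = 0.01),
                           angle_grid = seq(-15, 15, by = 1),
                           step_px = 1) {
  if (sd(as.vector(template)) == 0)
    stop("zero-variance template: correlation undefined")
  best <- list(correlation = -Inf)
  ny <- nrow(template); nx <- ncol(template)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  for (s in scale_grid) {
    oy <- max(2L, round(ny * s)); ox <- max(2L, round(nx * s))
    ocy <- (oy - 1) / 2; ocx <- (ox - 1) / 2
    if (oy >= nrow(target) || ox >= ncol(target)) next
    gy <- matrix(seq_len(oy) - 1 - ocy, oy, ox)
    gx <- matrix(seq_len(ox) - 1 - ocx, oy, ox, byrow = TRUE)
    for (a in angle_grid) {
      th <- a * pi / 180
      # inverse map: rotate by -a, scale by 1/s, about centres
      sy <- (cos(th) * gy - sin(th) * gx) / s + cy
      sx <- (sin(th) * gy + cos(th) * gx) / s + cx
      w <- matrix(bilinear_sample(template, as.vector(sy), as.vector(sx)),
                  oy, ox)
      mask <- !is.na(w)
      if (sum(mask) < 4) next
      w[!mask] <- 0
      cc <- tryCatch(
        .ncc_offsets_cpp(target, w, mask + 0),
        error = function(e) NULL)
      if (is.null(cc)) next
      if (step_px > 1) {
        keep_r <- seq(1, nrow(cc), by = step_px)
        keep_c <- seq(1, ncol(cc), by = step_px)
        cc <- cc[keep_r, keep_c, drop = FALSE]
        rr <- keep_r; rc <- keep_c
      } else {
        rr <- seq_len(nrow(cc)); rc <- seq_len(ncol(cc))
      }
      mx <- which.max(cc)
      if (cc[mx] > best$correlation) {
        iy <- (mx - 1) %% nrow(cc) + 1
        ix <- (mx - 1) %/% nrow(cc) + 1
        best <- list(scale = s, angle_deg = a,
                     ty_px = rr[iy] - 1L, tx_px = rc[ix] - 1L,
                     correlation = cc[mx], warped_template = w,
                     mask = mask)
      }
    }
  }
  if (!is.finite(best$correlation))
    stop("no feasible (scale, angle) placement found")
  structure(best, class = "affine_match")
}

#' @export
print.affine_match <- function(x, ...) {
  cat(sprintf(
    "Affine match: scale %.3g, angle %g deg, offset (ty=%d, tx=%d), r = %.4f\n",
    x$scale, x$angle_deg, x$ty_px, x$tx_px, x$correlation))
  invisible(x)
}

#' Least-squares projective transform from point pairs
#'
#' Direct linear estimate of the 3x3 homography mapping `src` to `dst`
#' (bottom-right element fixed to 1).  Four exact pairs give an exact
#' projection (zero residual); more pairs give the least-squares solution.
#' Points are `(x, y)` 0-based pixel-centre coordinates.
#'
#' @param src,dst `n x 2` matrices of corresponding points, `n >= 4`.
#' @return A `homography`: the matrix `H`, per-point `residuals_px`, and
#'   `rms_px`.
#' @export
fit_projective_transform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n || ncol(src) != 2 || ncol(dst) != 2)
    stop("need >= 4 point pairs of (x, y) coordinates")
  A <- matrix(0, 2 * n, 8)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  qa <- qr(A)
  if (qa$rank < 8)
    stop("degenerate point configuration (collinear or repeated points)")
  h <- qr.coef(qa, b)
  H <- rbind(matrix(h[1:6], 2, 3, byrow = TRUE), c(h[7], h[8], 1))
  mapped <- apply_homography(H, src)
  res <- sqrt(rowSums((mapped - dst)^2))
  structure(list(H = H, residuals_px = res,
                 rms_px = sqrt(mean(res^2))), class = "homography")
}

#' Apply a homography to points
#'
#' @param H 3x3 projective matrix (or a `homography` object).
#' @param pts `n x 2` matrix of `(x, y)` points.
#' @return `n x 2` matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  if (inherits(H, "homography")) H <- H$H
  pts <- as.matrix(pts)
  ph <- cbind(pts, 1) %*% t(H)
  ph[, 1:2] / ph[, 3]
}

#' Warp an image through a homography
#'
#' Inverse-mapped bilinear resampling: each output pixel is pulled from the
#' source image through `H^-1`; pixels mapping outside the source are
#' filled with `fill`.
#'
#' @param image numeric matrix.
#' @param h a [fit_projective_transform()] result or 3x3 matrix.
#' @param output_dim `(ny, nx)` of the output (default the input size).
#' @param fill sentinel for out-of-domain pixels (default `NA`).
#' @return Warped matrix.
#' @export
warp_image <- function(image, h, output_dim = dim(image), fill = NA_real_) {
  H <- if (inherits(h, "homography")) h$H else h
  if (abs(det(H)) < 1e-12) stop("singular homography")
  Hi <- solve(H)
  ny <- output_dim[1]; nx <- output_dim[2]
  gx <- rep(seq_len(nx) - 1, each = ny)
  gy <- rep(seq_len(ny) - 1, times = nx)
  srcp <- apply_homography(Hi, cbind(gx, gy))
  v <- bilinear_sample(image, srcp[, 2], srcp[, 1])
  v[is.na(v)] <- fill
  matrix(v, ny, nx)
}
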