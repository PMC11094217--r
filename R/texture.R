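# Texture descriptors for the segmented cell ROI: Haralick statistics of
# gray-level co-occurrence matrices at two distances and four orientations,
# a uniform local-binary-pattern histogram, and mean/sd responses of a
# 2-frequency x 4-orientation Gabor bank. Concatenated in a fixed,
# documented order into the 58-value feature vector.

#' GLCM configuration
#'
#' @param levels Gray re-quantization levels (uniform binning of \[0,255\]).
#' @param distances Pixel-pair distances.
#' @param angles Orientations in degrees.
#' @param symmetric Add the transposed counts (order-independent pairs).
#' @param normalize Scale counts to sum to 1.
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(levels = 8, distances = c(1, 2),
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, normalize = TRUE) {
  stopifnot(levels >= 2, all(distances >= 1))
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances), angles = angles,
                 symmetric = isTRUE(symmetric),
                 normalize = isTRUE(normalize)),
            class = "glcm_config")
}

#' Gabor filter-bank configuration
#'
#' Eight filters: every combination of `frequencies` (cycles/pixel) and
#' `orientations` (degrees), with a square kernel, Gaussian envelope width
#' `sigma`, phase `psi` and aspect ratio `gamma_aspect`.
#'
#' @param frequencies Spatial frequencies in cycles/pixel.
#' @param orientations Orientations in degrees.
#' @param kernel_size Odd kernel side length.
#' @param sigma Envelope standard deviation (pixels).
#' @param psi Phase offset (radians).
#' @param gamma_aspect Spatial aspect ratio.
#' @return A `gabor_config` list.
#' @export
gabor_config <- function(frequencies = c(0.3, 0.6),
                         orientations = c(0, 45, 90, 135),
                         kernel_size = 5, sigma = 2.0, psi = 0,
                         gamma_aspect = 1.0) {
  if (kernel_size %% 2 != 1) stop("kernel side must be odd", call. = FALSE)
  structure(list(frequencies = frequencies, orientations = orientations,
                 kernel_size = as.integer(kernel_size), sigma = sigma,
                 psi = psi, gamma_aspect = gamma_aspect),
            class = "gabor_config")
}

# uniform re-quantization of [0,255] into `levels` bins -> values 0..levels-1
quantize_levels <- function(m, levels) {
  q <- (as.vector(m) * levels) %/% 256L
  matrix(pmin(q, levels - 1L), nrow(m), ncol(m))
}

glcm_offset <- function(d, angle) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d), "180" = c(0L, -d), "225" = c(d, -d),
         "270" = c(d, 0L), "315" = c(d, d),
         stop("unsupported GLCM angle: ", angle, call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring quantized levels at displacement `(d, angle)`; pairs
#' with either pixel outside the frame are skipped. Symmetrization adds the
#' transpose; normalization scales to total mass 1.
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param d Pixel distance.
#' @param angle Orientation in degrees (0, 45, 90, 135, or +180 variants).
#' @param cfg A [glcm_config()].
#' @return `levels` x `levels` matrix.
#' @export
glcm <- function(img, d = 1, angle = 0, cfg = glcm_config()) {
  m <- as_gray_matrix(img)
  q <- quantize_levels(m, cfg$levels)
  off <- glcm_offset(as.integer(d), angle)
  nr <- nrow(q); nc <- ncol(q)
  rlo <- max(1L, 1L - off[1]); rhi <- min(nr, nr - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(nc, nc - off[2])
  if (rhi < rlo || chi < clo)
    stop("image smaller than GLCM displacement", call. = FALSE)
  r0 <- rlo:rhi; c0 <- clo:chi
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off[1], c0 + off[2], drop = FALSE]
  L <- cfg$levels
  counts <- tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L)
  P <- matrix(counts, L, L, byrow = TRUE)  # row = first pixel's level
  if (cfg$symmetric) P <- P + t(P)
  if (cfg$normalize) P <- P / sum(P)
  P
}

#' Haralick statistics of a co-occurrence matrix
#'
#' With 0-based level indices and marginal moments of the normalized
#' matrix: contrast \eqn{\sum (i-j)^2 P_{ij}}, energy \eqn{\sum P_{ij}^2},
#' entropy \eqn{-\sum P_{ij}\log_2 P_{ij}} and correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j)P_{ij}/(\sigma_i\sigma_j)}. A degenerate
#' single-level matrix (zero marginal variance) has correlation 1 by
#' convention.
#'
#' @param P Normalized co-occurrence matrix (sums to 1).
#' @return Named numeric vector (contrast, energy, entropy, correlation).
#' @export
glcm_stats <- function(P) {
  if (abs(sum(P) - 1) > 1e-8)
    stop("co-occurrence matrix must be normalized", call. = FALSE)
  L <- nrow(P)
  i <- matrix(rep(0:(L - 1), times = L), L, L)  # row index, 0-based
  j <- matrix(rep(0:(L - 1), each = L), L, L)   # col index, 0-based
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  pi_ <- rowSums(P); pj <- colSums(P)
  mi <- sum((0:(L - 1)) * pi_); mj <- sum((0:(L - 1)) * pj)
  si <- sqrt(sum((0:(L - 1) - mi)^2 * pi_))
  sj <- sqrt(sum((0:(L - 1) - mj)^2 * pj))
  correlation <- if (si == 0 || sj == 0) 1 else
    sum((i - mi) * (j - mj) * P) / (si * sj)
  c(contrast = contrast, energy = energy, entropy = entropy,
    correlation = correlation)
}

#' Uniform local-binary-pattern histogram
#'
#' For each interior pixel, an 8-bit code thresholds the 8 ring neighbors
#' (radius 1) at the center value (`>=` gives 1), ordered east then
#' counterclockwise. Codes whose circular 0/1 transition count is at most 2
#' ("uniform") are binned by their number of ones (9 bins); all others
#' share a tenth bin. The histogram is normalized to sum 1. Invariant to
#' any strictly increasing intensity remap.
#'
#' @param img A [gray_image()] or intensity matrix, at least 3x3.
#' @return Numeric vector of 10 bin frequencies.
#' @export
lbp_histogram <- function(img) {
  m <- as_gray_matrix(img)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) stop("image too small for LBP", call. = FALSE)
  ctr <- m[2:(nr - 1), 2:(nc - 1)]
  # neighbor offsets (row, col): east, NE, north, NW, west, SW, south, SE
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bits <- vector("list", 8)
  for (k in 1:8) {
    o <- offs[[k]]
    bits[[k]] <- m[2:(nr - 1) + o[1], 2:(nc - 1) + o[2]] >= ctr
  }
  ones <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(1:8, function(k)
    bits[[k]] != bits[[k %% 8 + 1]]))
  bin <- ifelse(trans <= 2, ones + 1L, 10L)
  h <- tabulate(bin, nbins = 10L)
  h / sum(h)
}

#' Gabor kernel
#'
#' \eqn{g(x,y)=\exp(-(x'^2+\gamma^2 y'^2)/(2\sigma^2))
#' \cos(2\pi f x' + \psi)} on the theta-rotated, kernel-centered grid,
#' mean-subtracted so the kernel has zero DC response.
#'
#' @param size Odd kernel side length.
#' @param frequency Cycles per pixel.
#' @param theta Orientation in degrees.
#' @param sigma Envelope standard deviation.
#' @param psi Phase offset (radians).
#' @param gamma_aspect Aspect ratio of the envelope.
#' @return `size` x `size` numeric kernel summing to 0.
#' @export
gabor_kernel <- function(size = 5, frequency = 0.6, theta = 0, sigma = 2.0,
                         psi = 0, gamma_aspect = 1.0) {
  if (size %% 2 != 1) stop("kernel side must be odd", call. = FALSE)
  half <- (size - 1) / 2
  x <- matrix(rep(-half:half, each = size), size, size)   # column offset
  y <- matrix(rep(-half:half, times = size), size, size)  # row offset
  th <- theta * pi / 180
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  g <- exp(-(xr^2 + gamma_aspect^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * frequency * xr + psi)
  g - mean(g)
}

# 2-D convolution (correlation with the symmetric-grid kernel) with reflect
# padding, realized as a sum of shifted copies — fast for small kernels
convolve2d_reflect <- function(m, kern) {
  k <- nrow(kern); half <- (k - 1L) %/% 2L
  pm <- reflect_pad(m, half)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    w <- kern[dr + 1L, dc + 1L]
    if (w != 0)
      out <- out + w * pm[dr + seq_len(nr), dc + seq_len(nc)]
  }
  out
}

#' Gabor-bank response statistics
#'
#' Convolves the image (reflect padding) with each kernel of the bank,
#' takes absolute responses and emits their mean and standard deviation:
#' 2 values x 8 filters = 16 features, frequency-major then orientation.
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param cfg A [gabor_config()].
#' @return Named numeric vector of 16 values.
#' @export
gabor_features <- function(img, cfg = gabor_config()) {
  m <- as_gray_matrix(img) * 1.0
  if (min(dim(m)) < cfg$kernel_size)
    stop("image smaller than Gabor kernel", call. = FALSE)
  out <- numeric(0)
  for (f in cfg$frequencies) for (th in cfg$orientations) {
    kern <- gabor_kernel(cfg$kernel_size, f, th, cfg$sigma, cfg$psi,
                         cfg$gamma_aspect)
    resp <- abs(convolve2d_reflect(m, kern))
    nm <- sprintf("gabor_f%g_t%g", f, th)
    out <- c(out, stats::setNames(c(mean(resp), stats::sd(resp)),
                                  paste0(nm, c("_mean", "_sd"))))
  }
  out
}

#' Canonical feature names
#'
#' @param glcm_cfg A [glcm_config()].
#' @param gabor_cfg A [gabor_config()].
#' @return Character vector of the 58 canonical feature names.
#' @export
feature_names <- function(glcm_cfg = glcm_config(),
                          gabor_cfg = gabor_config()) {
  stats_names <- c("contrast", "energy", "entropy", "correlation")
  g <- character(0)
  for (d in glcm_cfg$distances) for (a in glcm_cfg$angles)
    g <- c(g, sprintf("glcm_d%d_a%g_%s", d, a, stats_names))
  l <- sprintf("lbp_u%02d", 1:10)
  gb <- character(0)
  for (f in gabor_cfg$frequencies) for (th in gabor_cfg$orientations)
    gb <- c(gb, sprintf("gabor_f%g_t%g_%s", f, th, c("mean", "sd")))
  c(g, l, gb)
}

#' Extract the full texture feature vector
#'
#' Fixed order: 32 GLCM statistics (distance-major, angle-minor; per cell
#' contrast, energy, entropy, correlation), 10 uniform-LBP bins, 16 Gabor
#' statistics.
#'
#' @param img Preprocessed ROI image.
#' @param glcm_cfg A [glcm_config()].
#' @param gabor_cfg A [gabor_config()].
#' @param lbp_on_gabor If `TRUE`, compute the LBP histogram on the summed
#'   absolute Gabor response instead of the raw ROI.
#' @return Named numeric vector of length 58, all finite.
#' @export
extract_features <- function(img, glcm_cfg = glcm_config(),
                             gabor_cfg = gabor_config(),
                             lbp_on_gabor = FALSE) {
  m <- as_gray_matrix(img)
  out <- numeric(0)
  for (d in glcm_cfg$distances) for (a in glcm_cfg$angles) {
    st <- glcm_stats(glcm(m, d, a, glcm_cfg))
    names(st) <- sprintf("glcm_d%d_a%g_%s", d, a, names(st))
    out <- c(out, st)
  }
  lbp_src <- if (lbp_on_gabor) {
    resp <- matrix(0, nrow(m), ncol(m))
    for (f in gabor_cfg$frequencies) for (th in gabor_cfg$orientations)
      resp <- resp + abs(convolve2d_reflect(
        m * 1.0, gabor_kernel(gabor_cfg$kernel_size, f, th, gabor_cfg$sigma,
                              gabor_cfg$psi, gabor_cfg$gamma_aspect)))
    gray_image(pmin(pmax(round(resp / max(resp, 1e-12) * 255), 0), 255))
  } else m
  lbp <- stats::setNames(lbp_histogram(lbp_src), sprintf("lbp_u%02d", 1:10))
  out <- c(out, lbp, gabor_features(m, gabor_cfg))
  stopifnot(all(is.finite(out)))
  out
}

#' Fit a z-score feature transform on training vectors
#'
#' Per-feature standardization using the training mean and standard
#' deviation; zero-variance features are dropped and the kept-index list
#' recorded so the identical transform applies at test time.
#'
#' @param X Numeric matrix, one row per training sample.
#' @return List with `transform` (mean, sd, keep indices, names) and `X`
#'   (the transformed training matrix).
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training vectors", call. = FALSE)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  keep <- which(sd_ > 1e-12)
  tr <- list(mean = mu[keep], sd = sd_[keep], keep = keep,
             names = colnames(X)[keep])
  list(transform = tr, X = apply_standardization(tr, X))
}

#' Apply a stored feature transform
#'
#' @param transform The `transform` element from [standardize_features()].
#' @param X Feature matrix (or single vector) on the original scale.
#' @return Standardized matrix restricted to the kept features.
#' @export
apply_standardization <- function(transform, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xk <- X[, transform$keep, drop = FALSE]
  sweep(sweep(Xk, 2, transform$mean, "-"), 2, transform$sd, "/")
}
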