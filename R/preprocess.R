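# Pre-segmentation enhancement: median filtering for impulse noise, wavelet
# shrinkage (Daubechies-4, universal threshold) for Gaussian noise, min-max
# intensity normalization. The stage order is configurable because median
# filtering and wavelet denoising are both legitimate first steps.

#' Preprocessing configuration
#'
#' @param median_kernel Odd window side for the median filter; the
#'   default 1 disables it (wavelet shrinkage is the default denoiser; the
#'   median stage is for impulse noise and moves region-boundary pixels,
#'   which costs segmentation accuracy on clean images).
#' @param wavelet_levels Decomposition levels for wavelet denoising; 0
#'   disables.
#' @param threshold_rule `"soft"` (shrinkage) or `"hard"` (keep/kill).
#' @param threshold_scale Multiplier on the universal threshold
#'   \eqn{\hat\sigma\sqrt{2\log n}}.
#' @param order Character vector of stage names from
#'   `c("median", "wavelet", "normalize")`, applied left to right.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(median_kernel = 1, wavelet_levels = 2,
                              threshold_rule = c("soft", "hard"),
                              threshold_scale = 1,
                              order = c("median", "wavelet", "normalize")) {
  threshold_rule <- match.arg(threshold_rule)
  if (median_kernel %% 2 != 1 || median_kernel < 1)
    stop("median kernel must be an odd integer >= 1", call. = FALSE)
  if (wavelet_levels < 0) stop("wavelet_levels must be >= 0", call. = FALSE)
  bad <- setdiff(order, c("median", "wavelet", "normalize"))
  if (length(bad)) stop("unknown preprocessing stage(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(median_kernel = as.integer(median_kernel),
                 wavelet_levels = as.integer(wavelet_levels),
                 threshold_rule = threshold_rule,
                 threshold_scale = threshold_scale,
                 order = order),
            class = "preprocess_config")
}

# reflect-pad a matrix by `p` pixels on every side
reflect_pad <- function(m, p) {
  if (p == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(p, nr))), seq_len(nr),
          nr + 1 - seq_len(min(p, nr)))
  ci <- c(rev(seq_len(min(p, nc))), seq_len(nc),
          nc + 1 - seq_len(min(p, nc)))
  m[ri, ci]
}

#' Median filter with reflect padding
#'
#' Each pixel is replaced by the median of its `kernel` x `kernel`
#' neighborhood; borders are reflect-padded so output size equals input.
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param kernel Odd window side length.
#' @return A [gray_image()].
#' @export
median_filter <- function(img, kernel = 3) {
  if (kernel %% 2 != 1 || kernel < 1)
    stop("median kernel must be an odd integer >= 1", call. = FALSE)
  m <- as_gray_matrix(img)
  if (kernel == 1) return(gray_image(m))
  p <- (kernel - 1L) %/% 2L
  pm <- reflect_pad(m, p)
  nr <- nrow(m); nc <- ncol(m)
  k2 <- kernel * kernel
  stack <- matrix(0L, nr * nc, k2)
  s <- 0L
  for (dc in 0:(kernel - 1L)) for (dr in 0:(kernel - 1L)) {
    s <- s + 1L
    stack[, s] <- pm[dr + seq_len(nr), dc + seq_len(nc)]
  }
  med <- row_medians(stack)
  gray_image(matrix(med, nr, nc))
}

# row medians of an integer matrix with an odd, small column count;
# pmin/pmax tournament for the common 3x3 case, sort fallback otherwise
row_medians <- function(x) {
  if (ncol(x) == 9L) {
    a <- x
    # median-of-9 exchange network (19 min/max ops)
    swp <- function(i, j) {
      lo <- pmin.int(a[, i], a[, j]); hi <- pmax.int(a[, i], a[, j])
      a[, i] <<- lo; a[, j] <<- hi
    }
    swp(2, 3); swp(5, 6); swp(8, 9); swp(1, 2); swp(4, 5); swp(7, 8)
    swp(2, 3); swp(5, 6); swp(8, 9); swp(1, 4); swp(6, 9); swp(5, 8)
    swp(4, 7); swp(2, 5); swp(3, 6); swp(5, 8); swp(3, 5); swp(6, 8)
    swp(5, 6)
    return(a[, 5])
  }
  apply(x, 1L, function(v) sort.int(v, method = "quick")[(length(v) + 1L) %/% 2L])
}

# Daubechies-4 (8-tap) analysis low-pass filter; high-pass by QMF relation.
db4_lo <- c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)
db4_hi <- rev(db4_lo) * c(1, -1, 1, -1, 1, -1, 1, -1)

# periodic 1-D analysis along columns of a matrix (even number of rows)
dwt_cols <- function(m) {
  n <- nrow(m); L <- length(db4_lo)
  idx <- outer(seq(1, n, by = 2), 0:(L - 1), "+")
  idx <- (idx - 1) %% n + 1
  lo <- matrix(0, n / 2, ncol(m)); hi <- lo
  for (k in seq_len(L)) {
    rows <- idx[, k]
    lo <- lo + db4_lo[k] * m[rows, , drop = FALSE]
    hi <- hi + db4_hi[k] * m[rows, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# periodic 1-D synthesis (inverse of dwt_cols)
idwt_cols <- function(lo, hi) {
  n2 <- nrow(lo); n <- 2L * n2; L <- length(db4_lo)
  out <- matrix(0, n, ncol(lo))
  for (k in seq_len(L)) {
    rows <- ((seq(1, n, by = 2) + k - 2) %% n) + 1
    out[rows, ] <- out[rows, ] + db4_lo[k] * lo + db4_hi[k] * hi
  }
  out
}

dwt2 <- function(m) {
  cb <- dwt_cols(m)
  ll <- dwt_cols(t(cb$lo)); lh <- dwt_cols(t(cb$hi))
  list(LL = t(ll$lo), LH = t(lh$lo), HL = t(ll$hi), HH = t(lh$hi))
}

idwt2 <- function(b) {
  lo <- t(idwt_cols(t(b$LL), t(b$HL)))
  hi <- t(idwt_cols(t(b$LH), t(b$HH)))
  idwt_cols(lo, hi)
}

#' Wavelet shrinkage denoising
#'
#' Multilevel periodic Daubechies-4 decomposition; detail coefficients are
#' thresholded at the universal threshold
#' \eqn{\hat\sigma\sqrt{2\log n}} (scaled by `threshold_scale`), where
#' \eqn{\hat\sigma} is the median absolute deviation of the finest diagonal
#' details divided by 0.6745. Odd image sides are reflect-extended by one
#' pixel before transforming and cropped back afterwards. Output is clipped
#' to \[0, 255\] and rounded.
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param cfg A [preprocess_config()].
#' @return A [gray_image()].
#' @export
wavelet_denoise <- function(img, cfg = preprocess_config()) {
  m <- as_gray_matrix(img) * 1.0
  levels <- cfg$wavelet_levels
  if (levels == 0) return(gray_image(m))
  if (min(dim(m)) < 2^levels)
    stop("image too small for ", levels, " decomposition levels",
         call. = FALSE)
  nr0 <- nrow(m); nc0 <- ncol(m)
  # extend to a multiple of 2^levels by edge reflection
  mult <- 2^levels
  nr <- ceiling(nr0 / mult) * mult; nc <- ceiling(nc0 / mult) * mult
  if (nr != nr0) m <- m[c(seq_len(nr0), nr0 + 1 - seq_len(nr - nr0)), ,
                        drop = FALSE]
  if (nc != nc0) m <- m[, c(seq_len(nc0), nc0 + 1 - seq_len(nc - nc0)),
                        drop = FALSE]
  bands <- vector("list", levels)
  cur <- m
  for (l in seq_len(levels)) {
    b <- dwt2(cur)
    bands[[l]] <- b
    cur <- b$LL
  }
  hh1 <- bands[[1]]$HH
  sigma <- stats::median(abs(hh1)) / 0.6745
  thr <- cfg$threshold_scale * sigma * sqrt(2 * log(nr0 * nc0))
  shrink <- function(x) {
    if (cfg$threshold_rule == "soft") sign(x) * pmax(abs(x) - thr, 0)
    else x * (abs(x) > thr)
  }
  for (l in seq_len(levels)) {
    bands[[l]]$LH <- shrink(bands[[l]]$LH)
    bands[[l]]$HL <- shrink(bands[[l]]$HL)
    bands[[l]]$HH <- shrink(bands[[l]]$HH)
  }
  rec <- bands[[levels]]$LL
  for (l in rev(seq_len(levels))) {
    bands[[l]]$LL <- rec
    rec <- idwt2(bands[[l]])
  }
  rec <- rec[seq_len(nr0), seq_len(nc0), drop = FALSE]
  gray_image(pmin(pmax(floor(rec + 0.5), 0), 255))
}

#' Min-max intensity normalization
#'
#' Linear stretch of the intensity range to \[0, 255\]; a constant image
#' maps to 0 (the degenerate-range rule).
#'
#' @param img A [gray_image()] or intensity matrix.
#' @return A [gray_image()].
#' @export
normalize_intensity <- function(img) {
  m <- as_gray_matrix(img)
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(gray_image(matrix(0L, nrow(m), ncol(m))))
  gray_image(floor((m - lo) / (hi - lo) * 255 + 0.5))
}

#' Apply the configured preprocessing chain
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param cfg A [preprocess_config()]; stages run in `cfg$order`.
#' @return A [gray_image()].
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  out <- gray_image(as_gray_matrix(img))
  for (stage in cfg$order) {
    out <- switch(stage,
      median = median_filter(out, cfg$median_kernel),
      wavelet = wavelet_denoise(out, cfg),
      normalize = normalize_intensity(out))
  }
  out
}
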