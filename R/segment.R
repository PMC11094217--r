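# Multilevel-threshold segmentation. The optimizer searches threshold space
# (not pixel space): G = number of thresholds, box [1, 254], objective the
# Otsu between-class variance (default) or Kapur summed class entropy.
# Labels are inverted so the darkest class — the hematoxylin-dark nucleus —
# gets the highest label.

#' 256-bin intensity histogram
#'
#' @param img A [gray_image()] or intensity matrix.
#' @return Integer vector of length 256 (bin `i` counts intensity `i - 1`);
#'   sums to the pixel count.
#' @export
histogram256 <- function(img) {
  m <- as_gray_matrix(img)
  tabulate(as.vector(m) + 1L, nbins = 256L)
}

# Prefix sums used by both objectives: each class entropy / moment is then
# O(1) per candidate threshold set.
hist_prefix <- function(hist) {
  p <- hist / sum(hist)
  plogp <- ifelse(p > 0, p * log(p), 0)
  list(P = cumsum(p), S = cumsum(plogp), M = cumsum(p * (0:255)),
       mu = sum(p * (0:255)))
}

# class boundaries: thresholds t partition intensities into
# [0..t1], [t1+1..t2], ..., [tn+1..255]
class_bounds <- function(t) {
  lo <- c(0L, as.integer(t) + 1L)
  hi <- c(as.integer(t), 255L)
  cbind(lo, hi)
}

#' Kapur entropy of a threshold partition
#'
#' Sum over classes of the within-class Shannon entropy (natural log) of
#' the normalized histogram: for class mass \eqn{\omega_c},
#' \eqn{H_c = \log\omega_c - (\sum p_i\log p_i)/\omega_c}; empty classes
#' contribute 0. Higher is better; the optimizer minimizes the negation.
#'
#' @param hist 256-bin counts from [histogram256()].
#' @param thresholds Strictly increasing integers in \[1, 254\].
#' @return Scalar total entropy.
#' @export
kapur_fitness <- function(hist, thresholds) {
  pre <- hist_prefix(hist)
  kapur_from_prefix(pre, thresholds)
}

kapur_from_prefix <- function(pre, thresholds) {
  b <- class_bounds(thresholds)
  tot <- 0
  for (c in seq_len(nrow(b))) {
    lo <- b[c, 1]; hi <- b[c, 2]
    w <- pre$P[hi + 1L] - if (lo > 0L) pre$P[lo] else 0
    if (w > 0) {
      s <- pre$S[hi + 1L] - if (lo > 0L) pre$S[lo] else 0
      tot <- tot + log(w) - s / w
    }
  }
  tot
}

#' Otsu between-class variance of a threshold partition
#'
#' \eqn{\sum_c \omega_c(\mu_c-\mu)^2}; higher is better.
#'
#' @inheritParams kapur_fitness
#' @return Scalar between-class variance.
#' @export
otsu_fitness <- function(hist, thresholds) {
  pre <- hist_prefix(hist)
  otsu_from_prefix(pre, thresholds)
}

otsu_from_prefix <- function(pre, thresholds) {
  b <- class_bounds(thresholds)
  tot <- 0
  for (c in seq_len(nrow(b))) {
    lo <- b[c, 1]; hi <- b[c, 2]
    w <- pre$P[hi + 1L] - if (lo > 0L) pre$P[lo] else 0
    if (w > 0) {
      m <- pre$M[hi + 1L] - if (lo > 0L) pre$M[lo] else 0
      tot <- tot + w * (m / w - pre$mu)^2
    }
  }
  tot
}

threshold_objective <- function(objective = c("otsu", "kapur")) {
  objective <- match.arg(objective)
  if (objective == "kapur") kapur_from_prefix else otsu_from_prefix
}

#' Exhaustive multilevel-threshold search
#'
#' Brute-force scan over all strictly increasing integer threshold tuples
#' in \[1, 254\]; tractable for 1-3 thresholds thanks to O(1) per-candidate
#' evaluation on histogram prefix sums. Serves as the optimality reference
#' for the metaheuristic search.
#'
#' @param hist 256-bin counts.
#' @param n_thresholds 1, 2 or 3.
#' @param objective `"kapur"` or `"otsu"`.
#' @return List with `thresholds` (first-found argmax) and `fitness`.
#' @export
exhaustive_threshold_search <- function(hist, n_thresholds,
                                        objective = c("otsu", "kapur")) {
  stopifnot(n_thresholds %in% 1:3)
  fobj <- threshold_objective(objective)
  pre <- hist_prefix(hist)
  best <- -Inf; best_t <- NULL
  if (n_thresholds == 1) {
    for (t1 in 1:254) {
      v <- fobj(pre, t1)
      if (v > best) { best <- v; best_t <- t1 }
    }
  } else if (n_thresholds == 2) {
    for (t1 in 1:253) for (t2 in (t1 + 1):254) {
      v <- fobj(pre, c(t1, t2))
      if (v > best) { best <- v; best_t <- c(t1, t2) }
    }
  } else {
    for (t1 in 1:252) for (t2 in (t1 + 1):253) for (t3 in (t2 + 1):254) {
      v <- fobj(pre, c(t1, t2, t3))
      if (v > best) { best <- v; best_t <- c(t1, t2, t3) }
    }
  }
  list(thresholds = best_t, fitness = best)
}

# round a continuous position to a valid strictly-increasing threshold set,
# repairing duplicates by +1 shifts
repair_thresholds <- function(x) {
  t <- sort(as.integer(pmin(pmax(round(x), 1), 254)))
  for (k in seq_along(t)[-1]) if (t[k] <= t[k - 1]) t[k] <- t[k - 1] + 1L
  pmin(t, 254L)
}

#' Optimizer-driven multilevel threshold search
#'
#' Runs the heap-based optimizer in threshold space (continuous positions
#' in \[1, 254\]^n, rounded and sorted for evaluation, duplicates repaired
#' by +1 shifts). Deterministic given the seed.
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param n_thresholds Number of thresholds (1-4); 2 gives the standard
#'   background / cytoplasm / nucleus split.
#' @param objective `"otsu"` (default) or `"kapur"`. Otsu's
#'   between-class variance is the default because Kapur entropy degenerates
#'   on images with a flat (zero-entropy) background region.
#' @param population_size,max_iterations Optimizer budget.
#' @param seed Integer seed.
#' @return List with `thresholds` (integer vector), `fitness` (the
#'   objective value, higher better) and the optimizer `history`.
#' @export
ho_threshold_search <- function(img, n_thresholds = 2,
                                objective = c("otsu", "kapur"),
                                population_size = 30, max_iterations = 150,
                                seed = 1L) {
  stopifnot(n_thresholds >= 1, n_thresholds <= 4)
  hist <- histogram256(img)
  if (sum(hist > 0) < 2) {
    warning("degenerate histogram (single gray level); ",
            "returning evenly spaced thresholds", call. = FALSE)
    t <- round(seq(0, 255, length.out = n_thresholds + 2))[2:(n_thresholds + 1)]
    return(list(thresholds = as.integer(t), fitness = 0, history = numeric(0)))
  }
  fobj <- threshold_objective(objective)
  pre <- hist_prefix(hist)
  f <- function(x) -fobj(pre, repair_thresholds(x))
  cfg <- ho_config(population_size = population_size,
                   max_iterations = max_iterations,
                   lower_bounds = rep(1, n_thresholds),
                   upper_bounds = rep(254, n_thresholds), seed = seed)
  res <- ho_optimize(f, cfg)
  list(thresholds = repair_thresholds(res$best_position),
       fitness = -res$best_fitness, history = res$history)
}

#' Apply thresholds to get a label mask
#'
#' A pixel with intensity `v` falls in partition class `#(thresholds < v)`;
#' labels are inverted so the darkest class has the highest label. With two
#' thresholds this yields the convention 0 = background (brightest),
#' 1 = cytoplasm, 2 = nucleus (darkest).
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param thresholds Strictly increasing integer thresholds.
#' @return Integer label matrix, same shape as `img`.
#' @export
apply_thresholds <- function(img, thresholds) {
  m <- as_gray_matrix(img)
  t <- sort(as.integer(thresholds))
  raw <- matrix(findInterval(as.vector(m), t + 0.5), nrow(m), ncol(m))
  lab <- length(t) - raw
  storage.mode(lab) <- "integer"
  lab
}

#' Overlap scores between predicted and ground-truth masks
#'
#' Per label: Dice `2|A∩B| / (|A|+|B|)` and intersection-over-union; both
#' defined as 1 when the label is absent from both masks. Plus overall
#' pixel accuracy.
#'
#' @param pred,truth Integer label matrices of identical shape.
#' @param labels Labels to score (default 0, 1, 2).
#' @return List with per-label `dice`, `iou` vectors and `pixel_accuracy`.
#' @export
overlap_metrics <- function(pred, truth, labels = 0:2) {
  if (!all(dim(pred) == dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  dice <- iou <- stats::setNames(numeric(length(labels)),
                                 paste0("label_", labels))
  for (k in seq_along(labels)) {
    a <- pred == labels[k]; b <- truth == labels[k]
    inter <- sum(a & b); na <- sum(a); nb <- sum(b)
    if (na + nb == 0L) {
      dice[k] <- 1; iou[k] <- 1
    } else {
      dice[k] <- 2 * inter / (na + nb)
      iou[k] <- inter / (na + nb - inter)
    }
  }
  list(dice = dice, iou = iou,
       pixel_accuracy = mean(pred == truth))
}

#' Crop the image to the segmented cell
#'
#' Bounding box of the cell labels (1 = cytoplasm, 2 = nucleus) expanded by
#' `margin` pixels and clipped to the frame.
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param mask Integer label mask of the same shape.
#' @param margin Margin in pixels.
#' @return A [gray_image()] crop.
#' @export
extract_roi <- function(img, mask, margin = 2) {
  m <- as_gray_matrix(img)
  cell <- which(mask == 1L | mask == 2L, arr.ind = TRUE)
  if (nrow(cell) == 0L)
    stop("segmentation failure: no cell pixels in mask", call. = FALSE)
  r1 <- max(1L, min(cell[, 1]) - margin); r2 <- min(nrow(m), max(cell[, 1]) + margin)
  c1 <- max(1L, min(cell[, 2]) - margin); c2 <- min(ncol(m), max(cell[, 2]) + margin)
  gray_image(m[r1:r2, c1:c2, drop = FALSE])
}
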