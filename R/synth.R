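# Synthetic single-cell phantoms: a dark elliptical nucleus inside a lighter
# elliptical cytoplasm on a bright background, with band-limited texture and
# additive Gaussian noise. These emulate stained cervical cytology at the
# statistical level needed to exercise segmentation and classification; they
# are not a stain or optics simulation.

#' Per-class phantom generator parameters
#'
#' Defaults encode the two separability axes of the seven-class scheme:
#' the nucleus/cytoplasm area ratio grows monotonically with dysplasia
#' severity (normal squamous < intermediate squamous < normal columnar <
#' low-grade < moderate < high-grade dysplasia < carcinoma in situ), and
#' chromatin texture amplitude grows with grade. Radii are in pixels for
#' the default 64x64 frame; intensities are 8-bit means with background >
#' cytoplasm > nucleus, as in a bright-field Pap image.
#'
#' @return Named list (one entry per class) of parameter lists.
#' @export
phantom_class_params <- function() {
  p <- function(nuc, amp) list(
    nucleus_radius_range = nuc,
    cytoplasm_radius_range = c(20, 26),
    intensity_means = c(background = 230, cytoplasm = 150, nucleus = 60),
    texture_amplitude = amp)
  list(
    normal_squamous       = p(c(4, 5),   2),
    intermediate_squamous = p(c(5, 6),   3),
    normal_columnar       = p(c(6, 7),   4),
    low_grade_dysplasia   = p(c(9, 11),  8),
    moderate_dysplasia    = p(c(11, 13), 10),
    high_grade_dysplasia  = p(c(13, 15), 12),
    carcinoma_in_situ     = p(c(15, 18), 14))
}

#' Specify one synthetic cell image
#'
#' @param class_label One of [cyto_classes()].
#' @param image_size Side length in pixels (square frame).
#' @param nucleus_radius_range,cytoplasm_radius_range Length-2 ranges (px)
#'   from which the ellipse semi-axes are drawn; nucleus must fit inside
#'   the cytoplasm.
#' @param intensity_means Named vector (background, cytoplasm, nucleus) of
#'   8-bit base intensities, ordered background > cytoplasm > nucleus.
#' @param texture_amplitude Amplitude (intensity units) of the band-limited
#'   sinusoidal texture painted over the cell.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; rendering is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(class_label, image_size = 64,
                         nucleus_radius_range = NULL,
                         cytoplasm_radius_range = NULL,
                         intensity_means = NULL,
                         texture_amplitude = NULL,
                         noise_sigma = 5, seed = 1L) {
  class_label <- canonical_label(class_label)
  if (!class_label %in% cyto_classes())
    stop("unknown class label: ", class_label, call. = FALSE)
  defaults <- phantom_class_params()[[class_label]]
  spec <- list(
    class_label = class_label,
    image_size = as.integer(image_size),
    nucleus_radius_range = nucleus_radius_range %||%
      defaults$nucleus_radius_range,
    cytoplasm_radius_range = cytoplasm_radius_range %||%
      defaults$cytoplasm_radius_range,
    intensity_means = intensity_means %||% defaults$intensity_means,
    texture_amplitude = texture_amplitude %||% defaults$texture_amplitude,
    noise_sigma = noise_sigma,
    seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_phantom_spec <- function(spec) {
  im <- spec$intensity_means
  if (!(im[["background"]] > im[["cytoplasm"]] &&
          im[["cytoplasm"]] > im[["nucleus"]]))
    stop("intensity means must be ordered background > cytoplasm > nucleus",
         call. = FALSE)
  if (max(spec$nucleus_radius_range) >= min(spec$cytoplasm_radius_range))
    stop("nucleus radius range must lie below cytoplasm radius range",
         call. = FALSE)
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (max(spec$cytoplasm_radius_range) >= spec$image_size / 2)
    stop("cytoplasm radius exceeds image bounds", call. = FALSE)
  invisible(spec)
}

# interior test for an axis-aligned-then-rotated ellipse
ellipse_mask <- function(n, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)  # column coord
  ys <- matrix(rep(seq_len(n) - 0.5, times = n), n, n) # row coord
  dx <- xs - cx; dy <- ys - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Render one synthetic cell image with its ground-truth mask
#'
#' Paints an elliptical cytoplasm and an interior elliptical nucleus on a
#' uniform background, adds low-frequency sinusoidal texture (amplitude
#' `texture_amplitude`, over the cell only) and pixelwise Gaussian noise,
#' then clips and rounds to 8 bits. Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [gray_image()]) and `mask` (integer matrix,
#'   0 = background, 1 = cytoplasm, 2 = nucleus).
#' @export
render_cell <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$image_size
  with_seed(spec$seed, {
    cy_ab <- stats::runif(2, spec$cytoplasm_radius_range[1],
                          spec$cytoplasm_radius_range[2])
    nu_ab <- stats::runif(2, spec$nucleus_radius_range[1],
                          spec$nucleus_radius_range[2])
    theta_c <- stats::runif(1, 0, pi)
    theta_n <- stats::runif(1, 0, pi)
    # nucleus center jitter, kept well inside the cytoplasm
    slack <- max(min(cy_ab) - max(nu_ab), 0)
    jit <- stats::runif(2, -0.3, 0.3) * slack
    cx <- n / 2; cy <- n / 2
    cyto <- ellipse_mask(n, cx, cy, cy_ab[1], cy_ab[2], theta_c)
    nuc <- ellipse_mask(n, cx + jit[1], cy + jit[2],
                        nu_ab[1], nu_ab[2], theta_n) & cyto
    mask <- matrix(0L, n, n)
    mask[cyto] <- 1L
    mask[nuc] <- 2L
    im <- spec$intensity_means
    img <- matrix(im[["background"]], n, n)
    img[cyto] <- im[["cytoplasm"]]
    img[nuc] <- im[["nucleus"]]
    if (spec$texture_amplitude > 0) {
      tex <- matrix(0, n, n)
      xs <- matrix(rep(seq_len(n), each = n), n, n)
      ys <- matrix(rep(seq_len(n), times = n), n, n)
      for (k in 1:3) {  # three low-frequency plane waves
        per <- stats::runif(1, 8, 24)
        ang <- stats::runif(1, 0, pi)
        ph <- stats::runif(1, 0, 2 * pi)
        tex <- tex + sin(2 * pi / per * (xs * cos(ang) + ys * sin(ang)) + ph)
      }
      tex <- tex / 3 * spec$texture_amplitude
      img[mask > 0L] <- img[mask > 0L] + tex[mask > 0L]
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
    img <- pmin(pmax(floor(img + 0.5), 0), 255)
    list(image = gray_image(img), mask = mask)
  })
}

# largest-remainder apportionment of n into fractions summing to 1
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic labelled dataset on disk
#'
#' Writes `images/*.png`, `masks/*.png` (labels 0/1/2 stored directly as
#' pixel values), `manifest.csv` and `params.yaml` under `out_dir`. Per-class
#' counts are exact; split sizes use largest-remainder rounding and split
#' assignment is a seeded permutation, so identical seeds give identical
#' bytes on disk.
#'
#' @param n_per_class Images per class (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param split_fractions Length-3 numeric (train, test, validation) summing
#'   to 1.
#' @param noise_sigma Gaussian noise s.d. applied to every image.
#' @param image_size Frame side length in pixels.
#' @return The manifest data frame (invisibly also written to disk).
#' @export
generate_dataset <- function(n_per_class, out_dir, seed = 1L,
                             split_fractions = c(0.7, 0.3, 0),
                             noise_sigma = 5, image_size = 64) {
  stopifnot(n_per_class >= 1)
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  classes <- cyto_classes()
  recs <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    sizes <- largest_remainder(n_per_class, split_fractions)
    splits <- rep(split_vocabulary, times = sizes)
    perm <- with_seed(seed + 1000L * ci, sample.int(n_per_class))
    splits <- splits[order(perm)]  # seeded assignment, exact counts
    for (k in seq_len(n_per_class)) {
      sd_k <- seed + 1000L * ci + k
      spec <- phantom_spec(cl, image_size = image_size,
                           noise_sigma = noise_sigma, seed = sd_k)
      cell <- render_cell(spec)
      stem <- sprintf("%s_%03d", cl, k)
      img_path <- file.path(out_dir, "images", paste0(stem, ".png"))
      write_image(cell$image, img_path)
      png::writePNG(cell$mask / 255,
                    target = file.path(out_dir, "masks",
                                       paste0(stem, ".png")))
      recs[[length(recs) + 1L]] <- data.frame(
        image_path = img_path, class_label = cl, split = splits[k],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- validate_manifest(do.call(rbind, recs))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  yaml::write_yaml(
    list(n_per_class = n_per_class, seed = seed,
         split_fractions = as.numeric(split_fractions),
         noise_sigma = noise_sigma, image_size = image_size),
    file.path(out_dir, "params.yaml"))
  invisible(manifest)
}

#' Read a ground-truth label mask written by [generate_dataset()]
#'
#' @param path Mask PNG path (pixel values are the labels 0/1/2).
#' @return Integer matrix of labels.
#' @export
read_mask <- function(path) {
  m <- round(png::readPNG(path) * 255)
  storage.mode(m) <- "integer"
  m
}
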