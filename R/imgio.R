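#' Canonical seven-class cytology scheme
#'
#' Ordered class labels for the single-cell classifier: three normal cell
#' types followed by four abnormal (dysplastic/malignant) types.
#'
#' @return Character vector of the 7 canonical class labels.
#' @export
cyto_classes <- function() {
  c("intermediate_squamous", "normal_columnar", "normal_squamous",
    "high_grade_dysplasia", "low_grade_dysplasia", "moderate_dysplasia",
    "carcinoma_in_situ")
}

#' Normal and abnormal class groupings
#'
#' The binary screening reduction: squamous/columnar normals versus
#' dysplasia grades and carcinoma in situ.
#'
#' @return Character vector of labels in the group.
#' @export
normal_classes <- function() {
  c("intermediate_squamous", "normal_columnar", "normal_squamous")
}

#' @rdname normal_classes
#' @export
abnormal_classes <- function() {
  c("high_grade_dysplasia", "low_grade_dysplasia", "moderate_dysplasia",
    "carcinoma_in_situ")
}

# canonical form of a class label: lowercase, spaces/hyphens -> underscore
canonical_label <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}

#' Construct a grayscale image object
#'
#' A `gray_image` is an integer matrix of 8-bit intensities (0-255),
#' row-major with the origin at the top-left; it is the unit every pipeline
#' stage consumes and produces.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @return A `gray_image` (integer matrix with class attribute).
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px)) stop("image contains NA intensities", call. = FALSE)
  if (min(px) < 0L || max(px) > 255L)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  class(px) <- c("gray_image", class(px))
  px
}

as_gray_matrix <- function(img) {
  m <- unclass(img)
  if (!is.matrix(m)) stop("expected a matrix image", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Read a grayscale image from PNG or BMP
#'
#' RGB inputs are converted to luminance with fixed ITU-R 601 weights
#' (0.299, 0.587, 0.114), rounded half-up. Alpha channels are ignored.
#'
#' @param path Path to a `.png` or `.bmp` file.
#' @return A [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    arr <- round(a * 255)
  } else if (ext == "bmp") {
    arr <- read_bmp(path)
  } else {
    stop("unsupported image format: .", ext, " (PNG or BMP expected)",
         call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    d <- dim(arr)
    if (d[3] >= 3L) {
      g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      arr <- matrix(floor(g + 0.5), d[1], d[2])  # round half-up
    } else {
      arr <- matrix(arr[, , 1], d[1], d[2])
    }
  }
  gray_image(pmin(pmax(arr, 0), 255))
}

#' Write an 8-bit grayscale PNG
#'
#' Bit-exact round trip with [read_image()] for 8-bit grayscale data.
#'
#' @param img A [gray_image()] or intensity matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  m <- as_gray_matrix(img)
  png::writePNG(m / 255, target = path)
  invisible(path)
}

# Minimal BMP reader: uncompressed 24-bit true color or 8-bit palette.
# BMP rows are stored bottom-up and padded to 4-byte boundaries.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path, call. = FALSE)
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  offset <- u32(11)
  hdr_size <- u32(15)
  width <- u32(19); height <- u32(23)
  bpp <- u16(29); compression <- u32(31)
  if (compression != 0)
    stop("compressed BMP not supported", call. = FALSE)
  if (!bpp %in% c(8, 24))
    stop("only 8-bit and 24-bit BMP supported (got ", bpp, ")", call. = FALSE)
  if (bpp == 8) {
    n_colors <- u32(47)
    if (n_colors == 0) n_colors <- 256
    pal_start <- 14 + hdr_size
    pal <- matrix(as.integer(raw[pal_start + seq_len(n_colors * 4)]),
                  ncol = 4, byrow = TRUE)  # B,G,R,reserved
    gray_lut <- floor(0.299 * pal[, 3] + 0.587 * pal[, 2] +
                        0.114 * pal[, 1] + 0.5)
    row_bytes <- 4 * ceiling(width / 4)
    out <- matrix(0L, nrow = height, ncol = width)
    for (r in seq_len(height)) {
      start <- offset + (r - 1) * row_bytes
      idx <- as.integer(raw[start + seq_len(width)])
      out[height - r + 1, ] <- gray_lut[idx + 1L]
    }
    out
  } else {
    row_bytes <- 4 * ceiling(3 * width / 4)
    out <- array(0L, dim = c(height, width, 3))
    for (r in seq_len(height)) {
      start <- offset + (r - 1) * row_bytes
      v <- as.integer(raw[start + seq_len(3 * width)])
      bgr <- matrix(v, ncol = 3, byrow = TRUE)
      out[height - r + 1, , 1] <- bgr[, 3]
      out[height - r + 1, , 2] <- bgr[, 2]
      out[height - r + 1, , 3] <- bgr[, 1]
    }
    out
  }
}

manifest_header <- c("image_path", "class_label", "split")
split_vocabulary <- c("train", "test", "validation")

#' Load and validate a dataset manifest
#'
#' A manifest is a UTF-8 CSV with header exactly
#' `image_path,class_label,split` mapping each image to one of the seven
#' canonical class labels and a split role.
#'
#' @param path CSV file path.
#' @param class_names Ordered vector of allowed labels.
#' @return A `data.frame` with columns image_path, class_label, split and
#'   attribute `class_names`.
#' @export
load_manifest <- function(path, class_names = cyto_classes()) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), manifest_header))
    stop("manifest header must be exactly `image_path,class_label,split`",
         call. = FALSE)
  if (nrow(df) == 0L) stop("manifest validation error: no records",
                           call. = FALSE)
  validate_manifest(df, class_names)
}

validate_manifest <- function(df, class_names = cyto_classes()) {
  df$class_label <- canonical_label(df$class_label)
  bad <- which(!df$class_label %in% class_names)
  if (length(bad))
    stop("manifest validation error: unknown class label(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(df$class_label[bad]), collapse = ", "), call. = FALSE)
  bad_split <- which(!df$split %in% split_vocabulary)
  if (length(bad_split))
    stop("manifest validation error: invalid split in row(s) ",
         paste(bad_split, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$image_path))
    stop("manifest validation error: duplicate image paths", call. = FALSE)
  attr(df, "class_names") <- class_names
  df
}

#' Write a dataset manifest to CSV
#'
#' @param manifest Data frame as returned by [load_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, manifest_header], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Build a manifest from a class-per-directory layout
#'
#' Adapts the common archive layout (one subdirectory per class, images
#' inside)
#' into a manifest. Directory names are matched case-insensitively after
#' space/underscore normalization; non-class directories are skipped with a
#' warning. All records get split `"train"`.
#'
#' @param root Directory containing one subdirectory per class.
#' @param class_names Allowed labels.
#' @return A validated manifest data frame.
#' @export
scan_class_directories <- function(root, class_names = cyto_classes()) {
  if (!dir.exists(root)) stop("directory not found: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE)
  recs <- list()
  for (d in dirs) {
    lab <- canonical_label(basename(d))
    if (!lab %in% class_names) {
      warning("ignoring non-class directory: ", basename(d), call. = FALSE)
      next
    }
    files <- list.files(d, pattern = "\\.(png|bmp)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files))
      recs[[length(recs) + 1L]] <- data.frame(
        image_path = files, class_label = lab, split = "train",
        stringsAsFactors = FALSE)
  }
  if (!length(recs))
    stop("no recognized class directories under ", root, call. = FALSE)
  validate_manifest(do.call(rbind, recs), class_names)
}

# Run `code` under a temporarily-seeded RNG, restoring global RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
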