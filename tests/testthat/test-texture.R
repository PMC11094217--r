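test_that("GLCM enumerates co-occurring pairs with symmetrization", {
  # 1x2 image [0, 255], 2 levels, d=1, 0 degrees: one pair + transpose
  img <- gray_image(matrix(c(0L, 255L), 1, 2))
  P <- glcm(img, 1, 0, glcm_config(levels = 2))
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # constant image: single diagonal entry 1
  Pc <- glcm(gray_image(matrix(100L, 5, 5)), 1, 0)
  expect_equal(sum(Pc), 1)
  lvl <- (100L * 8L) %/% 256L
  expect_equal(Pc[lvl + 1, lvl + 1], 1)
  # normalization holds for random images at all configured displacements
  img2 <- random_gray(12, 12, seed = 14)
  for (d in c(1, 2)) for (a in c(0, 45, 90, 135))
    expect_equal(sum(glcm(img2, d, a)), 1, tolerance = 1e-12)
  expect_error(glcm(gray_image(matrix(1L, 1, 1)), 1, 0), "smaller")
})

test_that("GLCM with symmetrization is invariant to angle + 180 degrees", {
  img <- random_gray(10, 10, seed = 15)
  for (a in c(0, 45, 90, 135))
    expect_equal(glcm(img, 1, a), glcm(img, 1, a + 180), tolerance = 1e-12)
})

test_that("Haralick statistics match hand sums and the brute-force oracle", {
  # constant image conventions
  stc <- glcm_stats(glcm(gray_image(matrix(7L, 4, 4)), 1, 0))
  expect_equal(unname(stc), c(0, 1, 0, 1))
  # four-term hand computation
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  st <- glcm_stats(P)
  expect_equal(st[["contrast"]], 1)
  expect_equal(st[["energy"]], 0.5)
  expect_equal(st[["entropy"]], 1)      # 1 bit
  expect_equal(st[["correlation"]], -1)
  expect_error(glcm_stats(P * 2), "normalized")
  # oracle equivalence on random images
  for (s in 1:25) {
    img <- random_gray(16, 16, seed = 600 + s, levels = 8)
    Pr <- glcm(img, 1 + s %% 2, c(0, 45, 90, 135)[1 + s %% 4])
    expect_equal(glcm_stats(Pr), oracle_glcm_stats(Pr), tolerance = 1e-12)
  }
  # bounds: energy in (0, 1], entropy >= 0
  img <- random_gray(9, 9, seed = 16)
  st2 <- glcm_stats(glcm(img, 1, 45))
  expect_gt(st2[["energy"]], 0); expect_lte(st2[["energy"]], 1)
  expect_gte(st2[["entropy"]], 0)
})

test_that("LBP histogram matches the per-pixel oracle and its invariances", {
  # constant image: all neighbors >= center -> all-ones uniform bin
  h <- lbp_histogram(gray_image(matrix(5L, 6, 6)))
  expect_equal(h[9], 1)  # 8 ones -> bin 9
  expect_equal(sum(h), 1)
  # random image: full histogram equals explicit per-pixel enumeration
  img <- random_gray(9, 9, seed = 17)
  m <- unclass(img)
  bins <- integer(0)
  for (r in 2:8) for (c in 2:8) bins <- c(bins, oracle_lbp_bin(m, r, c))
  expect_equal(lbp_histogram(img), tabulate(bins, 10) / length(bins))
  # single bright center on a dark field: neighbors' codes enumerated
  m2 <- matrix(10L, 5, 5); m2[3, 3] <- 200L
  bins2 <- integer(0)
  for (r in 2:4) for (c in 2:4) bins2 <- c(bins2, oracle_lbp_bin(m2, r, c))
  expect_equal(lbp_histogram(gray_image(m2)), tabulate(bins2, 10) / 9)
  # invariance under a strictly increasing intensity remap
  expect_equal(lbp_histogram(img), lbp_histogram(m * 3L + 7L))
})

test_that("Gabor kernels are zero-DC with the expected symmetries", {
  k <- gabor_kernel(5, 0.6, 45, 2.0, 0, 1.0)
  expect_equal(sum(k), 0, tolerance = 1e-12)
  # the kernel is the mean-subtracted Gabor wave: rebuild it from the
  # closed form and check, including the center value cos(0)*exp(0) = 1
  x <- matrix(rep(-2:2, each = 5), 5, 5); y <- matrix(rep(-2:2, times = 5), 5, 5)
  th <- 45 * pi / 180
  xr <- x * cos(th) + y * sin(th); yr <- -x * sin(th) + y * cos(th)
  raw <- exp(-(xr^2 + yr^2) / (2 * 2^2)) * cos(2 * pi * 0.6 * xr)
  expect_equal(raw[3, 3], 1)
  expect_equal(k, raw - mean(raw), tolerance = 1e-12)
  # theta and theta + 180 give identical kernels
  expect_equal(gabor_kernel(7, 0.3, 30), gabor_kernel(7, 0.3, 210),
               tolerance = 1e-12)
  expect_error(gabor_kernel(4, 0.6, 0), "odd")
})

test_that("Gabor features respond to orientation and vanish on constants", {
  cst <- gray_image(matrix(123L, 20, 20))
  expect_equal(unname(gabor_features(cst)), rep(0, 16), tolerance = 1e-9)
  # horizontal grating at f = 0.6 (varies along columns): 0-degree filter
  # responds more than the 90-degree filter at the same frequency
  g <- matrix(rep(round(127 + 100 * sin(2 * pi * 0.6 * (1:32))), each = 32),
              32, 32)
  feats <- gabor_features(gray_image(pmin(pmax(g, 0), 255)))
  expect_gt(feats[["gabor_f0.6_t0_mean"]], feats[["gabor_f0.6_t90_mean"]])
  expect_identical(feats, gabor_features(gray_image(pmin(pmax(g, 0), 255))))
})

test_that("feature vectors have the canonical 58-name layout and separate classes", {
  roi <- render_cell(phantom_spec("normal_squamous", seed = 20))$image
  fv <- extract_features(roi)
  expect_length(fv, 58)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_equal(sum(fv[grep("^lbp", names(fv))]), 1, tolerance = 1e-12)
  # identical spec/seed -> identical vector
  roi2 <- render_cell(phantom_spec("normal_squamous", seed = 20))$image
  expect_identical(extract_features(roi2), fv)
  # high-grade dysplasia phantoms have higher GLCM contrast than normal
  contrast_of <- function(cl, s) {
    img <- render_cell(phantom_spec(cl, seed = s))$image
    extract_features(img)[["glcm_d1_a0_contrast"]]
  }
  hgd <- vapply(1:12, function(s) contrast_of("high_grade_dysplasia", s), 0)
  nrm <- vapply(1:12, function(s) contrast_of("normal_squamous", s), 0)
  expect_gt(mean(hgd), mean(nrm))
  # the literal reading: LBP on the Gabor response image still sums to 1
  fvg <- extract_features(roi, lbp_on_gabor = TRUE)
  expect_equal(sum(fvg[grep("^lbp", names(fvg))]), 1, tolerance = 1e-12)
  expect_false(identical(fvg, fv))
})

test_that("feature standardization is reproducible and drops constants", {
  set.seed(23)
  X <- cbind(a = rnorm(20, 5, 2), b = rnorm(20), c = rep(3, 20))
  std <- standardize_features(X)
  expect_equal(colnames(std$X), c("a", "b"))
  expect_equal(unname(colMeans(std$X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std$X, 2, sd)), c(1, 1), tolerance = 1e-12)
  # stored transform reproduces the training projection
  expect_equal(apply_standardization(std$transform, X), std$X)
  expect_error(standardize_features(X[1, , drop = FALSE]), "at least 2")
})
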