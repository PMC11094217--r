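test_that("histogram256 conserves pixel counts", {
  img <- gray_image(matrix(7L, 10, 10))
  h <- histogram256(img)
  expect_equal(h[8], 100L)
  expect_equal(sum(h), 100L)
  two <- gray_image(matrix(c(rep(0L, 60), rep(255L, 40)), 10, 10))
  h2 <- histogram256(two)
  expect_equal(sum(h2 > 0), 2L)
  expect_equal(h2[c(1, 256)], c(60L, 40L))
})

test_that("Kapur entropy matches symmetry, degeneracy and a brute-force scan", {
  uniform <- rep(4L, 256)
  # reflection v -> 255 - v maps the partition at t to the one at 254 - t
  expect_equal(kapur_fitness(uniform, 126), kapur_fitness(uniform, 128),
               tolerance = 1e-12)
  expect_equal(kapur_fitness(uniform, c(84, 169)),
               kapur_fitness(uniform, c(254 - 169, 254 - 84)),
               tolerance = 1e-12)
  # single-bin histogram: zero entropy whatever the thresholds
  conc <- integer(256); conc[100] <- 500L
  expect_equal(kapur_fitness(conc, 127), 0)
  expect_equal(kapur_fitness(conc, c(50, 180)), 0)
  # argmax of a random 32-level histogram equals the exhaustive scan
  set.seed(41)
  h <- integer(256)
  h[seq(1, 256, by = 8)] <- rpois(32, 40)
  ex <- exhaustive_threshold_search(h, 1, "kapur")
  brute <- vapply(1:254, function(t) kapur_fitness(h, t), 0)
  expect_equal(ex$fitness, max(brute), tolerance = 1e-12)
  expect_equal(kapur_fitness(h, which.max(brute)), max(brute))
})

test_that("Otsu between-class variance has its closed-form two-point optimum", {
  h <- integer(256); h[51] <- 100L; h[201] <- 100L  # deltas at 50 and 200
  # any threshold in [50, 199] separates the deltas; variance = (75)^2
  vals <- vapply(c(50, 120, 199), function(t) otsu_fitness(h, t), 0)
  expect_equal(vals, rep(75^2, 3), tolerance = 1e-9)
  expect_lt(otsu_fitness(h, 210), 75^2)
  expect_equal(otsu_fitness(conc <- {z <- integer(256); z[5] <- 9L; z}, 100), 0)
  # matches exhaustive argmax on a random histogram
  set.seed(42)
  h2 <- integer(256); h2[sample(256, 20)] <- rpois(20, 30)
  ex <- exhaustive_threshold_search(h2, 1, "otsu")
  brute <- vapply(1:254, function(t) otsu_fitness(h2, t), 0)
  expect_equal(ex$fitness, max(brute), tolerance = 1e-12)
})

test_that("optimizer threshold search reaches the exhaustive optimum on phantoms", {
  # noise-free two-region image: any threshold in [60, 179] is optimal
  m <- matrix(60L, 20, 20); m[6:15, 6:15] <- 180L
  s1 <- ho_threshold_search(gray_image(m), 1, "otsu", seed = 1)
  ex1 <- exhaustive_threshold_search(histogram256(gray_image(m)), 1, "otsu")
  expect_equal(s1$fitness, ex1$fitness, tolerance = 1e-12)
  expect_gte(s1$thresholds, 60L); expect_lt(s1$thresholds, 180L)
  # three-region noise-free phantom, 2 thresholds
  cell <- render_cell(phantom_spec("moderate_dysplasia", noise_sigma = 0,
                                   texture_amplitude = 0, seed = 3))
  s2 <- ho_threshold_search(cell$image, 2, "kapur", seed = 2)
  ex2 <- exhaustive_threshold_search(histogram256(cell$image), 2, "kapur")
  expect_equal(s2$fitness, ex2$fitness, tolerance = 1e-10)
  # determinism
  s3 <- ho_threshold_search(cell$image, 2, "kapur", seed = 2)
  expect_identical(s2$thresholds, s3$thresholds)
  # degenerate single-level image
  expect_warning(sd_ <- ho_threshold_search(gray_image(matrix(9L, 8, 8)), 2),
                 "degenerate")
  expect_length(sd_$thresholds, 2)
})

test_that("threshold labels invert so the darkest class is the nucleus", {
  img <- gray_image(matrix(c(50L, 120L, 240L, 50L), 2, 2))
  lab <- apply_thresholds(img, c(100, 200))
  expect_equal(as.vector(lab), c(2L, 1L, 0L, 2L))
  # single threshold: dark pixels get label 1
  lab1 <- apply_thresholds(img, 100)
  expect_equal(as.vector(lab1), c(1L, 0L, 0L, 1L))
  # all pixels below t1: single-label mask; counts conserved
  lab2 <- apply_thresholds(gray_image(matrix(10L, 3, 3)), c(100, 200))
  expect_true(all(lab2 == 2L))
  expect_equal(sum(table(lab)), 4)
})

test_that("overlap metrics reproduce hand-computed Dice values", {
  a <- matrix(0L, 10, 20); a[, 1:10] <- 1L
  expect_equal(overlap_metrics(a, a)$dice, c(label_0 = 1, label_1 = 1,
                                             label_2 = 1))
  # disjoint equal-area regions -> Dice 0 for that label
  b <- matrix(0L, 10, 20); b[, 11:20] <- 1L
  expect_equal(overlap_metrics(a, b)$dice[["label_1"]], 0)
  # pred covers half of a 100-px truth region plus 50 extra px
  truth <- matrix(0L, 20, 20); truth[1:10, 1:10] <- 2L
  pred <- matrix(0L, 20, 20); pred[1:5, 1:10] <- 2L; pred[11:15, 1:10] <- 2L
  om <- overlap_metrics(pred, truth)
  expect_equal(om$dice[["label_2"]], 0.5)
  expect_equal(om$iou[["label_2"]], 1 / 3)
  expect_error(overlap_metrics(a, truth), "shapes")
})

test_that("ROI extraction crops the cell bounding box with clipped margins", {
  img <- random_gray(30, 30, seed = 9)
  mask <- matrix(0L, 30, 30); mask[11:21, 11:21] <- 1L
  expect_equal(dim(extract_roi(img, mask, margin = 0)), c(11L, 11L))
  expect_equal(dim(extract_roi(img, mask, margin = 100)), c(30L, 30L))
  expect_identical(unclass(extract_roi(img, mask, 0)),
                   unclass(img)[11:21, 11:21])
  expect_error(extract_roi(img, matrix(0L, 30, 30)), "segmentation failure")
})
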