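# Independent oracles and small fixture builders used across the suite.

# Brute-force Haralick statistics: explicit double loop over matrix cells,
# no shared code with glcm_stats().
oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  mi <- mj <- 0
  for (i in 1:L) for (j in 1:L) {
    mi <- mi + (i - 1) * P[i, j]
    mj <- mj + (j - 1) * P[i, j]
  }
  con <- en <- ent <- si2 <- sj2 <- cov <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    con <- con + ((i - 1) - (j - 1))^2 * p
    en <- en + p * p
    if (p > 0) ent <- ent - p * log2(p)
    si2 <- si2 + ((i - 1) - mi)^2 * p
    sj2 <- sj2 + ((j - 1) - mj)^2 * p
    cov <- cov + ((i - 1) - mi) * ((j - 1) - mj) * p
  }
  corr <- if (si2 == 0 || sj2 == 0) 1 else cov / sqrt(si2 * sj2)
  c(contrast = con, energy = en, entropy = ent, correlation = corr)
}

# Brute-force LBP uniform bin for one interior pixel: explicit neighbor
# list (east, counterclockwise), explicit transition count.
oracle_lbp_bin <- function(m, r, c) {
  nb <- c(m[r, c + 1], m[r - 1, c + 1], m[r - 1, c], m[r - 1, c - 1],
          m[r, c - 1], m[r + 1, c - 1], m[r + 1, c], m[r + 1, c + 1])
  bits <- as.integer(nb >= m[r, c])
  trans <- sum(bits != bits[c(2:8, 1)])
  if (trans <= 2) sum(bits) + 1L else 10L
}

peak_signal_noise_ratio <- function(a, b) {
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  10 * log10(255^2 / mse)
}

# quantize an 8-bit image to `levels` evenly spaced gray values
quantize_image <- function(img, levels = 32) {
  m <- unclass(img)
  step <- 256 %/% levels
  gray_image((m %/% step) * step)
}

random_gray <- function(nr, nc, seed, levels = 256) {
  set.seed(seed)
  vals <- sample.int(levels, nr * nc, replace = TRUE) - 1L
  gray_image(matrix(as.integer(vals * (256 %/% levels)), nr, nc))
}

# random small SsNF model for contract checks
random_model <- function(n_inputs, n_rules, n_classes, seed) {
  set.seed(seed)
  rules <- lapply(seq_len(n_rules), function(j) {
    list(center = stats::runif(n_inputs, -2, 2),
         width = stats::runif(n_inputs, 0.3, 3),
         k = matrix(stats::runif(n_inputs * n_classes, -2, 2),
                    n_inputs, n_classes),
         bias = stats::runif(n_classes, -2, 2))
  })
  structure(list(n_inputs = n_inputs,
                 class_names = paste0("class", seq_len(n_classes)),
                 rules = rules,
                 default_width = rep(1, n_inputs), transform = NULL,
                 schema_version = "1.0"),
            class = "ssnf_model")
}

# 7 Gaussian clusters in 8 dimensions with pairwise center distance 4*sqrt(2)
make_cluster_data <- function(n_per_class, seed, sd = 1) {
  set.seed(seed)
  classes <- cyto_classes()
  centers <- 4 * diag(8)[1:7, ]  # class i centered at 4 * e_i
  X <- NULL; y <- character(0)
  for (i in 1:7) {
    Xi <- matrix(stats::rnorm(n_per_class * 8, sd = sd), n_per_class, 8)
    Xi <- sweep(Xi, 2, centers[i, ], "+")
    X <- rbind(X, Xi)
    y <- c(y, rep(classes[i], n_per_class))
  }
  list(X = X, y = y)
}
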