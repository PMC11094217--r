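# Six-layer self-systematized neural fuzzy classifier.
# Layer 1 passes the (standardized) inputs through; layer 2 evaluates
# Gaussian memberships exp(-(x-d)^2/sigma^2); layer 3 forms rule firing
# strengths as the product over inputs (equivalently the quadratic form
# exp(-|R(x-d)|^2) with R = diag(1/sigma)); layer 4 normalizes firings
# across rules; layer 5 computes TSK-style linear consequents
# (sum_x k_x x + G0) scaled by the normalized firing — the local-mean-of-
# maximum reading in which only output-membership centers reach the crisp
# output; layer 6 sums rule contributions per class. Structure learning
# appends a rule whenever no existing rule fires above a novelty threshold;
# parameters are then fitted by the heap-based optimizer.

SSNF_SCHEMA_VERSION <- "1.0"

#' Gaussian membership function value
#'
#' \eqn{\mu(x) = \exp(-(x-d)^2/\sigma^2)}.
#'
#' @param x Input value.
#' @param center Membership center `d`.
#' @param width Membership width `sigma` (> 0).
#' @return Membership degree in (0, 1\].
#' @export
mf_eval <- function(x, center, width) {
  stopifnot(all(width > 0))
  exp(-((x - center)^2) / width^2)
}

#' Firing strength of one rule
#'
#' Product of the per-input Gaussian memberships,
#' \eqn{f = \exp(-\sum_m (x_m-d_m)^2/\sigma_m^2)}.
#'
#' @param rule A rule (list with `center`, `width`).
#' @param x Input vector (already standardized).
#' @return Scalar in (0, 1\].
#' @export
rule_firing <- function(rule, x) {
  if (length(x) != length(rule$center))
    stop("input dimension does not match rule", call. = FALSE)
  exp(-sum(((x - rule$center) / rule$width)^2))
}

#' Normalize firing strengths across rules
#'
#' Layer-4 operation: \eqn{\bar f_j = f_j / \sum_k f_k}. When every firing
#' underflows to zero the result falls back to the uniform distribution
#' with a warning.
#'
#' @param f Non-negative firing vector.
#' @return Vector on the simplex (sums to 1).
#' @export
normalize_firings <- function(f) {
  s <- sum(f)
  if (s <= 0 || !is.finite(s)) {
    warning("all rule firings underflowed; using uniform weights",
            call. = FALSE)
    return(rep(1 / length(f), length(f)))
  }
  f / s
}

#' Consequent contribution of one rule
#'
#' TSK-style linear consequent scaled by normalized firing: the rule's
#' contribution to class `c` is \eqn{(\sum_x k_{xc} x_x + G_{0c})\bar f_j}.
#'
#' @param rule A rule (list with `k` — inputs x classes weight matrix —
#'   and `bias` per class).
#' @param x Input vector.
#' @param fbar The rule's normalized firing.
#' @return Per-class contribution vector.
#' @export
consequent_output <- function(rule, x, fbar) {
  (as.vector(crossprod(rule$k, x)) + rule$bias) * fbar
}

new_rule <- function(center, width, n_classes, own_class = NULL) {
  k <- matrix(0, length(center), n_classes)
  bias <- numeric(n_classes)
  if (!is.null(own_class)) bias[own_class] <- 1
  list(center = as.numeric(center), width = as.numeric(width),
       k = k, bias = bias)
}

validate_model <- function(model) {
  stopifnot(length(model$rules) >= 1)
  for (r in model$rules) {
    stopifnot(length(r$center) == model$n_inputs,
              length(r$width) == model$n_inputs, all(r$width > 0),
              nrow(r$k) == model$n_inputs,
              ncol(r$k) == length(model$class_names),
              length(r$bias) == length(model$class_names))
  }
  invisible(model)
}

# firing matrix: n_samples x n_rules
firing_matrix <- function(model, X) {
  R <- length(model$rules)
  Fm <- matrix(0, nrow(X), R)
  for (j in seq_len(R)) {
    r <- model$rules[[j]]
    Z <- sweep(sweep(X, 2, r$center, "-"), 2, r$width, "/")
    Fm[, j] <- exp(-rowSums(Z * Z))
  }
  Fm
}

#' Class scores for a batch of inputs
#'
#' Full six-layer forward pass; rows of `X` must already be transformed by
#' the model's stored feature transform. Scores are convex combinations of
#' the per-rule consequent values (the normalized firings lie on the
#' simplex), so permuting the rules leaves them unchanged.
#'
#' @param model An SsNF model.
#' @param X Numeric matrix (samples x inputs) or a single vector.
#' @return Matrix samples x classes of raw scores.
#' @export
ssnf_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$n_inputs)
    stop("input dimension does not match model", call. = FALSE)
  Fm <- firing_matrix(model, X)
  s <- rowSums(Fm)
  under <- s <= 0 | !is.finite(s)
  if (any(under)) {
    warning("rule firings underflowed for ", sum(under),
            " sample(s); using uniform weights", call. = FALSE)
    Fm[under, ] <- 1
    s[under] <- length(model$rules)
  }
  Fbar <- Fm / s
  C <- length(model$class_names)
  scores <- matrix(0, nrow(X), C)
  for (j in seq_along(model$rules)) {
    r <- model$rules[[j]]
    lin <- X %*% r$k + matrix(r$bias, nrow(X), C, byrow = TRUE)
    scores <- scores + Fbar[, j] * lin
  }
  colnames(scores) <- model$class_names
  scores
}

#' Classify inputs
#'
#' Argmax over class scores; exact ties resolve to the lowest class index.
#'
#' @param model An SsNF model.
#' @param X Standardized feature matrix or vector.
#' @return Character vector of class labels.
#' @export
ssnf_classify <- function(model, X) {
  sc <- ssnf_scores(model, X)
  model$class_names[max.col(sc, ties.method = "first")]
}

#' Training configuration for the classifier
#'
#' @param n_init_mf Per-input membership functions used to set width
#'   scales (default 3: small / medium / large).
#' @param f_min Novelty threshold in (0, 1): a training input firing below
#'   it on every rule spawns a new rule.
#' @param budget Optimizer objective-evaluation budget. Default 2000 (desk
#'   scale); the full-scale schedule of 50000 evaluations is reachable by
#'   configuration.
#' @param population_size Optimizer population for parameter fitting. The
#'   default is small: with the warm-started population a short, deep
#'   descent refines the structure-learned solution better than a broad
#'   one at the same evaluation budget.
#' @param init_spread Warm-start radius (fraction of each parameter's box)
#'   for the optimizer population around the structure-learned vector.
#' @param seed Integer seed.
#' @return An `ssnf_train_config` list.
#' @export
ssnf_train_config <- function(n_init_mf = 3, f_min = 0.1, budget = 2000,
                              population_size = 6, init_spread = 0.01,
                              seed = 1L) {
  stopifnot(f_min > 0, f_min < 1, budget >= 1, n_init_mf >= 2)
  structure(list(n_init_mf = as.integer(n_init_mf), f_min = f_min,
                 budget = as.integer(budget),
                 population_size = as.integer(population_size),
                 init_spread = init_spread,
                 seed = as.integer(seed)),
            class = "ssnf_train_config")
}

#' Initialize model structure from training data
#'
#' Per-input membership centers are placed at the `n_init_mf` pooled
#' quantiles (equal counts per fuzzy set) with widths of half the mean
#' spacing of adjacent centers, floored at 0.1 (standardized units). One
#' initial rule per class sits at the class-conditional feature mean. Rule
#' widths are the per-input pooled *within-class* standard deviation
#' (residual spread about the class means; quantile spacing as fallback
#' for degenerate inputs) scaled by `2 * sqrt(n_inputs)`: the within-class
#' scale makes the rule firing a diagonal Mahalanobis distance to the
#' class prototype, and the dimension factor keeps the aggregate
#' multi-input firing in a usable dynamic range, so ordinary within-class
#' variation does not trip the novelty threshold. Consequent biases are
#' one-hot on the rule's own class; weights start at zero.
#'
#' @param X Standardized feature matrix.
#' @param labels Character class labels, one per row of `X`.
#' @param class_names Ordered class vocabulary.
#' @param cfg An [ssnf_train_config()].
#' @return An SsNF model (list).
#' @export
init_structure <- function(X, labels, class_names = cyto_classes(),
                           cfg = ssnf_train_config()) {
  X <- as.matrix(X)
  if (nrow(unique(X)) < cfg$n_init_mf)
    stop("degenerate training data: fewer than n_init_mf distinct points",
         call. = FALSE)
  G <- ncol(X)
  qs <- (seq_len(cfg$n_init_mf) - 0.5) / cfg$n_init_mf
  mf_width <- numeric(G)
  for (m in seq_len(G)) {
    centers_m <- stats::quantile(X[, m], qs, names = FALSE)
    mf_width[m] <- max(0.1, mean(diff(centers_m)) / 2)
  }
  present <- intersect(class_names, unique(labels))
  if (!length(present)) stop("no known class labels in training data",
                             call. = FALSE)
  class_means <- lapply(present, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]))
  names(class_means) <- present
  # residual (within-class) spread per input; quantile-based fallback
  resid <- X
  for (cl in present)
    resid[labels == cl, ] <- sweep(X[labels == cl, , drop = FALSE],
                                   2, class_means[[cl]], "-")
  within_sd <- sqrt(colMeans(resid^2))
  within_sd[within_sd < 1e-8] <- mf_width[within_sd < 1e-8]
  rule_width <- pmax(0.1, 2 * sqrt(G) * within_sd)
  rules <- list()
  for (cl in present) {
    ci <- match(cl, class_names)
    rules[[length(rules) + 1L]] <- new_rule(class_means[[cl]], rule_width,
                                            length(class_names), ci)
  }
  model <- list(n_inputs = G, class_names = class_names, rules = rules,
                default_width = rule_width, transform = NULL,
                schema_version = SSNF_SCHEMA_VERSION)
  class(model) <- "ssnf_model"
  validate_model(model)
}

#' Self-systematization: grow a rule on novel input
#'
#' If the maximum rule firing at `x` is below the novelty threshold
#' `f_min`, a new rule is appended centered at `x` with the model's default
#' widths and a one-hot consequent bias on the true class; otherwise the
#' model is returned unchanged. A repeated identical input therefore adds
#' at most one rule (the second pass fires at 1).
#'
#' @param model An SsNF model.
#' @param x Standardized input vector.
#' @param label True class label of `x`.
#' @param f_min Novelty threshold.
#' @return Possibly-extended model.
#' @export
self_systematize <- function(model, x, label, f_min = 0.1) {
  fmax <- max(firing_matrix(model, matrix(x, nrow = 1)))
  if (fmax >= f_min) return(model)
  ci <- match(label, model$class_names)
  model$rules[[length(model$rules) + 1L]] <-
    new_rule(x, model$default_width, length(model$class_names), ci)
  model
}

#' Mean squared error of raw scores against one-hot targets
#'
#' Averaged over samples and classes; zero exactly when the raw scores
#' reproduce the one-hot encoding.
#'
#' @param model An SsNF model.
#' @param X Standardized feature matrix.
#' @param labels True labels.
#' @return Non-negative scalar.
#' @export
ssnf_loss <- function(model, X, labels) {
  if (NROW(X) == 0) stop("empty dataset", call. = FALSE)
  S <- ssnf_scores(model, X)
  Y <- matrix(0, nrow(S), ncol(S))
  Y[cbind(seq_len(nrow(S)), match(labels, model$class_names))] <- 1
  mean((S - Y)^2)
}

# ---- flatten/unflatten all rule parameters for the optimizer -------------

pack_params <- function(model) {
  unlist(lapply(model$rules, function(r)
    c(r$center, r$width, as.vector(r$k), r$bias)))
}

unpack_params <- function(theta, skeleton) {
  G <- skeleton$n_inputs; C <- length(skeleton$class_names)
  per <- 2 * G + G * C + C
  model <- skeleton
  for (j in seq_along(model$rules)) {
    v <- theta[(j - 1) * per + seq_len(per)]
    model$rules[[j]]$center <- v[seq_len(G)]
    model$rules[[j]]$width <- pmax(v[G + seq_len(G)], 0.1)
    model$rules[[j]]$k <- matrix(v[2 * G + seq_len(G * C)], G, C)
    model$rules[[j]]$bias <- v[2 * G + G * C + seq_len(C)]
  }
  model
}

param_bounds <- function(model) {
  G <- model$n_inputs; C <- length(model$class_names)
  lo_r <- c(rep(-3, G), rep(0.1, G), rep(-5, G * C), rep(-5, C))
  hi_r <- c(rep(3, G), rep(5, G), rep(5, G * C), rep(5, C))
  R <- length(model$rules)
  list(lower = rep(lo_r, R), upper = rep(hi_r, R))
}

#' Train the classifier
#'
#' Three phases: structure initialization ([init_structure()]), one
#' self-systematization pass over the training data in row order, then
#' heap-optimizer fitting of all rule centers, widths, consequent weights
#' and biases flattened into a single search vector (centers in \[-3, 3\]
#' standardized units, widths in \[0.1, 5\], weights and biases in
#' \[-5, 5\]). The optimizer population is warm-started: one agent sits
#' exactly at the structure-learned vector (so the fitted loss never
#' exceeds the initial model's) and the rest perturb it by
#' `cfg$init_spread` of each box width, which makes the refinement a deep
#' local descent rather than a blind global search. Deterministic given
#' the seed.
#'
#' @param X Standardized feature matrix (samples x inputs).
#' @param labels Character labels, one per row.
#' @param class_names Ordered class vocabulary.
#' @param cfg An [ssnf_train_config()].
#' @param transform Optional feature transform (from
#'   [standardize_features()]) stored in the model for deployment.
#' @return A fitted `ssnf_model`.
#' @export
ssnf_train <- function(X, labels, class_names = cyto_classes(),
                       cfg = ssnf_train_config(), transform = NULL) {
  X <- as.matrix(X)
  if (length(unique(labels)) < 2)
    stop("need at least 2 classes to train", call. = FALSE)
  model <- init_structure(X, labels, class_names, cfg)
  for (i in seq_len(nrow(X)))
    model <- self_systematize(model, X[i, ], labels[i], cfg$f_min)
  theta0 <- pack_params(model)
  b <- param_bounds(model)
  # clamp the start point into the box so it remains representable
  theta0 <- pmin(pmax(theta0, b$lower), b$upper)
  f <- function(theta) ssnf_loss(unpack_params(theta, model), X, labels)
  K <- cfg$population_size
  P <- max(1L, as.integer(ceiling((cfg$budget - K) / K)))
  ho <- ho_config(population_size = K, max_iterations = P,
                  lower_bounds = b$lower, upper_bounds = b$upper,
                  init_position = theta0, init_spread = cfg$init_spread,
                  seed = cfg$seed)
  res <- suppressWarnings(ho_optimize(f, ho))
  fitted <- unpack_params(res$best_position, model)
  fitted$transform <- transform
  fitted$train_loss <- res$best_fitness
  fitted$loss_history <- res$history
  validate_model(fitted)
}

#' Save / load an SsNF model as JSON
#'
#' Full-precision JSON serialization with a `schema_version` field; loading
#' a file with a different schema version is an error.
#'
#' @param model An `ssnf_model`.
#' @param path Output path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  obj <- list(schema_version = model$schema_version,
              n_inputs = model$n_inputs,
              class_names = model$class_names,
              default_width = model$default_width,
              transform = model$transform,
              rules = lapply(model$rules, function(r)
                list(center = r$center, width = r$width,
                     k = as.vector(r$k), bias = r$bias)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, SSNF_SCHEMA_VERSION))
    stop("model schema version mismatch: expected ", SSNF_SCHEMA_VERSION,
         ", found ", obj$schema_version %||% "<none>", call. = FALSE)
  G <- obj$n_inputs; C <- length(obj$class_names)
  rules <- if (is.data.frame(obj$rules)) {
    lapply(seq_len(nrow(obj$rules)), function(j)
      list(center = obj$rules$center[[j]], width = obj$rules$width[[j]],
           k = matrix(obj$rules$k[[j]], G, C), bias = obj$rules$bias[[j]]))
  } else {
    lapply(obj$rules, function(r)
      list(center = r$center, width = r$width,
           k = matrix(r$k, G, C), bias = r$bias))
  }
  tr <- obj$transform
  if (!is.null(tr)) tr$keep <- as.integer(tr$keep)
  model <- list(n_inputs = G, class_names = obj$class_names, rules = rules,
                default_width = obj$default_width, transform = tr,
                schema_version = obj$schema_version)
  class(model) <- "ssnf_model"
  validate_model(model)
}
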