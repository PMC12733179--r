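#' Specification of a synthetic imbalanced multi-label task
#'
#' Generative parameters for tasks that emulate severely imbalanced
#' multi-label prediction: power-law label frequencies (negative:positive
#' ratios into the hundreds), label co-occurrence induced by shared latent
#' factors, and features that expose only part of the latent state — so
#' some labels are directly "visible" while correlated ones must be
#' inferred, the hidden-ingredient mechanism of image-based ingredient
#' prediction.
#'
#' @param n_samples Number of instances.
#' @param n_labels Number of binary labels.
#' @param feature_dim Feature dimensionality.
#' @param label_priors Vector of marginal positive rates in (0, 1), or
#'   `NULL` to derive power-law priors from `max_ratio`/`alpha`.
#' @param max_ratio Negative:positive ratio of the rarest label when priors
#'   are derived (e.g. 185).
#' @param alpha Power-law exponent for rank-frequency priors; `NULL` picks
#'   the exponent so the top `min(16, L)` labels hold about half the
#'   positive mass.
#' @param class_separation Scale of the label logit loadings on the latent
#'   factors; larger values make labels easier to predict.
#' @param co_occurrence_rank Number of shared latent factors (0 gives
#'   independent labels and uninformative features).
#' @param noise_sd Standard deviation of the feature observation noise.
#' @param loadings Optional `[L x rank]` label loading matrix overriding
#'   the default (each label tied to one factor, scaled by
#'   `class_separation`).
#' @param feature_map Optional `[feature_dim x rank]` matrix mapping latent
#'   factors into features; a zero column hides that factor from the
#'   features entirely.
#' @param seed Integer seed; identical specs generate bit-identical tasks.
#' @param split Train/validation/test fractions summing to 1.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(n_samples, n_labels, feature_dim = 2L * max(1L, co_occurrence_rank),
                      label_priors = NULL, max_ratio = 185, alpha = NULL,
                      class_separation = 2, co_occurrence_rank = 0L,
                      noise_sd = 1, loadings = NULL, feature_map = NULL,
                      seed = 1L, split = c(0.70, 0.15, 0.15)) {
  if (n_samples < 1L || n_labels < 1L || feature_dim < 1L) {
    abort("`n_samples`, `n_labels` and `feature_dim` must be positive.")
  }
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3L) {
    abort("`split` must be three fractions summing to 1.")
  }
  if (is.null(label_priors)) {
    label_priors <- power_law_priors(n_labels, max_ratio = max_ratio, alpha = alpha)
  }
  if (length(label_priors) != n_labels || any(label_priors <= 0 | label_priors >= 1)) {
    abort("`label_priors` must give one rate in (0, 1) per label.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  structure(
    list(n_samples = as.integer(n_samples), n_labels = as.integer(n_labels),
         feature_dim = as.integer(feature_dim), label_priors = label_priors,
         class_separation = class_separation,
         co_occurrence_rank = as.integer(co_occurrence_rank),
         noise_sd = noise_sd, loadings = loadings, feature_map = feature_map,
         seed = as.integer(seed), split = split),
    class = "task_spec"
  )
}

#' Power-law label priors
#'
#' Rank-frequency priors `p_k = c * k^(-alpha)`, scaled so the rarest label
#' has negative:positive ratio `max_ratio`. When `alpha` is `NULL` it is
#' solved so that the `min(16, n_labels)` most frequent labels carry
#' `top_mass` of the total positive mass, echoing the skew of real
#' ingredient vocabularies where a handful of staples dominate.
#'
#' @param n_labels Number of labels.
#' @param max_ratio Negative:positive ratio of the rarest label.
#' @param alpha Power-law exponent, or `NULL` to solve from `top_mass`.
#' @param top_k,top_mass Mass constraint used when `alpha` is `NULL`.
#' @return Decreasing vector of priors in (0, 1).
#' @export
power_law_priors <- function(n_labels, max_ratio = 185, alpha = NULL,
                             top_k = 16L, top_mass = 0.5) {
  if (max_ratio <= 0) abort("`max_ratio` must be positive.")
  k <- seq_len(n_labels)
  if (is.null(alpha)) {
    kk <- min(top_k, n_labels)
    if (kk == n_labels) {
      alpha <- 1
    } else {
      share <- function(a) sum(k[seq_len(kk)]^(-a)) / sum(k^(-a)) - top_mass
      lo <- share(1e-6); hi <- share(8)
      alpha <- if (lo >= 0) 1e-6 else if (hi <= 0) 8 else {
        uniroot(share, c(1e-6, 8), tol = 1e-9)$root
      }
    }
  }
  p <- k^(-alpha)
  p <- p / p[n_labels] * (1 / (1 + max_ratio))
  if (p[1] >= 1) abort("Infeasible priors: the most frequent label would exceed rate 1.")
  p
}

new_ml_task <- function(features, labels, split, posterior, spec) {
  structure(
    list(features = features, labels = labels, split = split,
         true_posterior = posterior, spec = spec),
    class = "ml_task"
  )
}

#' @export
print.ml_task <- function(x, ...) {
  cat(sprintf(
    "<ml_task> %d instances, %d feature(s), %d label(s); splits: %s\n",
    nrow(x$features), ncol(x$features), ncol(x$labels),
    paste(sprintf("%s=%d", names(table(x$split)), table(x$split)), collapse = ", ")
  ))
  invisible(x)
}

#' @method as_tibble ml_task
#' @export
as_tibble.ml_task <- function(x, ...) {
  ft <- as_tibble(x$features, .name_repair = "minimal")
  names(ft) <- paste0("x", seq_len(ncol(x$features)))
  lt <- as_tibble(x$labels, .name_repair = "minimal")
  names(lt) <- label_names(x$labels)
  dplyr::bind_cols(tibble(split = as.character(x$split)), ft, lt)
}

#' Extract one split of a task
#'
#' @param task An `ml_task`.
#' @param role `"train"`, `"val"` or `"test"`.
#' @return List with `features`, `labels` and (when available) `posterior`
#'   for the rows tagged with that role.
#' @export
dataset_role <- function(task, role = c("train", "val", "test")) {
  role <- match.arg(role)
  if (!inherits(task, "ml_task")) abort("`task` must be an ml_task.")
  idx <- which(task$split == role)
  if (length(idx) == 0L) abort(sprintf("Task has no '%s' rows.", role))
  list(
    features = task$features[idx, , drop = FALSE],
    labels = task$labels[idx, , drop = FALSE],
    posterior = if (is.null(task$true_posterior)) NULL else {
      task$true_posterior[idx, , drop = FALSE]
    }
  )
}

#' Random train/validation/test split
#'
#' @param n Number of rows, or an `ml_task` to (re-)tag.
#' @param fractions Three fractions summing to 1; sizes are
#'   `floor(f1 n)`, `floor(f2 n)` and the remainder.
#' @param seed Integer seed; the same seed yields the identical partition.
#' @return A factor of tags (`train`/`val`/`test`), or the re-tagged task.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  task <- NULL
  if (inherits(n, "ml_task")) {
    task <- n
    n <- nrow(task$features)
  }
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    abort("`fractions` must be three values summing to 1.")
  }
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L) {
    abort("`n` is too small for three non-empty splits.")
  }
  set.seed(seed)
  perm <- sample.int(n)
  tags <- factor(rep(NA_character_, n), levels = c("train", "val", "test"))
  tags[perm[seq_len(n_train)]] <- "train"
  tags[perm[n_train + seq_len(n_val)]] <- "val"
  tags[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  if (is.null(task)) return(tags)
  task$split <- tags
  task
}

#' Binary Gaussian verification task with analytic posterior
#'
#' Labels are Bernoulli(`prior`); features are isotropic Gaussians whose
#' class-conditional means are `separation` apart along the diagonal unit
#' direction. The true posterior is exactly logistic in the linear
#' discriminant, making every optimality claim checkable against closed
#' form.
#'
#' @param n Number of instances.
#' @param prior Positive-class rate in (0, 0.5].
#' @param separation Euclidean distance between the class-conditional
#'   feature means.
#' @param feature_dim Feature dimensionality.
#' @param seed Integer seed.
#' @param split Train/val/test fractions.
#' @return An `ml_task` with a single label and `true_posterior` filled in.
#' @export
make_binary_gaussian_task <- function(n, prior, separation, feature_dim = 2L,
                                      seed = 1L, split = c(0.70, 0.15, 0.15)) {
  if (prior <= 0 || prior > 0.5) abort("`prior` must lie in (0, 0.5].")
  if (separation <= 0) abort("`separation` must be positive.")
  set.seed(seed)
  y <- rbinom(n, 1L, prior)
  u <- rep(1 / sqrt(feature_dim), feature_dim)
  X <- matrix(rnorm(n * feature_dim), n, feature_dim) +
    outer((y - 0.5) * separation, u)
  posterior <- plogis(qlogis(prior) + separation * as.vector(X %*% u))
  spec <- task_spec(n, 1L, feature_dim, label_priors = prior,
                    class_separation = separation, co_occurrence_rank = 0L,
                    seed = seed, split = split)
  new_ml_task(X, matrix(y, ncol = 1L, dimnames = list(NULL, "L1")),
              split_dataset(n, split, seed = seed + 1L),
              matrix(posterior, ncol = 1L), spec)
}

# Default structure: label l loads factor 1 + (l-1) %% rank with weight
# class_separation; factor r maps into features ceiling(d / rank) wide.
default_loadings <- function(L, rank, scale) {
  A <- matrix(0, L, rank)
  A[cbind(seq_len(L), 1L + (seq_len(L) - 1L) %% rank)] <- scale
  A
}

default_feature_map <- function(d, rank) {
  M <- matrix(0, d, rank)
  M[cbind(seq_len(d), 1L + (seq_len(d) - 1L) %% rank)] <- 1
  M
}

# Solve the intercept b so that E_z plogis(s * z + b) = prior, z ~ N(0,1).
solve_intercept <- function(prior, s) {
  if (s == 0) return(qlogis(prior))
  f <- function(b) logit_normal_mean(b, s) - prior
  uniroot(f, c(qlogis(prior) - 6 * s - 6, qlogis(prior) + 6 * s + 6),
          tol = 1e-10)$root
}

#' Generate an imbalanced multi-label task with known posteriors
#'
#' Each instance draws latent factors `z ~ N(0, I)`; label `l` is positive
#' with probability `plogis(a_l . z + b_l)` where the intercepts `b_l`
#' realize the configured (power-law) priors and shared loadings induce
#' label co-occurrence. Features observe the latent factors through a
#' linear map plus Gaussian noise, so factors missing from the map are
#' invisible and their labels are predictable only through co-occurring
#' visible factors. The exact marginal posteriors `p(y_l = 1 | x)` are
#' computed by Gauss-Hermite quadrature over the Gaussian conditional
#' `z | x` and stored in the task.
#'
#' @param spec A [task_spec()].
#' @return An `ml_task` with `true_posterior` filled in.
#' @export
make_multilabel_task <- function(spec) {
  if (!inherits(spec, "task_spec")) abort("`spec` must be a task_spec.")
  n <- spec$n_samples; L <- spec$n_labels; d <- spec$feature_dim
  r <- spec$co_occurrence_rank
  priors <- spec$label_priors
  set.seed(spec$seed)

  if (r == 0L) {
    Y <- matrix(rbinom(n * L, 1L, rep(priors, each = n)), n, L)
    X <- matrix(rnorm(n * d, sd = spec$noise_sd), n, d)
    posterior <- matrix(priors, n, L, byrow = TRUE)
  } else {
    A <- spec$loadings %||% default_loadings(L, r, spec$class_separation)
    M <- spec$feature_map %||% default_feature_map(d, r)
    if (!all(dim(A) == c(L, r))) abort("`loadings` must be [n_labels x rank].")
    if (!all(dim(M) == c(d, r))) abort("`feature_map` must be [feature_dim x rank].")
    s_l <- sqrt(rowSums(A^2))
    b <- vapply(seq_len(L), function(l) solve_intercept(priors[l], s_l[l]), 0)
    Z <- matrix(rnorm(n * r), n, r)
    logits <- sweep(Z %*% t(A), 2L, b, `+`)
    Y <- matrix(rbinom(n * L, 1L, plogis(as.vector(logits))), n, L)
    X <- Z %*% t(M) + matrix(rnorm(n * d, sd = spec$noise_sd), n, d)
    # z | x is Gaussian: cov S, mean S M'x / noise_sd^2 (identity prior).
    S <- solve(crossprod(M) / spec$noise_sd^2 + diag(r))
    Mu_z <- X %*% (M %*% S) / spec$noise_sd^2
    lab_mu <- sweep(Mu_z %*% t(A), 2L, b, `+`)
    lab_sd <- sqrt(pmax(0, rowSums((A %*% S) * A)))
    posterior <- matrix(0, n, L)
    for (l in seq_len(L)) {
      posterior[, l] <- logit_normal_mean(lab_mu[, l], lab_sd[l])
    }
  }
  colnames(Y) <- paste0("L", seq_len(L))
  new_ml_task(X, Y, split_dataset(n, spec$split, seed = spec$seed + 1L),
              posterior, spec)
}

#' Write / read a task as plain-text files
#'
#' `write_task()` stores features, labels, split tags and (optionally) the
#' true posterior as CSV files plus a JSON sidecar of the generative
#' parameters; `read_task()` restores the task.
#'
#' @param task An `ml_task`.
#' @param dir Directory to create/read.
#' @param posterior Whether to store the posterior matrix.
#' @return `write_task()`: `dir`, invisibly. `read_task()`: an `ml_task`.
#' @export
write_task <- function(task, dir, posterior = TRUE) {
  if (!inherits(task, "ml_task")) abort("`task` must be an ml_task.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(task$features, .name_repair = "unique_quiet"),
                   file.path(dir, "features.csv"))
  readr::write_csv(as_tibble(task$labels, .name_repair = "unique_quiet"),
                   file.path(dir, "labels.csv"))
  readr::write_csv(tibble(split = as.character(task$split)),
                   file.path(dir, "split.csv"))
  if (posterior && !is.null(task$true_posterior)) {
    readr::write_csv(as_tibble(task$true_posterior, .name_repair = "unique_quiet"),
                     file.path(dir, "posterior.csv"))
  }
  sp <- task$spec
  sp$loadings <- NULL; sp$feature_map <- NULL
  jsonlite::write_json(unclass(sp), file.path(dir, "task.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_task
#' @export
read_task <- function(dir) {
  feat <- as.matrix(readr::read_csv(file.path(dir, "features.csv"),
                                    show_col_types = FALSE))
  lab <- as.matrix(readr::read_csv(file.path(dir, "labels.csv"),
                                   show_col_types = FALSE))
  split <- factor(readr::read_csv(file.path(dir, "split.csv"),
                                  show_col_types = FALSE)$split,
                  levels = c("train", "val", "test"))
  post_path <- file.path(dir, "posterior.csv")
  posterior <- if (file.exists(post_path)) {
    as.matrix(readr::read_csv(post_path, show_col_types = FALSE))
  }
  sp <- jsonlite::read_json(file.path(dir, "task.json"), simplifyVector = TRUE)
  spec <- task_spec(sp$n_samples, sp$n_labels, sp$feature_dim,
                    label_priors = sp$label_priors,
                    class_separation = sp$class_separation,
                    co_occurrence_rank = sp$co_occurrence_rank,
                    noise_sd = sp$noise_sd, seed = sp$seed, split = sp$split)
  new_ml_task(feat, lab, split, posterior, spec)
}
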