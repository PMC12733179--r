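# Internal helpers shared across modules.

# Coerce a vector or data frame to a numeric matrix; vectors become one column.
as_prob_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix or vector.", arg))
  }
  x
}

check_same_shape <- function(a, b, arg_a = "probs", arg_b = "labels") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf(
      "`%s` (%d x %d) and `%s` (%d x %d) must share the same shape.",
      arg_a, nrow(a), ncol(a), arg_b, nrow(b), ncol(b)
    ))
  }
}

check_binary <- function(labels, arg = "labels") {
  if (any(is.na(labels)) || !all(labels == 0 | labels == 1)) {
    abort(sprintf("`%s` must contain only 0 and 1.", arg))
  }
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
}

label_names <- function(labels) {
  colnames(labels) %||% paste0("L", seq_len(ncol(labels)))
}

# Gauss-Hermite nodes/weights, cached; used for E[plogis(N(mu, sd^2))].
gh_rule <- local({
  cache <- NULL
  function(n = 41L) {
    if (is.null(cache) || length(cache$x) != n) {
      cache <<- pracma::gaussHermite(n)
    }
    cache
  }
})

# Mean of plogis(t) for t ~ Normal(mu, sd^2), vectorized over mu (sd scalar).
logit_normal_mean <- function(mu, sd, n_nodes = 41L) {
  if (sd <= 0) return(plogis(mu))
  gh <- gh_rule(n_nodes)
  vals <- plogis(outer(mu, sqrt(2) * sd * gh$x, `+`))
  as.vector(vals %*% gh$w) / sqrt(pi)
}
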