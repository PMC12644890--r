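# small builders used across test files

ft_fix <- function(m, kind = "otu", marker = "16S") {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  feature_table(m, kind = kind, marker = marker)
}

# matrix stripped to dim/dimnames only, for value comparisons
bare <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

sf_fix <- function(stages, pair_id = NULL) {
  n <- length(stages)
  sample_frame(data.frame(
    sample_id = paste0("s", seq_len(n)),
    site_id = paste0("site", seq_len(n)),
    pair_id = pair_id %||% rep(NA_character_, n),
    stage = stages
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force Rao Q: explicit double loop
rao_brute <- function(p, d) {
  q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      q <- q + p[i] * p[j] * d[i, j]
    }
  }
  q
}

# independent hierarchical-partitioning oracle: average marginal R2 gain
# over all k! predictor orderings
hp_oracle <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  k <- ncol(predictors)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(stats::lm(response ~ ., data = predictors[, cols, drop = FALSE]))$r.squared
  }
  perms <- permutations_of(seq_len(k))
  contrib <- numeric(k)
  for (perm in perms) {
    for (pos in seq_len(k)) {
      before <- perm[seq_len(pos - 1)]
      i <- perm[pos]
      contrib[i] <- contrib[i] + r2(c(before, i)) - r2(before)
    }
  }
  contrib / length(perms)
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

random_community <- function(n_taxa) {
  p <- stats::runif(n_taxa)
  p <- p / sum(p)
  d <- matrix(stats::runif(n_taxa^2), n_taxa)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d <- d / max(d)
  list(p = p, d = d)
}
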