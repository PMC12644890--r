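#' Permutational multivariate analysis of variance (perMANOVA)
#'
#' One-factor perMANOVA on a distance matrix. Total sum of squares is
#' `sum(d_ij^2) / N` over unordered pairs; within-group sum of squares is
#' `sum_g (1/n_g) sum_{i<j in g} d_ij^2`; the pseudo-F is the ratio of
#' between/within mean squares. The p-value is `(1 + #(F_perm >= F_obs)) /
#' (1 + n_perm)` under seeded label permutations, optionally restricted
#' within strata (e.g. site pairs). A partial omega-squared for the grouping
#' factor is reported from the same partition.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param groups Grouping vector, one entry per sample; every group needs at
#'   least 2 samples.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @param strata Optional blocking vector; permutations shuffle labels only
#'   within blocks.
#' @return A `ms_permanova` object; see [tidy.ms_permanova()] and
#'   [glance.ms_permanova()].
#' @export
permanova <- function(d, groups, n_perm = 10000, seed = 1L, strata = NULL) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  g <- factor(groups)
  if (length(g) != n) ms_abort("`groups` length must match the distance matrix.",
                               "format_error")
  sizes <- table(g)
  if (nlevels(g) < 2 || any(sizes < 2)) {
    ms_abort("need >= 2 groups with >= 2 samples each.", "insufficient_data_error")
  }
  df_b <- nlevels(g) - 1
  df_w <- n - nlevels(g)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w_for <- function(idx_list) {
    s <- 0
    for (idx in idx_list) {
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  idx_obs <- split(seq_len(n), g)
  ss_w <- ss_w_for(idx_obs)
  ss_b <- ss_t - ss_w
  f_obs <- (ss_b / df_b) / (ss_w / df_w)
  degenerate <- !is.finite(f_obs)
  p <- NA_real_
  if (!degenerate && n_perm > 0) {
    perm_f <- with_rng(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- permute_labels(n, strata)
        ssw <- ss_w_for(lapply(idx_obs, function(idx) perm[idx]))
        ((ss_t - ssw) / df_b) / (ssw / df_w)
      }, numeric(1))
    })
    p <- (1 + sum(perm_f >= f_obs)) / (1 + n_perm)
  }
  ms_err <- ss_w / df_w
  omega <- (ss_b - df_b * ms_err) / (ss_t + ms_err)
  structure(list(pseudo_F = f_obs, R2 = ss_b / ss_t, p = p,
                 permutations = n_perm, partial_omega_sq = omega,
                 ss_total = ss_t, ss_within = ss_w, ss_between = ss_b,
                 df = c(between = df_b, within = df_w),
                 degenerate = degenerate, n = n),
            class = "ms_permanova")
}

# one permutation of 1..n, free or within strata
permute_labels <- function(n, strata) {
  if (is.null(strata)) return(sample.int(n))
  perm <- seq_len(n)
  for (idx in split(seq_len(n), strata)) {
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' @export
print.ms_permanova <- function(x, ...) {
  cat(sprintf("perMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.3f, p = %s [%d perms]\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2,
              format.pval(x$p, digits = 3), x$permutations))
  if (x$degenerate) cat("  (degenerate: zero within- or between-group variation)\n")
  invisible(x)
}

#' Tidy methods for perMANOVA results
#'
#' @param x An `ms_permanova` object.
#' @param ... Unused.
#' @return `tidy()` a one-row-per-term tibble; `glance()` a one-row model
#'   summary.
#' @export
tidy.ms_permanova <- function(x, ...) {
  tibble(term = c("groups", "residual"),
         df = as.integer(x$df),
         sum_sq = c(x$ss_between, x$ss_within),
         pseudo_F = c(x$pseudo_F, NA_real_),
         p = c(x$p, NA_real_))
}

#' @rdname tidy.ms_permanova
#' @export
glance.ms_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p = x$p,
         partial_omega_sq = x$partial_omega_sq,
         permutations = x$permutations, n = x$n,
         degenerate = x$degenerate)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
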