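#' Scale trait columns to the unit interval
#'
#' Per trait (gene family): `(x - min) / (max - min)`. Constant columns are
#' set to zero with a warning, since they carry no distance information.
#'
#' @param tm A [trait_matrix()] or plain numeric matrix (taxa x traits).
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
scale_traits <- function(tm) {
  m <- unclass(tm)
  if (!is.matrix(m) || nrow(m) < 2) {
    ms_abort("need a matrix with >= 2 taxa.", "format_error")
  }
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    ms_warn(sprintf("%d constant trait column(s) set to 0.", sum(const)),
            "scaling_warning")
  }
  span[const] <- 1
  out <- sweep(sweep(m, 2, rng[1, ], "-"), 2, span, "/")
  out[, const] <- 0
  out
}

#' Stage-specific functional distance matrix
#'
#' Euclidean distances between taxa on min-max scaled traits, computed over
#' the taxa present in the stage's metacommunity only (nonzero total
#' abundance across the stage's samples), then divided by the stage-specific
#' maximum so the largest distance is exactly 1.
#'
#' @param traits A [trait_matrix()] (raw copies; scaling happens here).
#' @param present Character vector of taxon ids present in the stage (or
#'   `NULL` for all taxa).
#' @return A symmetric matrix with zero diagonal and maximum 1 (all-zero when
#'   every pair is functionally identical, flagged by attribute
#'   `degenerate`).
#' @export
functional_distances <- function(traits, present = NULL) {
  m <- unclass(traits)
  if (!is.null(present)) {
    missing <- setdiff(present, rownames(m))
    if (length(missing)) {
      ms_abort(paste0("taxa absent from trait matrix: ",
                      paste(utils::head(missing, 5), collapse = ", ")),
               "alignment_error")
    }
    m <- m[present, , drop = FALSE]
  }
  if (nrow(m) < 2) {
    ms_abort("need >= 2 present taxa for functional distances.",
             "insufficient_data_error")
  }
  sc <- suppressWarnings(scale_traits(m))
  d <- as.matrix(stats::dist(sc))
  mx <- max(d)
  degenerate <- mx == 0
  if (!degenerate) d <- d / mx
  attr(d, "degenerate") <- degenerate
  d
}

#' Rao's quadratic entropy
#'
#' `Q = sum_i sum_j p_i p_j d_ij` over the full double sum (both (i, j) and
#' (j, i)). With distances scaled into \[0, 1\], `Q <= 1 - D` so the ternary
#' decomposition closes.
#'
#' @param p Relative abundances summing to 1, aligned with `d` (names are
#'   checked when both are named).
#' @param d Symmetric functional distance matrix with values in \[0, 1\].
#' @return A single number.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2)
#' rao_q(c(0.5, 0.5), d) # 0.5
rao_q <- function(p, d) {
  d <- as.matrix(d)
  if (length(p) != nrow(d) || nrow(d) != ncol(d)) {
    ms_abort("`p` and `d` dimensions disagree.", "alignment_error")
  }
  if (!is.null(names(p)) && !is.null(rownames(d)) &&
      !identical(names(p), rownames(d))) {
    ms_abort("`p` and `d` are aligned to different taxa.", "alignment_error")
  }
  check_rel_abund(p)
  if (any(d < -1e-12) || any(d > 1 + 1e-12)) {
    ms_abort("distances must lie in [0, 1]; rescale first.", "scaling_violation_error")
  }
  drop(crossprod(p, d %*% p))
}

#' Ternary decomposition of diversity
#'
#' Decomposes a community into Simpson dominance `D = sum(p^2)`, functional
#' diversity `Q` (Rao) and functional redundancy `R = (1 - D) - Q`, which
#' close to 1 exactly when distances lie in \[0, 1\]; uniqueness
#' (specialization) is `U = Q / (1 - D)`, undefined for a single-taxon
#' community.
#'
#' @inheritParams rao_q
#' @return A one-row tibble: `D`, `Q`, `R`, `U`.
#' @export
ternary_decompose <- function(p, d) {
  q <- rao_q(p, d)
  dom <- sum(p^2)
  r <- (1 - dom) - q
  if (r < -1e-9) {
    ms_abort("R < 0: distances exceed the [0, 1] scaling convention.",
             "scaling_violation_error")
  }
  r <- max(r, 0) # clamp numerical dust only (guarded above)
  tibble(D = dom, Q = q, R = r,
         U = if (1 - dom > 0) q / (1 - dom) else NA_real_)
}

#' Per-sample ternary coordinates along the gradient
#'
#' For each land-use stage, builds the stage-specific functional distance
#' matrix over the taxa present in that stage's metacommunity, then
#' decomposes every sample of the stage into (D, Q, R, U).
#'
#' @param otu OTU `feature_table`.
#' @param traits A [trait_matrix()] over the table's taxa.
#' @param sf Sample frame.
#' @param by Grouping for the metacommunity: `"stage"` (default) or
#'   `"ecosystem"`.
#' @return A tibble: `sample_id`, `stage`, `ecosystem`, `D`, `Q`, `R`, `U`.
#' @export
ternary_coordinates <- function(otu, traits, sf, by = c("stage", "ecosystem")) {
  by <- match.arg(by)
  al <- join_tables(otu, sf, quiet = TRUE)
  rel <- unclass(to_relative(al$ft))
  groups <- as.character(al$sf[[by]])
  out <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    present <- rownames(rel)[rowSums(rel[, cols, drop = FALSE]) > 0]
    d <- functional_distances(traits, present)
    for (j in cols) {
      p <- rel[present, j]
      p <- p / sum(p)
      out[[length(out) + 1]] <- ternary_decompose(p, d) |>
        mutate(sample_id = al$sf$sample_id[j], .before = 1)
    }
  }
  purrr::list_rbind(out) |>
    left_join(al$sf |> select("sample_id", "stage", "ecosystem"),
              by = "sample_id") |>
    relocate("sample_id", "stage", "ecosystem")
}

#' perMANOVA on ternary coordinates
#'
#' Tests whether groups (ecosystems by default) separate in (D, Q, R) space
#' using Bray-Curtis distances between the triples and [permanova()] with
#' 9999 permutations by default.
#'
#' @param coords Output of [ternary_coordinates()].
#' @param group_var Grouping column (default `"ecosystem"`).
#' @param n_perm Permutations (default 9999).
#' @param seed Integer seed.
#' @return An `ms_permanova` object.
#' @export
ternary_group_test <- function(coords, group_var = "ecosystem",
                               n_perm = 9999, seed = 1L) {
  m <- as.matrix(coords[, c("D", "Q", "R")])
  rownames(m) <- coords$sample_id
  d <- vegan::vegdist(m, method = "bray")
  permanova(d, coords[[group_var]], n_perm = n_perm, seed = seed)
}

#' Taxonomic-functional diversity decoupling regressions
#'
#' Within each ecosystem, OLS of functional diversity on taxonomic diversity
#' (plus average genome size as a covariate when supplied); a significant
#' slope indicates low functional redundancy. The slope difference between
#' ecosystems is the F-test of the `ecosystem x tax` interaction in the
#' pooled model.
#'
#' @param df Tibble with columns `sample_id`, `tax_H`, `fun_H` and
#'   `ecosystem` (and `AGS` when `ags = TRUE`).
#' @param ags Adjust for average genome size.
#' @return A `ms_decoupling` object: per-ecosystem tibble plus interaction
#'   test; see `tidy()`/`glance()`.
#' @export
decoupling_regression <- function(df, ags = FALSE) {
  need <- c("tax_H", "fun_H", "ecosystem")
  if (!all(need %in% names(df))) {
    ms_abort("need columns tax_H, fun_H, ecosystem.", "format_error")
  }
  if (ags && !"AGS" %in% names(df)) ms_abort("AGS column required.", "format_error")
  tab <- table(df$ecosystem)
  if (length(tab) < 2 || any(tab < 4)) {
    ms_abort("need >= 4 samples in each of two ecosystems.",
             "insufficient_data_error")
  }
  per <- df |> group_by(.data$ecosystem) |> group_modify(function(d, key) {
    if (nrow(d) < 4) ms_abort("need >= 4 samples per ecosystem.",
                              "insufficient_data_error")
    if (stats::sd(d$tax_H) == 0) ms_abort("constant predictor.", "domain_error")
    f <- if (ags) fun_H ~ tax_H + AGS else fun_H ~ tax_H
    fit <- stats::lm(f, d)
    cf <- summary(fit)$coefficients
    tibble(slope = cf["tax_H", "Estimate"],
           intercept = cf["(Intercept)", "Estimate"],
           se_slope = cf["tax_H", "Std. Error"],
           p_slope = cf["tax_H", "Pr(>|t|)"],
           r_squared = summary(fit)$r.squared,
           df_residual = fit$df.residual,
           n = nrow(d))
  }) |> ungroup()
  fpool <- if (ags) fun_H ~ tax_H * ecosystem + AGS else fun_H ~ tax_H * ecosystem
  pooled <- stats::lm(fpool, df)
  an <- stats::anova(pooled)
  ia <- grep(":", rownames(an))
  structure(list(per_ecosystem = per,
                 slope_difference_F = an$`F value`[ia],
                 p_difference = an$`Pr(>F)`[ia],
                 ags_adjusted = ags),
            class = "ms_decoupling")
}

#' @export
print.ms_decoupling <- function(x, ...) {
  print(x$per_ecosystem)
  cat(sprintf("slope difference: F = %.3f, p = %s%s\n",
              x$slope_difference_F, format.pval(x$p_difference, digits = 3),
              if (x$ags_adjusted) " (AGS-adjusted)" else ""))
  invisible(x)
}

#' @export
tidy.ms_decoupling <- function(x, ...) x$per_ecosystem

#' @export
glance.ms_decoupling <- function(x, ...) {
  tibble(slope_difference_F = x$slope_difference_F,
         p_difference = x$p_difference,
         ags_adjusted = x$ags_adjusted)
}

#' Hierarchical partitioning of regression predictors
#'
#' Decomposes the full-model OLS R-squared into one independent contribution
#' per predictor: the average, over all hierarchy levels, of the predictor's
#' marginal R-squared gain across all subsets of the other predictors. The
#' contributions sum to the full-model R-squared by construction.
#'
#' @param response Numeric response vector.
#' @param predictors Data frame of numeric predictors (at most 6; all-subset
#'   enumeration grows exponentially).
#' @return A tibble: `predictor`, `independent_contribution`, plus attribute
#'   `full_r_squared`.
#' @export
hierarchical_partitioning <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  k <- ncol(predictors)
  if (k < 1) ms_abort("need at least one predictor.", "config_error")
  if (k > 6) {
    ms_abort("more than 6 predictors: all-subsets enumeration refused; supply a subset.",
             "config_error")
  }
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    fit <- stats::lm(response ~ ., data = predictors[, cols, drop = FALSE])
    suppressWarnings(summary(fit)$r.squared)
  }
  key <- function(s) paste0("s", paste(sort(s), collapse = ","))
  subsets <- unlist(lapply(0:k, function(s) {
    if (s == 0) list(integer(0)) else utils::combn(k, s, simplify = FALSE)
  }), recursive = FALSE)
  r2_cache <- vapply(subsets, r2, numeric(1))
  names(r2_cache) <- vapply(subsets, key, "")
  contrib <- vapply(seq_len(k), function(i) {
    others <- setdiff(seq_len(k), i)
    gains_by_level <- vapply(0:(k - 1), function(s) {
      subs <- if (s == 0) list(integer(0)) else
        lapply(utils::combn(seq_along(others), s, simplify = FALSE),
               function(ix) others[ix])
      gains <- vapply(subs, function(S) {
        r2_cache[[key(c(S, i))]] - r2_cache[[key(S)]]
      }, numeric(1))
      mean(gains)
    }, numeric(1))
    mean(gains_by_level)
  }, numeric(1))
  out <- tibble(predictor = names(predictors),
                independent_contribution = contrib)
  attr(out, "full_r_squared") <- r2_cache[[key(seq_len(k))]]
  out
}
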