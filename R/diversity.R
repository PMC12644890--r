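#' Alpha-diversity indices
#'
#' `shannon()` is entropy of relative abundances, `-sum(p log p)` in nats by
#' default (`0 * log 0 := 0`); `simpson_dominance()` is `sum(p^2)`, the
#' probability that two random reads share a feature. Both take a relative
#' abundance vector summing to 1.
#'
#' @param p Non-negative numeric vector summing to 1 (tolerance 1e-9).
#' @param base Logarithm base for `shannon()`; default `exp(1)` (nats).
#' @return A single number.
#' @export
#' @examples
#' shannon(rep(0.25, 4)) # log(4)
#' simpson_dominance(c(0.5, 0.3, 0.2))
shannon <- function(p, base = exp(1)) {
  check_rel_abund(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
simpson_dominance <- function(p) {
  check_rel_abund(p)
  sum(p^2)
}

check_rel_abund <- function(p) {
  if (any(p < 0)) ms_abort("relative abundances must be non-negative.", "domain_error")
  if (abs(sum(p) - 1) > 1e-9) {
    ms_abort("relative abundances must sum to 1 (tolerance 1e-9).", "domain_error")
  }
  invisible(p)
}

#' Per-sample diversity profile
#'
#' Computes richness, Shannon H' (nats) and Simpson dominance for every
#' sample of a feature table. Counts are converted to relative abundances
#' per sample first.
#'
#' @param ft A `feature_table`.
#' @return A tibble: `sample_id`, `richness`, `shannon_H`, `simpson_D`.
#' @export
diversity_profile <- function(ft) {
  rel <- to_relative(ft)
  m <- unclass(rel)
  tibble(
    sample_id = sample_ids(ft),
    richness = colSums(m > 0),
    shannon_H = apply(m, 2, shannon),
    simpson_D = apply(m, 2, simpson_dominance)
  )
}

#' Bray-Curtis dissimilarity
#'
#' `bray_curtis()` for a single pair of non-negative vectors,
#' `bray_curtis_matrix()` for all sample pairs of a feature table (via
#' \pkg{vegan}).
#'
#' @param x,y Non-negative numeric vectors of equal length, not both all-zero.
#' @return `bray_curtis()` a number in \[0, 1\]; `bray_curtis_matrix()` a
#'   `dist` object over samples.
#' @export
#' @examples
#' bray_curtis(c(2, 1, 0), c(1, 2, 1)) # 3/7
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) ms_abort("vectors must have equal length.", "domain_error")
  if (any(x < 0) || any(y < 0)) ms_abort("inputs must be non-negative.", "domain_error")
  tot <- sum(x) + sum(y)
  if (tot == 0) ms_abort("Bray-Curtis undefined for two all-zero vectors.", "domain_error")
  sum(abs(x - y)) / tot
}

#' @rdname bray_curtis
#' @param ft A `feature_table` (samples in columns).
#' @export
bray_curtis_matrix <- function(ft) {
  vegan::vegdist(t(unclass(ft)), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: eigendecomposition of the
#' double-centered `-d^2/2` matrix. Axes are ordered by eigenvalue; negative
#' eigenvalues are reported, not corrected.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of axes (at most n - 1).
#' @return A list with `coordinates` (tibble, `sample_id` + `PCo1..PCok`),
#'   `eigenvalues`, and `relative_eig` (positive-part proportions).
#' @export
pcoa <- function(d, k = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) ms_abort("PCoA needs at least 3 samples.", "domain_error")
  if (k > n - 1) ms_abort("k must be at most n - 1.", "domain_error")
  fit <- suppressWarnings(stats::cmdscale(dm, k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k) { # degenerate input: pad with zero axes
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  colnames(pts) <- paste0("PCo", seq_len(k))
  ids <- rownames(dm) %||% paste0("s", seq_len(n))
  pos <- fit$eig[fit$eig > 0]
  list(
    coordinates = as_tibble(as.data.frame(pts)) |> mutate(sample_id = ids, .before = 1),
    eigenvalues = fit$eig,
    relative_eig = if (length(pos)) fit$eig / sum(pos) else rep(0, length(fit$eig))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: step-up
#' adjusted values, monotone, capped at 1, original order preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    ms_abort("p-values must lie in [0, 1].", "domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Rank-based stage comparisons
#'
#' Kruskal-Wallis across stages, or all pairwise two-sided Wilcoxon rank-sum
#' tests with Benjamini-Hochberg adjustment. Midranks handle ties. If every
#' value is identical the result is flagged degenerate.
#'
#' @param values Numeric response, one per sample.
#' @param sf Sample frame aligned with `values`.
#' @param test `"kruskal_wallis"` or `"wilcoxon_pairwise"`.
#' @param group_var Grouping column of `sf` (default `"stage"`).
#' @return A tibble of test results; pairwise mode has one row per stage pair
#'   with `p_adj`.
#' @export
stage_comparisons <- function(values, sf,
                              test = c("kruskal_wallis", "wilcoxon_pairwise"),
                              group_var = "stage") {
  test <- match.arg(test)
  g <- droplevels(factor(sf[[group_var]]))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    ms_abort("need >= 2 groups with >= 2 samples each.", "insufficient_data_error")
  }
  if (length(unique(values)) == 1) {
    return(tibble(test = test, statistic = NA_real_, p = NA_real_,
                  degenerate = TRUE))
  }
  if (test == "kruskal_wallis") {
    kt <- stats::kruskal.test(values, g)
    tibble(test = test, statistic = unname(kt$statistic),
           df = unname(kt$parameter), p = kt$p.value, degenerate = FALSE)
  } else {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2)
    res <- purrr::map(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      wt <- suppressWarnings(stats::wilcox.test(values[g == a], values[g == b],
                                                exact = FALSE))
      tibble(group1 = a, group2 = b, statistic = unname(wt$statistic),
             p = wt$p.value)
    }) |> purrr::list_rbind()
    res$p_adj <- bh_adjust(res$p)
    res$degenerate <- FALSE
    res
  }
}

# small-sample corrected AIC for an lm fit
aicc <- function(fit) {
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1 # + sigma
  stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

#' Classify a covariate's response shape along the gradient
#'
#' Classifies a per-sample response over the four ordered stages as `flat`,
#' `linear`, `unimodal` or `threshold`. The flat/non-flat decision is an
#' alpha-level F-test of the saturated stage-means model against the constant
#' model, so the false-positive rate against a truly flat covariate is the
#' nominal alpha. When that gate rejects, the shape is chosen by small-sample
#' AICc among a linear trend on stage rank, a quadratic (unimodal) trend, and
#' a step at the threshold stage; a winning margin below 2 AICc units is
#' flagged ambiguous.
#'
#' @param values Numeric response per sample.
#' @param sf Sample frame aligned with `values`; all four stages must be
#'   present.
#' @param alpha Gate level for the flat test (default 0.05).
#' @param threshold_stage Stage at which the step model places its break
#'   (default `"forest"`, i.e. the step separates forest from all grasslands).
#' @return A tibble with `shape`, `ambiguous`, `gate_F`, `gate_p`, and the
#'   AICc of each candidate model.
#' @export
response_shape <- function(values, sf, alpha = 0.05, threshold_stage = "forest") {
  st <- sf$stage
  if (!all(stage_levels() %in% as.character(st))) {
    ms_abort("all four stages must be present.", "insufficient_data_error")
  }
  x <- as.integer(factor(as.character(st), levels = stage_levels()))
  step <- as.integer(x >= match(threshold_stage, stage_levels()))
  df <- data.frame(y = values, x = x, step = step, stage = factor(x))
  m_const <- stats::lm(y ~ 1, df)
  m_cells <- stats::lm(y ~ stage, df)
  gate <- stats::anova(m_const, m_cells)
  gate_F <- gate$F[2]
  gate_p <- gate$`Pr(>F)`[2]
  if (is.na(gate_p)) { # zero residual variance everywhere -> flat
    gate_p <- 1
    gate_F <- 0
  }
  m_lin <- stats::lm(y ~ x, df)
  m_quad <- stats::lm(y ~ x + I(x^2), df)
  m_step <- stats::lm(y ~ step, df)
  aic <- c(linear = aicc(m_lin), unimodal = aicc(m_quad), threshold = aicc(m_step))
  if (gate_p > alpha) {
    shape <- "flat"
    ambiguous <- FALSE
  } else {
    ord <- sort(aic)
    shape <- names(ord)[1]
    ambiguous <- (ord[2] - ord[1]) < 2
  }
  tibble(shape = shape, ambiguous = ambiguous,
         gate_F = gate_F, gate_p = gate_p,
         aicc_linear = aic[["linear"]], aicc_unimodal = aic[["unimodal"]],
         aicc_threshold = aic[["threshold"]])
}
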