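#' Limit-of-quantification filter for gene families
#'
#' Signal-to-noise rule: within the given sample set, a feature is retained
#' when its mean relative abundance is at least `q` times the standard error
#' of that abundance across samples (`q = 1.65` approximates a one-sided 95%
#' z-criterion). Features with identical abundance in every sample (SE = 0)
#' are retained; `q = 0` is the identity filter.
#'
#' @param gene_table A `feature_table`; converted to per-sample relative
#'   abundances internally.
#' @param q Positive signal-to-noise threshold (default 1.65).
#' @return The filtered `feature_table`, with attribute `loq_report`: a
#'   tibble of feature, mean, SE, signal-to-noise ratio and retention.
#' @export
loq_filter <- function(gene_table, q = 1.65) {
  if (q < 0) ms_abort("`q` must be non-negative.", "domain_error")
  rel <- unclass(to_relative(gene_table))
  mu <- rowMeans(rel)
  n <- ncol(rel)
  se <- apply(rel, 1, stats::sd) / sqrt(n)
  snr <- ifelse(se == 0, Inf, mu / se)
  keep <- snr >= q
  report <- tibble(feature_id = rownames(rel), mean_rel = mu, se = se,
                   snr = snr, retained = keep)
  out <- ft_like(unclass(gene_table)[keep, , drop = FALSE], gene_table)
  for (a in c("family_class", "substrate_class")) {
    attr(out, a) <- attr(gene_table, a)
  }
  attr(out, "loq_report") <- report
  out
}

#' Levin's niche breadth of a feature across samples
#'
#' `B = 1 / sum(p^2)` of the feature's occupancy distribution over the `N`
#' samples, and its standardization `(B - 1) / (N - 1)` in \[0, 1\]; `B = N`
#' iff occupancy is perfectly even, `B = 1` iff the feature occupies a
#' single sample.
#'
#' @param x Non-negative abundances of one feature over the samples of a
#'   stage.
#' @return A one-row tibble: `breadth_B`, `breadth_std`, `n_samples`. All-zero
#'   input yields `NA` with a warning.
#' @export
levins_breadth <- function(x) {
  if (any(x < 0)) ms_abort("abundances must be non-negative.", "domain_error")
  n <- length(x)
  if (sum(x) == 0) {
    ms_warn("all-zero occupancy; breadth undefined.", "breadth_warning")
    return(tibble(breadth_B = NA_real_, breadth_std = NA_real_, n_samples = n))
  }
  p <- x / sum(x)
  b <- 1 / sum(p^2)
  tibble(breadth_B = b,
         breadth_std = if (n > 1) (b - 1) / (n - 1) else NA_real_,
         n_samples = n)
}

#' Levin's niche overlap of two features
#'
#' Directional overlaps `O_fg = sum(f g) / sum(g^2)` and
#' `O_gf = sum(f g) / sum(f^2)` on occupancy distributions normalized to sum
#' 1, plus their mean clipped to \[0, 1\] (`symmetric`). Directional values
#' can exceed 1; only the symmetric mean is clipped.
#'
#' @param f,g Non-negative occupancy vectors over the same samples.
#' @return A one-row tibble: `O_fg`, `O_gf`, `symmetric`.
#' @export
levins_overlap <- function(f, g) {
  if (length(f) != length(g)) ms_abort("vectors must have equal length.", "domain_error")
  if (sum(f) == 0 || sum(g) == 0) {
    ms_abort("overlap undefined for an all-zero occupancy vector.", "domain_error")
  }
  f <- f / sum(f)
  g <- g / sum(g)
  cross <- sum(f * g)
  o_fg <- cross / sum(g^2)
  o_gf <- cross / sum(f^2)
  tibble(O_fg = o_fg, O_gf = o_gf,
         symmetric = min(max((o_fg + o_gf) / 2, 0), 1))
}

# all pairwise symmetric overlaps among rows of a (features x samples)
# occupancy matrix; returns the upper-triangle values
pairwise_symmetric_overlap <- function(m) {
  p <- m / rowSums(m)
  cross <- tcrossprod(p)          # sum f_i g_i
  ss <- diag(cross)               # sum f^2
  o <- (sweep(cross, 1, ss, "/") + sweep(cross, 2, ss, "/")) / 2
  # o[i, j] = (cross/ss_i + cross/ss_j)/2 = symmetric mean of directions
  pmin(pmax(o[upper.tri(o)], 0), 1)
}

#' Stage-wise niche-overlap summaries
#'
#' For every land-use stage and feature class, computes all pairwise
#' symmetric Levin overlaps among the retained features of that class, using
#' the stage's samples as the niche space. Stage differences in overlap are
#' tested pairwise by Wilcoxon rank-sum with Benjamini-Hochberg adjustment.
#'
#' @param gene_table A (typically LOQ-filtered) gene `feature_table`.
#' @param sf Sample frame covering the table's samples.
#' @param class_map Named vector mapping features to classes; defaults to the
#'   table's `family_class` attribute. Features without a class are skipped.
#' @param loq Limit-of-quantification threshold applied within each stage's
#'   sample set before computing overlaps (see [loq_filter()]); a gene can be
#'   well quantified in one land use and below the LOQ in another, so the
#'   screen must use the same niche space as the overlaps. `NULL` skips it
#'   (table assumed pre-filtered).
#' @param min_features Classes with fewer retained features per stage yield
#'   an `NA` row with a warning (default 2).
#' @param balance Overlap values depend systematically on the number of
#'   samples spanning the niche space, so stages with more samples score
#'   lower for that reason alone. When `TRUE` (default) every stage is
#'   subsampled to the smallest stage's sample count before computing
#'   overlaps, making stages comparable.
#' @param seed Seed for the balancing subsample.
#' @return A list with `summary` (stage x class tibble: `mean_overlap`,
#'   `sd_overlap`, `n_features`, `n_pairs`) and `tests` (pairwise stage
#'   Wilcoxon results per class).
#' @export
stage_overlap_summary <- function(gene_table, sf, class_map = NULL,
                                  loq = 1.65, min_features = 2,
                                  balance = TRUE, seed = 1L) {
  class_map <- class_map %||% attr(gene_table, "family_class")
  if (is.null(class_map)) ms_abort("no feature class map available.", "config_error")
  al <- join_tables(gene_table, sf, quiet = TRUE)
  m <- unclass(al$ft)
  stages <- intersect(stage_levels(), as.character(unique(al$sf$stage)))
  stage_cols <- lapply(stages, function(st) {
    al$sf$sample_id[as.character(al$sf$stage) == st]
  })
  names(stage_cols) <- stages
  if (balance && length(stages) > 1) {
    n_min <- min(lengths(stage_cols))
    stage_cols <- with_rng(seed, {
      lapply(stage_cols, function(cols) sort(sample(cols, n_min)))
    })
  }
  classes <- unique(class_map[rownames(m)])
  classes <- classes[!is.na(classes)]
  rows <- list()
  raw <- list()
  for (st in stages) {
    cols <- stage_cols[[st]]
    stage_keep <- rownames(m)
    if (!is.null(loq)) {
      stage_ft <- ft_like(m[, cols, drop = FALSE], al$ft)
      stage_keep <- feature_ids(loq_filter(stage_ft, q = loq))
    }
    for (cl in classes) {
      feats <- stage_keep[!is.na(class_map[stage_keep]) &
                            class_map[stage_keep] == cl]
      sub <- m[feats, cols, drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      if (nrow(sub) < min_features) {
        ms_warn(sprintf("stage %s, class %s: < %d retained features.",
                        st, cl, min_features), "overlap_warning")
        rows[[length(rows) + 1]] <- tibble(stage = st, class = cl,
                                           mean_overlap = NA_real_,
                                           sd_overlap = NA_real_,
                                           n_features = nrow(sub), n_pairs = 0L)
        next
      }
      ov <- pairwise_symmetric_overlap(sub)
      rows[[length(rows) + 1]] <- tibble(stage = st, class = cl,
                                         mean_overlap = mean(ov),
                                         sd_overlap = stats::sd(ov),
                                         n_features = nrow(sub),
                                         n_pairs = length(ov))
      raw[[paste(st, cl, sep = ".")]] <- ov
    }
  }
  summary <- purrr::list_rbind(rows)
  summary$stage <- factor(summary$stage, levels = stage_levels(), ordered = TRUE)
  tests <- list()
  for (cl in classes) {
    have <- stages[paste(stages, cl, sep = ".") %in% names(raw)]
    if (length(have) < 2) next
    pr <- utils::combn(have, 2)
    tt <- purrr::map(seq_len(ncol(pr)), function(i) {
      a <- raw[[paste(pr[1, i], cl, sep = ".")]]
      b <- raw[[paste(pr[2, i], cl, sep = ".")]]
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      p <- wt$p.value
      tibble(class = cl, stage1 = pr[1, i], stage2 = pr[2, i],
             statistic = unname(wt$statistic),
             p = if (is.finite(p)) p else NA_real_) # ties everywhere -> NA
    }) |> purrr::list_rbind()
    tt$p_adj <- NA_real_
    ok_p <- !is.na(tt$p)
    tt$p_adj[ok_p] <- bh_adjust(tt$p[ok_p])
    tests[[cl]] <- tt
  }
  list(summary = summary, tests = purrr::list_rbind(tests))
}

#' Trend of mean overlap across the ordered stages
#'
#' Fits linear and quadratic OLS of mean overlap on stage rank. The
#' quadratic is selected when its second-order term is significant by the
#' nested F-test at `alpha`; otherwise the linear fit is reported.
#'
#' @param summaries Tibble with `stage` and `mean_overlap` (optionally
#'   several classes; supply one class at a time).
#' @param alpha Level of the nested F-test (default 0.05).
#' @return A one-row tibble: `selected`, `slope` (linear stage-rank slope),
#'   `quad_term`, `p_quad`, `r_squared_linear`, `r_squared_quadratic`.
#' @export
overlap_trend <- function(summaries, alpha = 0.05) {
  dat <- summaries[!is.na(summaries$mean_overlap), , drop = FALSE]
  x <- as.integer(factor(as.character(dat$stage), levels = stage_levels()))
  if (length(unique(x)) < 3) {
    ms_abort("need >= 3 stages with overlap values.", "insufficient_data_error")
  }
  y <- dat$mean_overlap
  lin <- stats::lm(y ~ x)
  quad <- stats::lm(y ~ x + I(x^2))
  r2_lin <- suppressWarnings(summary(lin)$r.squared)
  r2_quad <- suppressWarnings(summary(quad)$r.squared)
  cmp <- stats::anova(lin, quad)
  p_quad <- cmp$`Pr(>F)`[2]
  # perfect quadratic fits leave no residual; treat as decisively quadratic
  if (is.na(p_quad)) {
    p_quad <- if (isTRUE(r2_quad > r2_lin + 1e-12)) 0 else 1
  }
  selected <- if (p_quad < alpha) "quadratic" else "linear"
  tibble(selected = selected,
         slope = unname(stats::coef(lin)[2]),
         quad_term = unname(stats::coef(quad)[3]),
         p_quad = p_quad,
         r_squared_linear = r2_lin,
         r_squared_quadratic = r2_quad)
}
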