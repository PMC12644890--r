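#' Partial omega-squared from a (blocked) ANOVA
#'
#' Fixed-effects ANOVA of `values` on `groups`, with an optional blocking
#' factor (site pair). The effect size for the grouping factor is
#' `omega_p^2 = (SS_eff - df_eff * MS_err) / (SS_eff + (N - df_eff) * MS_err)`,
#' zero when the effect mean square equals the error mean square and bounded
#' above by 1.
#'
#' @param values Numeric response.
#' @param groups Factor of interest (e.g. ecosystem).
#' @param blocks Optional blocking factor (e.g. pair id).
#' @return A list with `estimate`, `ss_effect`, `df_effect`, `ms_error`, `n`,
#'   and `degenerate`.
#' @export
omega_sq_partial <- function(values, groups, blocks = NULL) {
  g <- droplevels(factor(groups))
  dat <- data.frame(y = values, g = g)
  if (!is.null(blocks)) dat$b <- droplevels(factor(blocks))
  if (length(unique(values)) == 1) {
    return(list(estimate = NA_real_, ss_effect = 0, df_effect = nlevels(g) - 1,
                ms_error = 0, n = length(values), degenerate = TRUE))
  }
  form <- if (is.null(blocks)) y ~ g else y ~ g + b
  fit <- stats::aov(form, dat)
  an <- stats::anova(fit)
  ss_eff <- an["g", "Sum Sq"]
  df_eff <- an["g", "Df"]
  ms_err <- an["Residuals", "Mean Sq"]
  n <- length(values)
  est <- (ss_eff - df_eff * ms_err) / (ss_eff + (n - df_eff) * ms_err)
  list(estimate = est, ss_effect = ss_eff, df_effect = df_eff,
       ms_error = ms_err, n = n, degenerate = !is.finite(est))
}

#' Paired grassland-forest effect size (partial omega-squared)
#'
#' Contrasts one grassland stage against its paired forest sites with a
#' two-way fixed-effects ANOVA (`ecosystem + pair`), the pair factor playing
#' the role of the study's random block. The 95% confidence interval comes
#' from a seeded nonparametric bootstrap over pairs.
#'
#' @param values Numeric response, one per sample, aligned with `sf`.
#' @param sf Sample frame.
#' @param grassland_stage Which grassland stage to contrast with forest
#'   (`"managed"`, `"recent"` or `"late"`).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return A one-row tibble: `name`, `stage`, `estimate`, `ci_low`,
#'   `ci_high`, `n1`, `n2`.
#' @export
paired_anova_omega <- function(values, sf, grassland_stage,
                               n_boot = 2000, seed = 1L) {
  if (!grassland_stage %in% setdiff(stage_levels(), "forest")) {
    ms_abort("`grassland_stage` must be managed, recent or late.", "config_error")
  }
  ok_pairs <- suppressWarnings(paired_ids(sf))
  keep <- !is.na(sf$pair_id) & sf$pair_id %in% ok_pairs &
    (as.character(sf$stage) == grassland_stage | sf$ecosystem == "forest")
  dat <- tibble(y = values[keep],
                eco = sf$ecosystem[keep],
                pair = sf$pair_id[keep])
  # keep only pairs represented in both ecosystems for this stage subset
  both <- dat |> distinct(.data$pair, .data$eco) |> count(.data$pair) |>
    filter(.data$n == 2) |> pull(.data$pair)
  dat <- dat |> filter(.data$pair %in% both)
  if (length(both) < 3) {
    ms_abort("need >= 3 complete grassland-forest pairs.", "insufficient_data_error")
  }
  est <- omega_sq_partial(dat$y, dat$eco, dat$pair)$estimate
  boot <- with_rng(seed, {
    vapply(seq_len(n_boot), function(i) {
      bp <- sample(both, length(both), replace = TRUE)
      # resampled pairs get fresh ids so duplicated pairs stay distinct blocks
      res <- purrr::imap(bp, function(p, k) {
        d <- dat[dat$pair == p, , drop = FALSE]
        d$pair <- paste0("bs", k)
        d
      }) |> purrr::list_rbind()
      if (length(unique(res$y)) == 1 || length(unique(res$eco)) < 2) {
        return(NA_real_)
      }
      omega_sq_partial(res$y, res$eco, res$pair)$estimate
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble(name = "partial_omega_sq", stage = grassland_stage,
         estimate = est, ci_low = ci[1], ci_high = ci[2],
         n1 = sum(dat$eco != "forest"), n2 = sum(dat$eco == "forest"))
}

#' Hedges' g (bias-corrected standardized mean difference)
#'
#' `g = J * (mean(x) - mean(y)) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4 (n_x + n_y - 2) - 1)`; the 95% CI uses the standard
#' normal approximation to the sampling variance of g.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A one-row tibble: `name`, `estimate`, `ci_low`, `ci_high`, `n1`,
#'   `n2`.
#' @export
#' @examples
#' hedges_g(c(1, 2, 3), c(3, 4, 5)) # g = -1.6
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) ms_abort("need >= 2 values per group.", "insufficient_data_error")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df)
  if (sp == 0) ms_abort("pooled SD is zero; g undefined.", "domain_error")
  j <- 1 - 3 / (4 * df - 1)
  g <- j * (mean(x) - mean(y)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
  tibble(name = "hedges_g", estimate = g,
         ci_low = g - 1.959963984540054 * se,
         ci_high = g + 1.959963984540054 * se,
         n1 = n1, n2 = n2)
}
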