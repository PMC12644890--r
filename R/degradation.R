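#' Read a substrate-induced respiration table
#'
#' TSV with columns `sample_id`, `basal` and the six substrate columns
#' glucose, glycine, oxalic_acid, yeast, lignin, chitin (raw rates, basal
#' not yet subtracted).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_sir <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "basal", sir_substrates())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ms_abort(paste0("missing SIR column(s): ", paste(miss, collapse = ", ")),
             "format_error")
  }
  df
}

#' Basal-corrected substrate respiration rates
#'
#' Subtracts the per-sample basal rate from every substrate rate (the water
#' flushing correction). Negative net rates are retained, not floored, and
#' flagged in the `negative_net` attribute.
#'
#' @param profiles SIR tibble (`sample_id`, `basal`, six substrate columns).
#' @return Tibble of the same shape with net rates; attribute `negative_net`
#'   lists flagged sample/substrate combinations.
#' @export
net_sir <- function(profiles) {
  subs <- sir_substrates()
  miss <- setdiff(c("basal", subs), names(profiles))
  if (length(miss)) {
    ms_abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
             "format_error")
  }
  out <- profiles
  flags <- list()
  for (s in subs) {
    out[[s]] <- profiles[[s]] - profiles$basal
    neg <- which(out[[s]] < 0)
    if (length(neg)) {
      flags[[s]] <- tibble(sample_id = profiles$sample_id[neg], substrate = s,
                           net_rate = out[[s]][neg])
    }
  }
  attr(out, "negative_net") <- purrr::list_rbind(flags)
  out
}

#' Multiple substrate-induced respiration (MSIR)
#'
#' Aggregate catabolic capacity: the sum of basal-corrected rates over the
#' six substrates, `MSIR = sum_s (rate_s - basal)`.
#'
#' @param profiles Raw SIR tibble (basal subtraction happens internally).
#' @return Tibble `sample_id`, `msir`.
#' @export
msir <- function(profiles) {
  net <- net_sir(profiles)
  tibble(sample_id = net$sample_id,
         msir = rowSums(as.matrix(net[, sir_substrates()])))
}

#' Paired effect sizes of substrate respiration
#'
#' Hedges' g of each substrate's net rate between every grassland stage and
#' its paired forest sites, oriented forest-minus-grassland (positive g
#' means higher forest rates).
#'
#' @param profiles Raw SIR tibble.
#' @param sf Sample frame covering the profiled samples.
#' @return A tibble with one row per (grassland stage, substrate):
#'   Hedges' g with normal-approximation CI and group sizes.
#' @export
substrate_effect_sizes <- function(profiles, sf) {
  net <- net_sir(profiles)
  dat <- net |> inner_join(sf |> select("sample_id", "stage", "ecosystem",
                                        "pair_id"),
                           by = "sample_id")
  ok <- suppressWarnings(paired_ids(sf))
  dat <- dat |> filter(!is.na(.data$pair_id), .data$pair_id %in% ok)
  out <- list()
  present <- intersect(setdiff(stage_levels(), "forest"),
                       as.character(unique(dat$stage)))
  if (!length(present)) {
    ms_abort("no paired grassland SIR samples available.",
             "insufficient_data_error")
  }
  for (gs in present) {
    g_rows <- dat |> filter(as.character(.data$stage) == gs)
    f_rows <- dat |> filter(.data$ecosystem == "forest",
                            .data$pair_id %in% g_rows$pair_id)
    if (nrow(g_rows) < 2 || nrow(f_rows) < 2) {
      ms_abort(sprintf("stage %s: need >= 2 complete pairs with SIR data.", gs),
               "insufficient_data_error")
    }
    for (s in sir_substrates()) {
      es <- hedges_g(f_rows[[s]], g_rows[[s]])
      out[[length(out) + 1]] <- es |>
        mutate(stage = gs, substrate = s, .before = 1)
    }
  }
  purrr::list_rbind(out)
}

#' MSIR against diversity predictors
#'
#' For each candidate diversity predictor: OLS of MSIR on the predictor
#' within each ecosystem and pooled, the ecosystem-slope-homogeneity
#' interaction F, and the pooled Pearson correlation with its degrees of
#' freedom.
#'
#' @param msir_tbl Tibble `sample_id`, `msir` (see [msir()]).
#' @param diversity Tibble with `sample_id` plus one numeric column per
#'   predictor (e.g. taxonomic H', C-gene H' per kingdom).
#' @param sf Sample frame.
#' @return A list with `fits` (per predictor x scope tibble) and
#'   `interactions` (per predictor slope-homogeneity tests).
#' @export
msir_diversity_regression <- function(msir_tbl, diversity, sf) {
  preds <- setdiff(names(diversity), "sample_id")
  dat <- msir_tbl |>
    inner_join(diversity, by = "sample_id") |>
    inner_join(sf |> select("sample_id", "ecosystem"), by = "sample_id")
  if (nrow(dat) < 4) ms_abort("too few aligned samples.", "insufficient_data_error")
  fits <- list()
  inters <- list()
  for (pv in preds) {
    x <- dat[[pv]]
    if (stats::sd(x) == 0) ms_abort(paste0("constant predictor: ", pv), "domain_error")
    scopes <- c(split(seq_len(nrow(dat)), dat$ecosystem),
                list(pooled = seq_len(nrow(dat))))
    for (sc in names(scopes)) {
      idx <- scopes[[sc]]
      fit <- stats::lm(dat$msir[idx] ~ x[idx])
      cf <- summary(fit)$coefficients
      ct <- stats::cor.test(x[idx], dat$msir[idx])
      fits[[length(fits) + 1]] <- tibble(
        predictor = pv, scope = sc,
        slope = cf[2, "Estimate"], se_slope = cf[2, "Std. Error"],
        p_slope = cf[2, "Pr(>|t|)"], r_squared = summary(fit)$r.squared,
        pearson_r = unname(ct$estimate), df = unname(ct$parameter),
        n = length(idx))
    }
    pool <- stats::lm(msir ~ x * ecosystem, data = dat |> mutate(x = x))
    an <- stats::anova(pool)
    ia <- grep(":", rownames(an))
    inters[[length(inters) + 1]] <- tibble(
      predictor = pv, interaction_F = an$`F value`[ia],
      p_interaction = an$`Pr(>F)`[ia])
  }
  list(fits = purrr::list_rbind(fits), interactions = purrr::list_rbind(inters))
}
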