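#' Per-sample design and covariate metadata
#'
#' A sample frame is a tibble with one row per sample. Required columns are
#' `sample_id`, `site_id`, `pair_id` (may be `NA` for unpaired sites) and
#' `stage`; `stage` is an ordered factor over the fixed vocabulary
#' `managed < recent < late < forest`, and `ecosystem` is derived from it
#' (`forest` stage -> forest, all grassland stages -> grassland). Any further
#' columns (pH, C:N, SOC, LDMC, climate, parent material, AGS, ...) are
#' carried along; empty cells become `NA` and are never imputed.
#'
#' @param df A data frame with at least the required columns.
#' @return A validated tibble with ordered `stage` and derived `ecosystem`.
#' @export
sample_frame <- function(df) {
  need <- c("sample_id", "site_id", "pair_id", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ms_abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
             "format_error")
  }
  df <- as_tibble(df)
  if (anyDuplicated(df$sample_id)) {
    ms_abort("duplicate sample_id in sample frame.", "format_error")
  }
  st <- as.character(df$stage)
  bad <- setdiff(unique(st), stage_levels())
  if (length(bad)) {
    ms_abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", "),
                    " (expected ", paste(stage_levels(), collapse = ", "), ")"),
             "vocabulary_error")
  }
  df$stage <- factor(st, levels = stage_levels(), ordered = TRUE)
  df$ecosystem <- ifelse(df$stage == "forest", "forest", "grassland")
  df$pair_id[!is.na(df$pair_id) & df$pair_id == ""] <- NA
  df
}

#' @rdname sample_frame
#' @param path TSV file path (tab-delimited, UTF-8, "." decimal; empty cells
#'   are read as missing).
#' @export
read_sample_frame <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  sample_frame(df)
}

#' @rdname sample_frame
#' @param sf A sample frame.
#' @export
write_sample_frame <- function(sf, path) {
  out <- sf
  out$stage <- as.character(out$stage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(sf)
}

#' Valid grassland-forest pairs
#'
#' A valid pair has at least one grassland and at least one forest sample.
#' Pairs broken on either side are excluded from paired analyses with a
#' warning naming them.
#'
#' @param sf A sample frame.
#' @return Character vector of valid `pair_id`s.
#' @export
paired_ids <- function(sf) {
  sub <- sf[!is.na(sf$pair_id), , drop = FALSE]
  tab <- table(factor(sub$pair_id),
               factor(sub$ecosystem, levels = c("grassland", "forest")))
  ok <- rownames(tab)[tab[, "grassland"] > 0 & tab[, "forest"] > 0]
  broken <- setdiff(rownames(tab), ok)
  if (length(broken)) {
    ms_warn(paste0("pair(s) without both ecosystems dropped from paired analyses: ",
                   paste(broken, collapse = ", ")), "pairing_warning")
  }
  ok
}
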