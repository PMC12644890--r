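#' Discard samples with insufficient sequencing depth
#'
#' Samples whose column sum falls below `min_reads` are removed; samples with
#' exactly `min_reads` reads are retained. Removed sample ids are reported in
#' the `removed` attribute and via a message.
#'
#' @param ft A `feature_table` of integer counts.
#' @param min_reads Minimum retained depth (reads). Conventional defaults are
#'   100 for ITS-like and 3000 for 16S-like tables.
#' @param quiet Suppress the removal message.
#' @return The filtered `feature_table`, with attribute `removed`.
#' @export
filter_low_depth <- function(ft, min_reads, quiet = FALSE) {
  depth <- colSums(ft)
  keep <- depth >= min_reads
  if (!any(keep)) {
    ms_abort(sprintf("all samples have depth < %s.", format(min_reads)),
             "empty_table_error")
  }
  removed <- sample_ids(ft)[!keep]
  if (length(removed) && !quiet) {
    inform(sprintf("filter_low_depth: removed %d sample(s): %s",
                   length(removed), paste(removed, collapse = ", ")))
  }
  out <- ft_like(unclass(ft)[, keep, drop = FALSE], ft)
  attr(out, "removed") <- removed
  out
}

#' Normalization specification
#'
#' @param method `"srs"`, `"rarefy"` or `"relative"`.
#' @param cmin Target depth (positive integer) for `srs` and `rarefy`.
#' @param seed Integer seed (used by `rarefy` and by the random SRS
#'   tie-break).
#' @param tie_break SRS tie handling among equal fractional parts:
#'   `"by_count_then_index"` (deterministic, default) or `"random"` (seeded).
#' @return A `normalization_spec` list.
#' @export
normalization_spec <- function(method = c("srs", "rarefy", "relative"),
                               cmin = NULL, seed = 1L,
                               tie_break = c("by_count_then_index", "random")) {
  method <- match.arg(method)
  tie_break <- match.arg(tie_break)
  if (method != "relative") {
    if (is.null(cmin) || cmin < 1 || cmin != round(cmin)) {
      ms_abort("`cmin` must be a positive integer.", "config_error")
    }
  }
  structure(list(method = method, cmin = cmin, seed = as.integer(seed),
                 tie_break = tie_break),
            class = "normalization_spec")
}

# one column of SRS: scale to cmin, keep integer parts, hand the remaining
# units to the largest fractional parts (ties by larger original count, then
# feature index, or seeded-random)
srs_column <- function(x, cmin, tie_break) {
  scaled <- x * cmin / sum(x)
  fl <- floor(scaled)
  left <- as.integer(round(cmin - sum(fl)))
  if (left > 0) {
    frac <- scaled - fl
    ord <- switch(tie_break,
      by_count_then_index = order(-frac, -x, seq_along(x)),
      random = order(-frac, sample.int(length(x)))
    )
    give <- ord[seq_len(left)]
    fl[give] <- fl[give] + 1
  }
  fl
}

#' Scaling with ranked subsampling (SRS)
#'
#' Deterministic depth normalization: each column is scaled by
#' `cmin / colsum`, integer parts are kept, and the remaining
#' `cmin - sum(floors)` units are distributed one each to the features with
#' the largest fractional parts. Every output column sums to exactly `cmin`.
#' Ties among fractional parts are broken by larger original count then
#' feature index (default) or by a seeded random draw.
#'
#' @param ft A `feature_table` of counts.
#' @param spec A [normalization_spec()] with `method = "srs"`.
#' @return A `feature_table` with integer columns summing to `cmin`.
#' @export
#' @examples
#' m <- matrix(c(6, 3, 1), 3, 1, dimnames = list(paste0("f", 1:3), "s1"))
#' ft <- feature_table(m, "otu", "16S")
#' srs_normalize(ft, normalization_spec("srs", cmin = 5))
srs_normalize <- function(ft, spec) {
  cmin <- spec$cmin
  depth <- colSums(ft)
  low <- which(depth < cmin)
  if (length(low)) {
    ms_abort(sprintf("cmin = %d exceeds depth of sample(s): %s",
                     cmin, paste(sample_ids(ft)[low], collapse = ", ")),
             "depth_error")
  }
  run <- function() {
    out <- vapply(seq_len(ncol(ft)),
                  function(j) srs_column(unclass(ft)[, j], cmin, spec$tie_break),
                  numeric(nrow(ft)))
    dimnames(out) <- dimnames(ft)
    ft_like(out, ft)
  }
  if (spec$tie_break == "random") with_rng(spec$seed, run()) else run()
}

#' Rarefaction to fixed depth
#'
#' Each column is subsampled without replacement to `cmin` reads (one
#' multivariate-hypergeometric draw per sample), seeded.
#' Features absent from a sample stay absent.
#'
#' @inheritParams srs_normalize
#' @param cmin Target depth; defaults to `spec$cmin`.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A `feature_table` of integer counts, columns summing to `cmin`.
#' @export
rarefy_table <- function(ft, cmin, seed = 1L) {
  depth <- colSums(ft)
  low <- which(depth < cmin)
  if (length(low)) {
    ms_abort(sprintf("cmin = %d exceeds depth of sample(s): %s",
                     cmin, paste(sample_ids(ft)[low], collapse = ", ")),
             "depth_error")
  }
  m <- unclass(ft)
  if (any(m != round(m))) {
    ms_abort("rarefaction requires integer counts.", "format_error")
  }
  with_rng(seed, {
    out <- vapply(seq_len(ncol(m)), function(j) {
      rmvhyper(m[, j], cmin)
    }, numeric(nrow(m)))
    dimnames(out) <- dimnames(ft)
    ft_like(out, ft)
  })
}

# multivariate hypergeometric draw via sequential rhyper
rmvhyper <- function(counts, n) {
  k <- length(counts)
  out <- numeric(k)
  remaining <- sum(counts)
  for (i in seq_len(k)) {
    if (n == 0) break
    if (counts[i] == 0) {
      remaining <- remaining - counts[i]
      next
    }
    if (remaining == counts[i]) {
      out[i] <- n
      n <- 0
      break
    }
    x <- stats::rhyper(1, counts[i], remaining - counts[i], n)
    out[i] <- x
    n <- n - x
    remaining <- remaining - counts[i]
  }
  out
}

#' Relative-abundance transform
#'
#' @param ft A `feature_table` with positive column sums.
#' @return A `feature_table` whose columns sum to 1.
#' @export
to_relative <- function(ft) {
  depth <- colSums(ft)
  if (any(depth <= 0)) {
    bad <- sample_ids(ft)[depth <= 0]
    ms_abort(paste0("zero-depth sample(s): ", paste(bad, collapse = ", ")),
             "empty_table_error")
  }
  ft_like(sweep(unclass(ft), 2, depth, "/"), ft)
}

#' Apply a normalization spec
#'
#' Dispatches to [srs_normalize()], [rarefy_table()] or [to_relative()].
#'
#' @inheritParams srs_normalize
#' @export
normalize_table <- function(ft, spec) {
  switch(spec$method,
         srs = srs_normalize(ft, spec),
         rarefy = rarefy_table(ft, spec$cmin, spec$seed),
         relative = to_relative(ft))
}

#' Community-weighted mean of a trait
#'
#' Weighted mean of per-species trait values with weights renormalized over
#' the species that have trait data; the covered fraction of total cover is
#' reported alongside.
#'
#' @param cover Non-negative per-species abundances or cover values.
#' @param trait Per-species trait values; `NA` where unknown.
#' @return A tibble with `cwm` and `coverage`. `cwm` is `NA` (with a warning)
#'   when no species has trait data.
#' @export
community_weighted_mean <- function(cover, trait) {
  if (length(cover) != length(trait)) {
    ms_abort("`cover` and `trait` must have equal length.", "format_error")
  }
  has <- !is.na(trait)
  total <- sum(cover)
  if (!any(has) || sum(cover[has]) == 0) {
    ms_warn("no species with trait data; CWM is NA.", "cwm_warning")
    return(tibble(cwm = NA_real_, coverage = 0))
  }
  w <- cover[has] / sum(cover[has])
  tibble(cwm = sum(w * trait[has]),
         coverage = if (total > 0) sum(cover[has]) / total else NA_real_)
}
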