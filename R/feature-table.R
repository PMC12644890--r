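#' Feature-by-sample count tables
#'
#' A `feature_table` is a numeric matrix with features (OTUs or gene families)
#' in rows and samples in columns, following the common OTU-table convention,
#' plus two tags: `kind` (`"otu"` or `"gene"`) and `marker` (`"16S"`, `"ITS"`,
#' `"metagenome"` or `"predicted"`). Values must be non-negative; integer
#' counts before normalization, non-negative reals after.
#'
#' @param values Numeric matrix, features x samples, with row and column names.
#' @param kind `"otu"` or `"gene"`.
#' @param marker `"16S"`, `"ITS"`, `"metagenome"` or `"predicted"`.
#' @return A `feature_table` object.
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' ft <- feature_table(m, kind = "otu", marker = "16S")
#' sample_ids(ft)
feature_table <- function(values, kind = c("otu", "gene"),
                          marker = c("16S", "ITS", "metagenome", "predicted")) {
  kind <- match.arg(kind)
  marker <- match.arg(marker)
  if (!is.matrix(values) || !is.numeric(values)) {
    ms_abort("`values` must be a numeric matrix (features x samples).", "format_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ms_abort("feature and sample ids (dimnames) are required.", "format_error")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    ms_abort(paste0("duplicate feature id(s): ", paste(dup, collapse = ", ")),
             "format_error")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    ms_abort(paste0("duplicate sample id(s): ", paste(dup, collapse = ", ")),
             "format_error")
  }
  if (anyNA(values)) ms_abort("missing values are not allowed.", "format_error")
  if (any(values < 0)) ms_abort("negative values are not allowed.", "format_error")
  structure(values, class = c("feature_table", "matrix", "array"),
            kind = kind, marker = marker)
}

#' @rdname feature_table
#' @param ft A `feature_table`.
#' @export
feature_ids <- function(ft) rownames(ft)

#' @rdname feature_table
#' @export
sample_ids <- function(ft) colnames(ft)

#' @rdname feature_table
#' @export
table_kind <- function(ft) attr(ft, "kind")

#' @rdname feature_table
#' @export
table_marker <- function(ft) attr(ft, "marker")

# rebuild tags after matrix surgery
ft_like <- function(values, template) {
  feature_table(values, kind = attr(template, "kind"),
                marker = attr(template, "marker"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples [kind=%s, marker=%s]\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "marker")))
  n <- min(nrow(x), 5L); m <- min(ncol(x), 5L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

#' @export
as_tibble.feature_table <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)), rownames = "feature_id")
}

#' Read and write feature tables as TSV
#'
#' Tab-delimited UTF-8 text with feature ids in the first column and sample
#' ids in the header row. Duplicated ids, negative values and non-numeric
#' cells are rejected with informative errors; integer counts round-trip
#' bit-exactly.
#'
#' @param path File path.
#' @inheritParams feature_table
#' @return `read_feature_table()` a `feature_table`;
#'   `write_feature_table()` the input, invisibly.
#' @export
read_feature_table <- function(path, kind = c("otu", "gene"),
                               marker = c("16S", "ITS", "metagenome", "predicted")) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) ms_abort("need a feature-id column plus >= 1 sample.", "format_error")
  ids <- raw[[1]]
  num <- raw[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad)) {
      ms_abort(sprintf("non-numeric value '%s' at row %d, column '%s'.",
                       num[[j]][bad[1]], bad[1], names(num)[j]), "parse_error")
    }
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  feature_table(m, kind = kind, marker = marker)
}

#' @rdname read_feature_table
#' @param ft A `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(feature_id = rownames(ft), unclass(ft),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ft)
}

#' Align a feature table with a sample frame
#'
#' Restricts both objects to their common samples in the feature table's
#' order and reports how many samples were dropped from each side. The
#' operation is idempotent.
#'
#' @param ft A `feature_table`.
#' @param sf A sample frame (see [read_sample_frame()]).
#' @param quiet Suppress the dropped-sample message.
#' @return A list with elements `ft`, `sf`, and `dropped` (named counts).
#' @export
join_tables <- function(ft, sf, quiet = FALSE) {
  common <- intersect(sample_ids(ft), sf$sample_id)
  if (length(common) == 0) {
    ms_abort("no samples shared between feature table and sample frame.",
             "alignment_error")
  }
  common <- sample_ids(ft)[sample_ids(ft) %in% common]
  dropped <- c(feature_table = ncol(ft) - length(common),
               sample_frame = nrow(sf) - length(common))
  if (!quiet && sum(dropped) > 0) {
    inform(sprintf("join_tables: dropped %d table sample(s), %d metadata sample(s).",
                   dropped[[1]], dropped[[2]]))
  }
  sf2 <- sf[match(common, sf$sample_id), , drop = FALSE]
  list(ft = ft_like(unclass(ft)[, common, drop = FALSE], ft),
       sf = sf2, dropped = dropped)
}
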