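#' Taxa-by-gene-family trait matrices
#'
#' Gene-copy counts per taxon, used for functional distances. Each gene
#' family is assigned exactly one nutrient class (C, N or P); C-cycling
#' families may additionally carry a substrate class (oligosaccharides up to
#' chitin/lignin) used when partitioning niche overlap by substrate.
#'
#' @param values Non-negative numeric matrix, taxa x gene families, with
#'   dimnames.
#' @param family_class Named character vector mapping every gene family to
#'   `"C"`, `"N"` or `"P"`.
#' @param substrate_class Optional named character vector mapping C-cycling
#'   families to substrate categories.
#' @return A `trait_matrix` object.
#' @export
trait_matrix <- function(values, family_class, substrate_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    ms_abort("`values` must be a numeric matrix (taxa x gene families).",
             "format_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ms_abort("taxon and gene-family ids (dimnames) are required.", "format_error")
  }
  if (any(values < 0) || anyNA(values)) {
    ms_abort("gene-copy counts must be non-negative and complete.", "format_error")
  }
  fams <- colnames(values)
  if (!all(fams %in% names(family_class))) {
    ms_abort("every gene family needs a nutrient class (C/N/P).", "format_error")
  }
  fc <- family_class[fams]
  if (!all(fc %in% c("C", "N", "P"))) {
    ms_abort("nutrient classes must be C, N or P.", "format_error")
  }
  structure(values, class = c("trait_matrix", "matrix", "array"),
            family_class = fc,
            substrate_class = substrate_class)
}

#' @rdname trait_matrix
#' @param tm A `trait_matrix`.
#' @export
family_classes <- function(tm) attr(tm, "family_class")

#' @rdname trait_matrix
#' @export
substrate_classes <- function(tm) attr(tm, "substrate_class")

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d taxa x %d gene families (C=%d, N=%d, P=%d)\n",
              nrow(x), ncol(x),
              sum(attr(x, "family_class") == "C"),
              sum(attr(x, "family_class") == "N"),
              sum(attr(x, "family_class") == "P")))
  invisible(x)
}

#' @rdname trait_matrix
#' @param path TSV path. The matrix is written taxa-in-rows; classes go to a
#'   companion two/three-column TSV (`<path>.classes.tsv` by default).
#' @param classes_path Companion class-map path.
#' @export
write_trait_matrix <- function(tm, path,
                               classes_path = paste0(path, ".classes.tsv")) {
  df <- data.frame(taxon_id = rownames(tm), unclass(tm),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- attr(tm, "substrate_class")
  cls <- data.frame(gene_family = colnames(tm),
                    nutrient_class = unname(attr(tm, "family_class")),
                    substrate_class = if (is.null(sc)) NA_character_ else
                      unname(sc[colnames(tm)]),
                    check.names = FALSE)
  utils::write.table(cls, classes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(tm)
}

#' @rdname trait_matrix
#' @export
read_trait_matrix <- function(path, classes_path = paste0(path, ".classes.tsv")) {
  raw <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(raw[-1])
  rownames(m) <- raw[[1]]
  cls <- utils::read.delim(classes_path, check.names = FALSE,
                           na.strings = c("", "NA"))
  fc <- stats::setNames(cls$nutrient_class, cls$gene_family)
  sc <- NULL
  if (!all(is.na(cls$substrate_class))) {
    keep <- !is.na(cls$substrate_class)
    sc <- stats::setNames(cls$substrate_class[keep], cls$gene_family[keep])
  }
  trait_matrix(m, fc, sc)
}
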