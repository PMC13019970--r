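#' Construct a feature-by-sample abundance table
#'
#' The central container of the package: a non-negative numeric matrix with
#' features (ASVs or rank-aggregated taxa) as rows and samples as columns,
#' tagged with the kingdom it describes and whether it holds read counts or
#' relative abundances. Bacterial and fungal data are never mixed in one
#' matrix; the kingdom travels with the table as an attribute.
#'
#' @param values numeric matrix, features x samples, with unique row and
#'   column names. All entries must be finite and non-negative.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param mode `"counts"` (reads) or `"relative"` (per-sample fractions). In
#'   relative mode every sample column must sum to 1 within `1e-9`.
#' @return An `abundance_table` object (a classed matrix with `kingdom` and
#'   `mode` attributes).
#' @examples
#' m <- matrix(c(3, 1, 0, 2, 2, 2), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' abundance_table(m, "bacteria")
#' @export
abundance_table <- function(values, kingdom = c("bacteria", "fungi"),
                            mode = c("counts", "relative")) {
  kingdom <- match.arg(kingdom)
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("`values` contains NA/NaN/Inf entries")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (mode == "relative") {
    cs <- colSums(values)
    if (any(cs == 0)) {
      stop("all-zero sample column(s) in relative mode: ",
           paste(colnames(values)[cs == 0], collapse = ", "))
    }
    if (any(abs(cs - 1) > 1e-9)) {
      stop("relative-mode columns must sum to 1 (off: ",
           paste(colnames(values)[abs(cs - 1) > 1e-9], collapse = ", "), ")")
    }
  }
  structure(values, class = c("abundance_table", "matrix", "array"),
            kingdom = kingdom, mode = mode)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "kingdom"), attr(x, "mode")))
  if (attr(x, "mode") == "counts") {
    cat(sprintf("  reads per sample: %s-%s\n",
                format(min(colSums(x))), format(max(colSums(x)))))
  }
  invisible(x)
}

#' @rdname abundance_table
#' @param x object to test or strip.
#' @export
is_abundance_table <- function(x) inherits(x, "abundance_table")

#' @rdname abundance_table
#' @export
table_kingdom <- function(x) attr(x, "kingdom")

#' @rdname abundance_table
#' @export
table_mode <- function(x) attr(x, "mode")

# plain numeric matrix view (internal)
at_matrix <- function(x) {
  stopifnot(is_abundance_table(x))
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

# column subset preserving class/attrs (internal; keeps both modes valid)
at_samples <- function(x, ids) {
  miss <- setdiff(ids, colnames(x))
  if (length(miss)) stop("unknown sample IDs: ", paste(miss, collapse = ", "))
  abundance_table(at_matrix(x)[, ids, drop = FALSE],
                  kingdom = table_kingdom(x), mode = table_mode(x))
}

#' Read an abundance table from TSV
#'
#' Expects features as rows and samples as columns, with the feature IDs in
#' the first column (header cell `#FeatureID`) and sample IDs in the header
#' row -- the dominant amplicon-table dialect. Values must be non-negative
#' counts.
#'
#' @param path path to a tab-separated table.
#' @param kingdom `"bacteria"` or `"fungi"` tag for the table.
#' @return A counts-mode [abundance_table()].
#' @export
read_abundance_table <- function(path, kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed table header in ", path,
                         ": need a feature-ID column plus >=1 sample column")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    stop("non-numeric sample column(s): ", paste(names(vals)[nonnum], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  abundance_table(m, kingdom = kingdom, mode = "counts")
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_table()]; integer counts round-trip losslessly.
#'
#' @param x an [abundance_table()].
#' @param path output path.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(is_abundance_table(x))
  df <- data.frame("#FeatureID" = rownames(x), at_matrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its total. Source indices (SSI, HSP,
#' FaRMI) are all defined on relative abundances.
#'
#' @param x a counts-mode [abundance_table()] with no all-zero sample.
#' @return The table in relative mode.
#' @export
to_relative <- function(x) {
  stopifnot(is_abundance_table(x))
  if (table_mode(x) != "counts") stop("`x` is already in relative mode")
  cs <- colSums(x)
  if (any(cs == 0)) {
    stop("cannot normalise all-zero sample(s): ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  }
  abundance_table(sweep(at_matrix(x), 2, cs, "/"),
                  kingdom = table_kingdom(x), mode = "relative")
}

# internal: accept counts or relative, return relative
as_relative <- function(x) if (table_mode(x) == "relative") x else to_relative(x)
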