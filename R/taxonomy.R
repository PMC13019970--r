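#' Taxonomy tables
#'
#' A taxonomy maps each feature ID to an ordered set of rank labels
#' (domain, phylum, class, order, family, genus). Ranks that were not
#' assigned are `NA`. On disk the lineage is a single semicolon-joined
#' string with rank prefixes (`d__`, `p__`, `c__`, `o__`, `f__`, `g__`);
#' an empty label after the prefix marks an unassigned rank.
#'
#' @name taxonomy
NULL

#' @rdname taxonomy
#' @export
tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")

rank_prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__")

#' Build a taxonomy from lineage strings
#'
#' @param feature_ids character vector of feature IDs.
#' @param lineages character vector of semicolon-joined, rank-prefixed
#'   lineage strings, e.g. `"d__Bacteria;p__Proteobacteria;...;g__Massilia"`.
#'   Trailing ranks may be omitted.
#' @return A `taxonomy` data frame with columns `feature_id` and the six
#'   ranks of [tax_ranks()].
#' @export
taxonomy_from_lineages <- function(feature_ids, lineages) {
  stopifnot(length(feature_ids) == length(lineages))
  if (anyDuplicated(feature_ids)) stop("duplicate feature IDs in taxonomy")
  ranks <- tax_ranks()
  out <- matrix(NA_character_, nrow = length(feature_ids), ncol = length(ranks),
                dimnames = list(NULL, ranks))
  parts <- strsplit(lineages, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    for (p in trimws(parts[[i]])) {
      if (!nzchar(p)) next
      hit <- which(startsWith(p, rank_prefixes))
      if (!length(hit)) stop("unrecognised rank prefix in lineage: '", p, "'")
      lab <- substring(p, 4L)
      if (nzchar(lab)) out[i, hit[1]] <- lab
    }
  }
  df <- data.frame(feature_id = as.character(feature_ids), out,
                   stringsAsFactors = FALSE)
  if (any(rowSums(!is.na(out)) == 0)) {
    bad <- df$feature_id[rowSums(!is.na(out)) == 0]
    stop("feature(s) with no assigned rank: ", paste(bad, collapse = ", "))
  }
  class(df) <- c("taxonomy", "data.frame")
  df
}

#' @rdname taxonomy
#' @param path path to a 2-column TSV (`feature_id`, lineage).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("taxonomy TSV must have exactly 2 columns")
  taxonomy_from_lineages(df[[1]], df[[2]])
}

#' @rdname taxonomy
#' @param tax a `taxonomy` object.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  ranks <- tax_ranks()
  lin <- apply(tax[ranks], 1, function(r) {
    paste0(rank_prefixes, ifelse(is.na(r), "", r), collapse = ";")
  })
  utils::write.table(data.frame(feature_id = tax$feature_id, lineage = lin),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate features to a taxonomic rank
#'
#' Features sharing the same label at `rank` are summed. Features with no
#' assignment at `rank` are kept, relabelled
#' `"<deepest assigned rank label>_unclassified"`, so per-sample totals are
#' conserved exactly. Rows of the result are sorted by label for
#' determinism.
#'
#' @param x an [abundance_table()] whose rows are raw features.
#' @param tax a [taxonomy] covering every feature of `x`.
#' @param rank one of [tax_ranks()].
#' @return An [abundance_table()] with rank-level labels as rows, same mode
#'   and kingdom as `x`.
#' @export
aggregate_to_rank <- function(x, tax, rank = "genus") {
  stopifnot(is_abundance_table(x), inherits(tax, "taxonomy"))
  rank <- match.arg(rank, tax_ranks())
  idx <- match(rownames(x), tax$feature_id)
  if (anyNA(idx)) {
    stop("feature(s) missing from taxonomy: ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  }
  sub <- tax[idx, , drop = FALSE]
  lab <- sub[[rank]]
  need <- is.na(lab)
  if (any(need)) {
    ranks <- tax_ranks()
    deepest <- apply(sub[need, ranks, drop = FALSE], 1, function(r) {
      a <- r[!is.na(r)]
      a[length(a)]
    })
    lab[need] <- paste0(deepest, "_unclassified")
  }
  agg <- rowsum(at_matrix(x), group = lab, reorder = TRUE)
  abundance_table(agg, kingdom = table_kingdom(x), mode = table_mode(x))
}
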