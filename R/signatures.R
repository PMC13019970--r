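#' Build a source signature from seeding-soil aliquots
#'
#' The soil source index (SSI) is defined by the most abundant taxa that are
#' detected in EVERY source aliquot: prevalence across aliquots acts as a
#' hard filter (a taxon absent from even one aliquot is excluded regardless
#' of abundance), and the survivors are ranked by unweighted mean relative
#' abundance across aliquots, descending, with lexicographic tie-break for
#' determinism. The study configuration keeps the top 19 bacterial or 28
#' fungal taxa, which are the kingdom-specific defaults for `n_taxa`.
#'
#' @param aliquots [abundance_table()] restricted to the source aliquot
#'   samples (>= 2 columns), rank-aggregated labels; counts are normalised
#'   internally.
#' @param n_taxa number of taxa to keep; default 19 for bacteria, 28 for
#'   fungi. If fewer candidates pass the prevalence filter, all are kept
#'   with a warning.
#' @return A `source_signature`: list with `kingdom`, ordered `taxa`,
#'   `n_requested`, and per-taxon `selection_stats` (mean relative
#'   abundance, aliquot prevalence).
#' @export
build_source_signature <- function(aliquots, n_taxa = NULL) {
  stopifnot(is_abundance_table(aliquots))
  if (ncol(aliquots) < 2) stop("need >= 2 source aliquot samples")
  if (is.null(n_taxa)) {
    n_taxa <- if (table_kingdom(aliquots) == "bacteria") 19L else 28L
  }
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  rel <- at_matrix(as_relative(aliquots))
  prev <- rowMeans(rel > 0)
  cand <- prev == 1
  if (!any(cand)) stop("no taxon is detected in every aliquot")
  mu <- rowMeans(rel[cand, , drop = FALSE])
  ord <- order(-mu, names(mu))
  taxa <- names(mu)[ord]
  if (length(taxa) < n_taxa) {
    warning("only ", length(taxa), " taxa pass the prevalence filter ",
            "(requested ", n_taxa, "); keeping all of them")
  }
  keep <- utils::head(taxa, n_taxa)
  structure(list(
    kingdom = table_kingdom(aliquots),
    taxa = keep,
    n_requested = as.integer(n_taxa),
    selection_stats = data.frame(
      taxon = keep,
      mean_abundance = unname(mu[keep]),
      prevalence = 1,
      row.names = NULL, stringsAsFactors = FALSE)
  ), class = "source_signature")
}

#' @export
print.source_signature <- function(x, ...) {
  cat(sprintf("source_signature (%s): %d taxa (requested %d)\n",
              x$kingdom, length(x$taxa), x$n_requested))
  cat("  top:", paste(utils::head(x$taxa, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / read a source signature (JSON)
#'
#' @param sig a `source_signature`.
#' @param path JSON file path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "source_signature"))
  jsonlite::write_json(unclass(sig), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$taxa <- as.character(obj$taxa)
  obj$n_requested <- as.integer(obj$n_requested)
  structure(obj, class = "source_signature")
}

#' Signature score (SSI) of a sample
#'
#' Sum of the relative abundances of the signature taxa in a sample; taxa
#' absent from the sample contribute 0, so the score is always in [0, 1]
#' and additive over disjoint taxon sets.
#'
#' @param sample named numeric vector of relative abundances (one sample).
#' @param signature a `source_signature` (or a plain character vector of
#'   taxon labels).
#' @return a fraction in [0, 1].
#' @export
signature_score <- function(sample, signature) {
  taxa <- if (inherits(signature, "source_signature")) signature$taxa else signature
  if (is.null(names(sample))) stop("`sample` must be a named abundance vector")
  sum(sample[names(sample) %in% taxa])
}

#' Per-sample SSI series for a table
#'
#' @param x [abundance_table()] (relative, or counts normalised internally).
#' @param signature a `source_signature`.
#' @return tidy data frame `sample_id`, `index` ("SSI"), `value`.
#' @export
ssi_scores <- function(x, signature) {
  rel <- at_matrix(as_relative(x))
  taxa <- if (inherits(signature, "source_signature")) signature$taxa else signature
  v <- colSums(rel[rownames(rel) %in% taxa, , drop = FALSE])
  data.frame(sample_id = colnames(rel), index = "SSI", value = unname(v),
             stringsAsFactors = FALSE)
}

#' Signature coverage of the source aliquots
#'
#' Applies [signature_score()] to each aliquot: the fraction of aliquot
#' reads captured by the signature (the study reports 63--77% for bacteria
#' and 87--93% for fungi).
#'
#' @inheritParams build_source_signature
#' @param signature a `source_signature`.
#' @return list with `per_aliquot` (named fractions) and `range`
#'   (min, max).
#' @export
source_coverage <- function(signature, aliquots) {
  rel <- at_matrix(as_relative(aliquots))
  taxa <- if (inherits(signature, "source_signature")) signature$taxa else signature
  v <- colSums(rel[rownames(rel) %in% taxa, , drop = FALSE])
  list(per_aliquot = v, range = c(min = min(v), max = max(v)))
}

#' The human source proxy (HSP) taxon list
#'
#' Five human-body-associated bacterial taxa -- two genera and three
#' families -- used as a proxy for occupant-shed bacteria.
#'
#' @return data frame with columns `label`, `rank`.
#' @export
hsp_default_taxa <- function() {
  data.frame(
    label = c("Staphylococcus", "Streptococcus", "Propionibacteriaceae",
              "Corynebacteriaceae", "Enterobacteriaceae"),
    rank = c("genus", "genus", "family", "family", "family"),
    stringsAsFactors = FALSE
  )
}

#' Human source proxy score
#'
#' Sum of relative abundances of the HSP taxa, resolved against the
#' taxonomy: genus entries are summed over features of that genus, family
#' entries over features of that family. A genus named in the genus list is
#' excluded from its family's term only if both appear in the list (the
#' default study list has no such overlap, so nothing is double-counted).
#'
#' @param x feature-level [abundance_table()] (relative, or counts
#'   normalised internally).
#' @param tax a [taxonomy] covering the features of `x`.
#' @param hsp_taxa data frame `label`,`rank` (rank in `"genus"`/`"family"`);
#'   default [hsp_default_taxa()].
#' @return tidy data frame `sample_id`, `index` ("HSP"), `value`.
#' @export
hsp_scores <- function(x, tax, hsp_taxa = hsp_default_taxa()) {
  stopifnot(inherits(tax, "taxonomy"))
  bad <- setdiff(hsp_taxa$rank, c("genus", "family"))
  if (length(bad)) stop("unknown rank tag(s) in hsp_taxa: ", paste(bad, collapse = ", "))
  rel <- at_matrix(as_relative(x))
  idx <- match(rownames(rel), tax$feature_id)
  if (anyNA(idx)) {
    stop("feature(s) missing from taxonomy: ",
         paste(rownames(rel)[is.na(idx)], collapse = ", "))
  }
  gen <- tax$genus[idx]
  fam <- tax$family[idx]
  genus_list <- hsp_taxa$label[hsp_taxa$rank == "genus"]
  family_list <- hsp_taxa$label[hsp_taxa$rank == "family"]
  in_genus <- !is.na(gen) & gen %in% genus_list
  in_family <- !is.na(fam) & fam %in% family_list & !in_genus
  v <- colSums(rel[in_genus | in_family, , drop = FALSE])
  data.frame(sample_id = colnames(rel), index = "HSP", value = unname(v),
             stringsAsFactors = FALSE)
}

#' FaRMI logistic model
#'
#' The farm-home resembling microbiota index is a logistic-GLM probability
#' score: each predictor taxon's relative abundance is percentile-ranked
#' across the scored samples, and the linear predictor
#' \eqn{\eta = \beta_0 + \sum_k \beta_k r_k} is mapped through the inverse
#' logit. The published model has an intercept plus 45 taxon coefficients;
#' the coefficients are an external input (2-column CSV `term,coefficient`
#' with an `(Intercept)` row), never hardcoded here.
#'
#' @param intercept real intercept.
#' @param coefficients named numeric vector, taxon label -> coefficient
#'   (unique names).
#' @return a `farmi_model`.
#' @export
farmi_model <- function(intercept, coefficients) {
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    stop("coefficients must have unique taxon names")
  }
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients),
            class = "farmi_model")
}

#' @rdname farmi_model
#' @param path CSV path (`term,coefficient`, one `(Intercept)` row).
#' @export
read_farmi_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "coefficient") %in% names(df))) {
    stop("FaRMI model CSV needs columns term,coefficient")
  }
  ic <- df$term == "(Intercept)"
  if (sum(ic) != 1) stop("FaRMI model CSV needs exactly one (Intercept) row")
  farmi_model(df$coefficient[ic],
              stats::setNames(df$coefficient[!ic], df$term[!ic]))
}

#' @rdname farmi_model
#' @param model a `farmi_model`.
#' @export
write_farmi_model <- function(model, path) {
  stopifnot(inherits(model, "farmi_model"))
  df <- data.frame(term = c("(Intercept)", names(model$coefficients)),
                   coefficient = c(model$intercept, unname(model$coefficients)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' FaRMI scores for a set of samples
#'
#' Percentile ranks are computed within the set of samples passed in one
#' call (the ranking population): for each predictor taxon,
#' \eqn{r = \mathrm{rank}/n} with 1-based average ranks and ties averaged,
#' so \eqn{r \in (0, 1]}. Taxa absent from the table contribute abundance 0
#' for every sample (and hence a tied, maximal-entropy rank). Being
#' rank-based, the score is invariant to strictly monotone transforms of
#' any predictor's abundances.
#'
#' @param x [abundance_table()] with >= 2 samples (relative, or counts
#'   normalised internally).
#' @param model a [farmi_model()].
#' @return tidy data frame `sample_id`, `index` ("FaRMI"), `value` in
#'   (0, 1).
#' @export
farmi_scores <- function(x, model) {
  stopifnot(inherits(model, "farmi_model"))
  if (ncol(x) < 2) {
    stop("FaRMI percentile ranking needs >= 2 samples; ",
         "supply the whole ranking population in one call")
  }
  rel <- at_matrix(as_relative(x))
  n <- ncol(rel)
  taxa <- names(model$coefficients)
  abund <- matrix(0, nrow = length(taxa), ncol = n,
                  dimnames = list(taxa, colnames(rel)))
  hit <- taxa %in% rownames(rel)
  abund[hit, ] <- rel[taxa[hit], , drop = FALSE]
  r <- t(apply(abund, 1, rank, ties.method = "average")) / n
  eta <- model$intercept + drop(crossprod(r, model$coefficients))
  data.frame(sample_id = colnames(rel), index = "FaRMI",
             value = unname(stats::plogis(eta)), stringsAsFactors = FALSE)
}
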