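#' Prevalence-based contaminant flagging
#'
#' Flags features that are detected more often in negative-control samples
#' (swab/reagent blanks) than in experimental samples, the signature of
#' reagent contamination. For each feature a 2x2 presence/absence table
#' (control vs experimental x detected vs not; detection = count > 0) is
#' scored with a one-sided Fisher exact (hypergeometric) p-value against the
#' alternative "more prevalent in controls"; features with score below
#' `threshold` are flagged. The exact test is direction-explicit and stable
#' at the small control-set sizes typical of amplicon studies.
#'
#' @param x counts-mode [abundance_table()] containing both control and
#'   experimental samples.
#' @param control_ids sample IDs of the negative controls (non-empty,
#'   proper subset of the samples).
#' @param threshold probability threshold in (0, 1]; default 0.5.
#' @return A `contaminant_report` data frame with one row per feature:
#'   `feature_id`, `prevalence_controls`, `prevalence_samples`, `score`,
#'   `flagged`.
#' @export
flag_contaminants_prevalence <- function(x, control_ids, threshold = 0.5) {
  stopifnot(is_abundance_table(x))
  if (table_mode(x) != "counts") stop("contaminant flagging needs counts mode")
  if (length(control_ids) == 0) stop("empty control sample set")
  miss <- setdiff(control_ids, colnames(x))
  if (length(miss)) stop("control IDs not in table: ", paste(miss, collapse = ", "))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  is_ctrl <- colnames(x) %in% control_ids
  n_ctrl <- sum(is_ctrl)
  n_samp <- sum(!is_ctrl)
  if (n_samp == 0) stop("no experimental (non-control) samples")
  det <- at_matrix(x) > 0
  det_ctrl <- rowSums(det[, is_ctrl, drop = FALSE])
  det_all <- rowSums(det)
  # P(X >= det_ctrl) drawing n_ctrl from det_all positives among n samples
  score <- stats::phyper(det_ctrl - 1, m = det_all, n = n_ctrl + n_samp - det_all,
                         k = n_ctrl, lower.tail = FALSE)
  out <- data.frame(
    feature_id = rownames(x),
    prevalence_controls = det_ctrl / n_ctrl,
    prevalence_samples = rowSums(det[, !is_ctrl, drop = FALSE]) / n_samp,
    score = score,
    flagged = score < threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("contaminant_report", "data.frame")
  out
}

#' Remove features from a counts table
#'
#' Drops the given feature rows. Samples whose total becomes zero are also
#' dropped, with a warning listing them (their IDs are kept in the
#' `dropped_samples` attribute).
#'
#' @param x counts-mode [abundance_table()].
#' @param feature_ids features to remove (must all exist; empty set is a
#'   no-op).
#' @return The reduced [abundance_table()].
#' @export
remove_features <- function(x, feature_ids) {
  stopifnot(is_abundance_table(x))
  if (table_mode(x) != "counts") stop("remove_features needs counts mode")
  if (length(feature_ids) == 0) return(x)
  miss <- setdiff(feature_ids, rownames(x))
  if (length(miss)) stop("unknown feature ID(s): ", paste(miss, collapse = ", "))
  m <- at_matrix(x)[!rownames(x) %in% feature_ids, , drop = FALSE]
  empty <- colSums(m) == 0
  dropped <- colnames(m)[empty]
  if (length(dropped)) {
    warning("dropping sample(s) left empty by feature removal: ",
            paste(dropped, collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  out <- abundance_table(m, kingdom = table_kingdom(x), mode = "counts")
  attr(out, "dropped_samples") <- dropped
  out
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads WITHOUT replacement (multivariate
#' hypergeometric) to exactly `depth`. Samples with fewer than `depth` reads
#' are dropped and reported via a message and the `dropped_samples`
#' attribute. Fully deterministic given `seed`.
#'
#' @param x counts-mode [abundance_table()] with integer counts.
#' @param depth target reads per sample (>= 1); the study design value is
#'   2000.
#' @param seed integer RNG seed.
#' @return Rarefied counts-mode [abundance_table()]; every column sums to
#'   `depth`.
#' @export
rarefy <- function(x, depth = 2000, seed) {
  stopifnot(is_abundance_table(x))
  if (table_mode(x) != "counts") stop("rarefy needs counts mode")
  if (length(depth) != 1 || depth < 1) stop("depth must be a positive integer")
  depth <- as.integer(depth)
  m <- at_matrix(x)
  if (any(abs(m - round(m)) > 1e-8)) stop("rarefy needs integer counts")
  m <- round(m)
  tot <- colSums(m)
  shallow <- tot < depth
  dropped <- colnames(m)[shallow]
  if (length(dropped)) {
    message("rarefy: dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
    m <- m[, !shallow, drop = FALSE]
  }
  if (ncol(m) == 0) stop("no samples at or above rarefaction depth ", depth)
  set.seed(seed)
  nf <- nrow(m)
  out <- matrix(0L, nrow = nf, ncol = ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    reads <- rep.int(seq_len(nf), m[, j])
    keep <- sample(reads, depth, replace = FALSE)
    out[, j] <- tabulate(keep, nbins = nf)
  }
  res <- abundance_table(out, kingdom = table_kingdom(x), mode = "counts")
  attr(res, "dropped_samples") <- dropped
  res
}

#' Centred log-ratio transform
#'
#' Adds `pseudocount` to every count (the standard zero-replacement) and
#' maps each sample to \eqn{clr_i = \ln x'_i - \frac{1}{D}\sum_j \ln x'_j}.
#' Each transformed sample sums to zero. Note that with a pseudocount the
#' transform is not invariant to rescaling a sample's counts (the
#' pseudocount's relative weight changes with depth), which is one reason
#' the pipeline applies it after rarefaction to a common depth.
#'
#' @param x counts-mode [abundance_table()].
#' @param pseudocount positive offset added before taking logs; default 1.
#' @return A plain numeric matrix with the same dimnames as `x`.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  stopifnot(is_abundance_table(x))
  if (table_mode(x) != "counts") stop("clr_transform expects counts mode")
  if (length(pseudocount) != 1 || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  lx <- log(at_matrix(x) + pseudocount)
  sweep(lx, 2, colMeans(lx), "-")
}
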