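#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{1 - 2\sum_i \min(x_i, y_i) / (\sum x + \sum y)}, in [0, 1]: 0 means
#' identical communities, 1 disjoint ones. Used on rarefied counts (or
#' equivalently relative abundances at a common depth); no pseudocount is
#' ever applied here.
#'
#' @param x,y non-negative numeric vectors on the same feature axis.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must share the feature axis")
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y))) {
    stop("feature names disagree between x and y")
  }
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  s <- sum(x) + sum(y)
  if (s == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / s
}

#' Aitchison distance between two CLR-transformed samples
#'
#' Euclidean distance between centred log-ratio vectors (see
#' [clr_transform()]).
#'
#' @param clr_x,clr_y CLR-transformed numeric vectors of equal length.
#' @return non-negative distance.
#' @export
aitchison_distance <- function(clr_x, clr_y) {
  if (length(clr_x) != length(clr_y)) stop("CLR vectors differ in length")
  sqrt(sum((clr_x - clr_y)^2))
}

#' Pairwise distance matrix for an abundance table
#'
#' Bray-Curtis directly on the abundances; Aitchison applies the CLR
#' transform internally (counts mode required) with the given pseudocount
#' and takes Euclidean distances.
#'
#' @param x [abundance_table()] with >= 2 samples.
#' @param metric `"bray_curtis"` or `"aitchison"`.
#' @param pseudocount CLR offset (Aitchison only); default 1.
#' @return a [stats::dist] object with the metric recorded in its `method`
#'   attribute.
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "aitchison"),
                            pseudocount = 1) {
  stopifnot(is_abundance_table(x))
  metric <- match.arg(metric)
  if (ncol(x) < 2) stop("need >= 2 samples for a distance matrix")
  if (metric == "bray_curtis") {
    d <- vegan::vegdist(t(at_matrix(x)), method = "bray")
  } else {
    d <- stats::dist(t(clr_transform(x, pseudocount)), method = "euclidean")
  }
  attr(d, "method") <- metric
  d
}

#' Per-home averaged source baseline
#'
#' For each home, the arithmetic mean of that home's source-aliquot
#' relative-abundance profiles (renormalised to sum 1): the matching
#' baseline community each dust sample is compared against.
#'
#' @param aliquots [abundance_table()] of source aliquot samples.
#' @param meta [sample_metadata()] covering the aliquots (used for the home
#'   assignment).
#' @param homes optional home labels that must all have aliquots; errors
#'   listing any without.
#' @return matrix taxa x homes; every column sums to 1.
#' @export
source_baseline <- function(aliquots, meta, homes = NULL) {
  stopifnot(is_abundance_table(aliquots), inherits(meta, "sample_metadata"))
  rel <- at_matrix(as_relative(aliquots))
  idx <- match(colnames(rel), meta$sample_id)
  if (anyNA(idx)) {
    stop("aliquot sample(s) missing from metadata: ",
         paste(colnames(rel)[is.na(idx)], collapse = ", "))
  }
  home <- meta$home[idx]
  if (!is.null(homes)) {
    missing_homes <- setdiff(homes, unique(home))
    if (length(missing_homes)) {
      stop("home(s) with no source aliquots: ",
           paste(missing_homes, collapse = ", "))
    }
  }
  prof <- vapply(split(seq_along(home), home), function(cols) {
    p <- rowMeans(rel[, cols, drop = FALSE])
    p / sum(p)
  }, numeric(nrow(rel)))
  prof
}

#' Bray-Curtis distance of each dust sample to its home's source baseline
#'
#' A decrease over time means the dust community is converging toward the
#' seeding-soil composition.
#'
#' @param dust [abundance_table()] of dust samples (counts normalised
#'   internally).
#' @param meta [sample_metadata()] covering the dust samples.
#' @param baseline matrix from [source_baseline()].
#' @return tidy data frame `sample_id`, `home`, `distance`.
#' @export
beta_to_baseline <- function(dust, meta, baseline) {
  stopifnot(is_abundance_table(dust), inherits(meta, "sample_metadata"))
  rel <- at_matrix(as_relative(dust))
  idx <- match(colnames(rel), meta$sample_id)
  if (anyNA(idx)) {
    stop("dust sample(s) missing from metadata: ",
         paste(colnames(rel)[is.na(idx)], collapse = ", "))
  }
  home <- meta$home[idx]
  unmatched <- setdiff(unique(home), colnames(baseline))
  if (length(unmatched)) {
    stop("no baseline for home(s): ", paste(unmatched, collapse = ", "))
  }
  taxa <- union(rownames(rel), rownames(baseline))
  rx <- matrix(0, length(taxa), ncol(rel), dimnames = list(taxa, colnames(rel)))
  rx[rownames(rel), ] <- rel
  bx <- matrix(0, length(taxa), ncol(baseline),
               dimnames = list(taxa, colnames(baseline)))
  bx[rownames(baseline), ] <- baseline
  d <- vapply(seq_len(ncol(rx)),
              function(j) bray_curtis(rx[, j], bx[, home[j]]),
              numeric(1))
  data.frame(sample_id = colnames(rel), home = home, distance = d,
             stringsAsFactors = FALSE)
}

#' Chao1 estimated species richness
#'
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} with singleton/doubleton counts
#' \eqn{F_1, F_2}; when \eqn{F_2 = 0} the bias-corrected fallback
#' \eqn{S_{obs} + F_1 (F_1 - 1) / 2} is used (the classic estimator is
#' undefined there). Requires integer counts -- Chao1 has no meaning on
#' fractions.
#'
#' @param counts integer count vector for one sample.
#' @return richness estimate, always >= observed richness.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("Chao1 requires integer counts")
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Shannon diversity (natural log)
#'
#' \eqn{-\sum_i p_i \ln p_i} over the non-zero proportions.
#'
#' @param x counts or fractions for one sample (not all zero).
#' @return Shannon index; bounded by `log(S_obs)`.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s == 0) stop("all-zero sample")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Principal Coordinates Analysis
#'
#' Classical metric MDS: Gower double-centering of the squared distances,
#' eigendecomposition, coordinates scaled by the square root of each
#' eigenvalue. Axes with non-positive eigenvalues carry no real coordinates
#' and are dropped (negative eigenvalues are still reported); the sign of
#' each axis is fixed so its largest-magnitude loading is positive.
#'
#' @param dm a [stats::dist] or symmetric matrix of dissimilarities.
#' @param k number of axes requested (>= 1); truncated with a warning when
#'   it exceeds the number of positive eigenvalues.
#' @return list with `points` (samples x axes), `eigenvalues` (all, in
#'   descending order), and `n_negative`.
#' @export
pcoa <- function(dm, k = 2) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  if (k < 1) stop("k must be >= 1")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  npos <- sum(eig > tol)
  if (k > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning ", npos,
            " axes instead of ", k)
    k <- npos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = eig, n_negative = sum(eig < -tol))
}
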