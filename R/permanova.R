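# Gower-centred inner-product matrix of a dissimilarity matrix
# (McArdle & Anderson partitioning: A = -d^2/2, G = (I-11'/n) A (I-11'/n))
gower_matrix <- function(dm) {
  d2 <- as.matrix(stats::as.dist(dm))^2
  a <- -d2 / 2
  rm <- rowMeans(a)
  a - outer(rm, rm, "+") + mean(a)
}

# symmetric projection (hat) matrix of a model matrix, via thin QR
hat_matrix <- function(x) {
  qx <- qr(x)
  q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(q)
}

# all permutations of 1..n (n small), as a list: insert n at every
# position of every permutation of 1..(n-1)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 1L
  for (sub in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[k]] <- append(sub, n, after = pos)
      k <- k + 1L
    }
  }
  out
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix: the total sum of squares of the Gower-centred matrix is
#' partitioned into among- and within-group components and the pseudo-F
#' statistic is referenced against free permutations of the sample labels.
#' The reported p-value is \eqn{(1 + \#\{F_{perm} \ge F_{obs}\}) /
#' (1 + n_{perm})}, which includes the identity permutation and therefore
#' is never zero. When the full permutation set is no larger than `n_perm`
#' it is enumerated exhaustively and the p-value is the exact fraction.
#'
#' @param dm [stats::dist] or symmetric dissimilarity matrix.
#' @param grouping factor (or coercible) with >= 2 levels, one per sample.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed making the sampled permutations
#'   reproducible.
#' @return a `permanova` data frame: `term`, `df`, `SS`, `F`, `R2`, `p`,
#'   `n_permutations`, `exhaustive`.
#' @export
permanova <- function(dm, grouping, n_perm = 999, seed = NULL) {
  g <- droplevels(as.factor(grouping))
  gmat <- gower_matrix(dm)
  n <- nrow(gmat)
  if (length(g) != n) stop("grouping length must match the number of samples")
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (n_perm < 1) stop("n_perm must be >= 1")
  h <- hat_matrix(stats::model.matrix(~g))
  df1 <- nlevels(g) - 1L
  df2 <- n - nlevels(g)
  ss_tot <- sum(diag(gmat))
  res_tol <- 1e-10 * max(abs(ss_tot), 1)
  fstat <- function(hp) {
    ssm <- sum(gmat * hp)
    ssr <- ss_tot - ssm
    if (ssr < res_tol) return(Inf)  # perfect separation: zero residual
    (ssm / df1) / (ssr / df2)
  }
  f_obs <- fstat(h)
  nperm_total <- factorial(n)
  if (nperm_total <= n_perm) {
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(p) fstat(h[p, p]), numeric(1))
    p_val <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
    exhaustive <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      if (fstat(h[p, p]) >= f_obs - 1e-12) hits <- hits + 1L
    }
    p_val <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
    exhaustive <- FALSE
  }
  ssm <- sum(gmat * h)
  out <- data.frame(term = "grouping", df = df1, SS = ssm, F = f_obs,
                    R2 = ssm / ss_tot, p = p_val, n_permutations = n_used,
                    exhaustive = exhaustive, stringsAsFactors = FALSE)
  class(out) <- c("permanova", "data.frame")
  out
}

#' Marginal (type-III-like) PERMANOVA over several covariates
#'
#' Tests each covariate independently while accounting for all others: the
#' partial sum of squares of a term is SS(full model) minus SS(model
#' without that term), and its pseudo-F uses the full-model residual. All
#' terms share one permutation stream, so results are reproducible given
#' `seed`. A rank-deficient (collinear) design is rejected with the aliased
#' columns named.
#'
#' @param dm [stats::dist] or symmetric dissimilarity matrix.
#' @param covariates data frame of factors / numerics, one row per sample.
#' @inheritParams permanova
#' @return a `permanova` data frame with one row per term.
#' @export
permanova_marginal <- function(dm, covariates, n_perm = 999, seed = NULL) {
  covariates <- as.data.frame(covariates)
  gmat <- gower_matrix(dm)
  n <- nrow(gmat)
  if (nrow(covariates) != n) stop("covariates rows must match the samples")
  x_full <- stats::model.matrix(~., data = covariates)
  qx <- qr(x_full)
  if (qx$rank < ncol(x_full)) {
    aliased <- colnames(x_full)[qx$pivot[(qx$rank + 1):ncol(x_full)]]
    stop("rank-deficient (collinear) model; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  terms_lab <- attr(stats::terms(~., data = covariates), "term.labels")
  assign_idx <- attr(x_full, "assign")
  h_full <- hat_matrix(x_full)
  df_res <- n - qx$rank
  if (df_res < 1) stop("no residual degrees of freedom in the full model")
  ss_tot <- sum(diag(gmat))
  h_red <- lapply(seq_along(terms_lab), function(t_i) {
    keep <- assign_idx != t_i
    hat_matrix(x_full[, keep, drop = FALSE])
  })
  df_term <- vapply(seq_along(terms_lab),
                    function(t_i) sum(assign_idx == t_i), integer(1))
  res_tol <- 1e-10 * max(abs(ss_tot), 1)
  stat_all <- function(g) {
    ss_full <- sum(g * h_full)
    ss_res <- sum(diag(g)) - ss_full
    ss_t <- vapply(h_red, function(h0) ss_full - sum(g * h0), numeric(1))
    if (ss_res < res_tol) return(rep(Inf, length(ss_t)))
    (ss_t / df_term) / (ss_res / df_res)
  }
  f_obs <- stat_all(gmat)
  if (!is.null(seed)) set.seed(seed)
  hits <- numeric(length(terms_lab))
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    hits <- hits + (stat_all(gmat[p, p]) >= f_obs - 1e-12)
  }
  ss_full <- sum(gmat * h_full)
  ss_t <- vapply(h_red, function(h0) ss_full - sum(gmat * h0), numeric(1))
  out <- data.frame(term = terms_lab, df = df_term, SS = ss_t, F = f_obs,
                    R2 = ss_t / ss_tot, p = (1 + hits) / (1 + n_perm),
                    n_permutations = n_perm, exhaustive = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("permanova", "data.frame")
  out
}
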