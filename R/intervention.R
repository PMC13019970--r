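#' Seeding-intervention design
#'
#' Describes the longitudinal design: seeding events on the biweekly grid,
#' a pre-intervention baseline window, and the post-event lags used for
#' pairing (2 and 4 weeks).
#'
#' @param seeding_weeks strictly increasing even integers (study: 0, 4, 8).
#' @param baseline_window `c(first, last)` week of the baseline period
#'   (study: -8 to 0).
#' @param post_lags named integer vector of pairing lags.
#' @return a `seeding_design` list.
#' @export
seeding_design <- function(seeding_weeks = c(0L, 4L, 8L),
                           baseline_window = c(-8L, 0L),
                           post_lags = c(pre2w_post2w = 2L, pre2w_post4w = 4L)) {
  seeding_weeks <- as.integer(seeding_weeks)
  if (is.unsorted(seeding_weeks, strictly = TRUE)) {
    stop("seeding weeks must be strictly increasing")
  }
  if (any(seeding_weeks %% 2L != 0L)) stop("seeding weeks must be on the biweekly grid")
  structure(list(seeding_weeks = seeding_weeks,
                 baseline_window = as.integer(baseline_window),
                 post_lags = post_lags),
            class = "seeding_design")
}

#' Build pre/post sample pairs around each seeding event
#'
#' For every intervention home x dust stratum x seeding week `w`, the pre
#' member is the sample whose 2-week window ends at `w` (collected before
#' that week's rug deployment) and the post member is the sample at
#' `w + lag`. Pairs with either member missing are dropped. The control
#' home is excluded (it is analysed separately, descriptively). The pair
#' list is sorted, so it is independent of metadata row order. Note the
#' deliberate design overlap: with 4-week event spacing, the `pre2w_post4w`
#' post sample of one event is simultaneously the pre sample of the next.
#'
#' @param meta [sample_metadata()].
#' @param design a [seeding_design()].
#' @param comparison `"pre2w_post2w"` or `"pre2w_post4w"`.
#' @return data frame `pre_id`, `post_id`, `home`, `stratum`,
#'   `event_week`, `comparison`.
#' @export
make_pairs <- function(meta, design = seeding_design(),
                       comparison = c("pre2w_post2w", "pre2w_post4w")) {
  stopifnot(inherits(meta, "sample_metadata"), inherits(design, "seeding_design"))
  comparison <- match.arg(comparison)
  lag <- unname(design$post_lags[[comparison]])
  stratum <- dust_stratum(meta)
  keep <- !is.na(stratum) & !meta$is_control_home
  if (!any(keep)) stop("no intervention-home dust samples in metadata")
  md <- data.frame(sample_id = meta$sample_id, home = meta$home,
                   week = meta$week, stratum = stratum,
                   stringsAsFactors = FALSE)[keep, ]
  key <- function(h, s, w) paste(h, s, w, sep = "\r")
  lookup <- stats::setNames(md$sample_id, key(md$home, md$stratum, md$week))
  grid <- expand.grid(home = sort(unique(md$home)),
                      stratum = sort(unique(md$stratum)),
                      event_week = design$seeding_weeks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$home, grid$stratum, grid$event_week), ]
  pre <- lookup[key(grid$home, grid$stratum, grid$event_week)]
  post <- lookup[key(grid$home, grid$stratum, grid$event_week + lag)]
  ok <- !is.na(pre) & !is.na(post)
  data.frame(pre_id = unname(pre[ok]), post_id = unname(post[ok]),
             home = grid$home[ok], stratum = grid$stratum[ok],
             event_week = grid$event_week[ok], comparison = comparison,
             row.names = NULL, stringsAsFactors = FALSE)
}

# coerce an IndexSeries / named vector to a named value vector
series_values <- function(values) {
  if (is.data.frame(values)) {
    if (!all(c("sample_id", "value") %in% names(values))) {
      stop("series data frame needs columns sample_id, value")
    }
    stats::setNames(values$value, values$sample_id)
  } else {
    if (is.null(names(values))) stop("values must be named by sample_id")
    values
  }
}

#' Paired pre/post comparison of one metric
#'
#' Differences are post minus pre (positive = increase after seeding).
#' Normality of the differences is screened with Shapiro-Wilk at
#' `normality_alpha`; normal-looking differences get a two-sided paired
#' Student t-test, the rest a two-sided Wilcoxon signed-rank test (zero
#' differences dropped, exact distribution when the non-zero count is
#' <= 25). All-zero differences are the documented degenerate case:
#' `mean_diff = 0`, `p = 1`, `test_used = "wilcoxon"`.
#'
#' @param values named numeric vector, or tidy series data frame with
#'   `sample_id` and `value` columns.
#' @param pairs data frame from [make_pairs()] (or any with `pre_id`,
#'   `post_id`).
#' @param normality_alpha Shapiro-Wilk level gating the test choice;
#'   default 0.05.
#' @return a `paired_result` list: `n_pairs`, `mean_diff`, `test_used`,
#'   `statistic`, `p`, `comparison`.
#' @export
paired_compare <- function(values, pairs, normality_alpha = 0.05) {
  v <- series_values(values)
  pre <- v[pairs$pre_id]
  post <- v[pairs$post_id]
  ok <- !is.na(pre) & !is.na(post)
  d <- (post - pre)[ok]
  if (length(d) < 2) stop("need >= 2 usable pairs")
  comparison <- if ("comparison" %in% names(pairs)) pairs$comparison[1] else NA_character_
  res <- list(n_pairs = length(d), mean_diff = mean(d), comparison = comparison)
  if (all(d == 0)) {
    res$test_used <- "wilcoxon"
    res$statistic <- NA_real_
    res$p <- 1
  } else {
    sw_p <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
    if (sw_p >= normality_alpha) {
      tt <- stats::t.test(d)
      res$test_used <- "t"
      res$statistic <- unname(tt$statistic)
      res$p <- tt$p.value
    } else {
      dd <- d[d != 0]
      wt <- suppressWarnings(
        stats::wilcox.test(dd, exact = length(dd) <= 25))
      res$test_used <- "wilcoxon"
      res$statistic <- unname(wt$statistic)
      res$p <- wt$p.value
    }
  }
  class(res) <- "paired_result"
  res
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("paired comparison (%s): n = %d, mean diff = %.4g, %s-test p = %.4g\n",
              x$comparison, x$n_pairs, x$mean_diff, x$test_used, x$p))
  invisible(x)
}

#' Paired comparisons per dust stratum
#'
#' Runs [paired_compare()] within each stratum of a pair list, mirroring
#' the per-location rows of the study's paired pre/post table.
#'
#' @inheritParams paired_compare
#' @param metric optional metric name recorded in the output.
#' @return data frame `metric`, `stratum`, `comparison`, `n_pairs`,
#'   `mean_diff`, `test_used`, `p`.
#' @export
paired_by_stratum <- function(values, pairs, normality_alpha = 0.05,
                              metric = NA_character_) {
  do.call(rbind, lapply(sort(unique(pairs$stratum)), function(s) {
    r <- paired_compare(values, pairs[pairs$stratum == s, ], normality_alpha)
    data.frame(metric = metric, stratum = s, comparison = r$comparison,
               n_pairs = r$n_pairs, mean_diff = r$mean_diff,
               test_used = r$test_used, p = r$p, stringsAsFactors = FALSE)
  }))
}

#' Spearman rank correlation
#'
#' Rho on average-ranked data; the p-value is exact (permutation
#' distribution) when n <= 9 and there are no ties, and the t
#' approximation otherwise. Incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("rho undefined for constant input")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 9 && !ties))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Cross-location correlations of microbial metrics
#'
#' Spearman correlations between each metric's values at an anchor stratum
#' (by default the entrance infant breathing zone, nearest the intervention
#' rug) and every other dust stratum, pairing samples on home x week.
#'
#' @param values tidy series data frame `sample_id`, `index`, `value`
#'   (one or more metrics).
#' @param meta [sample_metadata()].
#' @param anchor anchor stratum label; default `"entrance_IBZ"`.
#' @return data frame `metric`, `stratum`, `rho`, `p`, `n`.
#' @export
cross_location_correlations <- function(values, meta, anchor = "entrance_IBZ") {
  stopifnot(is.data.frame(values),
            all(c("sample_id", "index", "value") %in% names(values)))
  stratum <- dust_stratum(meta)
  info <- data.frame(sample_id = meta$sample_id, home = meta$home,
                     week = meta$week, stratum = stratum,
                     stringsAsFactors = FALSE)
  df <- merge(values, info, by = "sample_id")
  df <- df[!is.na(df$stratum), ]
  if (!anchor %in% df$stratum) stop("no samples in anchor stratum '", anchor, "'")
  out <- list()
  for (m in sort(unique(df$index))) {
    dm <- df[df$index == m, ]
    a <- dm[dm$stratum == anchor, c("home", "week", "value")]
    for (s in sort(unique(dm$stratum))) {
      b <- dm[dm$stratum == s, c("home", "week", "value")]
      mg <- merge(a, b, by = c("home", "week"), suffixes = c("_anchor", "_other"))
      if (nrow(mg) < 3) next
      r <- spearman_cor(mg$value_anchor, mg$value_other)
      out[[length(out) + 1]] <- data.frame(
        metric = m, stratum = s, rho = r$rho, p = r$p, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no stratum had >= 3 complete home x week pairs with the anchor")
  do.call(rbind, out)
}

#' Rank-based group comparison
#'
#' Two groups: two-sided Wilcoxon rank-sum; more than two: Kruskal-Wallis
#' with tie correction. Used for alpha-diversity comparisons between sample
#' groups.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length.
#' @return list `test_used`, `statistic`, `p`.
#' @export
group_compare <- function(values, groups) {
  g <- as.factor(groups)
  if (any(table(g) == 0) || nlevels(droplevels(g)) < 2) {
    stop("every group must be non-empty and >= 2 groups are required")
  }
  g <- droplevels(g)
  if (nlevels(g) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(values ~ g))
    list(test_used = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
         p = wt$p.value)
  } else {
    kt <- stats::kruskal.test(values, g)
    list(test_used = "kruskal_wallis", statistic = unname(kt$statistic),
         p = kt$p.value)
  }
}
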