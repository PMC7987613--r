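#' Descriptive pre/post comparison of a paired endpoint
#'
#' Summarizes paired pre- and post-intervention values the way treatment
#' tables report them: mean and SD (sample SD, `n - 1` denominator) of
#' each phase, the absolute difference of means (`post - pre`), and the
#' signed percent change `100 * diff / mean_pre`. For reporting, the
#' difference is rounded to 2 decimals and the percent change to the
#' nearest integer; full precision is kept in the returned fields.
#'
#' @param pre,post numeric vectors of paired values (equal length >= 1,
#'   finite).
#' @param endpoint name of the endpoint being compared.
#' @return list of class `PairedDescription` with `n`, `mean_pre`,
#'   `sd_pre`, `mean_post`, `sd_post`, `diff_means`, `pct_change`,
#'   `report_diff`, `report_pct`, and `pct_defined` (`FALSE`, with
#'   `pct_change = NA`, when `mean_pre` is 0).
#' @examples
#' describe_pair(0.44, 0.80)  # diff +0.36, +82 %
#' @export
describe_pair <- function(pre, post, endpoint = "") {
  if (length(pre) != length(post) || length(pre) < 1L)
    stop("pre and post must be paired vectors of equal length >= 1")
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop("pre/post values must be finite")
  m1 <- mean(pre); m2 <- mean(post)
  dm <- m2 - m1
  pct_defined <- m1 != 0
  pct <- if (pct_defined) 100 * dm / m1 else NA_real_
  structure(list(endpoint = endpoint, n = length(pre),
                 mean_pre = m1, sd_pre = stats::sd(pre),
                 mean_post = m2, sd_post = stats::sd(post),
                 diff_means = dm, pct_change = pct,
                 pct_defined = pct_defined,
                 report_diff = round(dm, 2),
                 report_pct = if (pct_defined) round(pct) else NA_real_),
            class = "PairedDescription")
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Tests whether paired differences `post - pre` are symmetric about zero.
#' Zero differences are dropped (Wilcoxon's original rule; the count is
#' reported), absolute differences are ranked with mid-ranks for ties, and
#' the reported statistic is `W = min(W+, W-)`, the smaller of the
#' positive- and negative-rank sums.
#'
#' For `m <= 25` nonzero differences the two-sided p-value is **exact**:
#' the null distribution of `W+` is obtained over all `2^m` equally likely
#' sign assignments (computed by subset-sum convolution over the doubled
#' ranks, which enumerates the same distribution in polynomial time), and
#' `p = min(1, 2 * min(P(W+ <= w+), P(W+ >= w+)))`. Above 25 pairs a
#' normal approximation with tie correction and continuity correction is
#' used and flagged in `method`.
#'
#' @param pre,post numeric vectors of paired values (equal length >= 1).
#' @return list of class `WilcoxonExact` with `statistic` (W), `w_pos`,
#'   `w_neg`, `p_value`, `n_pairs`, `n_zero_dropped`, `ties` and `method`.
#'   All-zero differences give `p_value = 1` with a warning.
#' @examples
#' wilcoxon_exact(rep(0, 10), 1:10)$p_value  # 2/1024 = 0.001953125
#' @export
wilcoxon_exact <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 1L)
    stop("pre and post must be paired vectors of equal length >= 1")
  d <- post - pre
  if (any(!is.finite(d))) stop("pre/post values must be finite")
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  m <- length(d)
  if (m == 0L) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = 0, w_pos = 0, w_neg = 0, p_value = 1,
                          n_pairs = length(pre), n_zero_dropped = n_zero,
                          ties = FALSE, method = "degenerate (all zeros)"),
                     class = "WilcoxonExact"))
  }
  r <- rank(abs(d))
  ties <- any(duplicated(r))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  if (m <= 25L) {
    # distribution of 2*W+ over all 2^m sign assignments; doubled ranks are
    # integers even with mid-ranks
    dr <- as.integer(round(2 * r))
    total <- sum(dr)
    counts <- numeric(total + 1L)   # counts[i+1] = #assignments with 2W+ = i
    counts[1L] <- 1
    for (di in dr) {
      shifted <- c(numeric(di), counts[seq_len(total + 1L - di)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / 2^m
    p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^m
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration of sign assignments"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  structure(list(statistic = min(w_pos, w_neg), w_pos = w_pos,
                 w_neg = w_neg, p_value = p, n_pairs = length(pre),
                 n_zero_dropped = n_zero, ties = ties, method = method),
            class = "WilcoxonExact")
}

#' @export
print.WilcoxonExact <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  if (x$n_zero_dropped > 0)
    cat(sprintf("  %d zero difference(s) dropped\n", x$n_zero_dropped))
  invisible(x)
}

#' Full paired comparison of one endpoint
#'
#' Combines [describe_pair()] and [wilcoxon_exact()] into the complete
#' pre/post comparison of one ratio endpoint, with a significance call at
#' `p <= alpha`.
#'
#' @inheritParams describe_pair
#' @param alpha significance level; the call is `p_value <= alpha`
#'   (default 0.05).
#' @return list of class `PairedComparison` merging the descriptive and
#'   test fields, plus `w_statistic`, `p_value`, `significant`, `alpha`.
#' @export
paired_comparison <- function(pre, post, endpoint = "", alpha = 0.05) {
  d <- describe_pair(pre, post, endpoint = endpoint)
  w <- wilcoxon_exact(pre, post)
  structure(c(unclass(d),
              list(w_statistic = w$statistic, p_value = w$p_value,
                   test_method = w$method,
                   n_zero_dropped = w$n_zero_dropped,
                   significant = w$p_value <= alpha, alpha = alpha)),
            class = "PairedComparison")
}

#' @export
print.PairedComparison <- function(x, ...) {
  cat(sprintf(
    "%s: %.3g +/- %.3g -> %.3g +/- %.3g | diff %+.2f (%s%%) | p = %.3g%s\n",
    if (nzchar(x$endpoint)) x$endpoint else "endpoint",
    x$mean_pre, x$sd_pre, x$mean_post, x$sd_post, x$report_diff,
    if (x$pct_defined) sprintf("%+d", as.integer(x$report_pct)) else "NA",
    x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Treatment-table summary of all ratio endpoints
#'
#' Builds the study's summary table — one row per endpoint with pre/post
#' mean +/- SD, absolute and percent difference, Wilcoxon W and p, and the
#' significance call — from a long data frame of paired ratios.
#'
#' @param ratios data frame with columns `endpoint`, `pre`, `post` (one
#'   row per intervention per endpoint).
#' @param alpha significance level (default 0.05).
#' @return data frame, one row per endpoint.
#' @export
summarize_endpoints <- function(ratios, alpha = 0.05) {
  stopifnot(all(c("endpoint", "pre", "post") %in% names(ratios)))
  rows <- lapply(split(ratios, ratios$endpoint), function(df) {
    cmp <- paired_comparison(df$pre, df$post, endpoint = df$endpoint[1],
                             alpha = alpha)
    data.frame(endpoint = cmp$endpoint, n = cmp$n,
               mean_pre = cmp$mean_pre, sd_pre = cmp$sd_pre,
               mean_post = cmp$mean_post, sd_post = cmp$sd_post,
               diff = cmp$report_diff, pct_change = cmp$report_pct,
               W = cmp$w_statistic, p_value = cmp$p_value,
               significant = cmp$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
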