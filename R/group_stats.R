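new_test_result <- function(test_name, statistic, p_value, n, method_detail,
                            adjusted_p = NULL, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, n = n, method_detail = method_detail,
                   adjusted_p = adjusted_p), extra),
            class = "gaze_test_result")
}

#' @export
print.gaze_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, %s)\n",
              x$test_name, x$statistic, x$p_value, x$n, x$method_detail))
  if (!is.null(x$adjusted_p)) {
    cat(sprintf("  Bonferroni-adjusted p = %.4g\n", x$adjusted_p))
  }
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed paired signed-rank test, the comparison used for original vs
#' filtered gaze rates. Zero differences are dropped (classic Wilcoxon
#' convention; the dropped count is reported). For n <= `exact_max` effective
#' pairs with untied absolute differences, the exact null distribution of the
#' positive-rank sum is used ([stats::psignrank()]); otherwise a normal
#' approximation with the standard tie correction of the rank variance.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n using the exact null (default 25, so a
#'   16-subject cohort takes the exact path).
#' @return A `gaze_test_result` with fields `test_name`, `statistic` (V, the
#'   positive-rank sum), `p_value`, `n` (pairs after zero-dropping),
#'   `method_detail`, and `n_zero_dropped`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)",
                                   call. = FALSE)
  d <- x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero: degenerate test, p = 1", call. = FALSE)
    return(new_test_result("wilcoxon_signed_rank", 0, 1, 0, "degenerate",
                           extra = list(n_zero_dropped = n_zero)))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= exact_max && !ties) {
    # exact two-tailed p from the signed-rank null
    p_lo <- stats::psignrank(v, n)
    p_hi <- 1 - stats::psignrank(v - 1, n)
    p <- min(1, 2 * min(p_lo, p_hi))
    detail <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    # continuity-corrected z, as in the standard large-sample treatment
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    detail <- if (ties) "normal approximation (tie-corrected)"
              else "normal approximation"
  }
  new_test_result("wilcoxon_signed_rank", v, p, n, detail,
                  extra = list(n_zero_dropped = n_zero))
}

#' Friedman repeated-measures test
#'
#' Nonparametric test for a condition (column) effect across subjects (rows):
#' within-subject average ranks, chi-square statistic with k - 1 degrees of
#' freedom. Delegates to [stats::friedman.test()]; missing cells are refused
#' rather than imputed. Used here to test for temporal effects across trial
#' positions.
#'
#' @param data numeric matrix or data frame, subjects x repeated conditions.
#' @return A `gaze_test_result` (statistic = Friedman chi-square, `n` =
#'   number of subjects, plus `df`).
#' @export
friedman <- function(data) {
  m <- as.matrix(data)
  if (ncol(m) < 2 || nrow(m) < 2) {
    stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  }
  if (any(is.na(m))) stop("missing cells are not allowed", call. = FALSE)
  ranks <- t(apply(m, 1, rank))
  if (all(apply(ranks, 1, stats::var) == 0)) {
    # every row fully tied (e.g. identical columns): no evidence of an effect
    return(new_test_result("friedman", 0, 1, nrow(m),
                           sprintf("chi-square, df = %d (degenerate)",
                                   ncol(m) - 1L),
                           extra = list(df = ncol(m) - 1L)))
  }
  ft <- stats::friedman.test(m)
  new_test_result("friedman", unname(ft$statistic), unname(ft$p.value),
                  nrow(m), sprintf("chi-square, df = %d",
                                   unname(ft$parameter)),
                  extra = list(df = unname(ft$parameter)))
}

#' Bonferroni-corrected post hoc pairwise Wilcoxon tests
#'
#' Paired Wilcoxon signed-rank test on every pair of columns, with each raw p
#' multiplied by the number of pairs m = k(k-1)/2 and capped at 1 — the
#' post hoc follow-up to a significant [friedman()] result.
#'
#' @param data numeric matrix or data frame, subjects x repeated conditions.
#' @param correction multiplicity correction; only `"bonferroni"`.
#' @return Data frame with one row per pair: `a`, `b` (column names or
#'   indices), `statistic`, `p_value`, `adjusted_p`, `n`.
#' @export
posthoc_pairs <- function(data, correction = c("bonferroni")) {
  correction <- match.arg(correction)
  m <- as.matrix(data)
  k <- ncol(m)
  if (k < 2) stop("need >= 2 conditions", call. = FALSE)
  cn <- colnames(m)
  if (is.null(cn)) cn <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- suppressWarnings(wilcoxon_signed_rank(m[, a], m[, b]))
    data.frame(a = cn[a], b = cn[b], statistic = res$statistic,
               p_value = res$p_value,
               adjusted_p = min(1, res$p_value * n_pairs),
               n = res$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
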