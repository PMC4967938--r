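# Species-group hypothesis tests on the pairwise concordance values:
# Kruskal-Wallis across the human-human / mouse-mouse / human-mouse groups,
# Dunn's pairwise post-hoc z-tests with Bonferroni correction, and the
# two-sample equality-of-proportions test on significant-pair counts.
# Note: pairwise values sharing a dataset are not independent; the tests
# ignore this, and reports should carry the caveat.

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test]) across the
#' groups, followed by Dunn's z-tests on mean ranks with tie-corrected
#' variance for every group pair, Bonferroni-adjusted (raw p times the
#' number of comparisons, capped at 1).
#'
#' @param values numeric vector of the per-pair statistic (e.g. mean
#'   predictive values).
#' @param groups group label per value (e.g. \code{"hh"}, \code{"mm"},
#'   \code{"hm"}); at least two groups, each with >= 2 values.
#' @return object of class \code{"group_test"}: \code{H}, \code{df},
#'   \code{p}, and \code{dunn} (data.frame: group1, group2, z, p_raw,
#'   p_bonferroni).
#' @examples
#' kruskal_wallis_dunn(c(1, 2, 3, 4, 5, 6),
#'                     rep(c("hh", "mm", "hm"), each = 2))
#' @export
kruskal_wallis_dunn <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  cnt <- table(groups)
  if (length(cnt) < 2L) stop("need >= 2 non-empty groups")
  if (any(cnt < 2L))
    stop("group with < 2 values: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  g_fac <- factor(groups)
  if (length(unique(values)) == 1L) {
    # all observations tied: no evidence of any group difference
    combos <- utils::combn(levels(g_fac), 2L)
    dunn <- data.frame(group1 = combos[1L, ], group2 = combos[2L, ],
                       z = 0, p_raw = 1, p_bonferroni = 1,
                       stringsAsFactors = FALSE)
    return(structure(list(H = 0, df = nlevels(g_fac) - 1L, p = 1,
                          dunn = dunn), class = "group_test"))
  }
  kw <- stats::kruskal.test(values, g_fac)
  # Dunn: mean-rank z-tests with tie-corrected variance
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  g_names <- names(cnt)
  mean_rank <- tapply(r, groups, mean)
  combos <- utils::combn(g_names, 2L)
  n_cmp <- ncol(combos)
  dunn <- do.call(rbind, lapply(seq_len(n_cmp), function(k) {
    a <- combos[1L, k]; b <- combos[2L, k]
    z <- (mean_rank[[a]] - mean_rank[[b]]) /
      sqrt(var_base * (1 / cnt[[a]] + 1 / cnt[[b]]))
    p_raw <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = a, group2 = b, z = z, p_raw = p_raw,
               p_bonferroni = min(1, p_raw * n_cmp),
               stringsAsFactors = FALSE)
  }))
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, dunn = dunn),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  cat("Dunn post-hoc (Bonferroni-adjusted):\n")
  for (i in seq_len(nrow(x$dunn)))
    cat(sprintf("  %s vs %s: z = %+.3f, p = %.4g (adj %.4g)\n",
                x$dunn$group1[i], x$dunn$group2[i], x$dunn$z[i],
                x$dunn$p_raw[i], x$dunn$p_bonferroni[i]))
  invisible(x)
}

#' Two-sample test for equality of proportions
#'
#' Chi-squared test on the 2x2 table with Yates continuity correction (the
#' correction magnitude is capped so that equal observed and expected
#' counts give a statistic of exactly 0), two-sided, df = 1. Wraps
#' [stats::prop.test].
#'
#' @param k1,n1 successes and trials in group 1 (e.g. significant pairs
#'   among human-human comparisons).
#' @param k2,n2 successes and trials in group 2.
#' @return list with \code{stat}, \code{df}, \code{p}, \code{prop1},
#'   \code{prop2}.
#' @examples
#' proportions_test(27, 28, 17, 36)
#' @export
proportions_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1L, n2 >= 1L, k1 >= 0L, k2 >= 0L, k1 <= n1, k2 <= n2)
  pt <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                          correct = TRUE))
  list(stat = unname(pt$statistic), df = unname(pt$parameter),
       p = pt$p.value, prop1 = k1 / n1, prop2 = k2 / n2)
}
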