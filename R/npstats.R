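# Nonparametric group comparisons (Kruskal-Wallis + Dunn post-hoc) and
# isolate-screening summaries.

check_groups <- function(g) {
  if (!is.list(g) || is.null(names(g)) || any(names(g) == ""))
    stop("groups must be a named list of numeric vectors")
  if (length(g) < 2L) stop("need at least 2 groups")
  n <- lengths(g)
  if (any(n == 0L))
    stop("group '", names(g)[which(n == 0L)[1L]], "' has 0 observations")
  vals <- unlist(g, use.names = FALSE)
  if (any(!is.finite(vals))) stop("measurements must be finite")
  if (length(vals) < 3L) stop("need at least 3 observations in total")
  invisible(g)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with df = k - 1 and a chi-square p-value,
#' computed via [stats::kruskal.test()]. When every observation is
#' identical the tie correction degenerates to 0/0; the limiting convention
#' H = 0, p = 1 is returned instead.
#'
#' @param g named list of numeric vectors, one per group.
#' @return object of class `test_result` with `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
kruskal_wallis <- function(g) {
  check_groups(g)
  vals <- unlist(g, use.names = FALSE)
  grp <- factor(rep(names(g), lengths(g)), levels = names(g))
  if (length(unique(vals)) == 1L) {
    # all tied: no rank variation, H defined as its limit 0
    res <- list(statistic = 0, df = length(g) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(vals, grp)
    res <- list(statistic = unname(kt$statistic),
                df = as.integer(unname(kt$parameter)),
                p_value = kt$p.value)
  }
  structure(c(res, list(method = "Kruskal-Wallis rank sum test",
                        pairwise = NULL)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise comparisons:\n")
    print(x$pairwise)
  }
  invisible(x)
}

# Dunn's pairwise z statistics on mid-ranks with tie correction.
dunn_z_table <- function(g) {
  vals <- unlist(g, use.names = FALSE)
  grp <- rep(names(g), lengths(g))
  r <- rank(vals)  # mid-ranks
  N <- length(vals)
  rbar <- vapply(names(g), function(nm) mean(r[grp == nm]), numeric(1L))
  n_i <- lengths(g)
  tie_counts <- table(vals)
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  var_unit <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(g), 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se2 <- var_unit * (1 / n_i[[i1]] + 1 / n_i[[i2]])
    num <- rbar[[i1]] - rbar[[i2]]
    z <- if (num == 0) 0 else num / sqrt(se2)
    data.frame(group_i = i1, group_j = i2, z = z,
               p_raw = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  }))
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean mid-ranks with the standard tie
#' correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided
#' p-values are adjusted for multiple comparisons with
#' [stats::p.adjust()]; Holm is the default (family-wise control without
#' Bonferroni's conservatism).
#'
#' @param g named list of numeric vectors, one per group.
#' @param adjustment one of `"holm"`, `"none"`, `"bonferroni"`, `"bh"`.
#' @return `test_result` carrying the omnibus Kruskal-Wallis result plus a
#'   `pairwise` data.frame (group_i, group_j, z, p_raw, p_adjusted).
#' @export
dunn_posthoc <- function(g, adjustment = c("holm", "none", "bonferroni", "bh")) {
  adjustment <- match.arg(adjustment)
  check_groups(g)
  kw <- kruskal_wallis(g)
  pw <- dunn_z_table(g)
  method <- switch(adjustment, holm = "holm", none = "none",
                   bonferroni = "bonferroni", bh = "BH")
  pw$p_adjusted <- stats::p.adjust(pw$p_raw, method = method)
  structure(list(statistic = kw$statistic, df = kw$df,
                 p_value = kw$p_value,
                 method = paste0("Dunn post-hoc (", adjustment,
                                 " adjustment) after Kruskal-Wallis"),
                 pairwise = pw),
            class = "test_result")
}

#' Summarize isolate screening counts
#'
#' Converts per-trait positive counts out of a screened total into
#' percentages (displayed to one decimal, full precision retained), and,
#' when exclusive counts are supplied for two traits, cross-checks the
#' both-traits count by set arithmetic:
#' `both = positive_A - exclusive_A = positive_B - exclusive_B`.
#' Inconsistent exclusives are flagged in the output, never silently
#' reconciled.
#'
#' @param positives named integer vector of positive counts per trait label.
#' @param total total number screened.
#' @param exclusive optional named integer vector (same labels) of counts
#'   positive for that trait only.
#' @return object of class `screening_summary`: `table` (label, count,
#'   percent, percent_display), and when exclusives are given `both`
#'   (named vector of both-count estimates per label) and `consistent`.
#' @export
screening_summary <- function(positives, total, exclusive = NULL) {
  stopifnot(is.numeric(positives), length(positives) >= 1L,
            !is.null(names(positives)), length(total) == 1L, total > 0)
  if (any(positives < 0)) stop("counts must be non-negative")
  if (any(positives > total))
    stop("count exceeds total for '",
         names(positives)[which(positives > total)[1L]], "'")
  pct <- 100 * positives / total
  tab <- data.frame(label = names(positives),
                    count = as.integer(positives),
                    percent = unname(pct),
                    percent_display = round(unname(pct), 1L),
                    row.names = NULL)
  both <- NULL
  consistent <- NA
  if (!is.null(exclusive)) {
    if (!all(names(exclusive) %in% names(positives)))
      stop("exclusive labels must match positives labels")
    if (any(exclusive > positives[names(exclusive)]))
      stop("exclusive count exceeds positive count")
    both <- positives[names(exclusive)] - exclusive
    consistent <- length(unique(both)) == 1L
  }
  structure(list(table = tab, total = as.integer(total),
                 both = both, consistent = consistent),
            class = "screening_summary")
}

#' @export
print.screening_summary <- function(x, ...) {
  cat(sprintf("screening_summary (n = %d screened):\n", x$total))
  print(x$table)
  if (!is.null(x$both)) {
    cat(sprintf("positive for both traits: %s%s\n",
                paste(unique(x$both), collapse = " vs "),
                if (isTRUE(x$consistent)) " (consistent)"
                else " [INCONSISTENT exclusive counts]"))
  }
  invisible(x)
}
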