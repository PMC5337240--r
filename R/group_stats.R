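#' Summarize a group of observers
#'
#' Arithmetic means of per-observer metrics for one reader group, the row
#' format of the study summary tables. Values are kept unrounded; apply
#' [round_half_up()] (3 decimals for FOMs, 1 for percentages) only when
#' rendering a report.
#'
#' @param members data.frame of per-observer rows (e.g. from
#'   [study_metrics()]); all numeric columns are averaged.
#' @param group_label label for the group.
#' @return An object of class `group_summary`: `group_label`, `n`, `means`
#'   (named numeric) and the retained `members`.
#' @examples
#' m <- data.frame(fom = c(0.713, 0.729, 0.743, 0.707, 0.746, 0.751))
#' s <- summarize_group(m, "RT students (before)")
#' round_half_up(s$means[["fom"]], 3) # 0.732
#' @export
summarize_group <- function(members, group_label = "") {
  members <- as.data.frame(members)
  if (!nrow(members)) stop("cannot summarize an empty group", call. = FALSE)
  num <- vapply(members, is.numeric, logical(1))
  if (!any(num)) stop("group members carry no numeric metric columns", call. = FALSE)
  out <- list(
    group_label = as.character(group_label),
    n = nrow(members),
    means = vapply(members[num], mean, numeric(1)),
    members = members
  )
  class(out) <- "group_summary"
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s (n = %d)\n", x$group_label, x$n))
  print(round(x$means, 4))
  invisible(x)
}

make_fom_test <- function(statistic, df, p_value, kind, alpha, estimate,
                          zero_variance = FALSE, note = NA_character_) {
  out <- list(
    statistic = statistic, df = df, p_value = p_value, kind = kind,
    alpha = alpha, significant = is.finite(p_value) && p_value < alpha,
    estimate = estimate, zero_variance = zero_variance, note = note
  )
  class(out) <- "fom_test"
  out
}

#' t tests on reader figures of merit
#'
#' Two-sided t tests comparing per-observer figures of merit, as used to test
#' reader groups against each other (unpaired) and the same readers before
#' and after training (paired).
#'
#' * `kind = "unpaired"`: two-sample Student t test, by default the pooled
#'   equal-variance formulation with `n_x + n_y - 2` degrees of freedom
#'   (`var_equal = FALSE` gives the Welch form).
#' * `kind = "paired"`: one-sample t test on the positional differences
#'   `y - x` (e.g. after minus before) with `n - 1` degrees of freedom.
#'
#' Degenerate data that an exact t test cannot handle is resolved in the
#' limit and flagged via `zero_variance`: identical groups (or all-zero
#' differences) give `t = 0, p = 1`; zero within-variance with unequal means
#' (or constant nonzero differences) gives `p = 0`.
#'
#' @param x,y numeric vectors of per-observer FOMs. For the paired test, `x`
#'   and `y` must have equal length and positional pairing (`x` first
#'   session, `y` second).
#' @param kind `"unpaired"` (default) or `"paired"`.
#' @param var_equal use the pooled equal-variance formulation for the
#'   unpaired test (default `TRUE`); ignored when paired.
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `fom_test` with `statistic`, `df`, `p_value`,
#'   `kind`, `alpha`, `significant`, `estimate` (mean difference `y - x` for
#'   paired, `mean(x) - mean(y)` convention of [stats::t.test()] otherwise)
#'   and `zero_variance`.
#' @examples
#' before <- c(0.713, 0.729, 0.743, 0.707, 0.746)
#' after <- c(0.799, 0.788, 0.764, 0.751, 0.756)
#' fom_t_test(before, after, kind = "paired")
#' @export
fom_t_test <- function(x, y, kind = c("unpaired", "paired"), var_equal = TRUE,
                       alpha = 0.05) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x), is.numeric(y), alpha > 0, alpha < 1)
  if (kind == "paired") {
    if (length(x) != length(y)) {
      stop("paired test requires equal-length vectors (positional pairing)", call. = FALSE)
    }
    if (length(x) < 2) stop("paired test requires at least 2 pairs", call. = FALSE)
    d <- y - x
    if (stats::var(d) == 0) {
      if (mean(d) == 0) {
        return(make_fom_test(0, length(d) - 1, 1, "paired", alpha, 0,
          zero_variance = TRUE,
          note = "all paired differences are zero"
        ))
      }
      return(make_fom_test(sign(mean(d)) * Inf, length(d) - 1, 0, "paired", alpha,
        mean(d),
        zero_variance = TRUE,
        note = "all paired differences identical and nonzero; p is the zero-variance limit"
      ))
    }
    tt <- stats::t.test(y, x, paired = TRUE, conf.level = 1 - alpha)
    return(make_fom_test(
      unname(tt$statistic), unname(tt$parameter), tt$p.value,
      "paired", alpha, unname(tt$estimate)
    ))
  }
  if (length(x) < 2 || length(y) < 2) {
    stop("unpaired test requires at least 2 values per group", call. = FALSE)
  }
  kind_label <- if (var_equal) "unpaired" else "unpaired_welch"
  pooled_var <- if (var_equal) {
    ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
  } else {
    stats::var(x) + stats::var(y)
  }
  if (pooled_var == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) {
      return(make_fom_test(0, df, 1, kind_label, alpha, 0,
        zero_variance = TRUE, note = "both groups constant and equal"
      ))
    }
    return(make_fom_test(sign(mean(x) - mean(y)) * Inf, df, 0, kind_label, alpha,
      mean(x) - mean(y),
      zero_variance = TRUE,
      note = "zero within-group variance with unequal means; p is the zero-variance limit"
    ))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal, conf.level = 1 - alpha)
  make_fom_test(
    unname(tt$statistic), unname(tt$parameter), tt$p.value,
    kind_label, alpha, unname(diff(rev(tt$estimate)))
  )
}

#' @export
print.fom_test <- function(x, ...) {
  cat(sprintf(
    "<fom_test> %s t test: t = %.4f, df = %.4g, two-sided p = %.4g (%ssignificant at alpha = %g)\n",
    x$kind, x$statistic, x$df, x$p_value,
    if (x$significant) "" else "not ", x$alpha
  ))
  if (isTRUE(x$zero_variance)) cat("  note:", x$note, "\n")
  invisible(x)
}
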