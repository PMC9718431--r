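# Statistical battery: 3-SD outlier removal, Welch t-tests of AD vs non-AD
# features at alpha = 0.01, and one-way ANOVA across stimuli with
# per-stimulus vs-baseline comparisons. No multiple-testing correction is
# applied; reports carry the number of tests so a correction can be applied
# externally.

#' Remove 3-SD outliers
#'
#' Single-pass removal of values more than `k` standard deviations from the
#' group's own mean (both estimated from the full group). Zero-variance
#' groups are returned untouched with a warning.
#'
#' @param values numeric vector (one group).
#' @param k SD multiplier.
#' @return list: `values` (cleaned), `removed` (indices into the input).
#' @export
remove_outliers <- function(values, k = 3) {
  if (length(values) < 3L) stop("group size must be >= 3", call. = FALSE)
  s <- sd(values)
  if (s == 0) {
    warning("zero variance; no outliers removed")
    return(list(values = values, removed = integer(0)))
  }
  z <- (values - mean(values)) / s
  removed <- which(abs(z) > k)
  list(values = if (length(removed)) values[-removed] else values,
       removed = removed)
}

group_compare_t <- function(v1, v2, feature, comparison, alpha) {
  if (length(v1) < 2L || length(v2) < 2L)
    stop("group size < 2 after outlier removal", call. = FALSE)
  if (sd(v1) == 0 && sd(v2) == 0 && mean(v1) == mean(v2)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- t.test(v1, v2, var.equal = FALSE)
  }
  data.frame(feature = feature, comparison = comparison, test = "welch_t",
             statistic = as.numeric(tt$statistic),
             p_value = as.numeric(tt$p.value),
             significant = as.numeric(tt$p.value) < alpha,
             direction = sign(mean(v1) - mean(v2)),
             n1 = length(v1), n2 = length(v2))
}

#' Compare features between AD and non-AD windows
#'
#' Per-feature Welch (unequal-variance) two-sample t-test after per-group
#' 3-SD outlier removal.
#'
#' @param windows labeled feature windows.
#' @param features feature columns to test.
#' @param alpha significance level.
#' @param against which windows form the non-AD group: `"none"` (baseline
#'   windows only) or `"all"` (every non-AD window).
#' @return data.frame, one row per feature.
#' @export
compare_ad_vs_non <- function(windows, features = FEATURE_NAMES,
                              alpha = 0.01, against = c("none", "all")) {
  against <- match.arg(against)
  g1 <- windows$label == "ad"
  g2 <- if (against == "none") windows$label == "none" else !g1
  if (!any(g1) || !any(g2)) stop("both groups must be non-empty",
                                 call. = FALSE)
  out <- lapply(features, function(f) {
    v1 <- remove_outliers(windows[[f]][g1 & is.finite(windows[[f]])])$values
    v2 <- remove_outliers(windows[[f]][g2 & is.finite(windows[[f]])])$values
    group_compare_t(v1, v2, f, paste0("ad_vs_", against), alpha)
  })
  do.call(rbind, out)
}

#' Compare features across the three stimuli
#'
#' Per-feature one-way ANOVA (equal-variance F test) across the AD, startle
#' and tail-pinch groups, with per-stimulus vs-baseline Welch t-tests
#' reported alongside (directions of change included, since tail pinch
#' lowers pnn5 while AD and startle raise it).
#'
#' @param windows labeled feature windows.
#' @param features feature columns to test.
#' @param alpha significance level.
#' @return data.frame: `comparison` is `anova_stimuli` or
#'   `<stimulus>_vs_none`.
#' @export
compare_stimuli <- function(windows, features = FEATURE_NAMES,
                            alpha = 0.01) {
  stim <- c("ad", "startle", "tail_pinch")
  out <- list()
  for (f in features) {
    groups <- lapply(stim, function(s) {
      v <- windows[[f]][windows$label == s & is.finite(windows[[f]])]
      if (length(v) >= 3L) remove_outliers(v)$values else v
    })
    names(groups) <- stim
    present <- vapply(groups, function(v) length(v) >= 2L, logical(1))
    if (sum(present) >= 2L) {
      vals <- unlist(groups[present])
      grp <- factor(rep(names(groups)[present],
                        vapply(groups[present], length, integer(1))))
      if (sd(vals) == 0) {
        ftest <- list(statistic = 0, p.value = 1)
      } else {
        ftest <- oneway.test(vals ~ grp, var.equal = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        feature = f, comparison = "anova_stimuli", test = "anova_f",
        statistic = as.numeric(ftest$statistic),
        p_value = as.numeric(ftest$p.value),
        significant = as.numeric(ftest$p.value) < alpha,
        direction = NA_real_,
        n1 = length(vals), n2 = NA_integer_)
    }
    base <- windows[[f]][windows$label == "none" & is.finite(windows[[f]])]
    if (length(base) >= 3L) base <- remove_outliers(base)$values
    for (s in stim) {
      if (length(groups[[s]]) >= 2L && length(base) >= 2L) {
        out[[length(out) + 1L]] <-
          group_compare_t(groups[[s]], base, f, paste0(s, "_vs_none"),
                          alpha)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_tests") <- nrow(res)
  res
}
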