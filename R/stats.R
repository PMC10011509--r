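#' One-way ANOVA from sums of squares
#'
#' Classic between/within mean-square ratio across genotype groups, with the
#' p-value from the F distribution.
#'
#' @param values numeric metric values, one per subject.
#' @param groups group labels (character or factor), e.g. WT/Het/KO.
#' @return list of class `anova_fit`: `F`, `df_between`, `df_within`, `p`,
#'   `ms_between`, `ms_within`, `group_means`, `group_n`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.character(groups)
  if (anyNA(values) || anyNA(groups)) stop("NA in values or groups")
  tb <- table(groups)
  k <- length(tb)
  if (k < 2) stop("need >= 2 groups")
  if (any(tb < 2)) stop("need >= 2 subjects per group")
  n <- length(values)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(tb * (gm[names(tb)] - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df_b <- k - 1
  df_w <- n - k
  msw <- ssw / df_w
  msb <- ssb / df_b
  if (msw == 0) {
    if (msb == 0) stop("degenerate input: zero variance within and between groups")
    return(structure(list(F = Inf, df_between = df_b, df_within = df_w, p = 0,
                          ms_between = msb, ms_within = 0,
                          group_means = gm, group_n = as.numeric(tb)),
                     class = "anova_fit"))
  }
  Fv <- msb / msw
  structure(list(F = Fv, df_between = df_b, df_within = df_w,
                 p = stats::pf(Fv, df_b, df_w, lower.tail = FALSE),
                 ms_between = msb, ms_within = msw,
                 group_means = gm, group_n = stats::setNames(as.numeric(tb), names(tb))),
            class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ",", x$df_within, ") = ",
      signif(x$F, 5), ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' For each group pair, the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MSW / n_h)` with `n_h` the harmonic mean of
#' the pair's sizes (the Tukey-Kramer form for unbalanced groups). Adjusted
#' p-values come from the studentized-range distribution with the ANOVA's
#' within-group degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @return data.frame: `group1`, `group2`, `mean_diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  a <- one_way_anova(values, groups)
  gs <- names(a$group_means)
  k <- length(gs)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ni <- a$group_n[[gs[i]]]; nj <- a$group_n[[gs[j]]]
      nh <- 2 / (1 / ni + 1 / nj)
      d <- a$group_means[[gs[j]]] - a$group_means[[gs[i]]]
      if (a$ms_within == 0) {
        q <- if (d == 0) 0 else Inf
        p <- if (d == 0) 1 else 0
      } else {
        q <- abs(d) / sqrt(a$ms_within / nh)
        p <- stats::ptukey(q, nmeans = k, df = a$df_within, lower.tail = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(group1 = gs[i], group2 = gs[j],
                                            mean_diff = d, q = q, p_adj = p)
    }
  }
  do.call(rbind, out)
}

#' Percent change of group means relative to a reference group
#'
#' `100 * (mean_g - mean_ref) / mean_ref` for every non-reference group.
#'
#' @inheritParams one_way_anova
#' @param reference reference group label (default "WT").
#' @return named numeric vector of percent changes.
#' @export
percent_change <- function(values, groups, reference = "WT") {
  groups <- as.character(groups)
  if (!reference %in% groups) stop("reference group '", reference, "' not present")
  gm <- tapply(values, groups, mean)
  if (gm[[reference]] == 0) stop("reference mean is zero")
  others <- setdiff(names(gm), reference)
  stats::setNames(100 * (unlist(gm[others]) - gm[[reference]]) / gm[[reference]],
                  others)
}
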