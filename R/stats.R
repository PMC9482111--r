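# Assumption-gated group comparisons: Anderson-Darling normality and Bartlett
# homogeneity decide between one-way ANOVA + Tukey HSD and Kruskal-Wallis +
# Dunn (Bonferroni) pairwise follow-up. Each (metric, timepoint) family is
# tested independently, mirroring per-panel comparisons.

star_code <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' Choose the parametric or nonparametric testing path
#'
#' Parametric iff every group passes the Anderson-Darling normality test at
#' `alpha_gate` and Bartlett's k-sample homogeneity-of-variance test passes
#' at `alpha_gate`. Groups too small or too degenerate to test (n < 8 for
#' Anderson-Darling, zero variance) route to the nonparametric path with a
#' warning.
#'
#' @param values Numeric vector of per-cell measurements.
#' @param groups Factor/character vector of group labels, same length.
#' @param alpha_gate Significance level of the assumption tests (default
#'   0.05).
#' @return A list: `gate` (`"parametric"` or `"nonparametric"`),
#'   `normality_p` (named per group), `bartlett_p`.
#' @export
gate_assumptions <- function(values, groups, alpha_gate = 0.05) {
  stopifnot(length(values) == length(groups), is.numeric(values))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  ns <- tapply(values, groups, length)
  if (any(ns < 3L)) {
    warning("group with n < 3; using nonparametric path")
    return(list(gate = "nonparametric",
                normality_p = setNames(rep(NA_real_, nlevels(groups)),
                                       levels(groups)),
                bartlett_p = NA_real_))
  }
  norm_p <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (length(x) < 8L || stats::sd(x) == 0) return(NA_real_)
    nortest::ad.test(x)$p.value
  }, numeric(1))
  bart_p <- if (all(tapply(values, groups, stats::sd) > 0)) {
    stats::bartlett.test(values, groups)$p.value
  } else {
    NA_real_
  }
  testable <- !anyNA(norm_p) && !is.na(bart_p)
  if (!testable) {
    warning("assumption tests not computable (small n or zero variance); ",
            "using nonparametric path")
    gate <- "nonparametric"
  } else {
    gate <- if (all(norm_p > alpha_gate) && bart_p > alpha_gate) {
      "parametric"
    } else {
      "nonparametric"
    }
  }
  list(gate = gate, normality_p = norm_p, bartlett_p = bart_p)
}

# Dunn's rank-based pairwise z tests after Kruskal-Wallis, with tie
# correction and Bonferroni adjustment. No installed package provides this.
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  cmb <- utils::combn(levels(groups), 2)
  m <- ncol(cmb)
  p <- numeric(m); z <- numeric(m)
  for (k in seq_len(m)) {
    a <- cmb[1, k]; b <- cmb[2, k]
    se <- sqrt(s2 * (1 / ni[[a]] + 1 / ni[[b]]))
    z[k] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p[k] <- min(1, 2 * stats::pnorm(-abs(z[k])) * m)  # Bonferroni
  }
  tibble::tibble(group_a = cmb[1, ], group_b = cmb[2, ],
                 statistic = z, p = p)
}

#' Gated omnibus and pairwise comparison of measurement groups
#'
#' Runs [gate_assumptions()], then either one-way ANOVA with Tukey HSD
#' pairwise comparisons (parametric path) or Kruskal-Wallis with Dunn's
#' Bonferroni-corrected pairwise follow-up (nonparametric path). Pairwise
#' significance is flagged at `alpha` and annotated with the conventional
#' star codes (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @inheritParams gate_assumptions
#' @param alpha Pairwise/omnibus significance level (default 0.05).
#' @param gate Optional override, `"parametric"` or `"nonparametric"`, to
#'   bypass the assumption gate.
#' @return A list of class `group_comparison`: `gate`, `omnibus_test`,
#'   `omnibus_stat`, `omnibus_p`, `pairwise` (tibble: group_a, group_b,
#'   statistic, p, significant, stars), `normality_p`, `bartlett_p`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, alpha_gate = 0.05,
                           gate = NULL) {
  stopifnot(length(values) == length(groups), is.numeric(values))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  gi <- NULL
  if (is.null(gate)) {
    gi <- gate_assumptions(values, groups, alpha_gate)
    gate <- gi$gate
  }
  gate <- match.arg(gate, c("parametric", "nonparametric"))
  if (stats::sd(values) == 0) {
    # all observations identical: nothing to compare
    cmb <- utils::combn(levels(groups), 2)
    pw <- tibble::tibble(group_a = cmb[1, ], group_b = cmb[2, ],
                         statistic = 0, p = 1)
  } else if (gate == "parametric") {
    fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
    an <- summary(fit)[[1]]
    omnibus_stat <- an[["F value"]][1]
    omnibus_p <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    parts <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- tibble::tibble(group_a = vapply(parts, `[`, "", 1),
                         group_b = vapply(parts, `[`, "", 2),
                         statistic = tk[, "diff"], p = tk[, "p adj"])
  } else {
    kw <- stats::kruskal.test(values, groups)
    omnibus_stat <- unname(kw$statistic)
    omnibus_p <- kw$p.value
    pw <- dunn_pairwise(values, groups)
  }
  if (stats::sd(values) == 0) {
    omnibus_stat <- 0
    omnibus_p <- 1
  }
  pw$significant <- pw$p < alpha
  pw$stars <- star_code(pw$p)
  structure(list(gate = gate,
                 omnibus_test = if (gate == "parametric") "anova" else
                   "kruskal-wallis",
                 omnibus_stat = omnibus_stat, omnibus_p = omnibus_p,
                 pairwise = pw,
                 normality_p = gi$normality_p, bartlett_p = gi$bartlett_p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s path: %s stat = %.3f, p = %.4g\n", x$gate,
              x$omnibus_test, x$omnibus_stat, x$omnibus_p))
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' Box-whisker summary per group
#'
#' Median and quartiles (type-7 linear interpolation), Tukey whiskers at the
#' most extreme observations within 1.5 IQR of the quartiles, outliers
#' beyond them listed separately. Mean and SD are included so that a
#' median +/- SD convention can also be rendered.
#'
#' @inheritParams gate_assumptions
#' @return Tibble with one row per group: `group`, `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `mean`, `sd`, `outliers`
#'   (list-column).
#' @export
summarise_box <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  rows <- lapply(levels(groups), function(g) {
    x <- values[groups == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x >= lo_fence & x <= hi_fence
    tibble::tibble(group = g, n = length(x), median = q[2],
                   q1 = q[1], q3 = q[3],
                   whisker_low = min(x[inside]),
                   whisker_high = max(x[inside]),
                   mean = mean(x), sd = stats::sd(x),
                   outliers = list(x[!inside]))
  })
  do.call(rbind, rows)
}
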