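#' Group summary (mean, SEM, n)
#'
#' The unit of published comparison is usually a group summarized as
#' mean +/- SEM with its sample size; the group SD is reconstructable as
#' `sem * sqrt(n)`.
#'
#' @param label Group label.
#' @param mean Group mean.
#' @param sem Standard error of the mean (> 0).
#' @param n Number of observations (integer >= 2).
#' @param values Optional raw observations; when given, mean/sem/n are
#'   computed from them and must not be supplied.
#' @return A list of class `group_summary` with `label`, `mean`, `sem`,
#'   `n`, `sd`.
#' @export
group_summary <- function(label, mean = NULL, sem = NULL, n = NULL,
                          values = NULL) {
  if (!is.null(values)) {
    if (!is.null(mean) || !is.null(sem) || !is.null(n)) {
      stop("give either raw 'values' or mean/sem/n, not both", call. = FALSE)
    }
    n <- length(values)
    if (n < 2L) stop("need at least 2 observations", call. = FALSE)
    mean <- base::mean(values)
    sem <- stats::sd(values) / sqrt(n)
  }
  if (is.null(mean) || is.null(sem) || is.null(n)) {
    stop("mean, sem and n are all required", call. = FALSE)
  }
  if (n < 2L || n != round(n)) {
    stop("'n' must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(sem) || sem <= 0) stop("'sem' must be > 0", call. = FALSE)
  structure(list(label = label, mean = mean, sem = sem, n = as.integer(n),
                 sd = sem * sqrt(n)),
            class = "group_summary")
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Reconstructs group SDs from the SEMs and performs a two-tailed unpaired
#' t-test. The `"student"` variant pools the variances with
#' `df = n_a + n_b - 2`; the `"welch"` variant uses the Satterthwaite
#' degrees of freedom. When the summaries are computed from raw samples the
#' student variant reproduces `stats::t.test(var.equal = TRUE)` exactly.
#'
#' @param a,b [group_summary()] objects.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A list of class `test_result`: `method`, `statistic`, `df`,
#'   `p_value`, `comparison`, `stars`.
#' @export
ttest_from_summary <- function(a, b, variant = c("student", "welch")) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  variant <- match.arg(variant)
  diff <- a$mean - b$mean
  if (variant == "student") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t_stat <- diff / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  test_result(if (variant == "student") "student_t" else "welch_t",
              t_stat, df, p, paste(a$label, "vs", b$label))
}

test_result <- function(method, statistic, df, p_value, comparison) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, comparison = comparison,
                 stars = significance_stars(p_value)),
            class = "test_result")
}

#' Significance stars
#'
#' The star convention of the source figure legends: `*` for p < 0.05,
#' `**` for p < 0.01, `***` for p < 0.0001, `ns` otherwise.
#'
#' @param p P-value.
#' @return Character string of stars.
#' @export
significance_stars <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 1e-4) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

as_group_summaries <- function(groups) {
  lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (inherits(g, "group_summary")) return(g)
    if (is.numeric(g)) {
      lab <- if (!is.null(names(groups))) names(groups)[i] else
        paste0("group", i)
      return(group_summary(lab, values = g))
    }
    stop("groups must be numeric vectors or group_summary objects",
         call. = FALSE)
  })
}

#' One-way ANOVA with Tukey or Bonferroni multiple comparisons
#'
#' Accepts raw per-observation values or published summaries (mean, SEM, n);
#' raw groups are reduced to summaries, from which the omnibus F and the
#' pairwise comparisons follow exactly (the one-way F statistic depends on
#' the data only through group means, SDs and sizes). Post hoc adjusted
#' p-values use the studentized-range distribution (Tukey-Kramer) or
#' Bonferroni scaling of the pooled-variance pairwise t-tests (raw p times
#' the number of comparisons, capped at 1). With only two groups the
#' omnibus F equals the square of the pooled t statistic.
#'
#' @param groups Named list of numeric vectors and/or [group_summary()]
#'   objects (>= 2 groups, each with n >= 2).
#' @param posthoc `"tukey"` (default) or `"bonferroni"`.
#' @param comparisons For Bonferroni: optional list of 2-element vectors of
#'   group labels selecting the compared pairs (default: all pairs).
#' @return A list of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `p_omnibus`, and `comparisons`, a data.frame with one row
#'   per pair (`a`, `b`, `diff`, `statistic`, `p_raw`, `p_adjusted`,
#'   `stars`).
#' @export
anova_mc <- function(groups, posthoc = c("tukey", "bonferroni"),
                     comparisons = NULL) {
  posthoc <- match.arg(posthoc)
  gs <- as_group_summaries(groups)
  k <- length(gs)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(gs, `[[`, integer(1), "n")
  means <- vapply(gs, `[[`, numeric(1), "mean")
  sds <- vapply(gs, `[[`, numeric(1), "sd")
  labels <- vapply(gs, `[[`, character(1), "label")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ms_between <- sum(ns * (means - grand)^2) / (k - 1)
  df_within <- N - k
  ms_within <- sum((ns - 1) * sds^2) / df_within
  f_stat <- ms_between / ms_within
  p_omnibus <- stats::pf(f_stat, k - 1, df_within, lower.tail = FALSE)

  pairs <- utils::combn(k, 2L, simplify = FALSE)
  if (!is.null(comparisons)) {
    if (posthoc != "bonferroni") {
      stop("selected comparisons are a Bonferroni feature", call. = FALSE)
    }
    pairs <- lapply(comparisons, function(cmp) {
      idx <- match(cmp, labels)
      if (anyNA(idx)) stop("unknown group label in 'comparisons'",
                           call. = FALSE)
      idx
    })
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    diff <- means[i] - means[j]
    se_t <- sqrt(ms_within * (1 / ns[i] + 1 / ns[j]))
    if (posthoc == "tukey") {
      # Tukey-Kramer: studentized range with the pooled within-group MS
      q_stat <- abs(diff) / sqrt(ms_within / 2 * (1 / ns[i] + 1 / ns[j]))
      p_raw <- 2 * stats::pt(abs(diff) / se_t, df_within, lower.tail = FALSE)
      p_adj <- stats::ptukey(q_stat, k, df_within, lower.tail = FALSE)
      stat <- q_stat
    } else {
      stat <- diff / se_t
      p_raw <- 2 * stats::pt(abs(stat), df_within, lower.tail = FALSE)
      p_adj <- min(1, p_raw * m)
    }
    data.frame(a = labels[i], b = labels[j], diff = diff, statistic = stat,
               p_raw = p_raw, p_adjusted = p_adj,
               stars = significance_stars(p_adj),
               stringsAsFactors = FALSE)
  })
  structure(list(f_statistic = f_stat, df_between = k - 1,
                 df_within = df_within, p_omnibus = p_omnibus,
                 posthoc = posthoc,
                 comparisons = do.call(rbind, rows)),
            class = "anova_result")
}

#' Fold change of a treated value over a reference
#'
#' @param reference Reference (control) value; must be positive.
#' @param treated Treated value.
#' @return `treated / reference`.
#' @export
fold_change <- function(reference, treated) {
  if (!is.numeric(reference) || reference <= 0) {
    stop("'reference' must be positive", call. = FALSE)
  }
  treated / reference
}

#' Assemble a grouped summary table
#'
#' Joins group summaries into one data.frame (label, mean, sem, n, sd) in
#' the order given, the shape of a published dot-plot panel.
#'
#' @param summaries List of [group_summary()] objects.
#' @return A data.frame.
#' @export
summary_table <- function(summaries) {
  gs <- as_group_summaries(summaries)
  do.call(rbind, lapply(gs, function(g)
    data.frame(label = g$label, mean = g$mean, sem = g$sem, n = g$n,
               sd = g$sd, stringsAsFactors = FALSE)))
}
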