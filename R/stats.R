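#' Significance stars
#'
#' Maps p values to the star convention used throughout the figures:
#' `*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001, `ns` otherwise.
#'
#' @param p numeric vector of p values.
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

new_stat_result <- function(method, statistic, p_value, comparisons = NULL,
                            extra = list()) {
  structure(
    c(list(method = method, statistic = unname(statistic),
           p_value = unname(p_value), comparisons = comparisons), extra),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$method, "\n", sep = "")
  cat("  statistic = ", format(x$statistic), ", p = ", format.pval(x$p_value),
      " ", p_stars(x$p_value), "\n", sep = "")
  if (!is.null(x$comparisons)) {
    print(x$comparisons)
  }
  invisible(x)
}

#' Tidy a stat_result
#' @param x a `stat_result`.
#' @param ... unused.
#' @return tibble: one row per post-hoc comparison when present, otherwise
#'   one row for the test itself.
#' @method tidy stat_result
#' @export
tidy.stat_result <- function(x, ...) {
  if (!is.null(x$comparisons)) return(tibble::as_tibble(x$comparisons))
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, stars = p_stars(x$p_value))
}

#' Glance at a stat_result
#' @param x a `stat_result`.
#' @param ... unused.
#' @return one-row tibble with the omnibus statistic and p value.
#' @method glance stat_result
#' @export
glance.stat_result <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, stars = p_stars(x$p_value))
}

check_groups <- function(data, value, group) {
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  v <- data[[value]]
  if (!all(is.finite(v))) stop("non-finite values in '", value, "'", call. = FALSE)
  g <- as.character(data[[group]])
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  invisible(TRUE)
}

#' Normality-gated choice of the test family
#'
#' Applies a Shapiro-Wilk test per group at `alpha`; the analysis is
#' parametric iff every group passes. Groups with fewer than 3 values cannot
#' be tested and force the nonparametric path with a warning.
#'
#' @param data data frame with one row per intestine.
#' @param value,group column names of the measured value and the grouping.
#' @param alpha per-group significance level (default 0.05).
#' @return list with `parametric` (logical) and `per_group` (tibble: group,
#'   n, W, p_value, normal).
#' @export
assess_normality <- function(data, value = "value", group = "group",
                             alpha = 0.05) {
  check_groups(data, value, group)
  per <- data |>
    dplyr::group_by(.g = as.character(.data[[group]])) |>
    dplyr::summarise(
      n = dplyr::n(),
      W = ifelse(dplyr::n() >= 3 && stats::sd(.data[[value]]) > 0,
                 tryCatch(stats::shapiro.test(.data[[value]])$statistic,
                          error = function(e) NA_real_), NA_real_),
      p_value = ifelse(dplyr::n() >= 3 && stats::sd(.data[[value]]) > 0,
                       tryCatch(stats::shapiro.test(.data[[value]])$p.value,
                                error = function(e) NA_real_), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::rename(group = ".g") |>
    dplyr::mutate(normal = !is.na(.data$p_value) & .data$p_value >= alpha)
  if (any(per$n < 3)) {
    warning("group(s) with n < 3: normality untestable, using the ",
            "nonparametric path", call. = FALSE)
  }
  list(parametric = all(per$normal) && all(per$n >= 3), per_group = per)
}

#' Two-group comparison (one-tailed t or Mann-Whitney)
#'
#' One-tailed unpaired Welch t-test on the parametric path, Mann-Whitney
#' (Wilcoxon rank-sum) otherwise. The tail direction is a required analysis
#' input — it encodes the experimental hypothesis and is never inferred from
#' the data. When `parametric` is `NULL` the path is chosen by
#' [assess_normality()].
#'
#' @param data data frame with exactly two groups.
#' @param value,group column names.
#' @param alternative `"greater"` or `"less"`: position of the first group
#'   (alphabetical or factor order) relative to the second under the
#'   alternative hypothesis. `"two.sided"` is accepted for completeness.
#' @param parametric logical, or `NULL` to gate on normality.
#' @return a `stat_result`.
#' @export
compare_two <- function(data, value = "value", group = "group",
                        alternative, parametric = NULL) {
  check_groups(data, value, group)
  if (missing(alternative)) {
    stop("`alternative` is required: the tail encodes the hypothesis ",
         "('greater', 'less' or 'two.sided')", call. = FALSE)
  }
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) stop("compare_two needs exactly 2 groups", call. = FALSE)
  a <- data[[value]][g == levels(g)[1]]
  b <- data[[value]][g == levels(g)[2]]
  if (is.null(parametric)) {
    parametric <- assess_normality(data, value, group)$parametric
  }
  if (parametric) {
    ht <- stats::t.test(a, b, alternative = alternative, paired = FALSE)
    method <- paste0("Unpaired t-test (", alternative, ")")
  } else {
    ht <- stats::wilcox.test(a, b, alternative = alternative, exact = NULL)
    method <- paste0("Mann-Whitney (", alternative, ")")
  }
  new_stat_result(method, ht$statistic, ht$p.value,
                  extra = list(parametric = parametric,
                               groups = levels(g), alternative = alternative))
}

#' Multi-group comparison with post-hocs versus control
#'
#' Parametric path: one-way ANOVA followed by Dunnett's test against the
#' control group (single-step multivariate-t adjustment via `multcomp`).
#' Nonparametric path: Kruskal-Wallis with midrank tie correction followed by
#' Dunn's test versus control with Bonferroni adjustment over the
#' control-vs-treatment family. When `parametric` is `NULL` the path is
#' chosen by [assess_normality()].
#'
#' @param data data frame with >= 3 groups.
#' @param value,group column names.
#' @param control name of the control group (required).
#' @param parametric logical or `NULL`.
#' @return a `stat_result`; `$comparisons` holds one row per treatment group
#'   with raw and adjusted p values and stars.
#' @export
compare_multi <- function(data, value = "value", group = "group", control,
                          parametric = NULL) {
  check_groups(data, value, group)
  if (missing(control) || !control %in% as.character(data[[group]])) {
    stop("a control group present in the data must be designated", call. = FALSE)
  }
  g <- factor(as.character(data[[group]]))
  if (nlevels(g) < 3L) stop("compare_multi needs >= 3 groups", call. = FALSE)
  g <- stats::relevel(g, ref = control)
  v <- data[[value]]
  if (is.null(parametric)) {
    parametric <- assess_normality(data, value, group)$parametric
  }
  if (parametric) {
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1]]
    fstat <- an$`F value`[1]
    p_omni <- an$`Pr(>F)`[1]
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    raw <- 2 * stats::pt(-abs(sm$test$tstat), df = fit$df.residual)
    comp <- tibble::tibble(
      comparison = names(sm$test$coefficients),
      estimate = as.numeric(sm$test$coefficients),
      statistic = as.numeric(sm$test$tstat),
      p_raw = as.numeric(raw),
      p_adj = pmax(as.numeric(sm$test$pvalues), as.numeric(raw)),
      stars = p_stars(pmax(as.numeric(sm$test$pvalues), as.numeric(raw)))
    )
    new_stat_result("One-way ANOVA + Dunnett", fstat, p_omni, comp,
                    extra = list(parametric = TRUE, control = control))
  } else {
    kw <- stats::kruskal.test(v, g)
    comp <- dunn_vs_control(v, g, control)
    new_stat_result("Kruskal-Wallis + Dunn (Bonferroni)", kw$statistic,
                    kw$p.value, comp,
                    extra = list(parametric = FALSE, control = control))
  }
}

# Dunn's z-tests of mean midranks versus control with the standard tie
# correction; Bonferroni over the k-1 vs-control comparisons.
dunn_vs_control <- function(v, g, control) {
  r <- rank(v)  # midranks
  n <- length(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  var_term <- n * (n + 1) / 12 - tie_corr
  lv <- levels(g)
  treat <- setdiff(lv, control)
  rc <- mean(r[g == control]); nc <- sum(g == control)
  rows <- purrr::map_dfr(treat, function(tg) {
    rt <- mean(r[g == tg]); nt <- sum(g == tg)
    z <- (rt - rc) / sqrt(var_term * (1 / nt + 1 / nc))
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(comparison = paste(tg, "-", control),
                   estimate = rt - rc, statistic = z, p_raw = p)
  })
  rows$p_adj <- pmin(rows$p_raw * length(treat), 1)
  rows$stars <- p_stars(rows$p_adj)
  rows
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group; censored individuals leave the risk set
#' after their censoring time.
#'
#' @param table survival data frame with columns `time_days` (> 0), `event`
#'   (1 = death, 0 = censored) and optionally `group`.
#' @param group optional single group name to restrict to.
#' @return a `km_fit`: the underlying [survival::survfit] object plus a tidy
#'   curve accessor via [tidy.km_fit()].
#' @export
km_estimate <- function(table, group = NULL) {
  check_survival_table(table)
  df <- tibble::as_tibble(table)
  if (!is.null(group)) {
    df <- df[as.character(df$group) == group, ]
    if (nrow(df) == 0L) stop("empty group '", group, "'", call. = FALSE)
  }
  has_groups <- is.null(group) && "group" %in% names(df) &&
    length(unique(df$group)) > 1L
  fit <- if (has_groups) {
    survival::survfit(survival::Surv(time_days, event) ~ group, data = df)
  } else {
    survival::survfit(survival::Surv(time_days, event) ~ 1, data = df)
  }
  structure(list(fit = fit, data = df, grouped = has_groups),
            class = "km_fit")
}

check_survival_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("time_days", "event") %in% names(table)))
  if (nrow(table) == 0L) stop("empty survival table", call. = FALSE)
  stopifnot(all(table$time_days > 0), all(table$event %in% c(0, 1)))
  invisible(TRUE)
}

#' Tidy a Kaplan-Meier fit
#' @param x a `km_fit`.
#' @param ... unused.
#' @return tibble: `time`, `n_risk`, `n_event`, `n_censor`, `estimate`,
#'   `std_error`, and `group` when fitted by group.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  out <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv, std_error = s$std.err
  )
  if (!is.null(s$strata)) {
    out$group <- sub("^group=", "", as.character(s$strata))
  }
  out
}

#' Glance at a Kaplan-Meier fit
#' @param x a `km_fit`.
#' @param ... unused.
#' @return one-row (or one-per-group) tibble with n, events and median
#'   survival.
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tb <- summary(x$fit)$table
  if (is.null(dim(tb))) tb <- t(as.matrix(tb))
  out <- tibble::tibble(
    n = tb[, "records"], events = tb[, "events"], median = tb[, "median"]
  )
  if (!is.null(rownames(tb)) && nrow(out) > 1) {
    out$group <- sub("^group=", "", rownames(tb))
  }
  out
}

#' Mantel-Cox log-rank test between two groups
#'
#' Standard log-rank chi-square built from observed-versus-expected event
#' tables at each distinct event time; p from a chi-square with 1 df.
#'
#' @param table survival data frame (`time_days`, `event`, `group`).
#' @param group_a,group_b the two groups to compare.
#' @return a `stat_result`.
#' @export
logrank <- function(table, group_a, group_b) {
  check_survival_table(table)
  stopifnot("group" %in% names(table))
  df <- tibble::as_tibble(table)
  df <- df[as.character(df$group) %in% c(group_a, group_b), ]
  if (!all(c(group_a, group_b) %in% as.character(df$group))) {
    stop("both groups must be present and non-empty", call. = FALSE)
  }
  if (any(tapply(df$event, as.character(df$group), sum) == 0)) {
    warning("a group has zero observed deaths; log-rank is still defined",
            call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  new_stat_result("Mantel-Cox log-rank", sd$chisq, p,
                  extra = list(groups = c(group_a, group_b),
                               observed = as.numeric(sd$obs),
                               expected = as.numeric(sd$exp)))
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes per-replicate delta-Ct (target minus reference), the
#' delta-delta-Ct between each group and the control, and the fold change
#' `2^(-ddCt)` with a confidence interval from error propagation on the
#' replicate delta-Ct values (Welch-type standard error, t critical value).
#'
#' @param ct_table data frame with columns `group`, `replicate`, `gene`,
#'   `ct`.
#' @param target target gene name.
#' @param reference_gene housekeeping/reference gene name.
#' @param control_group control group name.
#' @param conf_level confidence level (default 0.95).
#' @return tibble: one row per non-control group with `delta_delta_ct`,
#'   `fold_change`, `conf_low`, `conf_high`.
#' @export
relative_expression <- function(ct_table, target, reference_gene,
                                control_group, conf_level = 0.95) {
  df <- tibble::as_tibble(ct_table)
  stopifnot(all(c("group", "replicate", "gene", "ct") %in% names(df)))
  if (!reference_gene %in% df$gene) {
    stop("reference gene '", reference_gene, "' missing from the Ct table",
         call. = FALSE)
  }
  if (!target %in% df$gene) {
    stop("target gene '", target, "' missing from the Ct table", call. = FALSE)
  }
  wide <- df |>
    dplyr::filter(.data$gene %in% c(target, reference_gene)) |>
    tidyr::pivot_wider(id_cols = c("group", "replicate"),
                       names_from = "gene", values_from = "ct")
  if (anyNA(wide[[target]]) || anyNA(wide[[reference_gene]])) {
    stop("target and reference Ct must be present for every replicate",
         call. = FALSE)
  }
  wide$delta_ct <- wide[[target]] - wide[[reference_gene]]
  if (!control_group %in% wide$group) {
    stop("control group '", control_group, "' missing", call. = FALSE)
  }
  ctrl <- wide$delta_ct[wide$group == control_group]
  n0 <- length(ctrl); m0 <- mean(ctrl)
  v0 <- if (n0 > 1) stats::var(ctrl) / n0 else 0
  groups <- setdiff(unique(wide$group), control_group)
  purrr::map_dfr(groups, function(gr) {
    x <- wide$delta_ct[wide$group == gr]
    n1 <- length(x)
    ddct <- mean(x) - m0
    v1 <- if (n1 > 1) stats::var(x) / n1 else 0
    se <- sqrt(v0 + v1)
    dfree <- if (se > 0 && n0 > 1 && n1 > 1) {
      (v0 + v1)^2 / (v0^2 / (n0 - 1) + v1^2 / (n1 - 1))
    } else {
      max(n0 + n1 - 2, 1)
    }
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = dfree)
    tibble::tibble(
      group = gr, n = n1,
      delta_delta_ct = ddct,
      fold_change = 2^(-ddct),
      conf_low = 2^(-(ddct + tcrit * se)),
      conf_high = 2^(-(ddct - tcrit * se))
    )
  })
}
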