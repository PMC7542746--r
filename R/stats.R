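#' Statistical test result
#'
#' Light container mirroring the "statistic, df, p, test" reporting format
#' used throughout the analysis: one test statistic (t or chi-square), its
#' degrees of freedom, the two-sided p-value and a test label.
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (possibly non-integer).
#' @param p_value Two-sided p-value.
#' @param test_label Human-readable test name.
#' @param n_per_group Optional named sample sizes.
#' @param estimate Optional effect estimate (e.g. mean difference).
#' @return An object of class `okr_stat`.
#' @export
okr_stat <- function(statistic, df, p_value, test_label, n_per_group = NULL,
                     estimate = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_label = test_label, n_per_group = n_per_group,
                 estimate = estimate),
            class = "okr_stat")
}

#' @export
print.okr_stat <- function(x, ...) {
  stat_name <- if (grepl("mixed|likelihood", tolower(x$test_label))) "chi^2" else "t"
  cat(sprintf("%s = %s, df = %s, p = %s, %s\n",
              stat_name, format(x$statistic, digits = 4),
              format(x$df, digits = 4),
              format.pval(x$p_value, digits = 3), x$test_label))
  if (!is.null(x$n_per_group)) {
    cat("  n:", paste(sprintf("%s = %d", names(x$n_per_group),
                              as.integer(x$n_per_group)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paired t-test
#'
#' Classic paired t on the per-unit differences, df = n - 1, two-sided.
#' When every difference is exactly zero the statistic is reported as 0 with
#' p = 1 (no evidence of change); zero difference variance around a non-zero
#' mean is degenerate and rejected.
#'
#' @param x,y Paired samples (equal length, n >= 2).
#' @return An [okr_stat()] with `test_label = "Paired t-test"`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(okr_stat(0, n - 1, 1, "Paired t-test",
                      n_per_group = c(pairs = n), estimate = 0))
    }
    stop("zero variance of paired differences: the paired t statistic is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  okr_stat(unname(tt$statistic), unname(tt$parameter), tt$p.value,
           "Paired t-test", n_per_group = c(pairs = n),
           estimate = unname(tt$estimate))
}

#' Two-sample t-test (Welch by default)
#'
#' Welch's unequal-variance t with Welch-Satterthwaite degrees of freedom
#' (generally non-integer); the pooled-variance Student form is available
#' behind `pooled = TRUE`.
#'
#' @param x,y Samples, each n >= 2.
#' @param pooled Use the pooled-variance (equal-variance) form.
#' @return An [okr_stat()].
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(okr_stat(0, length(x) + length(y) - 2, 1,
                      if (pooled) "Two-sample t-test (pooled)" else "Two-sample t-test (Welch)",
                      n_per_group = c(x = length(x), y = length(y)), estimate = 0))
    }
    stop("zero variance in both samples: the t statistic is undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  okr_stat(unname(tt$statistic), unname(tt$parameter), tt$p.value,
           if (pooled) "Two-sample t-test (pooled)" else "Two-sample t-test (Welch)",
           n_per_group = c(x = length(x), y = length(y)),
           estimate = unname(diff(rev(tt$estimate))))
}

#' Long-format F-I table from extracted cell features
#'
#' @param results List of [extract_cell_features()] results (`protocol_result`
#'   objects), or a [cell_population] already run through [extract_features()].
#' @param regular_only Drop cells not labelled regular-spiking.
#' @return Data frame with columns `cell_id`, `group`, `current_step` (pA),
#'   `firing_rate` (Hz).
#' @export
fi_long_table <- function(results, regular_only = TRUE) {
  rows <- lapply(results, function(r) {
    if (is.null(r$fi_curve)) return(NULL)
    if (regular_only && !identical(r$pattern, "regular")) return(NULL)
    data.frame(cell_id = r$cell_id, group = r$group_label,
               current_step = r$fi_curve$currents,
               firing_rate = r$fi_curve$rates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cell_id = character(0), group = character(0),
                                      current_step = numeric(0),
                                      firing_rate = numeric(0))
  rownames(out) <- NULL
  out
}

#' Mixed-model comparison of F-I curves between groups
#'
#' Fits `firing_rate ~ group * step` (step categorical) with a random
#' intercept per cell by maximum likelihood, and reports the likelihood-ratio
#' chi-square of all group-involving terms (group main effect plus
#' group-by-step interaction) against the group-free null, with df equal to
#' the parameter-count difference of the two fitted models. Per-step group
#' contrasts follow with a single-step multivariate-t adjustment over the
#' step family ("mvt", in the Tukey spirit); if that adjustment fails
#' numerically the Holm correction is used and flagged.
#'
#' When the random-intercept variance collapses to zero (singular fit) both
#' models are refitted as fixed-effects linear models and the output is
#' labelled accordingly.
#'
#' @param table Long-format data frame from [fi_long_table()]: `cell_id`,
#'   `group`, `current_step`, `firing_rate`.
#' @param contrasts Compute per-step group contrasts (skippable for speed in
#'   simulation loops).
#' @return An object of class `lmm_fi`: `test` (the LRT [okr_stat()]),
#'   `contrasts` (data frame or NULL), `adjust_method`, `model_label`,
#'   `model` (the fitted full model).
#' @export
lmm_fi_comparison <- function(table, contrasts = TRUE) {
  need <- c("cell_id", "group", "current_step", "firing_rate")
  if (!all(need %in% names(table))) {
    stop("table must have columns cell_id, group, current_step, firing_rate",
         call. = FALSE)
  }
  d <- data.frame(cell_id = factor(table$cell_id),
                  group = factor(table$group),
                  step = factor(table$current_step),
                  rate = table$firing_rate)
  if (nlevels(d$group) != 2) stop("exactly two groups are required", call. = FALSE)
  cells_per_group <- tapply(d$cell_id, d$group, function(x) length(unique(x)))
  if (any(cells_per_group < 2)) stop("need at least 2 cells per group", call. = FALSE)
  if (nlevels(d$step) < 2) stop("need at least 2 current steps", call. = FALSE)

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  full <- suppressWarnings(
    lme4::lmer(rate ~ group * step + (1 | cell_id), data = d, REML = FALSE,
               control = ctrl))
  singular <- lme4::isSingular(full, tol = 1e-5)
  if (singular) {
    full <- stats::lm(rate ~ group * step, data = d)
    null <- stats::lm(rate ~ step, data = d)
    model_label <- "fixed-effects fallback (singular random intercept)"
  } else {
    null <- suppressWarnings(
      lme4::lmer(rate ~ step + (1 | cell_id), data = d, REML = FALSE,
                 control = ctrl))
    model_label <- "linear mixed model, random intercept per cell"
  }
  ll_full <- stats::logLik(full)
  ll_null <- stats::logLik(null)
  chi2 <- max(0, 2 * (as.numeric(ll_full) - as.numeric(ll_null)))
  df <- attr(ll_full, "df") - attr(ll_null, "df")
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  test <- okr_stat(chi2, df, p,
                   paste0("Likelihood-ratio test, group terms (",
                          model_label, ")"),
                   n_per_group = cells_per_group)

  ctr_tab <- NULL
  adjust_method <- NA_character_
  if (contrasts) {
    emm <- emmeans::emmeans(full, ~ group | step,
                            lmer.df = "asymptotic",
                            data = d)
    ctr <- emmeans::contrast(emm, "revpairwise")
    sm <- tryCatch(summary(ctr, by = NULL, adjust = "mvt"),
                   error = function(e) NULL)
    if (is.null(sm)) {
      sm <- summary(ctr, by = NULL, adjust = "holm")
      adjust_method <- "holm (mvt adjustment failed)"
    } else {
      adjust_method <- "mvt"
    }
    ctr_tab <- as.data.frame(sm)
  }
  structure(list(test = test, contrasts = ctr_tab,
                 adjust_method = adjust_method,
                 model_label = model_label, model = full),
            class = "lmm_fi")
}

#' @export
print.lmm_fi <- function(x, ...) {
  print(x$test)
  cat("  model:", x$model_label, "\n")
  if (!is.null(x$contrasts)) {
    cat("  per-step group contrasts (", x$adjust_method, " adjusted):\n", sep = "")
    print(x$contrasts, digits = 3)
  }
  invisible(x)
}

#' Feature-wise group comparison battery
#'
#' Applies the two-sample (Welch) comparison to each single-cell feature
#' (rheobase, AP threshold, AP amplitude, AHP amplitude, input resistance)
#' and the mixed-model comparison to the F-I table, after excluding cells not
#' labelled regular-spiking. Exclusion counts are always reported; a feature
#' missing for an entire group is skipped with a warning, never silently.
#'
#' @param results List of `protocol_result` objects (see
#'   [extract_cell_features()]).
#' @param contrasts Forwarded to [lmm_fi_comparison()].
#' @return An object of class `group_summary`: `tests` (named list of
#'   [okr_stat()]), `fi` (an `lmm_fi` or NULL), `included_n`, `exclusions`
#'   (data frame), `feature_table`.
#' @export
summarize_groups <- function(results, contrasts = TRUE) {
  tab <- feature_table(results)
  excl <- tab[tab$pattern != "regular", c("cell_id", "group", "pattern")]
  if (nrow(excl)) excl$reason <- "non-regular firing pattern"
  reg <- tab[tab$pattern == "regular", ]
  groups <- sort(unique(tab$group))
  if (length(groups) != 2) stop("exactly two groups are required", call. = FALSE)
  included_n <- vapply(groups, function(g) sum(reg$group == g), numeric(1))
  if (any(included_n < 2)) {
    stop("need at least 2 regular-spiking cells per group", call. = FALSE)
  }
  features <- c(rheobase = "rheobase", ap_threshold = "ap_threshold",
                ap_amplitude = "ap_amplitude", ahp_amplitude = "ahp_amplitude",
                input_resistance = "input_resistance")
  tests <- list()
  for (f in names(features)) {
    x <- reg[[f]][reg$group == groups[1]]
    y <- reg[[f]][reg$group == groups[2]]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("feature '%s' missing for (nearly) all of one group; comparison skipped", f),
              call. = FALSE)
      next
    }
    tests[[f]] <- welch_t(x, y)
  }
  fi_tab <- fi_long_table(results, regular_only = TRUE)
  fi <- NULL
  if (nrow(fi_tab)) {
    fi <- tryCatch(lmm_fi_comparison(fi_tab, contrasts = contrasts),
                   error = function(e) {
                     warning("F-I mixed-model comparison skipped: ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
  }
  structure(list(tests = tests, fi = fi, included_n = included_n,
                 exclusions = excl, feature_table = tab),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group comparison summary\n")
  cat("  included regular-spiking cells:",
      paste(sprintf("%s = %d", names(x$included_n), as.integer(x$included_n)),
            collapse = ", "), "\n")
  cat("  excluded:", nrow(x$exclusions), "cell(s)\n")
  for (nm in names(x$tests)) {
    cat(sprintf("  %-17s ", nm))
    print(x$tests[[nm]])
  }
  if (!is.null(x$fi)) {
    cat("  F-I curve: ")
    print(x$fi$test)
  }
  invisible(x)
}
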