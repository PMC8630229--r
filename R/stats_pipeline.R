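#' Average trials per individual and treatment
#'
#' Collapses repeated trials to one arithmetic mean per individual x
#' treatment cell before inference, so the individual (not the trial) is the
#' experimental unit (pseudoreplication guard). Every individual must have at
#' least one trial in every treatment; gaps are an error.
#'
#' @param table Data frame with columns `individual_id`, `treatment`, `value`.
#' @return Data frame with one row per individual x treatment and the mean
#'   `value`.
#' @export
average_trials <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("individual_id", "treatment", "value") %in% names(table)))
  if (any(!is.finite(table$value))) stop("non-finite metric values", call. = FALSE)
  agg <- stats::aggregate(value ~ individual_id + treatment, data = table, FUN = mean)
  ids <- unique(table$individual_id)
  trts <- unique(table$treatment)
  full <- expand.grid(individual_id = ids, treatment = trts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$individual_id, d$treatment, sep = "\r")
  gaps <- full[!(key(full) %in% key(agg)), , drop = FALSE]
  if (nrow(gaps) > 0L) {
    stop(sprintf("missing individual x treatment cell(s): %s",
                 paste(sprintf("%s/%s", gaps$individual_id, gaps$treatment),
                       collapse = ", ")), call. = FALSE)
  }
  agg[order(agg$treatment, agg$individual_id), , drop = FALSE]
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z-tests on mean ranks following a Kruskal-Wallis test, with the
#' standard tie correction. P-values are unadjusted by default (configurable
#' via any [stats::p.adjust()] method).
#'
#' @param value Numeric response.
#' @param group Grouping factor (or coercible).
#' @param p_adjust Adjustment method, default `"none"`.
#' @return Data frame with `comparison`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(value, group, p_adjust = "none") {
  group <- factor(group)
  stopifnot(length(value) == length(group), nlevels(group) >= 2L)
  N <- length(value)
  r <- rank(value)
  ties <- table(value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(group)
  rbar <- tapply(r, group, mean)
  n <- tapply(r, group, length)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    if (se <= 0) return(0)  # all observations tied
    (rbar[[i]] - rbar[[j]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = apply(pairs, 2, paste, collapse = " - "),
             z = as.numeric(z), p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

shapiro_by_group <- function(value, group) {
  vapply(split(value, group), function(v) {
    if (length(unique(v)) < 3L) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, 1)
}

levene_p <- function(value, group) {
  df <- data.frame(value = value, group = factor(group))
  tab <- car::leveneTest(value ~ group, data = df)
  tab[["Pr(>F)"]][1]
}

fit_rm_anova <- function(df) {
  # random-intercept model for individual; LRT against the fixed-effects-only
  # model decides whether the individual term is retained
  ctrl <- nlme::lmeControl(opt = "optim", returnObject = TRUE)
  lme_fit <- tryCatch(
    nlme::lme(value ~ treatment, random = ~ 1 | individual_id,
              data = df, method = "REML", control = ctrl),
    error = function(e) NULL)
  gls_fit <- tryCatch(nlme::gls(value ~ treatment, data = df, method = "REML"),
                      error = function(e) NULL)
  ind_p <- NA_real_
  if (!is.null(lme_fit) && !is.null(gls_fit)) {
    cmp <- tryCatch(stats::anova(lme_fit, gls_fit), error = function(e) NULL)
    if (!is.null(cmp)) ind_p <- cmp[["p-value"]][2]
  }
  retain <- !is.na(ind_p) && ind_p < 0.05 && !is.null(lme_fit)
  if (retain) {
    at <- stats::anova(lme_fit)
    omnibus <- at["treatment", "p-value"]
    model <- lme_fit
    test <- "RM-ANOVA"
  } else {
    model <- stats::lm(value ~ treatment, data = df)
    omnibus <- stats::anova(model)["treatment", "Pr(>F)"]
    test <- "ANOVA"
  }
  list(model = model, omnibus_p = omnibus, individual_p = ind_p,
       individual_retained = retain, test = test)
}

anova_posthoc <- function(model) {
  # the single-step adjustment integrates a multivariate t numerically with
  # Monte-Carlo error; pin the RNG locally so identical inputs give
  # identical reports, restoring the caller's RNG state afterwards
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(20211129L)
  gl <- multcomp::glht(model, linfct = multcomp::mcp(treatment = "Tukey"))
  sm <- summary(gl)  # single-step multiplicity adjustment
  data.frame(comparison = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             p = as.numeric(sm$test$pvalues),
             stringsAsFactors = FALSE)
}

#' Compare landing-surface inclines for one metric
#'
#' Implements the statistical decision tree used for the incline
#' comparisons. Trials are first averaged per individual x treatment
#' ([average_trials()]). Normality is checked per group with Shapiro-Wilk
#' and variance homogeneity across groups with Levene's test, both at 0.05.
#' If both pass, a repeated-measures ANOVA is fitted (random intercept per
#' individual via `nlme::lme`); the individual term is dropped when its
#' likelihood-ratio p-value is not significant. If an assumption fails, the
#' metric is transformed (an optional constant offset, used to clear
#' negative angles, then decadic logarithm) and the gates re-checked; if the
#' assumptions still fail (or the transform is unavailable because of
#' non-positive values), a Kruskal-Wallis test is used, with Dunn's
#' post-hoc pairwise tests when the omnibus test is significant. Post-hoc
#' results are only ever computed after a significant omnibus test.
#'
#' @param table Data frame with `individual_id`, `treatment`, `value`
#'   (one row per trial).
#' @param metric Name of the metric (bookkeeping only).
#' @param offset Constant added before the log transform (default 0; use 3
#'   for signed angle metrics in degrees).
#' @param alpha Significance level for all gates and tests (default 0.05).
#' @return A `test_report`: list with `metric`, `transform`, `shapiro_p`,
#'   `levene_p` (pre- and post-transform), `test` (`"RM-ANOVA"`, `"ANOVA"`
#'   or `"Kruskal-Wallis"`), `omnibus_p`, `individual_p`,
#'   `individual_retained`, `posthoc` (data frame or `NULL`),
#'   `group_means` (mean and standard error per treatment).
#' @export
compare_inclines <- function(table, metric = "metric", offset = 0, alpha = 0.05) {
  avg <- average_trials(table)
  if (length(unique(avg$individual_id)) < 2L) {
    stop("at least 2 individuals are required for a repeated-measures comparison",
         call. = FALSE)
  }
  avg$treatment <- factor(avg$treatment)
  if (nlevels(avg$treatment) < 2L) stop("need at least 2 treatments", call. = FALSE)

  gm <- do.call(rbind, lapply(split(avg$value, avg$treatment), function(v) {
    data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  }))
  gm$treatment <- rownames(gm)

  gate <- function(v) {
    sp <- shapiro_by_group(v, avg$treatment)
    lp <- levene_p(v, avg$treatment)
    list(shapiro = sp, levene = lp, pass = all(sp >= alpha) && lp >= alpha)
  }
  g1 <- gate(avg$value)
  transform <- "none"
  work <- avg
  g2 <- NULL
  if (!g1$pass) {
    shifted <- avg$value + offset
    if (all(shifted > 0)) {
      work$value <- log10(shifted)
      transform <- if (offset != 0) sprintf("+%g then log10", offset) else "log10"
      g2 <- gate(work$value)
    }
  }
  use_parametric <- g1$pass || (!is.null(g2) && g2$pass)
  if (!use_parametric) {
    work <- avg
    transform <- "none"
  }

  if (use_parametric) {
    fit <- fit_rm_anova(work)
    posthoc <- if (is.finite(fit$omnibus_p) && fit$omnibus_p < alpha) {
      anova_posthoc(fit$model)
    } else NULL
    report <- list(test = fit$test, omnibus_p = fit$omnibus_p,
                   individual_p = fit$individual_p,
                   individual_retained = fit$individual_retained,
                   posthoc = posthoc)
  } else {
    kw <- stats::kruskal.test(work$value, work$treatment)
    ind_p <- tryCatch(
      stats::kruskal.test(work$value, factor(work$individual_id))$p.value,
      error = function(e) NA_real_)
    posthoc <- if (kw$p.value < alpha) {
      dunn_test(work$value, work$treatment)
    } else NULL
    report <- list(test = "Kruskal-Wallis", omnibus_p = kw$p.value,
                   individual_p = ind_p, individual_retained = FALSE,
                   posthoc = posthoc)
  }
  structure(c(list(metric = metric, transform = transform,
                   shapiro_p = g1$shapiro, levene_p = g1$levene,
                   shapiro_p_transformed = if (!is.null(g2)) g2$shapiro else NULL,
                   levene_p_transformed = if (!is.null(g2)) g2$levene else NULL,
                   group_means = gm, alpha = alpha),
              report),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report '%s': %s%s, omnibus p = %.4g>\n",
              x$metric, x$test,
              if (x$transform != "none") sprintf(" on %s", x$transform) else "",
              x$omnibus_p))
  gm <- x$group_means
  for (i in seq_len(nrow(gm))) {
    cat(sprintf("  %s: %.4g +/- %.4g (SE)\n", gm$treatment[i], gm$mean[i], gm$se[i]))
  }
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    ph <- x$posthoc
    for (i in seq_len(nrow(ph))) {
      cat(sprintf("    %s: p = %.4g\n", ph$comparison[i], ph$p[i]))
    }
  }
  invisible(x)
}

#' Ordinary least-squares regression of one metric on another
#'
#' @param y Numeric response.
#' @param x Numeric predictor (at least 3 points, non-zero variance).
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope p-value).
#' @export
regress <- function(y, x) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("regression requires at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4])
}

#' Analyze a full study
#'
#' Runs [analyze_trial()] on every trial, then [compare_inclines()] on each
#' landing metric. The landing-angle metric uses the +3 degree offset before
#' its log transform (angles can be slightly negative); all other metrics
#' use no offset.
#'
#' @param trials List of [trial_recording()] objects.
#' @param geometries Named list of [platform_geometry()] keyed by treatment
#'   (names are the numeric treatment values as strings).
#' @param config An [analysis_config()].
#' @param metrics Character vector of summary columns to compare.
#' @return List with `summaries` (data frame, one row per trial) and
#'   `reports` (named list of `test_report`s).
#' @export
analyze_study <- function(trials, geometries, config = analysis_config(),
                          metrics = c("landing_duration_s", "landing_angle_deg",
                                      "max_curvature", "peak_deceleration_ms2",
                                      "landing_speed_ms", "impact_force_n")) {
  summaries <- do.call(rbind, lapply(trials, function(tr) {
    geom <- geometries[[as.character(tr$treatment)]]
    if (is.null(geom)) stop(sprintf("no geometry supplied for treatment %s",
                                    tr$treatment), call. = FALSE)
    analyze_trial(tr, geom, config)
  }))
  reports <- lapply(metrics, function(mt) {
    tab <- data.frame(individual_id = summaries$individual_id,
                      treatment = summaries$treatment,
                      value = summaries[[mt]])
    tab <- tab[is.finite(tab$value), , drop = FALSE]
    offset <- if (mt == "landing_angle_deg") 3 else 0
    compare_inclines(tab, metric = mt, offset = offset)
  })
  names(reports) <- metrics
  list(summaries = summaries, reports = reports)
}
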