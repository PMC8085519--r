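#' Transform and standardize process metrics for regression
#'
#' Process metrics are right-skewed, so all but LDLJ are natural-log
#' transformed before standardization. Signs are arranged so that for
#' every predictor larger = better (smoother / faster) performance:
#' T, PL and Pks get a negative modifier after the log; SPARC (which is
#' negative) is transformed as `-log(-SPARC)`, monotone in SPARC with
#' larger = smoother; LDLJ passes through untransformed. `Pks` may be 0,
#' so its log uses an offset, `log(Pks + pks_offset)`. Each column is
#' then centred and scaled to unit variance within each window span so
#' slopes are comparable across metrics.
#'
#' @param metrics data.frame with columns `window_span`, `T_s`, `PL_mm`,
#'   `Pks`, `LDLJ`, `SPARC` (rows with any `NA` metric are dropped).
#' @param sparc_log apply the `-log(-SPARC)` transform (default TRUE);
#'   FALSE z-scores raw SPARC.
#' @param pks_offset offset for the peak-count log (default 1).
#' @return data.frame with the identifying columns of `metrics` plus
#'   standardized predictor columns `T`, `PL`, `Pks`, `LDLJ`, `SPARC`.
#' @export
transform_standardize <- function(metrics, sparc_log = TRUE, pks_offset = 1) {
  need <- c("window_span", "T_s", "PL_mm", "Pks", "LDLJ", "SPARC")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    .stopf("metrics table is missing column(s): %s",
           paste(miss, collapse = ", "), class = "schema_error")
  if (nrow(metrics) == 0L)
    .stopf("metrics table is empty", class = "validation_error")
  ok <- stats::complete.cases(metrics[, c("T_s", "PL_mm", "Pks", "LDLJ", "SPARC")])
  metrics <- metrics[ok, , drop = FALSE]
  if (any(metrics$T_s <= 0) || any(metrics$PL_mm <= 0))
    .stopf("T and PL must be positive for the log transform",
           class = "validation_error")
  raw <- data.frame(
    T = -log(metrics$T_s),
    PL = -log(metrics$PL_mm),
    Pks = -log(metrics$Pks + pks_offset),
    LDLJ = metrics$LDLJ,
    SPARC = if (sparc_log) -log(-metrics$SPARC) else metrics$SPARC)
  out <- metrics[, setdiff(names(metrics),
                           c("T_s", "PL_mm", "Pks", "LDLJ", "SPARC")),
                 drop = FALSE]
  for (nm in names(raw)) out[[nm]] <- raw[[nm]]
  for (span in unique(out$window_span)) {
    sel <- out$window_span == span
    for (nm in names(raw)) {
      v <- out[[nm]][sel]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0)
        .stopf("predictor '%s' has zero variance at window span %s", nm,
               span, class = "validation_error")
      out[[nm]][sel] <- (v - mean(v)) / s
    }
  }
  out
}

# one simple OLS of indicator on a standardized predictor
.fit_one <- function(y, x) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  list(beta = co["x", "Estimate"], se = co["x", "Std. Error"],
       r_squared = sm$r.squared, r = stats::cor(x, y),
       sigma2 = sm$sigma^2, n = length(y))
}

#' Fit the indicator-on-metric regression grid
#'
#' For one window span, regresses each skill indicator on each
#' standardized process metric by ordinary least squares, recording the
#' slope, its standard error, R-squared, the Pearson correlation, the
#' residual variance and n. With a standardized predictor the slope
#' equals `r * sd(indicator)` and `R^2 = r^2`.
#'
#' @param indicators data.frame of indicator columns (e.g. `FR`, `GRS`,
#'   `Exp`), one row per trial.
#' @param predictors data.frame of standardized predictor columns
#'   (from [transform_standardize()]), aligned row-wise with
#'   `indicators`.
#' @param span the window span label to record.
#' @return data.frame with one row per (indicator, metric).
#' @export
fit_indicator_regressions <- function(indicators, predictors, span) {
  if (nrow(indicators) != nrow(predictors))
    .stopf("indicators (%d rows) and predictors (%d rows) are not aligned",
           nrow(indicators), nrow(predictors), class = "validation_error")
  if (nrow(indicators) < 3)
    .stopf("need at least 3 observations, got %d", nrow(indicators),
           class = "validation_error")
  grid <- expand.grid(indicator = names(indicators),
                      metric = names(predictors),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- .fit_one(indicators[[grid$indicator[i]]],
                  predictors[[grid$metric[i]]])
    data.frame(indicator = grid$indicator[i], metric = grid$metric[i],
               window_span = span, beta = f$beta, se = f$se, r = f$r,
               r_squared = f$r_squared, sigma2 = f$sigma2, n = f$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the full skill-association model
#'
#' The package's central fit: for every Savitzky-Golay window span in
#' the metrics table, each skill indicator (per-trial flash ratio FR,
#' and the participant-level GRS sum and years of experience broadcast
#' to trials) is regressed on each of the five standardized process
#' metrics. The returned object carries the complete slope/R-squared
#' grid and supports `print()`, `summary()`, `coef()`, `plot()` and
#' [tukey_pairwise()].
#'
#' @param metrics metrics table from [compute_metrics()] (or read back
#'   via [read_metrics_table()]); must contain an `FR` column.
#' @param participants participant-level data.frame with
#'   `participant_id`, `years_experience` and `grs_*` subscore columns
#'   (e.g. `cohort$participants`).
#' @param indicators which indicators to fit (default
#'   `c("FR", "GRS", "Exp")`).
#' @param grs_subscores subscore names summed into GRS; the default
#'   ignores palpation skill, which is unrelated to needle motion.
#' @param broadcast if TRUE (default) participant-level indicators are
#'   broadcast to trials and regressions pool all trials (the
#'   within-participant dependence is accepted, not corrected); if
#'   FALSE, predictors are averaged per participant and regressions run
#'   on participant-level points.
#' @param sparc_log,pks_offset passed to [transform_standardize()].
#' @return An object of class `"skill_assoc"` with elements `results`
#'   (the regression grid), `data` (per-span standardized analysis
#'   tables), `spans`, `indicators`, `call`.
#' @examples
#' \donttest{
#' co <- simulate_cohort(cohort_spec(n_participants = 8), seed = 42)
#' m <- compute_metrics(co, spans = c(5, 25))
#' fit <- skill_assoc(m, co$participants)
#' summary(fit)
#' }
#' @export
skill_assoc <- function(metrics, participants,
                        indicators = c("FR", "GRS", "Exp"),
                        grs_subscores = c("needle_holding",
                                          "needle_movement",
                                          "flashback_quality",
                                          "overall_quality"),
                        broadcast = TRUE, sparc_log = TRUE,
                        pks_offset = 1) {
  if (!"FR" %in% names(metrics) && "FR" %in% indicators)
    .stopf("metrics table has no FR column", class = "schema_error")
  std <- transform_standardize(metrics, sparc_log = sparc_log,
                               pks_offset = pks_offset)
  # attach participant-level indicators
  if (any(c("GRS", "Exp") %in% indicators)) {
    gcols <- paste0("grs_", grs_subscores)
    miss <- setdiff(c("participant_id", "years_experience", gcols),
                    names(participants))
    if (length(miss))
      .stopf("participants table is missing column(s): %s",
             paste(miss, collapse = ", "), class = "schema_error")
    ptab <- data.frame(participant_id = participants$participant_id,
                       GRS = rowSums(participants[, gcols, drop = FALSE]),
                       Exp = participants$years_experience)
    std <- merge(std, ptab, by = "participant_id", sort = FALSE)
  }
  metric_names <- c("T", "PL", "Pks", "LDLJ", "SPARC")
  spans <- sort(unique(std$window_span))
  data_by_span <- list()
  results <- list()
  for (span in spans) {
    d <- std[std$window_span == span, , drop = FALSE]
    if (!broadcast) {
      agg <- stats::aggregate(d[, c(metric_names, intersect(indicators, names(d)))],
                              by = list(participant_id = d$participant_id),
                              FUN = mean)
      # re-standardize predictors after aggregation
      for (nm in metric_names) agg[[nm]] <- as.numeric(scale(agg[[nm]]))
      d <- agg
    }
    ind <- d[, indicators, drop = FALSE]
    pred <- d[, metric_names, drop = FALSE]
    results[[as.character(span)]] <-
      fit_indicator_regressions(ind, pred, span)
    data_by_span[[as.character(span)]] <- d
  }
  structure(list(results = do.call(rbind, c(results, make.row.names = FALSE)),
                 data = data_by_span, spans = spans,
                 indicators = indicators, metrics = metric_names,
                 broadcast = broadcast, call = match.call()),
            class = "skill_assoc")
}

#' @export
print.skill_assoc <- function(x, ...) {
  cat("Skill-association fit (standardized simple regressions)\n")
  cat(sprintf("  indicators: %s\n", paste(x$indicators, collapse = ", ")))
  cat(sprintf("  process metrics: %s\n", paste(x$metrics, collapse = ", ")))
  cat(sprintf("  window spans: %s\n", paste(x$spans, collapse = ", ")))
  cat(sprintf("  observations per regression: %s\n",
              paste(unique(x$results$n), collapse = ", ")))
  cat("\nMean R^2 by indicator (across metrics and spans):\n")
  m <- tapply(x$results$r_squared, x$results$indicator, mean)
  print(round(m[order(-m)], 4))
  invisible(x)
}

#' Summarize a skill-association fit
#'
#' Emits the numeric content behind the study's summary displays: the
#' R-squared-by-span table per indicator with its mean, and the
#' absolute-correlation grid (metric x indicator x span).
#'
#' @param object a `"skill_assoc"` fit.
#' @param ... unused.
#' @return list of class `"summary.skill_assoc"` with `r_squared`
#'   (indicator x span matrix), `mean_r_squared`, `correlations`
#'   (long data.frame of |r|).
#' @export
summary.skill_assoc <- function(object, ...) {
  res <- object$results
  rs <- tapply(res$r_squared, list(res$indicator, res$window_span), mean)
  corr <- res[, c("indicator", "metric", "window_span", "r")]
  corr$abs_r <- abs(corr$r)
  structure(list(r_squared = rs,
                 mean_r_squared = rowMeans(rs),
                 correlations = corr,
                 n = unique(res$n)),
            class = "summary.skill_assoc")
}

#' @export
print.summary.skill_assoc <- function(x, ...) {
  cat("R^2 by window span (mean over process metrics):\n")
  print(round(x$r_squared, 4))
  cat("\nMean R^2 per indicator:\n")
  print(round(sort(x$mean_r_squared, decreasing = TRUE), 4))
  invisible(x)
}

#' @export
coef.skill_assoc <- function(object, ...) {
  res <- object$results
  out <- stats::reshape(res[, c("indicator", "metric", "window_span", "beta")],
                        direction = "wide", idvar = c("indicator", "window_span"),
                        timevar = "metric")
  names(out) <- sub("^beta\\.", "", names(out))
  out
}

#' @export
plot.skill_assoc <- function(x, ...) {
  s <- summary(x)
  rs <- s$r_squared
  graphics::matplot(as.numeric(colnames(rs)), t(rs), type = "b", pch = 16,
                    lty = 1, xlab = "SG window span (samples)",
                    ylab = expression(R^2),
                    main = "Model fit by smoothing window span", ...)
  graphics::legend("topleft", legend = rownames(rs), col = seq_len(nrow(rs)),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Tukey-adjusted pairwise slope comparisons
#'
#' Compares standardized regression slopes between groups with Tukey's
#' studentized-range adjustment at level `alpha`, in the study's two
#' analysis families: `by = "metric"` compares the five process metrics
#' within one indicator and window span; `by = "span"` compares the
#' window spans within one indicator and one smoothness metric. The
#' confidence interval for a pair (i, j) is
#' `(beta_i - beta_j) +/- q_{alpha; r, n-r} * SE`, where `r` is the
#' number of groups and `n` the (common) number of observations per
#' regression.
#'
#' Two readings of the error term are provided. `method = "pooled"`
#' (default) pools the residual variance across the r compared
#' regressions, giving `SE = sqrt(mean(se_i^2))` for the balanced
#' standardized design; `method = "per_pair"` is a Tukey-adjusted
#' slope-difference t-test with
#' `SE = sqrt((se_i^2 + se_j^2) / 2)`.
#'
#' @param fit a `"skill_assoc"`.
#' @param by `"metric"` or `"span"`.
#' @param indicator indicator name (e.g. `"FR"`).
#' @param span window span (required for `by = "metric"`).
#' @param metric smoothness metric name (required for `by = "span"`).
#' @param alpha significance level (default 0.05).
#' @param method error-term reading, `"pooled"` or `"per_pair"`.
#' @return data.frame of class `"tukey_skill"`: one row per unordered
#'   pair with `estimate`, `lower`, `upper`, `significant`; attributes
#'   `q`, `df`, `alpha`.
#' @export
tukey_pairwise <- function(fit, by = c("metric", "span"), indicator,
                           span = NULL, metric = NULL, alpha = 0.05,
                           method = c("pooled", "per_pair")) {
  stopifnot(inherits(fit, "skill_assoc"))
  by <- match.arg(by)
  method <- match.arg(method)
  res <- fit$results
  if (by == "metric") {
    if (is.null(span)) .stopf("span is required for by = 'metric'")
    g <- res[res$indicator == indicator & res$window_span == span, ]
    labels <- g$metric
  } else {
    if (is.null(metric)) .stopf("metric is required for by = 'span'")
    g <- res[res$indicator == indicator & res$metric == metric, ]
    labels <- as.character(g$window_span)
  }
  r <- nrow(g)
  if (r < 2)
    .stopf("need at least 2 groups to compare, got %d", r,
           class = "validation_error")
  if (length(unique(g$n)) != 1L)
    .stopf("groups have unequal n (%s); the design must be balanced",
           paste(unique(g$n), collapse = ", "), class = "validation_error")
  n <- g$n[1]
  if (n - r < 1)
    .stopf("only %d observations for %d groups; no residual degrees of freedom for the studentized range",
           n, r, class = "validation_error")
  q <- stats::qtukey(1 - alpha, nmeans = r, df = n - r)
  pairs <- utils::combn(r, 2)
  se_pool <- sqrt(mean(g$se^2))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    est <- g$beta[i] - g$beta[j]
    se <- if (method == "pooled") se_pool else
      sqrt((g$se[i]^2 + g$se[j]^2) / 2)
    hw <- q * se
    data.frame(group_i = labels[i], group_j = labels[j],
               estimate = est, lower = est - hw, upper = est + hw,
               significant = (est - hw > 0) | (est + hw < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("tukey_skill", "data.frame"),
            q = q, df = n - r, alpha = alpha, method = method,
            indicator = indicator, by = by)
}

#' @export
print.tukey_skill <- function(x, ...) {
  cat(sprintf("Tukey pairwise slope comparisons (%s, alpha = %g, q = %.3f, df = %d)\n",
              attr(x, "method"), attr(x, "alpha"), attr(x, "q"), attr(x, "df")))
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 4)
  df$lower <- round(df$lower, 4)
  df$upper <- round(df$upper, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write the report tables for a skill-association fit
#'
#' Emits tidy CSVs (R-squared by span + means, correlation grid, both
#' Tukey comparison families) and a JSON summary. Output is a pure
#' function of the fit.
#'
#' @param fit a `"skill_assoc"`.
#' @param dir output directory (created if needed).
#' @param alpha significance level for the comparisons.
#' @param method error-term reading for [tukey_pairwise()].
#' @return Invisibly, the directory path.
#' @export
write_report <- function(fit, dir, alpha = 0.05, method = "pooled") {
  stopifnot(inherits(fit, "skill_assoc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summary(fit)
  rs <- as.data.frame(s$r_squared)
  rs <- cbind(indicator = rownames(rs), rs, mean = s$mean_r_squared)
  utils::write.csv(rs, file.path(dir, "r_squared_by_span.csv"),
                   row.names = FALSE)
  utils::write.csv(s$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  tm <- list()
  for (ind in fit$indicators)
    for (span in fit$spans) {
      tk <- tukey_pairwise(fit, "metric", ind, span = span, alpha = alpha,
                           method = method)
      tm[[length(tm) + 1L]] <- cbind(indicator = ind, window_span = span,
                                     as.data.frame(tk))
    }
  utils::write.csv(do.call(rbind, tm), file.path(dir, "tukey_metrics.csv"),
                   row.names = FALSE)
  ts_ <- list()
  if (length(fit$spans) >= 2)
    for (ind in fit$indicators)
      for (met in intersect(c("LDLJ", "SPARC"), fit$metrics)) {
        tk <- tukey_pairwise(fit, "span", ind, metric = met, alpha = alpha,
                             method = method)
        ts_[[length(ts_) + 1L]] <- cbind(indicator = ind, metric = met,
                                         as.data.frame(tk))
      }
  if (length(ts_))
    utils::write.csv(do.call(rbind, ts_), file.path(dir, "tukey_spans.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(mean_r_squared = as.list(s$mean_r_squared),
         n = s$n, alpha = alpha, method = method,
         spans = fit$spans, indicators = fit$indicators),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
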