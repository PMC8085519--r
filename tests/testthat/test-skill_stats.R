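# small synthetic metrics table with known structure
fake_metrics <- function(n = 60, spans = c(5, 25), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(spans, function(sp) {
    data.frame(participant_id = sprintf("P%02d", rep(1:(n / 4), each = 4)),
               trial_id = sprintf("t%03d", 1:n),
               window_span = sp,
               T_s = exp(rnorm(n, 1.5, 0.4)),
               PL_mm = exp(rnorm(n, 3, 0.5)),
               Pks = rpois(n, 4),
               LDLJ = rnorm(n, -9, 1.5),
               SPARC = -exp(rnorm(n, 0.7, 0.3)),
               FR = runif(n),
               stringsAsFactors = FALSE)
  }))
}

test_that("transform/standardize yields unit-scale smoothness-positive predictors", {
  m <- fake_metrics()
  std <- transform_standardize(m)
  for (sp in unique(std$window_span)) {
    d <- std[std$window_span == sp, ]
    for (nm in c("T", "PL", "Pks", "LDLJ", "SPARC")) {
      expect_lt(abs(mean(d[[nm]])), 1e-10)
      expect_lt(abs(sd(d[[nm]]) - 1), 1e-10)
    }
    # LDLJ is z-scored with no log
    sel <- m$window_span == sp
    expect_equal(d$LDLJ, as.numeric(scale(m$LDLJ[sel])), tolerance = 1e-12)
    # negative modifier: larger T must map to smaller predictor
    expect_lt(cor(d$T, m$T_s[sel]), 0)
    # SPARC transform is monotone increasing in SPARC
    expect_identical(cor(d$SPARC, m$SPARC[sel], method = "spearman"), 1)
  }
  # scale invariance: doubling PL changes nothing after log + z-score
  m2 <- m; m2$PL_mm <- 2 * m2$PL_mm
  expect_equal(transform_standardize(m2)$PL, std$PL, tolerance = 1e-12)
  # Pks = 0 rows survive via the log offset
  m3 <- m; m3$Pks[1] <- 0
  expect_true(all(is.finite(transform_standardize(m3)$Pks)))
  # zero-variance column is named in the error
  m4 <- m; m4$LDLJ <- -7
  expect_error(transform_standardize(m4), regexp = "LDLJ",
               class = "validation_error")
  expect_error(transform_standardize(m[0, ]), class = "validation_error")
})

test_that("OLS results agree with the closed-form simple-regression oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    x <- as.numeric(scale(rnorm(n)))
    y <- 0.8 * x + rnorm(n)
    got <- fit_indicator_regressions(data.frame(Y = y), data.frame(X = x),
                                     span = 5)
    sxx <- sum((x - mean(x))^2)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - beta * (x - mean(x))
    se <- sqrt(sum(res^2) / (n - 2) / sxx)
    r <- cor(x, y)
    expect_lt(abs(got$beta - beta), 1e-10)
    expect_lt(abs(got$se - se), 1e-10)
    expect_lt(abs(got$r_squared - r^2), 1e-10)
    # with a standardized predictor, slope = r * sd(y)
    expect_lt(abs(got$beta - r * sd(y)), 1e-10)
  }
  expect_error(fit_indicator_regressions(data.frame(Y = 1:2),
                                         data.frame(X = 1:2), 5),
               class = "validation_error")
})

test_that("a perfectly linear indicator is recovered exactly", {
  x <- as.numeric(scale(rnorm(30)))
  got <- suppressWarnings(   # summary.lm flags the perfect fit
    fit_indicator_regressions(data.frame(Y = 2.5 * x + 1),
                              data.frame(X = x), span = 25))
  expect_equal(got$r_squared, 1, tolerance = 1e-12)
  expect_lt(got$se, 1e-8)
  expect_equal(got$beta, 2.5, tolerance = 1e-10)
})

test_that("independent indicators produce null-level fits", {
  set.seed(7)
  n <- 779
  r2 <- replicate(200, {
    x <- as.numeric(scale(rnorm(n)))
    y <- rnorm(n)
    f <- fit_indicator_regressions(data.frame(Y = y), data.frame(X = x), 5)
    f$r_squared
  })
  # E[R^2] = 1/(n-1) under the null
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 1 / (n - 1))
  expect_lt(quantile(sqrt(r2), 0.95), 0.1)
})

test_that("skill_assoc fits the full grid and its methods are consistent", {
  m <- fake_metrics(n = 80)
  participants <- data.frame(
    participant_id = sprintf("P%02d", 1:20),
    years_experience = sample(0:30, 20, replace = TRUE),
    grs_palpation = sample(1:7, 20, TRUE),
    grs_needle_holding = sample(1:7, 20, TRUE),
    grs_needle_movement = sample(1:7, 20, TRUE),
    grs_flashback_quality = sample(1:7, 20, TRUE),
    grs_overall_quality = sample(1:7, 20, TRUE))
  fit <- skill_assoc(m, participants)
  expect_s3_class(fit, "skill_assoc")
  expect_identical(nrow(fit$results), 3L * 5L * 2L)  # ind x metric x span
  expect_true(all(abs(fit$results$r_squared - fit$results$r^2) < 1e-10))

  s <- summary(fit)
  expect_identical(dim(s$r_squared), c(3L, 2L))
  expect_equal(unname(s$mean_r_squared), unname(rowMeans(s$r_squared)),
               tolerance = 1e-12)
  cf <- coef(fit)
  expect_identical(nrow(cf), 6L)   # 3 indicators x 2 spans
  expect_true(all(c("T", "PL", "Pks", "LDLJ", "SPARC") %in% names(cf)))

  # participant-level alternative runs on 20 points
  fitp <- skill_assoc(m, participants, broadcast = FALSE)
  expect_identical(unique(fitp$results$n), 20L)
  # missing indicator column is named
  expect_error(skill_assoc(m, participants[, -2]),
               regexp = "years_experience", class = "schema_error")
})

test_that("Tukey comparisons cover all pairs and respect the identity pair", {
  m <- fake_metrics(n = 80)
  participants <- data.frame(
    participant_id = sprintf("P%02d", 1:20),
    years_experience = 1:20,
    grs_palpation = 4, grs_needle_holding = 4, grs_needle_movement = 4,
    grs_flashback_quality = 4, grs_overall_quality = 4)
  fit <- skill_assoc(m, participants, indicators = c("FR", "Exp"))
  tk <- tukey_pairwise(fit, "metric", "FR", span = 5)
  expect_identical(nrow(tk), 10L)           # 5 choose 2
  # CI symmetric about the estimate; significance <=> 0 outside CI
  expect_equal(tk$upper - tk$estimate, tk$estimate - tk$lower,
               tolerance = 1e-12)
  expect_identical(tk$significant, tk$lower > 0 | tk$upper < 0)

  # spans family
  tks <- tukey_pairwise(fit, "span", "FR", metric = "LDLJ")
  expect_identical(nrow(tks), 1L)           # 2 spans -> 1 pair

  # duplicated identical group: estimate 0, not significant
  fit2 <- fit
  g <- fit2$results[fit2$results$indicator == "FR" &
                      fit2$results$window_span == 5 &
                      fit2$results$metric %in% c("T", "PL"), ]
  fit2$results[fit2$results$indicator == "FR" &
                 fit2$results$window_span == 5 &
                 fit2$results$metric == "PL",
               c("beta", "se")] <- g[g$metric == "T", c("beta", "se")]
  tk2 <- tukey_pairwise(fit2, "metric", "FR", span = 5)
  row <- tk2[tk2$group_i == "T" & tk2$group_j == "PL", ]
  expect_identical(row$estimate, 0)
  expect_false(row$significant)

  # mismatched n across groups is rejected
  fit3 <- fit
  fit3$results$n[1] <- fit3$results$n[1] - 1L
  expect_error(tukey_pairwise(fit3, "metric", "FR", span = 5),
               class = "validation_error")
})

test_that("Tukey CI width shrinks as 1/sqrt(n)", {
  width_at <- function(n, seed) {
    set.seed(seed)
    x <- as.numeric(scale(rnorm(n)))
    res <- do.call(rbind, lapply(c("T", "PL", "Pks", "LDLJ", "SPARC"),
      function(met) {
        y <- 0.3 * x + rnorm(n)
        fit_indicator_regressions(data.frame(FR = y),
                                  stats::setNames(data.frame(x), met), 5)
      }))
    fit <- structure(list(results = res), class = "skill_assoc")
    tk <- tukey_pairwise(fit, "metric", "FR", span = 5)
    mean(tk$upper - tk$lower)
  }
  w <- vapply(c(100, 400, 1600), width_at, numeric(1), seed = 13)
  expect_equal(w[1] / w[2], 2, tolerance = 0.35)
  expect_equal(w[2] / w[3], 2, tolerance = 0.35)
  expect_true(all(diff(w) < 0))
})
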