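#' Quarter-interval peak pairs for force–kinematics regression
#'
#' Splits every QC-passing interval into `n_sub` equal subintervals
#' (default: four 256-sample blocks) and tabulates peak force and peak
#' kinematic amplitudes per block. Subdividing improves the time resolution
#' of the force–kinematics pairing. Because parent intervals overlap 50%,
#' interior blocks would appear twice; duplicates (same start sample) are
#' dropped so each data point enters the regression once.
#'
#' @param analysis A `buzz_analysis` from [analyze_recording()].
#' @param n_sub Number of subintervals per interval; must divide the
#'   interval length.
#' @return Data frame with one row per unique subinterval: `bee_id`,
#'   `start_sample`, `peak_fx_mn`, `peak_fy_mn`, `peak_fz_mn`,
#'   `peak_displacement_um`, `peak_velocity_mm_s`, `peak_acceleration_m_s2`,
#'   `dominant_frequency_hz` (inherited from the parent interval).
#' @export
subdivide_for_regression <- function(analysis, n_sub = 4) {
  stopifnot(inherits(analysis, "buzz_analysis"))
  len <- analysis$interval_length
  if (len %% n_sub != 0) {
    stop("parameter error: n_sub must divide the interval length",
         call. = FALSE)
  }
  sub_len <- len %/% n_sub
  ch <- analysis$channels
  keep <- analysis$metrics[analysis$metrics$qc_pass, ]
  if (!nrow(keep)) {
    return(data.frame(bee_id = character(0), start_sample = integer(0),
                      peak_fx_mn = numeric(0), peak_fy_mn = numeric(0),
                      peak_fz_mn = numeric(0),
                      peak_displacement_um = numeric(0),
                      peak_velocity_mm_s = numeric(0),
                      peak_acceleration_m_s2 = numeric(0),
                      dominant_frequency_hz = numeric(0)))
  }
  rows <- list()
  for (i in seq_len(nrow(keep))) {
    for (j in seq_len(n_sub) - 1L) {
      s0 <- keep$start_sample[i] + j * sub_len
      idx <- (s0 + 1L):(s0 + sub_len)
      rows[[length(rows) + 1L]] <- data.frame(
        bee_id = keep$bee_id[i],
        start_sample = s0,
        peak_fx_mn = max(abs(ch$fx[idx])),
        peak_fy_mn = max(abs(ch$fy[idx])),
        peak_fz_mn = max(abs(ch$fz[idx])),
        peak_displacement_um = max(abs(ch$displacement_um[idx])),
        peak_velocity_mm_s = max(abs(ch$v[idx])),
        peak_acceleration_m_s2 = max(abs(ch$acceleration_m_s2[idx])),
        dominant_frequency_hz = keep$dominant_frequency_hz[i]
      )
    }
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out$start_sample), ]
}

predictor_columns <- c(
  frequency = "dominant_frequency_hz",
  displacement = "peak_displacement_um",
  velocity = "peak_velocity_mm_s",
  acceleration = "peak_acceleration_m_s2"
)

#' Linear model relating peak force to a thorax kinematic amplitude
#'
#' Ordinary least squares of peak x-force on one kinematic predictor, per
#' bee or pooled over all bees ("total"). Reports slope, intercept,
#' Pearson's correlation coefficient and 95% confidence intervals from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param pairs Data frame from [subdivide_for_regression()] (possibly
#'   rbind-ed over bees).
#' @param predictor One of `"frequency"`, `"displacement"`, `"velocity"`,
#'   `"acceleration"`.
#' @param scope A `bee_id` to fit one individual, or `"total"` to pool all
#'   points.
#' @param response Response column, default `"peak_fx_mn"`.
#' @return One-row data frame of class `linear_fit`: `predictor`, `scope`,
#'   `slope`, `intercept`, `pearson_r`, `slope_ci_lo`, `slope_ci_hi`,
#'   `intercept_ci_lo`, `intercept_ci_hi`, `n_points`, `p_value`.
#' @export
fit_force_kinematics <- function(pairs, predictor = "velocity",
                                 scope = "total", response = "peak_fx_mn") {
  predictor <- match.arg(predictor, names(predictor_columns))
  d <- if (identical(scope, "total")) pairs else pairs[pairs$bee_id == scope, ]
  x <- d[[predictor_columns[[predictor]]]]
  y <- d[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 finite pairs to fit", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate fit: predictor has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, level = 0.95)
  s <- summary(fit)
  structure(data.frame(
    predictor = predictor, scope = scope,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = stats::cor(x, y),
    slope_ci_lo = ci[2, 1], slope_ci_hi = ci[2, 2],
    intercept_ci_lo = ci[1, 1], intercept_ci_hi = ci[1, 2],
    n_points = length(x),
    p_value = unname(s$coefficients[2, 4])
  ), class = c("linear_fit", "data.frame"))
}

#' Fit the full table of force–kinematics models
#'
#' Convenience wrapper fitting each kinematic predictor for each bee and for
#' the pooled population (`scope = "total"`).
#'
#' @param pairs Data frame from [subdivide_for_regression()], rbind-ed over
#'   all bees.
#' @param predictors Predictors to fit.
#' @return Data frame of [fit_force_kinematics()] rows.
#' @export
fit_table <- function(pairs,
                      predictors = c("displacement", "velocity",
                                     "acceleration")) {
  scopes <- c(sort(unique(pairs$bee_id)), "total")
  rows <- list()
  for (sc in scopes) {
    for (pr in predictors) {
      f <- try(fit_force_kinematics(pairs, pr, sc), silent = TRUE)
      if (!inherits(f, "try-error")) rows[[length(rows) + 1L]] <- f
    }
  }
  do.call(rbind, rows)
}

#' Mixed-model ANOVA with bee as a random effect
#'
#' Tests whether a per-interval response depends on fixed factors (post
#' material, force direction, or their interaction) with the individual bee
#' as a random intercept. The model is fit by REML via `lmer` and fixed
#' effects are tested with Satterthwaite-denominator F-tests. Responses can
#' be natural-log transformed to meet the normality/homoscedasticity
#' assumptions: `"auto"` applies the transform when a Shapiro–Wilk test
#' rejects residual normality at p < 0.05 and the response is positive.
#'
#' @param data Data frame with a `bee_id` column, the fixed-factor columns,
#'   and the response.
#' @param fixed Character vector of fixed-effect terms (columns of `data`),
#'   e.g. `c("post")` or `c("direction", "post", "direction:post")`.
#' @param response Response column name.
#' @param log_transform `"auto"`, `"never"` or `"always"`.
#' @return Object of class `anova_result`: `terms` (data frame with `term`,
#'   `F`, `p`, `df_num`, `df_den`), `transform_applied`,
#'   `model_description`.
#' @export
mixed_anova <- function(data, fixed, response = "value",
                        log_transform = c("auto", "never", "always")) {
  log_transform <- match.arg(log_transform)
  if (length(unique(data$bee_id)) < 2) {
    stop("cannot estimate the bee random effect from a single bee",
         call. = FALSE)
  }
  if ("post" %in% fixed) {
    tab <- table(unique(data[c("bee_id", "post")])$post)
    if (length(tab) < 2 || any(tab < 2)) {
      stop("need >= 2 bees per post group to test the post effect",
           call. = FALSE)
    }
  }
  fml <- stats::as.formula(
    paste(".resp ~", paste(fixed, collapse = " + "), "+ (1 | bee_id)"))
  fit_once <- function(y) {
    d <- data
    d$.resp <- y
    suppressMessages(lmerTest::lmer(fml, data = d))
  }
  y <- data[[response]]
  m <- fit_once(y)
  applied <- FALSE
  if (log_transform == "always" ||
      (log_transform == "auto" && all(y > 0) &&
       shapiro_p(stats::resid(m)) < 0.05)) {
    if (all(y > 0)) {
      m <- fit_once(log(y))
      applied <- TRUE
    }
  }
  at <- stats::anova(m)   # lmerTest: Satterthwaite type III
  terms <- data.frame(
    term = rownames(at),
    F = at[["F value"]],
    p = at[["Pr(>F)"]],
    df_num = at[["NumDF"]],
    df_den = at[["DenDF"]],
    row.names = NULL
  )
  structure(list(
    terms = terms,
    transform_applied = applied,
    model_description = paste0(
      if (applied) "log(" else "", response, if (applied) ")" else "",
      " ~ ", paste(fixed, collapse = " + "),
      " + (1 | bee_id), REML, Satterthwaite F-tests")
  ), class = "anova_result")
}

# Shapiro-Wilk caps n at 5000; subsample deterministically above that
shapiro_p <- function(r) {
  if (length(r) > 5000) {
    r <- r[round(seq(1, length(r), length.out = 5000))]
  }
  stats::shapiro.test(r)$p.value
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>", x$model_description, "\n")
  print(x$terms, digits = 4)
  invisible(x)
}

summary_quantities <- c(
  frequency_hz = "dominant_frequency_hz",
  displacement_um = "peak_displacement_um",
  velocity_mm_s = "peak_velocity_mm_s",
  acceleration_m_s2 = "peak_acceleration_m_s2",
  fx_mn = "peak_fx_mn",
  fy_mn = "peak_fy_mn",
  fz_mn = "peak_fz_mn"
)

#' Population summary of kinematics and forces
#'
#' Mean, SD and quartiles of the seven reported quantities across the
#' population, computed from QC-passing intervals only. With
#' `aggregation = "bee_means"` (default) a mean per bee is computed first
#' and the statistics are taken across the n bee means, so individuals with
#' many intervals do not dominate; `"pooled"` computes across all intervals
#' of all bees.
#'
#' @param metrics Metrics table (rows from one or more
#'   [analyze_recording()] results).
#' @param aggregation `"bee_means"` or `"pooled"`.
#' @return Data frame of class `population_summary`: `quantity`, `mean`,
#'   `sd`, `q1`, `q3`; attribute `n_bees`.
#' @export
summarize_population <- function(metrics,
                                 aggregation = c("bee_means", "pooled")) {
  aggregation <- match.arg(aggregation)
  ok <- metrics[metrics$qc_pass, ]
  bees <- unique(metrics$bee_id)
  valid <- unique(ok$bee_id)
  dropped <- setdiff(bees, valid)
  if (length(dropped)) {
    warning("excluding bees with no QC-passing interval: ",
            paste(dropped, collapse = ", "))
  }
  if (!nrow(ok)) stop("no QC-passing intervals to summarize", call. = FALSE)
  rows <- lapply(names(summary_quantities), function(qn) {
    col <- summary_quantities[[qn]]
    x <- ok[[col]]
    if (aggregation == "bee_means") {
      x <- vapply(split(x, ok$bee_id), mean, numeric(1), na.rm = TRUE)
    }
    x <- x[is.finite(x)]
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    data.frame(quantity = qn, mean = mean(x), sd = stats::sd(x),
               q1 = qs[1], q3 = qs[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "n_bees") <- length(valid)
  class(out) <- c("population_summary", "data.frame")
  out
}
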