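#' Two-group comparison with distributional checks and effect size
#'
#' Mirrors the SPSS independent-samples workflow: Shapiro–Wilk normality
#' check per group, Levene's test for equality of variances (mean-centred
#' absolute deviations, the SPSS convention), then an independent-samples
#' t-test — pooled-variance when Levene's p > 0.05, Welch's unequal-variance
#' form otherwise. Cohen's d uses the pooled standard deviation and is
#' reported as a magnitude.
#'
#' @param sample_a,sample_b numeric vectors (>= 3 values each).
#' @return a `group_comparison` list: `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b`, `shapiro_p_a`, `shapiro_p_b`, `levene_F`, `levene_p`,
#'   `equal_variances`, `t_statistic`, `df`, `p_two_tailed`, `cohens_d`.
#' @export
compare_groups <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 3L || length(sample_b) < 3L) {
    stop("compare_groups: each sample needs at least 3 values")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("compare_groups: zero variance in both samples")
  }
  shapiro_p <- function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  values <- c(sample_a, sample_b)
  grp <- factor(rep(c("a", "b"), c(length(sample_a), length(sample_b))))
  lev <- car::leveneTest(values, grp, center = mean)
  levene_F <- lev[["F value"]][1]
  levene_p <- lev[["Pr(>F)"]][1]
  equal_var <- levene_p > 0.05
  tt <- stats::t.test(sample_a, sample_b, var.equal = equal_var)
  n_a <- length(sample_a); n_b <- length(sample_b)
  sp <- sqrt(((n_a - 1) * stats::var(sample_a) + (n_b - 1) * stats::var(sample_b)) /
               (n_a + n_b - 2))
  d <- if (sp == 0) 0 else abs(mean(sample_a) - mean(sample_b)) / sp
  structure(list(
    mean_a = mean(sample_a), mean_b = mean(sample_b),
    sd_a = stats::sd(sample_a), sd_b = stats::sd(sample_b),
    n_a = n_a, n_b = n_b,
    shapiro_p_a = shapiro_p(sample_a), shapiro_p_b = shapiro_p(sample_b),
    levene_F = levene_F, levene_p = levene_p, equal_variances = equal_var,
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_two_tailed = tt$p.value, cohens_d = d
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<group_comparison: mean %.4f (n=%d) vs %.4f (n=%d); Levene F=%.3f p=%.3f;",
           " %s t=%.3f df=%.1f p=%.4g; d=%.3f>\n"),
    x$mean_a, x$n_a, x$mean_b, x$n_b, x$levene_F, x$levene_p,
    if (x$equal_variances) "pooled" else "Welch",
    x$t_statistic, x$df, x$p_two_tailed, x$cohens_d
  ))
  invisible(x)
}

#' Pearson correlation screen against a target
#'
#' Retains predictors whose Pearson correlation with the target is both
#' significant (p < `alpha`) and non-negligible (|r| >= `r_min`). Constant
#' columns are dropped with a warning (their correlation is undefined).
#'
#' @param feature_matrix data frame or matrix, rows = transcripts.
#' @param target numeric vector aligned with the rows.
#' @param alpha significance threshold (default 0.05).
#' @param r_min minimum |r| (default 0.100).
#' @return a `screening_report` list: `retained` (names),
#'   `dropped_correlation` (data frame name/r/p), `dropped_constant`,
#'   `statistics` (r and p for every tested column).
#' @export
correlation_screen <- function(feature_matrix, target, alpha = 0.05, r_min = 0.100) {
  X <- as.data.frame(feature_matrix)
  stopifnot(nrow(X) == length(target))
  if (nrow(X) < 4L) stop("correlation_screen: need at least 4 rows")
  constant <- vapply(X, function(col) stats::var(col, na.rm = TRUE) == 0 ||
                       all(is.na(col)), logical(1))
  if (any(constant)) {
    warning("dropping constant column(s): ",
            paste(names(X)[constant], collapse = ", "))
  }
  tested <- names(X)[!constant]
  stats_df <- do.call(rbind, lapply(tested, function(nm) {
    ok <- stats::complete.cases(X[[nm]], target)
    ct <- stats::cor.test(X[[nm]][ok], target[ok], method = "pearson")
    data.frame(name = nm, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(stats_df)) stats_df <- data.frame(name = character(0), r = numeric(0), p = numeric(0))
  keep <- !is.na(stats_df$r) & abs(stats_df$r) >= r_min & stats_df$p < alpha
  structure(list(
    retained = stats_df$name[keep],
    dropped_correlation = stats_df[!keep, , drop = FALSE],
    dropped_constant = names(X)[constant],
    statistics = stats_df
  ), class = "screening_report")
}

vif_values <- function(X) {
  vapply(seq_along(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance-inflation-factor screen
#'
#' Iteratively removes the predictor with the highest VIF while any
#' VIF >= `threshold`. `VIF_j = 1 / (1 - R^2_j)` from regressing column `j`
#' on the remaining columns; perfect collinearity (infinite VIF) is handled
#' by removal, never by failure.
#'
#' @param feature_matrix data frame or matrix with >= 2 columns.
#' @param threshold exclusion threshold (default 5).
#' @return a `screening_report` list: `retained`, `dropped_vif` (data frame
#'   name/vif, in removal order), `vif` (final VIFs of retained columns).
#' @export
vif_screen <- function(feature_matrix, threshold = 5) {
  X <- as.data.frame(feature_matrix)
  if (ncol(X) < 2L) stop("vif_screen: need at least 2 columns")
  dropped <- data.frame(name = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    if (ncol(X) < 2L) break
    v <- vif_values(X)
    if (all(v < threshold)) break
    worst <- which.max(v)
    dropped[nrow(dropped) + 1L, ] <- list(names(X)[worst], v[worst])
    X <- X[-worst]
  }
  final_vif <- if (ncol(X) >= 2L) stats::setNames(vif_values(X), names(X))
               else stats::setNames(rep(1, ncol(X)), names(X))
  structure(list(retained = names(X), dropped_vif = dropped, vif = final_vif),
            class = "screening_report")
}

#' Stepwise (forward-with-backward-elimination) regression
#'
#' The SPSS stepwise procedure with its default thresholds: at each step the
#' candidate whose partial F test has the smallest p-value enters if
#' p < `p_enter`; after every entry, predictors whose p exceeds `p_remove`
#' are eliminated (largest first). For a single added coefficient the
#' partial F equals the squared t of that coefficient, so coefficient t
#' tests are used. Stops when no entry or removal changes the model.
#'
#' @param feature_matrix data frame or matrix of candidate predictors.
#' @param target numeric response (the per-transcript MDD in the intended
#'   workflow).
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return a `regression_model` list: `selected` (names in entry order),
#'   `coefficients` (data frame name/B/SE/beta/VIF), `intercept`,
#'   `r_squared`, `adjusted_r_squared`, `n`, `fit` (the final `lm`).
#' @export
stepwise_regression <- function(feature_matrix, target,
                                p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(feature_matrix)
  ok <- stats::complete.cases(X, target)
  X <- X[ok, , drop = FALSE]
  y <- target[ok]
  if (nrow(X) < ncol(X) + 2L) {
    stop("stepwise_regression: need rows >= columns + 2 after listwise deletion")
  }
  selected <- character(0)
  coef_p <- function(vars) {
    if (length(vars) == 0L) return(numeric(0))
    fit <- stats::lm(y ~ ., data = X[vars])
    p <- summary(fit)$coefficients[-1, 4]
    stats::setNames(as.numeric(p), vars)
  }
  repeat {
    changed <- FALSE
    candidates <- setdiff(names(X), selected)
    if (length(candidates) > 0L) {
      entry_p <- vapply(candidates, function(v) {
        p <- coef_p(c(selected, v))
        unname(p[v])
      }, numeric(1))
      entry_p[is.na(entry_p)] <- 1 # collinear with current model: never enters
      if (min(entry_p) < p_enter) {
        selected <- c(selected, candidates[which.min(entry_p)])
        changed <- TRUE
      }
    }
    repeat {
      p <- coef_p(selected)
      if (length(p) == 0L || max(p, na.rm = TRUE) <= p_remove) break
      selected <- setdiff(selected, names(which.max(p)))
      changed <- TRUE
    }
    if (!changed) break
  }
  if (length(selected) == 0L) {
    return(structure(list(
      selected = character(0),
      coefficients = data.frame(name = character(0), B = numeric(0),
                                SE = numeric(0), beta = numeric(0),
                                VIF = numeric(0), p = numeric(0)),
      intercept = mean(y), r_squared = 0, adjusted_r_squared = 0,
      n = length(y), fit = NULL
    ), class = "regression_model"))
  }
  fit <- stats::lm(y ~ ., data = X[selected])
  sm <- summary(fit)
  co <- sm$coefficients
  beta <- co[-1, 1] * vapply(X[selected], stats::sd, numeric(1)) / stats::sd(y)
  vif <- if (length(selected) >= 2L) vif_values(X[selected]) else 1
  structure(list(
    selected = selected,
    coefficients = data.frame(
      name = selected,
      B = unname(co[-1, 1]), SE = unname(co[-1, 2]),
      beta = unname(beta), VIF = unname(vif), p = unname(co[-1, 4]),
      stringsAsFactors = FALSE
    ),
    intercept = unname(co[1, 1]),
    r_squared = sm$r.squared, adjusted_r_squared = sm$adj.r.squared,
    n = length(y), fit = fit
  ), class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model: %d predictor(s), R^2 = %.3f, adj. R^2 = %.3f, n = %d>\n",
              length(x$selected), x$r_squared, x$adjusted_r_squared, x$n))
  if (length(x$selected) > 0L) print(x$coefficients, digits = 3)
  invisible(x)
}
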