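#' Schneider-Orelli corrected mortality
#'
#' Adjusts treatment mortality for background mortality in the untreated
#' control:
#' \deqn{CM = \frac{T - C}{100 - C} \times 100}
#' where `T` is the observed treatment mortality (%) and `C` the control
#' mortality (%). When the control exceeds the treatment the raw value is
#' negative; mortality cannot be negative, so such values are clamped to
#' 0 and flagged (attribute `"clamped"` gives their indices, and a
#' warning is raised).
#'
#' @param treat_pct observed treatment mortality, percent (0-100).
#' @param control_pct control mortality, percent (0-100, strictly below
#'   100; the correction is undefined at 100). Recycled against
#'   `treat_pct`.
#' @return Corrected mortality in percent, clamped to `[0, 100]`.
#' @examples
#' corrected_mortality(60, 20)  # 50
#' @export
corrected_mortality <- function(treat_pct, control_pct) {
  if (any(!is.finite(treat_pct)) || any(!is.finite(control_pct))) {
    stop("corrected_mortality: inputs must be finite", call. = FALSE)
  }
  if (any(treat_pct < 0 | treat_pct > 100) ||
      any(control_pct < 0 | control_pct > 100)) {
    stop("corrected_mortality: percentages must lie in [0, 100]",
         call. = FALSE)
  }
  if (any(control_pct >= 100)) {
    stop("corrected_mortality: undefined for control mortality of 100%",
         call. = FALSE)
  }
  raw <- (treat_pct - control_pct) / (100 - control_pct) * 100
  clamped <- which(raw < 0)
  out <- pmin(100, pmax(0, raw))
  if (length(clamped) > 0L) {
    warning(sprintf("corrected mortality clamped to 0 for %d value(s)",
                    length(clamped)), call. = FALSE)
    attr(out, "clamped") <- clamped
  }
  out
}

#' Arcsine square-root transformation of percentages
#'
#' The variance-stabilizing transform applied to percentage data before
#' ANOVA: \eqn{\theta = \arcsin\sqrt{p/100}}, expressed in degrees so 0%
#' maps to 0 and 100% to 90. `arcsine_back()` inverts it.
#'
#' @param p percentage in `[0, 100]`.
#' @param theta angle in degrees in `[0, 90]`.
#' @return Degrees (or percent for the inverse).
#' @examples
#' arcsine_transform(50)  # 45
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 100)) {
    stop("arcsine_transform: p must lie in [0, 100]", call. = FALSE)
  }
  asin(sqrt(p / 100)) * 180 / pi
}

#' @rdname arcsine_transform
#' @export
arcsine_back <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 90)) {
    stop("arcsine_back: theta must lie in [0, 90] degrees", call. = FALSE)
  }
  sin(theta * pi / 180)^2 * 100
}

#' Per-strain corrected mortality from replicate nymph counts
#'
#' For every strain and observation day, replicate mortality is
#' `100 * n_dead / n_marked`; each replicate is corrected against the
#' mean control mortality of the same day ([corrected_mortality()]) and
#' the corrected values are averaged across replicates. Control rows use
#' the reserved strain id `"CONTROL"` and must be present for every day
#' that appears in the treated data.
#'
#' @param bioassay bioassay count table (see [validate_tables]).
#' @return Data frame with `strain_id`, `day`, `n_reps`, `mortality`
#'   (mean corrected %, clamped at 0) and `control` (the day's mean
#'   control mortality, %).
#' @export
mortality_from_counts <- function(bioassay) {
  bioassay <- validate_bioassay(bioassay)
  ctrl <- bioassay[bioassay$strain_id == .control_id, , drop = FALSE]
  trt <- bioassay[bioassay$strain_id != .control_id, , drop = FALSE]
  days <- sort(unique(trt$day))
  ctrl_mean <- vapply(days, function(d) {
    rows <- ctrl[ctrl$day == d, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("mortality_from_counts: no control rows for day ", d,
           call. = FALSE)
    }
    mean(100 * rows$n_dead / rows$n_marked)
  }, numeric(1))
  names(ctrl_mean) <- as.character(days)

  out <- expand.grid(strain_id = unique(trt$strain_id), day = days,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$n_reps <- NA_integer_
  out$mortality <- NA_real_
  out$control <- ctrl_mean[as.character(out$day)]
  for (i in seq_len(nrow(out))) {
    rows <- trt[trt$strain_id == out$strain_id[i] & trt$day == out$day[i], ,
                drop = FALSE]
    raw <- 100 * rows$n_dead / rows$n_marked
    cm <- suppressWarnings(corrected_mortality(raw, out$control[i]))
    out$n_reps[i] <- nrow(rows)
    out$mortality[i] <- mean(cm)
  }
  out[order(out$strain_id, out$day), , drop = FALSE]
}

#' One-way ANOVA for a completely randomized design
#'
#' Classical fixed-effects decomposition of a single response by
#' treatment, fitted with [stats::aov()]. Unbalanced layouts are
#' analysed on the available cells. When the error mean square is zero
#' (replicates identical within every treatment) the F ratio is reported
#' as a large finite value with `degenerate = TRUE` rather than
#' crashing.
#'
#' @param values numeric response (typically arcsine-transformed
#'   percentages).
#' @param treatment treatment labels, one per value.
#' @return An object of class `epf_anova`: a list with `df_treat`,
#'   `df_error`, `ms_treat`, `ms_error`, `F`, `p`, `grand_mean`,
#'   `means` (named treatment means) and `degenerate`.
#' @export
anova_crd <- function(values, treatment) {
  treatment <- factor(treatment)
  if (nlevels(treatment) < 2L) {
    stop("anova_crd: need >= 2 treatments", call. = FALSE)
  }
  if (any(table(treatment) < 2L)) {
    warning("anova_crd: some treatment(s) have a single replicate",
            call. = FALSE)
  }
  fit <- aov(values ~ treatment)
  tab <- anova(fit)
  ms_treat <- tab$`Mean Sq`[1L]
  ms_error <- tab$`Mean Sq`[2L]
  degenerate <- !is.na(ms_error) && ms_error <= .Machine$double.eps *
    max(1, ms_treat)
  if (degenerate) {
    Fval <- if (ms_treat > 0) .Machine$double.xmax^0.5 else 0
    pval <- if (ms_treat > 0) 0 else 1
  } else {
    Fval <- tab$`F value`[1L]
    pval <- tab$`Pr(>F)`[1L]
  }
  structure(list(
    df_treat = tab$Df[1L], df_error = tab$Df[2L],
    ss_treat = tab$`Sum Sq`[1L], ss_error = tab$`Sum Sq`[2L],
    ms_treat = ms_treat, ms_error = if (degenerate) 0 else ms_error,
    F = Fval, p = pval,
    grand_mean = mean(values),
    means = tapply(values, treatment, mean),
    degenerate = degenerate
  ), class = "epf_anova")
}

#' @export
print.epf_anova <- function(x, ...) {
  cat(sprintf("CRD ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_treat, x$df_error, x$F, x$p))
  invisible(x)
}

#' Least significant difference report for a balanced CRD
#'
#' Computes, at level `alpha`,
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 * MSE / r)`, the standard
#' errors of a mean (`se_m = sqrt(MSE / r)`) and of a difference
#' (`se_d = sqrt(2) * se_m`), the coefficient of variation
#' (`cv = 100 * sqrt(MSE) / grand mean`), and a compact letter display:
#' treatments are sorted by descending mean and means closer than the
#' LSD share a letter (insertion grouping), so two means further apart
#' than the LSD never share one.
#'
#' @param anova an [anova_crd()] result.
#' @param r number of replicates per treatment (balanced design).
#' @param alpha significance level (default 0.05).
#' @return An object of class `epf_lsd`: list with `lsd`, `se_m`,
#'   `se_d`, `cv_pct`, `alpha` and `letters` (named character vector).
#' @export
lsd_test <- function(anova, r, alpha = 0.05) {
  stopifnot(inherits(anova, "epf_anova"))
  if (!is.numeric(r) || r <= 0) stop("lsd_test: r must be > 0",
                                     call. = FALSE)
  se_m <- sqrt(anova$ms_error / r)
  se_d <- sqrt(2) * se_m
  lsd <- qt(1 - alpha / 2, anova$df_error) * se_d
  cv <- 100 * sqrt(anova$ms_error) / anova$grand_mean
  structure(list(lsd = lsd, se_m = se_m, se_d = se_d, cv_pct = cv,
                 alpha = alpha,
                 letters = compact_letters(anova$means, lsd)),
            class = "epf_lsd")
}

#' @export
print.epf_lsd <- function(x, ...) {
  cat(sprintf("LSD(%.2g) = %.4g; SE(m) = %.4g; SE(d) = %.4g; CV = %.4g%%\n",
              x$alpha, x$lsd, x$se_m, x$se_d, x$cv_pct))
  invisible(x)
}

#' Compact letter display by insertion grouping
#'
#' @param means named numeric vector of treatment means.
#' @param threshold two means differing by more than this never share a
#'   letter.
#' @return Named character vector of letter groups, in the input order.
#' @export
compact_letters <- function(means, threshold) {
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  # maximal runs of means whose spread is <= threshold
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && m[i] - m[j + 1L] <= threshold) j <- j + 1L
    runs[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (h in seq_len(k)) {
      if (h != i && runs[[h]][1L] <= runs[[i]][1L] &&
          runs[[h]][2L] >= runs[[i]][2L]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  runs <- runs[keep]
  letts <- rep("", k)
  for (g in seq_along(runs)) {
    span <- seq(runs[[g]][1L], runs[[g]][2L])
    letts[span] <- paste0(letts[span], letters[(g - 1L) %% 26L + 1L])
  }
  out <- character(k)
  out[ord] <- letts
  names(out) <- names(means)
  out
}

#' Normality and homoscedasticity checks for ANOVA residuals
#'
#' Runs the Shapiro-Wilk test on within-treatment residuals and the
#' Brown-Forsythe test (Levene's test with group medians, via
#' [car::leveneTest()]) on the grouped values. Both are advisory: the
#' screening pipeline proceeds regardless, logging a warning when either
#' p-value is below `warn_below`. Constant input leaves the Shapiro
#' p-value as `NA` with `flagged = TRUE` instead of failing.
#'
#' @param values numeric response.
#' @param groups treatment labels.
#' @param warn_below warn when a p-value is below this (default 0.05).
#' @return List with `shapiro_p`, `brown_forsythe_p`, `flagged`.
#' @export
normality_checks <- function(values, groups, warn_below = 0.05) {
  if (length(values) < 3L) stop("normality_checks: need n >= 3",
                                call. = FALSE)
  groups <- factor(groups)
  resid <- values - ave(values, groups)
  flagged <- FALSE
  shapiro_p <- tryCatch(shapiro.test(resid)$p.value, error = function(e) {
    NA_real_
  })
  if (is.na(shapiro_p)) flagged <- TRUE
  bf_p <- NA_real_
  if (nlevels(groups) >= 2L && all(table(groups) >= 2L) && sd(values) > 0) {
    bf_p <- tryCatch(
      car::leveneTest(values ~ groups, center = median)[1L, "Pr(>F)"],
      error = function(e) NA_real_)
  }
  if (is.na(bf_p)) flagged <- TRUE
  low <- c(shapiro_p, bf_p) < warn_below
  if (any(low, na.rm = TRUE)) {
    warning("normality_checks: diagnostic p-value below ", warn_below,
            "; interpret mean comparisons with care", call. = FALSE)
  }
  list(shapiro_p = shapiro_p, brown_forsythe_p = bf_p, flagged = flagged)
}
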