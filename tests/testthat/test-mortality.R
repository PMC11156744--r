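test_that("corrected mortality follows the control-adjustment formula", {
  expect_equal(corrected_mortality(50, 0), 50)
  expect_equal(corrected_mortality(60, 20), 50)
  expect_equal(corrected_mortality(20, 20), 0)
  # control above treatment clamps to zero with a flag
  expect_warning(out <- corrected_mortality(10, 20), "clamped")
  expect_equal(as.numeric(out), 0)
  expect_identical(attr(out, "clamped"), 1L)
  expect_error(corrected_mortality(50, 100), "undefined")
  expect_error(corrected_mortality(120, 0), "\\[0, 100\\]")
})

test_that("corrected mortality is monotone and reduces to identity", {
  t_grid <- seq(0, 100, by = 5)
  for (ctrl in c(0, 10, 35, 80)) {
    out <- suppressWarnings(corrected_mortality(t_grid, ctrl))
    expect_true(all(diff(out) >= 0))
  }
  expect_equal(corrected_mortality(t_grid, 0), t_grid)
})

test_that("arcsine transform matches printed values and inverts exactly", {
  expect_equal(round1(arcsine_transform(95.1)), 77.2)
  expect_equal(round1(arcsine_transform(89.9)), 71.5)
  expect_equal(arcsine_transform(c(0, 100, 50)), c(0, 90, 45))
  p <- seq(0, 100, length.out = 201)
  expect_equal(arcsine_back(arcsine_transform(p)), p, tolerance = 1e-9)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(101), "\\[0, 100\\]")
  expect_error(arcsine_transform(-1), "\\[0, 100\\]")
})

test_that("mortality from counts corrects per replicate against day controls", {
  tab <- make_bioassay(list(S1 = c(38, 38, 38)), control_dead = c(0, 0, 0),
                       marked = 40)
  out <- mortality_from_counts(tab)
  expect_equal(out$mortality, 95)

  same <- make_bioassay(list(S1 = c(4, 4, 4)), control_dead = c(4, 4, 4),
                        marked = 40)
  expect_equal(mortality_from_counts(same)$mortality, 0)

  no_ctrl <- tab[tab$strain_id != "CONTROL", ]
  expect_error(mortality_from_counts(no_ctrl), "day 7")
})

test_that("mortality from counts matches a spreadsheet-style oracle", {
  set.seed(101)
  ids <- paste0("S", 1:5)
  dead <- lapply(ids, function(i) rbinom(3, 40, runif(1, 0.1, 0.9)))
  names(dead) <- ids
  tabs <- lapply(c(3L, 5L, 7L), function(d) {
    make_bioassay(dead, control_dead = rbinom(3, 40, 0.05), day = d,
                  marked = 40)
  })
  tab <- do.call(rbind, tabs)
  out <- mortality_from_counts(tab)
  # oracle: explicit loops, no shared code with the implementation
  for (d in c(3, 5, 7)) {
    ctrl_rows <- tab[tab$strain_id == "CONTROL" & tab$day == d, ]
    c_pct <- mean(100 * ctrl_rows$n_dead / ctrl_rows$n_marked)
    for (id in ids) {
      rows <- tab[tab$strain_id == id & tab$day == d, ]
      vals <- numeric(nrow(rows))
      for (k in seq_len(nrow(rows))) {
        raw <- 100 * rows$n_dead[k] / rows$n_marked[k]
        cm <- (raw - c_pct) / (100 - c_pct) * 100
        vals[k] <- max(0, cm)
      }
      got <- out$mortality[out$strain_id == id & out$day == d]
      expect_equal(got, mean(vals), tolerance = 1e-12)
    }
  }
})

test_that("CRD ANOVA matches a brute-force sums-of-squares oracle", {
  # textbook-style 3 treatments x 3 replicates
  vals <- c(21, 24, 22, 28, 30, 29, 35, 33, 36)
  trt <- rep(c("A", "B", "C"), each = 3)
  fit <- anova_crd(vals, trt)
  grand <- mean(vals)
  ss_total <- sum((vals - grand)^2)
  means <- tapply(vals, trt, mean)
  ss_treat <- sum(3 * (means - grand)^2)
  ss_error <- ss_total - ss_treat
  expect_equal(fit$ss_treat, ss_treat, tolerance = 1e-12)
  expect_equal(fit$ms_error, ss_error / 6, tolerance = 1e-12)
  expect_equal(fit$F, (ss_treat / 2) / (ss_error / 6), tolerance = 1e-12)
  expect_equal(fit$df_treat, 2)
  expect_equal(fit$df_error, 6)

  # SS conservation on random data
  set.seed(7)
  v2 <- rnorm(24)
  t2 <- rep(letters[1:4], each = 6)
  f2 <- anova_crd(v2, t2)
  expect_equal(f2$ss_treat + f2$ss_error, sum((v2 - mean(v2))^2),
               tolerance = 1e-9)
})

test_that("CRD ANOVA handles identical and degenerate layouts", {
  # identical treatment means: F = 0
  f0 <- anova_crd(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(f0$F, 0, tolerance = 1e-12)

  # constant within treatments, distinct between: flagged large finite F
  # (the underlying lm warns about the perfect fit)
  fd <- suppressWarnings(anova_crd(c(1, 1, 1, 5, 5, 5),
                                   rep(c("A", "B"), each = 3)))
  expect_true(fd$degenerate)
  expect_true(is.finite(fd$F) && fd$F > 1e6)
  expect_equal(fd$ms_error, 0)
  expect_equal(fd$p, 0)

  expect_error(anova_crd(1:3, rep("A", 3)), ">= 2 treatments")
})

test_that("LSD report satisfies its algebraic identities", {
  set.seed(11)
  vals <- rnorm(12, rep(c(10, 12, 15, 20), each = 3))
  fit <- anova_crd(vals, rep(letters[1:4], each = 3))
  rep_n <- 3
  lsd <- lsd_test(fit, r = rep_n)
  expect_equal(lsd$se_d, sqrt(2) * lsd$se_m, tolerance = 1e-12)
  expect_equal(lsd$se_m, sqrt(fit$ms_error / rep_n), tolerance = 1e-12)
  expect_equal(lsd$lsd, qt(0.975, fit$df_error) * lsd$se_d,
               tolerance = 1e-12)
  expect_equal(lsd$cv_pct, 100 * sqrt(fit$ms_error) / mean(vals),
               tolerance = 1e-12)
  expect_error(lsd_test(fit, r = 0), "> 0")

  fd <- suppressWarnings(anova_crd(c(1, 1, 5, 5),
                                   rep(c("A", "B"), each = 2)))
  expect_equal(lsd_test(fd, r = 2)$lsd, 0)
})

test_that("letter groups agree with an all-pairs pooled t-test oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    trt <- rep(letters[1:4], each = 3)
    vals <- rnorm(12, rep(sample(seq(8, 20, 2), 4), each = 3), 2)
    fit <- anova_crd(vals, trt)
    letts <- lsd_test(fit, r = 3)$letters
    means <- fit$means
    for (i in 1:3) for (j in (i + 1):4) {
      tstat <- abs(means[i] - means[j]) / sqrt(2 * fit$ms_error / 3)
      p <- 2 * pt(-tstat, fit$df_error)
      share <- any(strsplit(letts[i], "")[[1]] %in%
                     strsplit(letts[j], "")[[1]])
      expect_identical(share, unname(p >= 0.05))
    }
  }
})

test_that("means separated by more than the LSD never share a letter", {
  set.seed(21)
  for (rep in 1:25) {
    means <- setNames(runif(6, 0, 50), paste0("t", 1:6))
    thr <- runif(1, 0.5, 15)
    letts <- compact_letters(means, thr)
    for (i in 1:5) for (j in (i + 1):6) {
      share <- any(strsplit(letts[i], "")[[1]] %in%
                     strsplit(letts[j], "")[[1]])
      if (abs(means[i] - means[j]) > thr) expect_false(share)
      if (abs(means[i] - means[j]) <= thr) expect_true(share)
    }
  }
})

test_that("normality checks report the standard diagnostics and survive
           degenerate input", {
  set.seed(34)
  vals <- rnorm(100, rep(c(0, 1, 2, 3), each = 25))
  grp <- rep(letters[1:4], each = 25)
  out <- normality_checks(vals, grp)
  expect_gt(out$shapiro_p, 0.05)
  expect_gt(out$brown_forsythe_p, 0.05)
  expect_false(out$flagged)
  # agrees with the reference tests applied directly
  resid <- vals - ave(vals, grp)
  expect_equal(out$shapiro_p, shapiro.test(resid)$p.value)
  expect_equal(out$brown_forsythe_p,
               car::leveneTest(vals ~ factor(grp),
                               center = median)[1, "Pr(>F)"])

  const <- normality_checks(rep(5, 12), rep(c("A", "B"), each = 6))
  expect_true(is.na(const$shapiro_p))
  expect_true(const$flagged)
})
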