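test_that("paired t matches the textbook closed form", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 6)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), length(d) - 1)
  r <- paired_t(x, y)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$df, 3)
  expect_equal(r$p_value, p_hand, tolerance = 1e-10)
  expect_error(paired_t(x, x + 2), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("Welch t matches the Welch-Satterthwaite closed form", {
  x <- 1:5; y <- c(2, 4, 6, 8, 10)
  vx <- var(x) / 5; vy <- var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 4)
  r <- welch_t(x, y)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$df, df_hand, tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  # pooled variant reports integer df
  rp <- welch_t(x, y, pooled = TRUE)
  expect_equal(rp$df, 8)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("identical samples give a null statistic; label exchange flips its sign", {
  x <- c(3, 1, 4, 1, 5)
  r <- welch_t(x, rev(x))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(71)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  expect_equal(welch_t(a, b)$statistic, -welch_t(b, a)$statistic)
  expect_equal(paired_t(a[1:12], b[1:12])$statistic,
               -paired_t(b[1:12], a[1:12])$statistic)
})

test_that("the mixed-model LRT tests all group terms with the parameter-count df", {
  set.seed(72)
  d <- make_fi_table(n_per_group = 10, learned_deficit = 25)
  r <- lmm_fi_comparison(d, contrasts = FALSE)
  expect_equal(r$test$df, 12)  # group main effect + 11 interaction terms
  expect_lt(r$test$p_value, 0.01)
  expect_match(r$model_label, "random intercept")
  expect_error(lmm_fi_comparison(d[d$group == "control", ]), "two groups")
  one_cell <- d[d$cell_id %in% c("c001", "c011"), ]
  expect_error(lmm_fi_comparison(one_cell), "2 cells per group")
})

test_that("zero between-cell variance falls back to the fixed-effects model", {
  set.seed(73)
  d <- make_fi_table(n_per_group = 8, cell_sd = 0, res_sd = 5)
  r <- lmm_fi_comparison(d, contrasts = FALSE)
  expect_match(r$model_label, "fixed-effects fallback")
  ref <- lm(rate ~ group * step,
            data = data.frame(rate = d$firing_rate, group = factor(d$group),
                              step = factor(d$current_step)))
  expect_equal(unname(coef(r$model)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("per-step contrasts are adjusted and adjustment never shrinks p", {
  set.seed(74)
  d <- make_fi_table(n_per_group = 12, learned_deficit = 15)
  r <- lmm_fi_comparison(d, contrasts = TRUE)
  expect_equal(nrow(r$contrasts), 12)
  expect_true(r$adjust_method %in% c("mvt", "holm (mvt adjustment failed)"))
  z <- r$contrasts$estimate / r$contrasts$SE
  p_raw <- 2 * pnorm(-abs(z))
  expect_true(all(r$contrasts$p.value >= p_raw - 1e-12))
})

test_that("a threshold-shifted cohort shows lower learned rates at strong drive", {
  pop <- generate_cell_population(n_control = 30, n_learned = 30,
                                  learned_shift = c(soft_threshold = 4),
                                  nonregular_fraction = 0, seed = 81)
  res <- extract_features(pop)
  r <- lmm_fi_comparison(fi_long_table(res), contrasts = TRUE)
  expect_lt(r$test$p_value, 0.05)
  hi <- r$contrasts[as.numeric(as.character(r$contrasts$step)) >= 600, ]
  # contrast is learned - control (revpairwise on alphabetical levels)
  expect_true(all(hi$estimate < 0))
  expect_true(all(hi$p.value < 0.05))
})

test_that("the feature battery separates shifted rheobase but spares the AHP", {
  pop <- generate_cell_population(
    n_control = 15, n_learned = 15,
    learned_shift = c(soft_threshold = 4, reset_potential = 4),
    nonregular_fraction = 0, seed = 82)
  res <- extract_features(pop)
  gs <- summarize_groups(res, contrasts = FALSE)
  expect_lt(gs$tests$rheobase$p_value, 0.05)
  expect_lt(gs$tests$rheobase$statistic, 0)  # control minus learned
  expect_gt(gs$tests$ahp_amplitude$p_value, 0.05)
})

test_that("two copied groups give null statistics everywhere", {
  mk <- function(grp) lapply(1:5, function(i)
    fake_result(sprintf("%s_%d", grp, i), grp, rheobase = 100 + 10 * i,
                thr = -45 + i, amp = 60 + i, ahp = 10 + i, rin = 90 + i,
                rates = c(0, 5 * i, 10 * i)))
  gs <- summarize_groups(c(mk("control"), mk("learned")), contrasts = FALSE)
  for (nm in names(gs$tests)) expect_equal(gs$tests[[nm]]$statistic, 0)
})

test_that("non-regular cells are excluded with full accounting", {
  pop <- generate_cell_population(n_control = 10, n_learned = 10,
                                  nonregular_fraction = 0.3, seed = 83)
  res <- extract_features(pop)
  gs <- summarize_groups(res, contrasts = FALSE)
  tab <- feature_table(res)
  for (g in c("control", "learned")) {
    expect_equal(unname(gs$included_n[g]),
                 sum(tab$group == g & tab$pattern == "regular"))
  }
  expect_equal(nrow(gs$exclusions), sum(tab$pattern != "regular"))
  expect_true(all(gs$exclusions$reason == "non-regular firing pattern"))
})

test_that("a feature missing for a whole group is skipped with a warning", {
  mk <- function(grp, rheo) lapply(1:4, function(i)
    fake_result(sprintf("%s_%d", grp, i), grp, rheobase = rheo(i),
                thr = -45 + 0.1 * i, amp = 60, ahp = 10 + 0.2 * i,
                rin = 90 + i))
  res <- c(mk("control", function(i) NA_real_),
           mk("learned", function(i) 150 + i))
  expect_warning(gs <- summarize_groups(res, contrasts = FALSE),
                 "rheobase")
  expect_null(gs$tests$rheobase)
  expect_false(is.null(gs$tests$input_resistance))
})
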