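test_that("long tables enforce a complete subject-by-phase crossing", {
  expect_error(long_table(c(1, 1, 2), c("a", "a", "b"),
                          c("w1", "w2", "w1"), 1:3),
               class = "mobilekin_incomplete_design")
  expect_error(long_table(c(1, 1, 2, 2), c("a", "b", "b", "b"),
                          c("w1", "w2", "w1", "w2"), 1:4),
               class = "mobilekin_incomplete_design")
})

test_that("the split-plot partition matches a from-scratch sums-of-squares oracle", {
  # 8 subjects (4 per group) x 6 phases with hand-constructed values
  withr::with_seed(1, {
    g <- rep(c("g1", "g2"), each = 4)
    subj_eff <- rnorm(8, sd = 2)
    phase_eff <- seq(-1, 1, length.out = 6)
    d <- expand.grid(subject = 1:8, phase = paste0("p", 1:6))
    d$group <- g[d$subject]
    d$value <- subj_eff[d$subject] + phase_eff[as.integer(d$phase)] +
      ifelse(d$group == "g2", 0.5, 0) * as.integer(d$phase) + rnorm(48)
  })
  fit <- mixed_anova(long_table(d$subject, d$group, d$phase, d$value))

  # independent oracle: explicit marginal/cell means expanded per observation
  gm <- mean(d$value)
  subj_m <- tapply(d$value, d$subject, mean)[d$subject]
  grp_m <- tapply(d$value, d$group, mean)[d$group]
  ph_m <- tapply(d$value, d$phase, mean)[d$phase]
  cell_m <- ave(d$value, d$group, d$phase)
  ss_between <- sum((grp_m - gm)^2)
  ss_subj_err <- sum((subj_m - grp_m)^2)
  ss_phase <- sum((ph_m - gm)^2)
  ss_inter <- sum((cell_m - grp_m - ph_m + gm)^2)
  ss_within_err <- sum((d$value - cell_m - subj_m + grp_m)^2)

  expect_equal(fit$table$ss, c(ss_between, ss_phase, ss_inter),
               tolerance = 1e-9)
  expect_equal(fit$errors$between$ss, ss_subj_err, tolerance = 1e-9)
  expect_equal(fit$errors$within$ss, ss_within_err, tolerance = 1e-9)
  expect_equal(fit$table$df, c(1, 5, 5))
  expect_equal(fit$errors$between$df, 6)
  expect_equal(fit$errors$within$df, 30)
  expect_equal(fit$table$F,
               c((ss_between / 1) / (ss_subj_err / 6),
                 (ss_phase / 5) / (ss_within_err / 30),
                 (ss_inter / 5) / (ss_within_err / 30)),
               tolerance = 1e-9)
})

test_that("sums of squares decompose the total exactly", {
  withr::with_seed(6, {
    for (rep in 1:3) {
      lt <- null_long_table(n_per_group = 8)
      fit <- mixed_anova(lt)
      total <- sum((lt$value - mean(lt$value))^2)
      parts <- sum(fit$table$ss) + fit$errors$between$ss +
        fit$errors$within$ss
      expect_equal(parts, total, tolerance = 1e-9 * total)
    }
  })
})

test_that("identical groups with a shared phase effect yield no between effect", {
  p <- 6; n <- 10
  phase_eff <- c(0, 1, 2, 3, 4, 5)
  withr::with_seed(30, shared <- rep(phase_eff, n) +
                     rep(seq(0, 0.9, length.out = n), each = p) +
                     rnorm(n * p, sd = 0.2))
  lt <- long_table(subject = rep(1:(2 * n), each = p),
                   between = rep(c("a", "b"), each = n * p),
                   within = rep(paste0("w", 1:p), 2 * n),
                   value = c(shared, shared))
  fit <- mixed_anova(lt)
  b <- fit$table[fit$table$effect == "between", ]
  expect_lt(b$F, 1e-20)
  expect_gt(b$p, 0.999)
})

test_that("partial eta squared follows its defining ratio and is affine invariant", {
  withr::with_seed(2, lt <- null_long_table(n_per_group = 6))
  fit <- mixed_anova(lt)
  expect_equal(fit$table$partial_eta_sq[1],
               fit$table$ss[1] / (fit$table$ss[1] + fit$errors$between$ss))
  expect_equal(fit$table$partial_eta_sq[2],
               fit$table$ss[2] / (fit$table$ss[2] + fit$errors$within$ss))
  # an effect with SS_effect = SS_error has partial eta squared 0.5
  expect_equal(0.3 / (0.3 + 0.3), 0.5)

  lt2 <- lt; lt2$value <- 7 - 3 * lt$value
  fit2 <- mixed_anova(lt2)
  expect_equal(fit2$table$partial_eta_sq, fit$table$partial_eta_sq,
               tolerance = 1e-9)
  expect_equal(fit2$table$F, fit$table$F, tolerance = 1e-9)
  expect_equal(fit2$table[, c("eta_ci_lo", "eta_ci_hi")],
               fit$table[, c("eta_ci_lo", "eta_ci_hi")], tolerance = 1e-7)
})

test_that("eta-squared confidence intervals invert the noncentral F", {
  ci <- partial_eta_ci(10, 5, 100)
  lam <- function(eta) eta / (1 - eta) * (5 + 100 + 1)
  expect_equal(pf(10, 5, 100, ncp = lam(ci[1])), 0.975, tolerance = 1e-6)
  expect_equal(pf(10, 5, 100, ncp = lam(ci[2])), 0.025, tolerance = 1e-6)
  # tiny F: lower bound clamps to zero
  expect_equal(partial_eta_ci(0.1, 5, 100)[1], 0)
})

test_that("simple main effects use pooled error terms and Bonferroni thresholds", {
  # a strong phase effect in group A only, small iid noise
  withr::with_seed(13, {
    p <- 6; n <- 12
    eff <- c(0, 0, 1, 2, 3, 4)
    value <- c(rep(eff, n), rep(0, n * p)) + rnorm(2 * n * p, sd = 0.5)
    lt <- long_table(subject = rep(1:(2 * n), each = p),
                     between = rep(c("A", "B"), each = n * p),
                     within = rep(paste0("w", 1:p), 2 * n),
                     value = value)
  })
  fit <- mixed_anova(lt)
  sme <- simple_main_effects(fit, "within-at-between", alpha = 0.01)
  expect_equal(sme$threshold, rep(0.005, 2))
  expect_true(sme$significant[sme$slice == "A"])
  expect_false(sme$significant[sme$slice == "B"])
  expect_equal(sme$df2, rep(fit$errors$within$df, 2))

  smb <- simple_main_effects(fit, "between-at-within", alpha = 0.01)
  expect_equal(smb$threshold, rep(0.01 / 6, 6))
  expect_equal(smb$df2, rep(fit$errors$between$df, 6))

  # identical slices give identical F
  fit2 <- mixed_anova(long_table(lt$subject, lt$between, lt$within,
                                 rep(lt$value[1:(n * p)], 2)))
  sme2 <- simple_main_effects(fit2, "within-at-between")
  expect_equal(sme2$F[1], sme2$F[2], tolerance = 1e-9)
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      a <- rnorm(8); b <- rnorm(10, mean = rep * 0.3)
      ph <- tukey_hsd(c(a, b), rep(c("x", "y"), c(8, 10)))
      tt <- t.test(a, b, var.equal = TRUE)
      expect_equal(ph$p_adj, tt$p.value, tolerance = 1e-9)
      expect_equal(ph$q, sqrt(2) * abs(tt$statistic), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("Tukey HSD matches the reference implementation on a one-way layout", {
  withr::with_seed(8, {
    value <- rnorm(40, mean = rep(c(0, 0.5, 1, 2), each = 10))
    level <- factor(rep(paste0("L", 1:4), each = 10))
  })
  ours <- tukey_hsd(value, level)
  ref <- TukeyHSD(aov(value ~ level))$level
  expect_equal(nrow(ours), 6)
  key <- paste0(ours$level_b, "-", ours$level_a)
  expect_equal(ours$p_adj, ref[key, "p adj"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ours$mean_diff, ref[key, "diff"], ignore_attr = TRUE)
})

test_that("Tukey HSD handles equal means, level counts and bad input", {
  ph <- tukey_hsd(rep(c(1, 1, 1), each = 4) + rep(c(0.001, -0.001), 6),
                  rep(c("a", "b", "c"), each = 4))
  expect_true(all(ph$p_adj > 0.99))
  ph6 <- tukey_hsd(rnorm(36), rep(paste0("p", 1:6), each = 6))
  expect_equal(nrow(ph6), choose(6, 2))
  expect_error(tukey_hsd(1:3, c("a", "a", "b")),
               class = "mobilekin_insufficient_data")
})

test_that("through-origin regression matches its closed form", {
  x <- c(1, 2, 3); expect_equal(origin_regression(x, 2 * x), c(coef = 2))
  expect_equal(origin_regression(c(1, 0), c(0, 5)), c(coef = 0))
  withr::with_seed(4, {
    x <- rnorm(50); y <- 1.3 * x + rnorm(50)
    g <- rep(c("2mo", "3mo"), 25)
    ours <- origin_regression(x, y, g)
    for (lev in c("2mo", "3mo")) {
      ref <- unname(coef(lm(y ~ 0 + x, subset = g == lev)))
      expect_equal(unname(ours[lev]), ref, tolerance = 1e-12)
    }
  })
  expect_error(origin_regression(c(0, 0), c(1, 2)),
               class = "mobilekin_degenerate_baseline")
})

test_that("the 1.5x learning criterion flags the right subjects", {
  flat <- data.frame(block = c("B", paste0("P", 1:5)), mean = rep(1, 6))
  expect_false(learner_flag(flat))
  boundary <- flat; boundary$mean[4] <- 1.5
  expect_true(learner_flag(boundary))  # >= convention at the boundary
  # baseline block alone never triggers the flag
  basehigh <- flat; basehigh$mean[1] <- 3
  expect_false(learner_flag(basehigh))
  # a synthetic cluster-4 infant is a learner
  bm <- block_means(cluster4_session()$curves$ConA$ratio)
  expect_true(learner_flag(data.frame(block = bm$block, mean = bm$mean)))
})
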