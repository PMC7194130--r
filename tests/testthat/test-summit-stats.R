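test_that("richness per quadrat counts distinct species", {
  obs <- data.frame(summit_id = "GUL1", aspect = "N", quadrat_index = 1,
                    year = 2014, species_id = c("a", "b", "c"),
                    cover = c(1, 2, 3), stringsAsFactors = FALSE)
  r <- richness_per_quadrat(obs)
  expect_equal(r$richness, 3)
  # duplicate species in a quadrat is impossible upstream
  dup <- rbind(obs, obs[1, ])
  expect_error(richness_per_quadrat(dup), "duplicated")
})

test_that("group summaries aggregate consistently across levels", {
  sv <- generate_survey(survey_design(seed = 19))
  rich <- richness_per_quadrat(sv$observations)
  r14 <- rich[rich$year == 2014, ]
  by_summit <- group_summary(r14, "richness", "summit_id")
  by_aspect <- group_summary(r14, "richness", c("summit_id", "aspect"))
  for (s in by_summit$summit_id) {
    asp <- by_aspect[by_aspect$summit_id == s, ]
    expect_equal(by_summit$mean[by_summit$summit_id == s],
                 weighted.mean(asp$mean, asp$n))
  }
  expect_equal(by_summit$se,
               tapply(r14$richness, r14$summit_id,
                      function(x) sd(x) / sqrt(length(x)))[by_summit$summit_id],
               ignore_attr = TRUE)
})

test_that("cover change is simple subtraction with absent-as-zero", {
  base <- expand.grid(summit_id = "GUL1", aspect = c("N", "S", "E", "W"),
                      quadrat_index = 1:4, stringsAsFactors = FALSE)
  mk <- function(year, cover) {
    cbind(base, year = year, species_id = "sh", cover = cover)
  }
  # identical covers both years: delta 0, SE 0
  obs0 <- rbind(mk(2014, 5), mk(2018, 5))
  t0 <- cover_change_table(obs0)
  expect_equal(t0$mean_change, 0)
  expect_equal(t0$se_change, 0)
  # +2 percent in all 16 quadrats
  obs2 <- rbind(mk(2014, 5), mk(2018, 7))
  t2 <- cover_change_table(obs2)
  expect_equal(t2$mean_change, 2)
  expect_equal(t2$se_change, 0)
  expect_equal(t2$n_quadrats, 16)
  # species absent in one year contributes from/to zero
  gain <- rbind(mk(2014, 5)[1:8, ], mk(2018, 5))
  tg <- cover_change_table(gain)
  expect_equal(tg$mean_change, mean(c(rep(0, 8), rep(5, 8))))
})

test_that("grand total cover change equals the difference of year totals", {
  sv <- generate_survey(survey_design(seed = 29))
  obs <- as.data.frame(sv$observations)
  tab <- cover_change_table(obs)
  grand <- sum(tab$mean_change * tab$n_quadrats)
  expect_equal(grand,
               sum(obs$cover[obs$year == 2018]) -
                 sum(obs$cover[obs$year == 2014]),
               tolerance = 1e-9)
})

test_that("recovery: an imposed +3 percent shrub gain is estimated", {
  base <- expand.grid(summit_id = c("GUL1", "GUL2"),
                      aspect = c("N", "S", "E", "W"),
                      quadrat_index = 1:4, stringsAsFactors = FALSE)
  ests <- vapply(1:40, function(s) {
    set.seed(6000 + s)
    c1 <- pmax(0.5, rnorm(nrow(base), 10, 1))
    obs <- rbind(cbind(base, year = 2014, species_id = "sh", cover = c1),
                 cbind(base, year = 2018, species_id = "sh",
                       cover = c1 + rnorm(nrow(base), 3, 1)))
    cover_change_table(obs)$mean_change
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 3), 3 * se)
})

test_that("ANOVA reduces to the squared t statistic for two groups", {
  set.seed(11)
  d <- data.frame(summit_id = rep(c("GUL1", "GUL2"), each = 4),
                  aspect = "N", year = 2014, stringsAsFactors = FALSE)
  y <- c(rnorm(4, 0, 1), rnorm(4, 10, 1))
  an <- factor_effects(y, d, "oneway_nested")
  tt <- t.test(y ~ d$summit_id, var.equal = TRUE)
  expect_equal(an$statistic[an$term == "summit"],
               unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("ANOVA handles both designs and their degeneracies", {
  sv <- generate_survey(survey_design(seed = 37))
  rich <- richness_per_quadrat(sv$observations)
  r14 <- rich[rich$year == 2014, ]
  an1 <- factor_effects(r14$richness, r14, "oneway_nested")
  expect_setequal(an1$term, c("summit", "summit:aspect", "Residuals"))
  expect_equal(an1$df[an1$term == "summit"], 3)
  expect_equal(an1$df[an1$term == "summit:aspect"], 12)
  an2 <- factor_effects(rich$richness, rich, "twoway_interaction")
  expect_setequal(an2$term, c("summit", "year", "summit:year", "Residuals"))
  # constant response: all term F = 0, p = 1
  flat <- factor_effects(rep(4, nrow(r14)), r14, "oneway_nested")
  expect_true(all(flat$statistic[flat$term != "Residuals"] == 0))
  expect_true(all(flat$p_value[flat$term != "Residuals"] == 1))
  # single replicate per cell: no residual df for the interaction model
  one <- rich[rich$aspect == "N" & rich$quadrat_index == 1, ]
  expect_error(factor_effects(one$richness, one, "twoway_interaction"),
               "residual")
  # empty cell warning
  holey <- r14[!(r14$summit_id == "GUL1" & r14$aspect == "N"), ]
  expect_warning(factor_effects(holey$richness, holey, "oneway_nested"),
                 "empty cell")
})

test_that("ANOVA p-values are uniform under exchangeable null data", {
  pvals <- vapply(1:150, function(s) {
    set.seed(7000 + s)
    d <- expand.grid(quadrat = 1:4, aspect = c("N", "S", "E", "W"),
                     summit_id = c("GUL1", "GUL2", "GUL3", "GUL4"),
                     stringsAsFactors = FALSE)
    an <- factor_effects(rnorm(nrow(d)), d, "oneway_nested")
    an$p_value[an$term == "summit"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Tukey comparisons are family-wise conservative", {
  set.seed(13)
  g <- rep(c("a", "b", "c"), each = 8)
  # identical means: all adjusted p near 1
  y0 <- rnorm(24)
  tk0 <- tukey_posthoc(y0 + 0 * (g == "b"), g)
  expect_equal(nrow(tk0), 3)
  # one group shifted by 10 within-SDs
  y1 <- rnorm(24) + 10 * (g == "c")
  tk1 <- tukey_posthoc(y1, g)
  expect_true(all(tk1$p_adjusted[grepl("c", tk1$comparison)] < 0.001))
  expect_gt(tk1$p_adjusted[tk1$comparison == "b-a"], 0.05)
  # adjusted p >= unadjusted pairwise p
  pt <- pairwise.t.test(y1, g, p.adjust.method = "none")$p.value
  unadj <- c(pt["b", "a"], pt["c", "a"], pt["c", "b"])
  expect_true(all(tk1$p_adjusted >= unadj - 1e-12))
  # a level with a single observation is rejected by name
  expect_error(tukey_posthoc(y1[-(9:15)], g[-(9:15)]), "b")
})

test_that("assumption checks flag variance heterogeneity and heavy tails", {
  set.seed(14)
  g <- rep(c("a", "b"), each = 16)
  ok <- assumption_checks(rnorm(32), g)
  expect_true(ok$shapiro$p_value > 0 && ok$levene$p_value > 0)
  expect_error(assumption_checks(rep(1, 32), g), "constant")
  # Levene power: one group's SD 5x the other, n = 16 per group
  lev_rej <- vapply(1:40, function(s) {
    set.seed(8000 + s)
    y <- c(rnorm(16, 0, 1), rnorm(16, 0, 5))
    assumption_checks(y, g)$levene$p_value < 0.01
  }, logical(1))
  expect_gt(mean(lev_rej), 0.75)
  # Shapiro power against t2 residuals at n = 64
  sw_rej <- vapply(1:40, function(s) {
    set.seed(8500 + s)
    y <- rt(64, df = 2)
    assumption_checks(y, rep(c("a", "b"), each = 32))$shapiro$p_value < 0.05
  }, logical(1))
  expect_gt(mean(sw_rej), 0.35)
})
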