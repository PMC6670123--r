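test_that("chi-square matches hand computation and handles degeneracies", {
  # eye laterality by group: statistic by direct sum((O-E)^2/E)
  tab <- ref_cohort_summaries()$categorical_counts$eye
  res <- chi_square(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$statistic, 0.2278, tolerance = 1e-3)
  expect_equal(res$df, 2)

  expect_equal(chi_square(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square(matrix(10, 2, 2))$p_value, 1)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, 2)), "zero row")
  expect_error(chi_square(matrix(1:4, 1, 4)), "2 rows")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
})

test_that("chi-square p agrees with a multinomial Monte-Carlo oracle", {
  # independence null with margins of the observed table; expected counts
  # kept >= 5 so the asymptotic reference applies
  withr::with_seed(42, {
    for (rep in 1:3) {
      repeat {
        tab <- matrix(rmultinom(1, 40, c(0.3, 0.2, 0.25, 0.25)), 2, 2)
        e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (all(e >= 5)) break
      }
      obs <- chi_square(tab)
      pr <- as.vector(outer(rowSums(tab) / sum(tab),
                            colSums(tab) / sum(tab)))
      sims <- rmultinom(1e5, sum(tab), pr)
      x2s <- apply(sims, 2, function(v) {
        t2 <- matrix(v, 2, 2)
        e2 <- outer(rowSums(t2), colSums(t2)) / sum(t2)
        if (any(e2 == 0)) return(NA_real_)
        sum((t2 - e2)^2 / e2)
      })
      p_mc <- mean(x2s >= obs$statistic - 1e-12, na.rm = TRUE)
      expect_lt(abs(obs$p_value - p_mc), 0.03)
    }
  })
})

test_that("pooled t from summaries equals a raw-data pooled t-test", {
  a <- summary_stats(5.47, 5.34, 90)
  b <- summary_stats(7.02, 5.65, 36)
  res <- pooled_t_from_summary(a, b)
  expect_equal(abs(res$statistic), 1.448, tolerance = 1e-3)
  expect_equal(res$df, 124)

  # engineer raw samples with those exact summaries; compare to t.test
  mk <- function(n, m, s) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  withr::with_seed(8, {
    x <- mk(90, 5.47, 5.34); y <- mk(36, 7.02, 5.65)
  })
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)

  same <- pooled_t_from_summary(summary_stats(3, 1, 10),
                                summary_stats(3, 1, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(pooled_t_from_summary(summary_stats(3, 0, 5),
                                     summary_stats(3, 0, 5))$p_value, 1)
  expect_warning(
    z <- pooled_t_from_summary(summary_stats(3, 0, 5),
                               summary_stats(4, 0, 5)),
    "zero pooled variance")
  expect_equal(z$p_value, 0)
  expect_error(summary_stats(1, -1, 5), "non-negative")
  expect_error(summary_stats(1, 1, 1), "at least 2")
})

test_that("one-way ANOVA matches R's reference and a permutation oracle", {
  g <- withr::with_seed(3, list(rnorm(12), rnorm(12, 0.5), rnorm(12, 0.2)))
  res <- one_way_anova(g)
  y <- unlist(g); f <- factor(rep(1:3, each = 12))
  ref <- anova(lm(y ~ f))
  expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # permutation oracle
  perm <- withr::with_seed(5, replicate(2e4, {
    one_way_anova(split(y, sample(f)))$statistic
  }))
  expect_lt(abs(mean(perm >= res$statistic) - res$p_value), 0.01)

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1:3, 2)), "at least 2")
})

test_that("summary-statistics ANOVA equals raw ANOVA and t^2 for k = 2", {
  g <- withr::with_seed(9, list(rnorm(20, 0), rnorm(15, 1), rnorm(30, 0.3)))
  raw <- one_way_anova(g)
  summ <- anova_from_summary(lapply(g, function(x)
    summary_stats(mean(x), sd(x), length(x))))
  expect_equal(summ$statistic, raw$statistic, tolerance = 1e-10)
  expect_equal(summ$p_value, raw$p_value, tolerance = 1e-10)

  # F = t^2 for two groups
  a <- summary_stats(5.47, 5.34, 90); b <- summary_stats(7.02, 5.65, 36)
  f2 <- anova_from_summary(list(a, b))
  t2 <- pooled_t_from_summary(a, b)
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-10)

  flat <- anova_from_summary(list(summary_stats(2, 1, 5),
                                  summary_stats(2, 2, 8)))
  expect_equal(flat$statistic, 0)
})

test_that("multiple regression: exact fits, rank checks, complete cases", {
  co <- generate_cohort(cohort_spec(seed = 4))
  diab <- co[co$group != "control", ]
  diab$y <- 50 - 0.1 * diab$age
  # a noise-free response makes summary.lm warn about the perfect fit
  fit <- suppressWarnings(
    multiple_regression(diab, "y", c("age", "bmi", "hba1c")))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "age"], -0.1, tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "bmi"], 0, tolerance = 1e-8)
  expect_equal(fit$n_used, 126)

  diab$age2 <- diab$age
  expect_error(multiple_regression(diab, "y", c("age", "age2")),
               "rank deficient.*age2")
  expect_error(multiple_regression(diab, "y", c("age", "nope")),
               "not in cohort")

  diab$bmi[1:10] <- NA
  fit2 <- suppressWarnings(multiple_regression(diab, "y", c("age", "bmi")))
  expect_equal(fit2$n_used, 116)
  expect_equal(fit2$n_dropped, 10)
})

test_that("dichotomization reproduces composition bookkeeping", {
  # a cohort with exactly 53 NDR + 12 MDR below the age cutoff
  co <- data.frame(
    group = c(rep("control", 10), rep("ndr", 90), rep("mdr", 36)),
    age = c(rep(60, 10), rep(40, 53), rep(70, 37), rep(40, 12), rep(70, 24)))
  d <- dichotomize(co, subgroup_rule("age", 55, "y"))
  expect_equal(nrow(d$low), 65)
  expect_equal(d$composition["low", "ndr_pct"], 81.5)
  expect_equal(d$composition["low", "mdr_pct"], 18.5)
  # arm sizes always sum to the non-missing diabetic rows
  expect_equal(nrow(d$low) + nrow(d$high), 126)

  # ties go to the high arm
  co$age[11] <- 55
  d2 <- dichotomize(co, subgroup_rule("age", 55, "y"))
  expect_equal(nrow(d2$low), 64)
  expect_equal(nrow(d2$high), 62)

  # missing values are excluded from both arms
  co$age[12] <- NA
  expect_message(d3 <- dichotomize(co, subgroup_rule("age", 55, "y")),
                 "1 diabetic rows")
  expect_equal(nrow(d3$low) + nrow(d3$high), 125)
  expect_equal(d3$n_missing, 1)

  # a degenerate arm is flagged with NA composition
  co2 <- data.frame(group = rep("ndr", 5), age = rep(30, 5))
  d4 <- dichotomize(co2, subgroup_rule("age", 55, "y"))
  expect_true(is.na(d4$composition["high", "ndr_pct"]))
  expect_error(dichotomize(co2, subgroup_rule("height", 1.7)),
               "not in the cohort")
  expect_error(subgroup_rule("age", Inf), "finite")
})

test_that("subgroup analysis produces a complete per-rule, per-layer report", {
  co <- generate_cohort(cohort_spec(seed = 6))
  rep <- suppressMessages(
    subgroup_analysis(co, rules = list(subgroup_rule("age", 55, "y"),
                                       subgroup_rule("hba1c", 7, "%"))))
  expect_equal(nrow(rep), 4)  # 2 rules x 2 layers
  expect_true(all(c("p_low_vs_control", "p_high_vs_control",
                    "p_low_vs_high") %in% names(rep)))
  expect_true(all(rep$n_low + rep$n_high == 126))
  expect_true(all(rep$flag_low %in% c("", "a", "b", "c")))

  expect_equal(nrow(subgroup_analysis(co, rules = list())), 0)
  # an untestable arm yields NA p-values
  co_small <- co[co$group == "control" | co$age < 50, ]
  rep2 <- suppressMessages(subgroup_analysis(
    co_small, rules = list(subgroup_rule("age", 100, "y"))))
  expect_true(all(is.na(rep2$p_low_vs_high)))
})
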