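test_that("postnatal days map to the four age bins with gaps out of range", {
  expect_equal(ageBin(c(30, 35)), c(1, 1))
  expect_equal(ageBin(c(36, 42)), c(1.5, 1.5))
  expect_equal(ageBin(c(44, 58)), c(2, 2))
  expect_equal(ageBin(c(64, 103)), c(3, 3))
  expect_true(all(is.na(ageBin(c(29, 43, 59, 63, 104, 200)))))
  expect_error(ageBin(0))
})

test_that("session summaries average calls and count voicing percentages", {
  mk <- function(cls, f0) data.frame(
    call_id = 1, onset_s = 0, offset_s = 1, duration_s = 1, call_class = cls,
    voiced_frac = 1, level_db = 70,
    f0_mean = f0, f0_max = f0, f0_sd = 0, t_f0max_s = 0.1,
    hr_mean = 2, hr_sd = 0, hr_max = 2, t_hrmax_s = 0.1, hr_at_f0max = 2)

  one <- summarizeSession(mk("voiced", 1000), postnatalDay = 33)
  expect_equal(one$n_calls, 1)
  expect_equal(one$f0_mean, 1000)
  expect_equal(one$age_bin, 1)

  two <- summarizeSession(rbind(mk("voiced", 900), mk("voiced", 1100)))
  expect_equal(two$f0_mean, 1000)

  feats <- do.call(rbind, c(replicate(8, mk("voiced", 1000), simplify = FALSE),
                            replicate(2, mk("unvoiced", NA), simplify = FALSE)))
  expect_equal(summarizeSession(feats)$pct_voiced, 80)

  expect_error(summarizeSession(mk("voiced", 1000)[0, ]), "empty")
})

test_that("grand means are means of session means, not call-weighted", {
  s <- data.frame(session_id = c("a", "b"), animal_id = "x",
                  group = "hearing", postnatal_day = c(33, 70),
                  age_bin = c(1, 3), n_calls = c(10, 1000),
                  pct_voiced = c(80, 90), duration_s = c(0.4, 0.8),
                  level_db = c(60, 80), f0_mean = c(1100, 800))
  g <- grandMeans(s)
  expect_equal(g$duration_s, 0.6)   # unweighted by n_calls
  expect_equal(g$f0_mean, 950)
  expect_equal(g$level_db, 70)
})

test_that("normality statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(9)
  for (x in list(rnorm(50), rexp(40), runif(200), rnorm(8))) {
    ours <- normalityTest(x)
    ref <- nortest::ad.test(x)
    expect_equal(ours$statistic, unname(ref$statistic) *
                   (1 + 0.75 / length(x) + 2.25 / length(x)^2),
                 tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("normality test flags degenerate and skewed samples", {
  expect_false(normalityTest(rep(3, 20))$pass)
  expect_error(normalityTest(1:4), "at least 5")

  set.seed(17)
  fails <- vapply(1:100, function(i) !normalityTest(rexp(100))$pass,
                  logical(1))
  expect_gte(mean(fails), 0.95)

  # chi-square alternative behaves sanely
  expect_true(normalityTest(rnorm(500), method = "chisq")$pass)
  expect_false(normalityTest(rexp(500), method = "chisq")$pass)
})

test_that("group comparison reproduces closed-form t and F values", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  cmp <- compareGroups(a, b)
  tRow <- cmp[cmp$test == "t_two_tailed", ]
  fRow <- cmp[cmp$test == "f_var", ]
  # hand computation: means 3 and 4, pooled variance 2.5,
  # t = -1 / sqrt(2.5 * 2/5) = -1, df = 8, p = 2 P(T8 < -1)
  expect_equal(tRow$statistic, -1)
  expect_equal(tRow$df, 8)
  expect_equal(tRow$p_value, 2 * pt(-1, 8))
  expect_equal(fRow$statistic, 1)

  # F test two-sided p agrees with stats::var.test
  set.seed(3)
  x <- rnorm(12, sd = 2); y <- rnorm(15)
  ours <- compareGroups(x, y)
  expect_equal(ours$p_value[ours$test == "f_var"],
               var.test(x, y)$p.value, tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  same <- compareGroups(a, a)
  expect_equal(same$statistic[same$test == "t_two_tailed"], 0)
  expect_equal(same$p_value[same$test == "t_two_tailed"], 1)

  expect_error(compareGroups(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(compareGroups(1, 1:5), "at least 2")
})

test_that("clearly separated samples are detected with high power", {
  set.seed(8)
  sig <- vapply(1:100, function(i) {
    a <- rnorm(20); b <- rnorm(20, mean = 3)
    cmp <- compareGroups(a, b)
    cmp$p_value[cmp$test == "t_two_tailed"] < 0.001
  }, logical(1))
  expect_gte(mean(sig), 0.99)
})

test_that("developmental table compares across ages and groups", {
  set.seed(14)
  s <- expand.grid(rep = 1:4, group = c("hearing", "deaf"),
                   age_bin = c(1, 1.5, 2, 3), stringsAsFactors = FALSE)
  s$session_id <- paste0("s", seq_len(nrow(s)))
  s$f0_mean <- 1200 - 100 * s$age_bin + rnorm(nrow(s), 0, 10)
  s$level_db <- 70 + 10 * (s$group == "deaf") + rnorm(nrow(s), 0, 1)
  tab <- developmentalTable(s, features = c("f0_mean", "level_db"))
  expect_true(all(c("age_within_group", "group_within_age") %in%
                  tab$comparison))
  # age comparisons: 2 groups x 3 consecutive pairs x 2 tests per feature
  ageRows <- tab[tab$comparison == "age_within_group" &
                 tab$feature == "f0_mean", ]
  expect_equal(nrow(ageRows), 2 * 3 * 2)
  # the programmed level offset is significant within every age bin
  lev <- tab[tab$comparison == "group_within_age" &
             tab$feature == "level_db" & tab$test == "t_two_tailed", ]
  expect_equal(nrow(lev), 4)
  expect_true(all(lev$p_value < 0.05))

  expect_error(developmentalTable(s[s$age_bin == 1, ]), "age bins")
})
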