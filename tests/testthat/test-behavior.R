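# tiny trial list for simulator tests: n trials per rule x correctness
toy_trials <- function(n) {
  expand.grid(rule = c("recursion", "iteration", "repetition"),
              correctness = c("correct", "foil"),
              i = seq_len(n), stringsAsFactors = FALSE)[, 1:2]
}

test_that("the simulated responder matches equal-variance SDT closed forms", {
  trials <- toy_trials(2000)
  # zero sensitivity: long-run accuracy at chance
  rec0 <- simulate_responses(trials, sdt_config(dprime = c(
    recursion = 0, iteration = 0, repetition = 0)), seed = 4)
  expect_lt(abs(mean(rec0$accurate) - 0.5), 0.02)
  # extreme sensitivity: accuracy saturates
  rec20 <- simulate_responses(trials, sdt_config(dprime = c(
    recursion = 20, iteration = 20, repetition = 20)), seed = 4)
  expect_gt(mean(rec20$accurate), 0.999)
  # d' = 1, unbiased: hit rate pnorm(0.5) ~ 0.691
  rec1 <- simulate_responses(trials, sdt_config(dprime = c(
    recursion = 1, iteration = 1, repetition = 1)), seed = 4)
  hits <- rec1[rec1$correctness == "correct", ]
  expect_lt(abs(mean(hits$response == "correct-judgement") - pnorm(0.5)),
            0.02)
  # RT contract: capped, positive
  expect_true(all(rec1$rt > 0 & rec1$rt <= 5))
  # determinism
  expect_identical(rec1, simulate_responses(trials, sdt_config(dprime = c(
    recursion = 1, iteration = 1, repetition = 1)), seed = 4))
})

test_that("d-prime matches normal-quantile hand computations", {
  # H = 0.9, F = 0.1: d' = 2 * qnorm(0.9) = 2.563103
  make_cell <- function(hits, n_sig, fas, n_noi) {
    data.frame(subject = 1, rule = "recursion",
               correctness = rep(c("correct", "foil"), c(n_sig, n_noi)),
               response = c(rep("correct-judgement", hits),
                            rep("foil-judgement", n_sig - hits),
                            rep("correct-judgement", fas),
                            rep("foil-judgement", n_noi - fas)))
  }
  rec <- make_cell(9, 10, 1, 10)
  # 0.9 and 0.1 survive the halfcount correction untouched
  expect_equal(compute_dprime(rec, "halfcount")$dprime, 2.563103,
               tolerance = 1e-6)
  # perfect separation, log-linear correction: qnorm(12.5/13) - qnorm(0.5/13)
  perf <- make_cell(12, 12, 0, 12)
  expect_equal(compute_dprime(perf, "loglinear")$dprime, 3.537650,
               tolerance = 1e-6)
  expect_equal(compute_dprime(perf, "halfcount")$dprime,
               qnorm(1 - 1 / 24) - qnorm(1 / 24), tolerance = 1e-9)
  # H = F gives zero sensitivity
  even <- make_cell(5, 10, 5, 10)
  expect_equal(compute_dprime(even, "halfcount")$dprime, 0)
  # antisymmetry under swapping hits and false alarms
  swapped <- make_cell(1, 10, 9, 10)
  expect_equal(compute_dprime(swapped, "halfcount")$dprime,
               -compute_dprime(rec, "halfcount")$dprime)
  # empty cell errors
  empty <- rec[rec$correctness == "correct", ]
  expect_error(compute_dprime(empty), "at least one")
})

test_that("behavior summaries report per-cell and group statistics", {
  trials <- toy_trials(12)
  rec <- simulate_responses(trials, sdt_config(), seed = 9, subjects = 4)
  s <- summarize_behavior(rec)
  expect_identical(nrow(s$per_cell), 12L)  # 4 subjects x 3 rules
  expect_identical(nrow(s$group), 3L)
  expect_true(all(s$per_cell$hit_rate > 0 & s$per_cell$hit_rate < 1))
  expect_true(all(s$per_cell$mean_rt <= 5))
  # all-correct records give accuracy 1
  rec$accurate <- TRUE
  rec$response <- ifelse(rec$correctness == "correct", "correct-judgement",
                         "foil-judgement")
  expect_true(all(summarize_behavior(rec)$per_cell$accuracy == 1))
})

test_that("group d-prime recovers the generative sensitivities", {
  # moderate-scale recovery check (the full-scale one runs in acceptance)
  gen <- c(recursion = 1.1, iteration = 0.9, repetition = 1.3)
  trials <- toy_trials(12)  # 24 trials per rule, as in one 4-session plan
  est <- rowMeans(vapply(1:40, function(r) {
    rec <- simulate_responses(trials, sdt_config(dprime = gen),
                              seed = 1000 + r, subjects = 15)
    s <- compute_dprime(rec)
    vapply(split(s$dprime, s$rule), mean, numeric(1))
  }, numeric(3)))
  expect_true(all(abs(est[names(gen)] - gen) < 0.15))
})

test_that("repeated-measures ANOVA reproduces hand and aov computations", {
  # 4-subject toy table, hand sums of squares
  m <- matrix(c(1.0, 1.2, 0.8,
                0.6, 0.9, 0.7,
                1.4, 1.5, 1.1,
                0.9, 1.1, 0.8), nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("recursion", "iteration", "repetition")))
  res <- rm_anova_oneway(m)
  expect_identical(c(res$df1, res$df2), c(2L, 6L))
  grand <- mean(m)
  ss_cond <- 4 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_cond - ss_subj
  expect_equal(res$F, (ss_cond / 2) / (ss_err / 6))
  # independent cross-check against stats::aov with subject error stratum
  long <- data.frame(y = as.vector(m),
                     cond = factor(rep(colnames(m), each = 4)),
                     subj = factor(rep(1:4, times = 3)))
  aov_tab <- summary(stats::aov(y ~ cond + Error(subj), data = long))
  aov_row <- aov_tab[["Error: Within"]][[1]]["cond", ]
  expect_equal(res$F, aov_row[["F value"]], tolerance = 1e-12)
  expect_equal(res$p, aov_row[["Pr(>F)"]], tolerance = 1e-12)
  # degenerate cases
  same <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  expect_equal(rm_anova_oneway(same)$F, 0)
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3, 4, 5), 2)), "missing")
  # 15 subjects x 3 rules gives the design's F(2, 28)
  res15 <- rm_anova_oneway(matrix(rnorm(45), nrow = 15))
  expect_identical(c(res15$df1, res15$df2), c(2L, 28L))
})

test_that("pairwise post-hocs adjust p values and find planted differences", {
  set.seed(99)
  m <- cbind(recursion = rnorm(15, 1.0, 0.2),
             iteration = rnorm(15, 1.0, 0.2),
             repetition = rnorm(15, 2.0, 0.2))
  ph <- posthoc_pairwise(m)
  expect_identical(nrow(ph), 3L)
  expect_true(all(ph$p_adj >= ph$p))
  sig <- ph$p_adj < 0.05
  involves_rep <- ph$a == "repetition" | ph$b == "repetition"
  expect_true(all(sig[involves_rep]))
  expect_false(any(sig[!involves_rep]))
})
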