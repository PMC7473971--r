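#' Signal-detection configuration for the simulated responder
#'
#' Equal-variance signal detection: on trials with a correct fourth step the
#' decision evidence is drawn from `Normal(dprime_rule, 1)`, on foil trials
#' from `Normal(0, 1)`; the simulated participant judges the test sound
#' correct whenever evidence exceeds `dprime/2 + criterion`. The criterion is
#' thus the standard bias measure c: at `c = 0` the responder is unbiased
#' (hit rate `pnorm(dprime/2)`, false-alarm rate `pnorm(-dprime/2)`),
#' accuracy is 0.5 at `dprime = 0` and approaches 1 as `dprime` grows.
#' Response times are
#' lognormal with a per-rule median, capped at the decision limit. The
#' default sensitivities and RT medians sit in the range reported for trained
#' non-musicians on this paradigm (d' roughly 0.9-1.3, RTs 0.6-0.8 s).
#'
#' @param dprime Named numeric: generative sensitivity per rule.
#' @param criterion Named numeric or scalar: decision criterion per rule.
#' @param rt_median Named numeric: median RT per rule, s.
#' @param rt_sdlog Lognormal sdlog of RTs.
#' @param rt_cap Decision cap, s.
#' @return An object of class `sdt_config`.
#' @export
sdt_config <- function(dprime = c(recursion = 1.06, iteration = 0.88,
                                  repetition = 1.31),
                       criterion = 0,
                       rt_median = c(recursion = 0.78, iteration = 0.74,
                                     repetition = 0.58),
                       rt_sdlog = 0.35, rt_cap = 5) {
  if (any(!is.finite(dprime)) || any(dprime < 0))
    stop("dprime must be finite and non-negative")
  if (rt_sdlog <= 0) stop("rt_sdlog must be positive")
  if (length(criterion) == 1L && is.null(names(criterion)))
    criterion <- stats::setNames(rep(criterion, length(dprime)),
                                 names(dprime))
  structure(list(dprime = dprime, criterion = criterion,
                 rt_median = rt_median, rt_sdlog = rt_sdlog, rt_cap = rt_cap),
            class = "sdt_config")
}

#' Simulate button-press responses for an experiment plan
#'
#' One simulated participant per subject under the equal-variance
#' signal-detection model of [sdt_config()]. Deterministic given the seed.
#'
#' @param plan An `experiment_plan`, or a plain `data.frame` with columns
#'   `rule` and `correctness` (one row per trial) for simulation studies.
#' @param cfg An [sdt_config].
#' @param seed Integer seed.
#' @param subjects Number of simulated participants (each gets an independent
#'   pass over the same trial list).
#' @return `data.frame` of class `response_records`: one row per subject x
#'   trial with the trial's rule and correctness, the judgement
#'   (`"correct-judgement"` / `"foil-judgement"`), whether the response was
#'   accurate, and the response time in seconds.
#' @export
simulate_responses <- function(plan, cfg = sdt_config(), seed = 1L,
                               subjects = 1L) {
  trials <- if (inherits(plan, "experiment_plan")) plan$trials else plan
  stopifnot(all(c("rule", "correctness") %in% names(trials)))
  n <- nrow(trials)
  rules <- trials$rule
  dp <- cfg$dprime[rules]
  crit <- cfg$criterion[rules]
  if (anyNA(dp)) stop("sdt_config lacks a dprime for some rule in the plan")
  signal <- trials$correctness == "correct"
  with_seed(seed, {
    out <- lapply(seq_len(subjects), function(s) {
      evidence <- stats::rnorm(n, mean = ifelse(signal, dp, 0), sd = 1)
      say_correct <- evidence > dp / 2 + crit
      rt <- pmin(stats::rlnorm(n, meanlog = log(cfg$rt_median[rules]),
                               sdlog = cfg$rt_sdlog), cfg$rt_cap)
      data.frame(subject = s, trial = seq_len(n), rule = rules,
                 correctness = trials$correctness,
                 response = ifelse(say_correct, "correct-judgement",
                                   "foil-judgement"),
                 accurate = say_correct == signal, rt = rt,
                 row.names = NULL)
    })
    records <- do.call(rbind, out)
    class(records) <- c("response_records", "data.frame")
    records
  })
}

#' Sensitivity (d-prime) per subject and rule
#'
#' `d' = z(H) - z(F)` with `H` the hit rate (judging correct trials correct)
#' and `F` the false-alarm rate (judging foils correct), under the
#' equal-variance Gaussian model. Extreme rates of 0 or 1 are handled by the
#' configured correction: `"loglinear"` adds 0.5 to each count and 1 to each
#' N before forming rates; `"halfcount"` replaces 0 with `1/(2N)` and 1 with
#' `1 - 1/(2N)`.
#'
#' @param records A `response_records` data frame.
#' @param correction `"loglinear"` (default) or `"halfcount"`.
#' @return `data.frame` with one row per subject x rule: `n_signal`,
#'   `n_noise`, `hit_rate`, `fa_rate`, `dprime`.
#' @export
compute_dprime <- function(records, correction = c("loglinear", "halfcount")) {
  correction <- match.arg(correction)
  key <- interaction(records$subject, records$rule, drop = TRUE, sep = "\r")
  say <- records$response == "correct-judgement"
  sig <- records$correctness == "correct"
  n_sig <- as.vector(tapply(sig, key, sum))
  n_noi <- as.vector(tapply(!sig, key, sum))
  if (any(n_sig == 0L) || any(n_noi == 0L))
    stop("d-prime needs at least one correct and one foil trial per ",
         "subject x rule cell")
  hits <- as.vector(tapply(say & sig, key, sum))
  fas <- as.vector(tapply(say & !sig, key, sum))
  h <- rate_correct(hits, n_sig, correction)
  f <- rate_correct(fas, n_noi, correction)
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(subject = utils::type.convert(parts[, 1], as.is = TRUE),
                    rule = parts[, 2], n_signal = n_sig, n_noise = n_noi,
                    hit_rate = h, fa_rate = f,
                    dprime = stats::qnorm(h) - stats::qnorm(f))
  out <- out[order(out$subject, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}

rate_correct <- function(count, n, correction) {
  switch(correction,
         loglinear = (count + 0.5) / (n + 1),
         halfcount = {
           r <- count / n
           ifelse(r == 0, 1 / (2 * n), ifelse(r == 1, 1 - 1 / (2 * n), r))
         })
}

#' Summarize simulated (or imported) behavior
#'
#' Per subject x rule: accuracy, hit and false-alarm rates, d-prime, mean RT;
#' plus group means and SDs across subjects.
#'
#' @param records A `response_records` data frame.
#' @param correction Rate correction passed to [compute_dprime()].
#' @return An object of class `behavior_summary`: list with `per_cell` and
#'   `group` data frames.
#' @export
summarize_behavior <- function(records,
                               correction = c("loglinear", "halfcount")) {
  stopifnot(nrow(records) > 0L)
  dp <- compute_dprime(records, match.arg(correction))
  acc <- stats::aggregate(cbind(accuracy = accurate, mean_rt = rt)
                          ~ subject + rule, data = records, FUN = mean)
  per_cell <- merge(dp, acc, by = c("subject", "rule"), sort = TRUE)
  group <- do.call(rbind, lapply(split(per_cell, per_cell$rule), function(g)
    data.frame(rule = g$rule[1], n_subjects = nrow(g),
               accuracy = mean(g$accuracy), accuracy_sd = stats::sd(g$accuracy),
               dprime = mean(g$dprime), dprime_sd = stats::sd(g$dprime),
               mean_rt = mean(g$mean_rt), mean_rt_sd = stats::sd(g$mean_rt))))
  rownames(group) <- NULL
  structure(list(per_cell = per_cell, group = group),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("behavior_summary (group means across",
      x$group$n_subjects[1], "subjects):\n")
  print(x$group, digits = 3)
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Computed from sums of squares with subject blocking: the total variation
#' of the subjects x conditions table is partitioned into subject, condition,
#' and residual (subject x condition) components, and the condition effect is
#' tested against the residual with `df1 = k - 1`, `df2 = (k - 1)(n - 1)`.
#'
#' @param per_subject_stat Numeric matrix or data frame, one row per subject
#'   and one column per condition (e.g. per-rule d-prime); no missing cells.
#' @return List of class `rm_anova` with `F`, `df1`, `df2`, `p`, and the
#'   sums-of-squares table.
#' @export
rm_anova_oneway <- function(per_subject_stat) {
  m <- as.matrix(per_subject_stat)
  if (anyNA(m)) stop("missing cells: the repeated-measures table must be complete")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(F = f, df1 = df1, df2 = df2, p = p,
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err, total = ss_tot)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("one-way repeated-measures ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Pairwise post-hoc comparisons for a repeated-measures table
#'
#' Paired t tests between every pair of conditions with a configurable
#' multiplicity adjustment (see [stats::p.adjust]).
#'
#' @param per_subject_stat Subjects x conditions matrix or data frame.
#' @param adjust Adjustment method, default `"holm"`.
#' @return `data.frame` with one row per pair: mean difference, t, df, raw
#'   and adjusted p.
#' @export
posthoc_pairwise <- function(per_subject_stat, adjust = "holm") {
  m <- as.matrix(per_subject_stat)
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("cond", seq_len(ncol(m)))
  pairs <- utils::combn(ncol(m), 2)
  rows <- apply(pairs, 2, function(ij) {
    tt <- stats::t.test(m[, ij[1]], m[, ij[2]], paired = TRUE)
    data.frame(a = cols[ij[1]], b = cols[ij[2]],
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Per-subject d-prime table in wide (subjects x rules) form
#'
#' Convenience for feeding [rm_anova_oneway()].
#'
#' @param records A `response_records` data frame.
#' @param correction Rate correction passed to [compute_dprime()].
#' @return Numeric matrix, rows = subjects, columns = rules.
#' @export
dprime_table <- function(records, correction = c("loglinear", "halfcount")) {
  dp <- compute_dprime(records, match.arg(correction))
  stats::xtabs(dprime ~ subject + rule, data = dp)
}
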