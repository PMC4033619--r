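make_log <- function(correct) {
  n <- length(correct)
  structure(data.frame(trial = seq_len(n), label = 1L, action = 1L,
                       correct = correct, r = 1, rho = 1,
                       was_correct = TRUE, updated = TRUE),
            class = c("trial_log", "data.frame"),
            performance = 100 * mean(correct))
}

test_that("a frozen decoder performs at chance on balanced labels", {
  # label-uninformative inputs: with no learning the chosen action is
  # independent of the label, so per-trial success is a fair coin
  perfs <- vapply(1:12, function(s) {
    ses <- blob_session(100, sep = 0, seed = 400 + s)
    performance(run_session(ses, "plain", critic_config(1.0),
                            actor_seed = 500 + s,
                            mu_plus = 0, mu_minus = 0))
  }, numeric(1))
  expect_gt(mean(perfs), 44)
  expect_lt(mean(perfs), 56)
})

test_that("a perfect critic yields terminal-half convergence", {
  pool <- test_pool()
  set.seed(55)
  ses <- criticgate:::sample_pool_session(pool, 60)
  log <- run_session(ses, "plain", critic_config(1.0), actor_seed = 1)
  expect_gte(100 * mean(log$correct[31:60]), 90)
})

test_that("plain and confidence runs coincide when all feedback is correct", {
  pool <- test_pool()
  set.seed(66)
  ses <- criticgate:::sample_pool_session(pool, 40)
  stream <- rep(TRUE, 40)
  a <- init_actor(ncol(ses$rates), seed = 2)
  for (rule in c("literal", "gated")) {
    lp <- run_session(ses, "plain", critic_config(1.0), actor = a,
                      feedback_correct = stream)
    lc <- run_session(ses, "confidence", critic_config(1.0), actor = a,
                      confidence_rule = rule, feedback_correct = stream)
    expect_equal(as.data.frame(lp), as.data.frame(lc), ignore_attr = TRUE)
  }
})

test_that("gated mode updates exactly on the high-confidence trials", {
  pool <- test_pool()
  set.seed(21)
  ses <- criticgate:::sample_pool_session(pool, 50)
  stream <- stats::runif(50) < 0.6
  log <- run_session(ses, "confidence", critic_config(0.6), actor_seed = 3,
                     confidence_rule = "gated", feedback_correct = stream)
  expect_identical(log$updated, stream)
  # literal rule keeps adapting on low-confidence trials
  log2 <- run_session(ses, "confidence", critic_config(0.6), actor_seed = 3,
                      confidence_rule = "literal", feedback_correct = stream)
  expect_true(any(log2$updated[!stream]))
})

test_that("stability is perfection over the terminal window", {
  good <- make_log(rep(TRUE, 100))
  bad95 <- make_log(replace(rep(TRUE, 100), 95, FALSE))
  early_err <- make_log(c(FALSE, rep(TRUE, 99)))
  counts <- stability_counts(list(good, bad95, early_err), c(50, 30))
  expect_identical(counts, c(stable_50 = 2L, stable_30 = 2L))
  expect_identical(stability_counts(list(bad95), c(50, 30)),
                   c(stable_50 = 0L, stable_30 = 0L))
  expect_error(stability_counts(list(make_log(rep(TRUE, 20))), 50),
               "window longer")
})

test_that("paired comparison handles identical, degenerate and shifted data", {
  x <- c(50, 60, 70, 80)
  expect_identical(paired_comparison(x, x)[c("t", "p")], list(t = 0, p = 1))
  expect_error(paired_comparison(x, x + 5), "degenerate")
  expect_error(paired_comparison(x, x[1:3]), "equal length")
  set.seed(10)
  a <- stats::rnorm(1000, 70, 5)
  b <- a - 2 + stats::rnorm(1000, 0, 1)
  res <- paired_comparison(a, b, alpha = 0.001)
  expect_lt(res$p, 0.001)
  expect_true(res$significant)
  expect_equal(res$mean_diff, 2, tolerance = 0.1)
})

test_that("class overlap is near 0 for separated blobs, 0.5 for identical", {
  expect_lt(class_overlap_diagnostic(blob_session(100, sep = 30)), 0.02)
  expect_equal(class_overlap_diagnostic(blob_session(300, sep = 0)), 0.5,
               tolerance = 0.12)
  flat <- criticgate:::as_session_data(matrix(5, 10, 4), rep(1:2, each = 5))
  expect_error(class_overlap_diagnostic(flat), "zero variance")
  tiny <- blob_session(1, sep = 1)
  expect_error(class_overlap_diagnostic(tiny), "2 trials per class")
})

test_that("studies are bit-reproducible from the master seed", {
  args <- list(accuracy_grid = c(0.7, 1.0), n_sims = 4, n_trials = 20,
               layout = ensemble_layout(3, 3, 2),
               cfg = test_stim(), master_seed = 31, pool_size = 40)
  r1 <- do.call(run_study, args)
  r2 <- do.call(run_study, args)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$performances, r2$performances)
  expect_identical(r1$config_hash, r2$config_hash)
})

test_that("the two modes coincide at a perfect critic within a study", {
  r <- run_study(1.0, n_sims = 5, n_trials = 20,
                 layout = ensemble_layout(3, 3, 2), cfg = test_stim(),
                 master_seed = 8, pool_size = 40)
  perf <- r$performances
  expect_identical(perf[, "plain", 1], perf[, "confidence", 1])
  expect_identical(r$summary$t_stat, rep(0, 2))
  expect_identical(r$summary$p_value, rep(1, 2))
})

test_that("noise sweep stacks one study per noise level", {
  ns <- noise_sweep(c(0, 0.8), accuracy_grid = 0.9, n_sims = 4,
                    n_trials = 15, layout = ensemble_layout(3, 3, 2),
                    cfg = test_stim(), master_seed = 5, pool_size = 30)
  expect_identical(nrow(ns$summary), 4L)  # 2 noise x 1 accuracy x 2 modes
  expect_identical(unique(ns$summary$noise_fraction), c(0, 0.8))
  expect_named(ns$studies, c("0", "0.8"))
  # heavy stimulus noise degrades decodability of the generated data
  lo <- ns$studies[["0"]]$summary
  hi <- ns$studies[["0.8"]]$summary
  expect_gte(mean(lo$mean_perf), mean(hi$mean_perf) - 10)
})

test_that("study outputs round-trip to CSV + JSON", {
  r <- run_study(c(0.9), n_sims = 3, n_trials = 10,
                 layout = ensemble_layout(2, 2, 1), cfg = test_stim(),
                 master_seed = 2, pool_size = 20)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_study_result(r, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$mean_perf, r$summary$mean_perf)
  js <- jsonlite::read_json(sub("\\.csv$", ".json", csv))
  expect_identical(js$config_hash, r$config_hash)
  expect_equal(js$master_seed, 2)
})
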