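pr <- dbn_priors()

test_that("predict_next is the fitted linear form", {
  set.seed(210)
  # engineer a fit, then override with exact parameters for a hand check
  n <- 50
  x <- runif(n)
  tr <- make_transitions(data.frame(x = x),
                         data.frame(y = 0.1 + 0.5 * x + rnorm(n, 0, 0.01)))
  fit <- fit_dbn(dbn_structure(list(y = "x"), tr), tr, pr)
  fit$children$y$params[["(all)"]]$alpha <- 0.1
  fit$children$y$params[["(all)"]]$beta[["x"]] <- 0.5
  expect_equal(unname(predict_next(fit, list(x = 0.4))$continuous), 0.3)
  # all-zero coefficients predict the intercept
  fit$children$y$params[["(all)"]]$beta[["x"]] <- 0
  expect_equal(unname(predict_next(fit, list(x = 0.9))$continuous), 0.1)
})

test_that("normalize_prediction clips then renormalizes", {
  expect_equal(unname(normalize_prediction(
    c(a = 0.2, b = 0.3, c = 0.5))), c(0.2, 0.3, 0.5))
  expect_equal(unname(normalize_prediction(
    c(a = -0.1, b = 0.6, c = 0.6))), c(0, 0.5, 0.5))
  expect_equal(unname(normalize_prediction(c(a = 0.4, b = 0.4))),
               c(0.5, 0.5))
  expect_warning(out <- normalize_prediction(c(a = -1, b = 0)),
                 "uniform")
  expect_equal(as.numeric(out), c(0.5, 0.5))
  expect_true(attr(out, "degenerate"))
  expect_error(normalize_prediction(c(a = 1), c("a", "b")), "lacks")
})

test_that("one-step error approaches the folded-normal noise floor", {
  # children simulated from the fitted model itself: mean absolute
  # deviation from the conditional mean tends to sigma * sqrt(2/pi)
  co <- simulate_cohort(default_truth(),
                        cohort_spec(n_subjects = 40), seed = 220)
  tr <- build_transitions(co)
  st <- hill_climb(tr, pr)
  fit <- fit_dbn(st, tr, pr)
  set.seed(2201)
  big <- tr$parents[sample(nrow(tr$parents), 20000, replace = TRUE), ]
  null_tr <- simulate_from_fit(fit, big, seed = 221)
  mu <- microdbn:::predict_continuous(fit, big)
  for (ch in c("Bacilli", "Clostridia")) {
    sigma <- sqrt(fit$children[[ch]]$params[["(all)"]]$sigma2)
    expect_equal(mean(abs(mu[, ch] - null_tr$children[[ch]])),
                 sigma * sqrt(2 / pi), tolerance = 0.03)
  }
})

test_that("prediction records are valid compositions with correct MAE", {
  co <- simulate_cohort(default_truth(),
                        cohort_spec(n_subjects = 10), seed = 222)
  tr <- build_transitions(co)
  fit <- fit_dbn(hill_climb(tr, pr), tr, pr)
  taxa <- select_taxa(co, fit$structure)
  recs <- prediction_records(fit, tr, taxa)
  pred <- attr(recs, "predicted")
  obs <- attr(recs, "observed")
  expect_true(all(pred >= 0))
  expect_equal(unname(rowSums(pred)), rep(1, nrow(pred)))
  expect_equal(recs$mae, rowMeans(abs(pred - obs)))
})

test_that("LOSO refits parameters per held-out subject and needs 2+
           subjects", {
  co <- simulate_cohort(default_truth(),
                        cohort_spec(n_subjects = 8,
                                    samples_range = c(6, 10)), seed = 230)
  tr <- build_transitions(co)
  st <- hill_climb(tr, pr)
  ev <- evaluate_loso(co, st, pr)
  expect_equal(sort(ev$per_subject$subject),
               sort(unique(co$meta$subject_id)))
  expect_true(all(ev$per_subject$mae >= 0))
  expect_equal(nrow(ev$records), nrow(tr$parents))
  # single-subject cohort is an error
  keep <- co$meta$subject_id == "S01"
  co1 <- as_cohort(co$meta[keep, ], co$counts[keep, ])
  expect_error(evaluate_loso(co1, st, pr), ">= 2 subjects")
})

test_that("an injected abruption raises its subject's LOSO error over
           the abruption-free twin", {
  co <- simulate_cohort(default_truth(),
                        cohort_spec(n_subjects = 12,
                                    samples_range = c(8, 12)), seed = 231)
  tw <- inject_abruption(co, "S05", 4, "replace-with-unclassified")
  tr <- build_transitions(co)
  st <- hill_climb(tr, pr)
  mae_clean <- evaluate_loso(co, st, pr)$per_subject
  mae_abrupt <- evaluate_loso(tw, st, pr)$per_subject
  expect_gt(mae_abrupt$mae[mae_abrupt$subject == "S05"],
            mae_clean$mae[mae_clean$subject == "S05"])
})

test_that("identical variable sets give a zero k-fold difference and the
           folds are seed-reproducible", {
  co <- simulate_cohort(default_truth(),
                        cohort_spec(n_subjects = 10,
                                    samples_range = c(6, 9)), seed = 240)
  vs <- list(a = "postconceptional_age", b = "postconceptional_age")
  ev1 <- evaluate_kfold(co, pr, k = 3, variable_sets = vs, seed = 9)
  expect_equal(ev1$test$statistic, 0)
  expect_equal(ev1$test$p.value, 1)
  ev2 <- evaluate_kfold(co, pr, k = 3, variable_sets = vs, seed = 9)
  expect_identical(ev1$fold, ev2$fold)
  expect_equal(ev1$per_subject, ev2$per_subject)
  expect_error(evaluate_kfold(co, pr, k = 50, variable_sets = vs),
               "exceeds")
})

test_that("compare_error_sets matches the textbook paired t computation", {
  expect_equal(compare_error_sets(c(a = 1, b = 2, c = 3),
                                  c(a = 1, b = 2, c = 3))$p.value, 1)
  set.seed(241)
  a <- rnorm(30, 0.03, 0.001)
  b <- a + rnorm(30, 0.01, 0.001)
  names(a) <- names(b) <- paste0("s", 1:30)
  res <- compare_error_sets(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p.value, 2 * pt(-abs(t_hand), 29))
  expect_lt(res$p.value, 1e-6)
  # exclusions drop named subjects
  res2 <- compare_error_sets(a, b, exclusions = c("s1", "s2"))
  expect_equal(res2$n, 28)
  expect_error(compare_error_sets(a[1:2], b[1:2]), "insufficient")
})

test_that("grouped comparison splits by threshold and guards degenerate
           splits", {
  set.seed(242)
  err <- c(rnorm(20, 0.02, 0.004), rnorm(20, 0.05, 0.004))
  gap <- rep(c(1, 3), each = 20)
  res <- compare_error_sets(err, mode = "grouped", group = gap)
  expect_lt(res$p.value, 1e-6)
  expect_lt(res$mean_low, res$mean_high)
  expect_error(compare_error_sets(err, mode = "grouped",
                                  group = rep(1, 40)),
               "insufficient")
})
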