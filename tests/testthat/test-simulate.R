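test_that("cohort simulation is seed-reproducible and count-consistent", {
  co1 <- simulate_cohort(default_truth(),
                         cohort_spec(n_subjects = 6), seed = 5)
  co2 <- simulate_cohort(default_truth(),
                         cohort_spec(n_subjects = 6), seed = 5)
  expect_identical(co1$counts, co2$counts)
  expect_identical(co1$meta, co2$meta)
  co3 <- simulate_cohort(default_truth(),
                         cohort_spec(n_subjects = 6), seed = 6)
  expect_false(identical(co1$counts, co3$counts))
  # every latent profile sums to 1; counts are multinomial at depth
  lat <- attr(co1, "latent")
  expect_equal(unname(rowSums(lat)), rep(1, nrow(lat)))
  expect_true(all(rowSums(co1$counts) >= 500))
  # day of life strictly increases within subject
  for (s in unique(co1$meta$subject_id)) {
    d <- co1$meta$day_of_life[co1$meta$subject_id == s]
    expect_true(all(diff(d) >= 1))
  }
  # age covariates are consistent clocks
  expect_equal(co1$meta$postconceptional_age,
               co1$meta$gestational_age + co1$meta$day_of_life / 7)
})

test_that("default cohort design lands near the study scale", {
  totals <- vapply(1:5, function(seed) {
    nrow(simulate_cohort(default_truth(), cohort_spec(),
                         seed = seed)$meta)
  }, numeric(1))
  expect_true(all(totals >= 870 & totals <= 980))
  co <- simulate_cohort(default_truth(), cohort_spec(), seed = 1)
  expect_equal(length(unique(co$meta$subject_id)), 58)
  expect_equal(length(co$taxa), 14)
  depth <- rowSums(co$counts)
  expect_gt(median(depth), 5000)
  expect_lt(median(depth), 9500)
})

test_that("the default truth model reproduces the succession phenotype", {
  clo_up <- bac_down <- 0
  for (seed in 1:5) {
    co <- simulate_cohort(default_truth(),
                          cohort_spec(n_subjects = 30), seed = 30 + seed)
    ab <- abundances(co)
    first <- !duplicated(co$meta$subject_id)
    last <- !duplicated(co$meta$subject_id, fromLast = TRUE)
    clo_up <- clo_up + (mean(ab[last, "Clostridia"]) >
                          mean(ab[first, "Clostridia"]))
    bac_down <- bac_down + (mean(ab[last, "Bacilli"]) <
                              mean(ab[first, "Bacilli"]))
  }
  expect_equal(clo_up, 5)
  expect_equal(bac_down, 5)
})

test_that("planted coefficients are recovered by the OLS oracle", {
  # regression on the archived latent transitions: the linear step before
  # clipping/renormalization is exactly the planted model, so OLS on
  # (previous latent composition -> raw next step) is unbiased for beta
  truth <- planted_truth(n_taxa = 12, seed = 3)
  co <- simulate_cohort(truth,
                        cohort_spec(n_subjects = 300,
                                    samples_range = c(18, 20)), seed = 31)
  lat <- attr(co, "latent")
  raw <- attr(co, "latent_raw")
  src <- which(co$meta$subject_id[-1] == co$meta$subject_id[-nrow(lat)])
  expect_gt(length(src), 5000)
  edges <- attr(truth, "planted_edges")
  set.seed(32)
  for (i in sample(nrow(edges), 3)) {
    ch <- edges$child[i]
    pa <- unique(c(ch, edges$parent[edges$child == ch]))
    df <- as.data.frame(lat[src, pa, drop = FALSE])
    df$y <- raw[src + 1, ch]
    ols <- stats::lm(y ~ ., data = df)
    est <- coef(ols)[[edges$parent[i]]]
    se <- summary(ols)$coefficients[edges$parent[i], "Std. Error"]
    expect_lt(abs(est - edges$beta[i]), 3 * se)
  }
})

test_that("an unstable truth model is refused without an override", {
  taxa <- c("A", "B")
  W <- matrix(c(1.2, 0, 0, 0.5), 2, 2, dimnames = list(taxa, taxa))
  expect_error(ground_truth(taxa, c(0, 0), W, c(0, 0), c(0.1, 0.1)),
               "unstable")
  expect_s3_class(ground_truth(taxa, c(0, 0), W, c(0, 0), c(0.1, 0.1),
                               allow_unstable = TRUE), "dbn_truth")
})

test_that("abruption injection modifies exactly one sample", {
  co <- simulate_cohort(default_truth(),
                        cohort_spec(n_subjects = 5), seed = 8)
  inj <- inject_abruption(co, "S02", 3, "replace-with-unclassified")
  rows <- which(co$meta$subject_id == "S02")
  r <- rows[3]
  expect_equal(unname(inj$counts[r, "unclassified"]),
               sum(co$counts[r, ]))
  expect_equal(sum(inj$counts[r, ]), sum(co$counts[r, ]))
  expect_identical(inj$counts[-r, ], co$counts[-r, ])
  expect_equal(attr(inj, "injections")$row, r)
  # rare-taxon mode and shuffle mode preserve depth too
  inj2 <- inject_abruption(co, "S02", 3, "replace-with-rare-taxon")
  expect_equal(unname(inj2$counts[r, "Bacteroidia"]), sum(co$counts[r, ]))
  inj3 <- inject_abruption(co, "S02", 3, "shuffle-composition")
  expect_equal(sort(inj3$counts[r, ]), sort(co$counts[r, ]),
               ignore_attr = TRUE)
  expect_error(inject_abruption(co, "nope", 1), "unknown subject")
  expect_error(inject_abruption(co, "S02", 99), "no sample")
})

test_that("null draws from a fitted model score like training data", {
  co <- simulate_cohort(default_truth(),
                        cohort_spec(n_subjects = 15), seed = 9)
  tr <- build_transitions(co)
  pr <- dbn_priors()
  fit <- fit_dbn(hill_climb(tr, pr), tr, pr)
  null_tr <- simulate_from_fit(fit, tr$parents, seed = 10)
  expect_equal(nrow(null_tr$children), nrow(tr$parents))
  # same seed reproduces
  null_tr2 <- simulate_from_fit(fit, tr$parents, seed = 10)
  expect_identical(null_tr$children, null_tr2$children)
})
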