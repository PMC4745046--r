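## One-step prediction and the evaluation protocols: per-sample
## compositional prediction with mean absolute error, leave-one-subject-out
## parameter refitting, k-fold cross-validation with structure relearning,
## and the paired / grouped error comparisons.

#' One-step prediction from a single source sample
#'
#' Uses the expectation of each child given its parents at time t:
#' `alpha(u) + beta(u) . v` for continuous children, the argmax of the
#' Dirichlet-multinomial predictive for discrete children.
#'
#' @param fit A [fit_dbn()] result.
#' @param state Named list or 1-row data frame supplying every parent
#'   variable at time t (taxa abundances and covariates).
#' @return List with `continuous` (named numeric vector of raw predicted
#'   values, not yet normalized) and `discrete` (named character vector of
#'   predicted states, possibly empty).
#' @export
predict_next <- function(fit, state) {
  row <- as_parent_row(state)
  needed <- unique(unlist(lapply(fit$children, function(r) {
    c(r$cparents, r$dparents)
  })))
  for (v in needed) {
    if (is.null(row[[v]]) || is.na(row[[v]])) {
      stop("incomplete evidence: missing parent '", v, "'")
    }
  }
  kinds <- vapply(fit$children, `[[`, "", "kind")
  cont <- drop(predict_continuous(fit, row))
  disc <- vapply(names(kinds)[kinds == "discrete"], function(ch) {
    pr <- discrete_predictive(fit, ch, row)
    names(pr)[which.max(pr)]
  }, character(1))
  list(continuous = cont, discrete = disc)
}

#' Normalize raw predictions to a composition
#'
#' Clips negative raw values to zero and renormalizes the remaining mass to
#' sum to one over the selected taxa.  If no positive mass remains the
#' uniform profile is returned with a warning and a `degenerate` attribute.
#'
#' @param raw Named numeric vector of raw predicted values (must cover
#'   `taxa`).
#' @param taxa Selected taxa defining the composition.
#' @return Named numeric vector over `taxa`, nonnegative, summing to 1.
#' @export
normalize_prediction <- function(raw, taxa = names(raw)) {
  stopifnot(length(taxa) > 0)
  missing_taxa <- setdiff(taxa, names(raw))
  if (length(missing_taxa)) {
    stop("raw prediction lacks taxa: ", paste(missing_taxa, collapse = ", "))
  }
  v <- pmax(as.numeric(raw[taxa]), 0)
  s <- sum(v)
  if (s <= 0) {
    warning("all predicted values <= 0; returning uniform profile")
    out <- stats::setNames(rep(1 / length(taxa), length(taxa)), taxa)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::setNames(v / s, taxa)
}

# Row-wise clip-and-renormalize of a prediction matrix (no warning path;
# degenerate rows become uniform).
normalize_rows <- function(m) {
  m <- pmax(m, 0)
  s <- rowSums(m)
  bad <- s <= 0
  if (any(bad)) m[bad, ] <- 1 / ncol(m)
  m / pmax(rowSums(m), .Machine$double.eps)
}

#' Per-transition prediction records
#'
#' Predicts every transition's target composition from its source sample,
#' normalizes predicted and observed profiles over the selected taxa, and
#' computes the per-sample mean absolute error across those taxa.
#'
#' @param fit A [fit_dbn()] result.
#' @param transitions A `dbn_transitions`.
#' @param taxa Taxa over which the composition and MAE are computed
#'   (default: the fitted model's taxa children).
#' @return Data frame with columns `subject`, `target_day`, `gap_days`,
#'   `mae`; the normalized predicted and observed profiles are attached as
#'   matrix attributes `predicted` and `observed`.
#' @export
prediction_records <- function(fit, transitions, taxa = fit$taxa) {
  stopifnot(length(taxa) > 0)
  raw <- predict_continuous(fit, transitions$parents)
  missing_taxa <- setdiff(taxa, colnames(raw))
  if (length(missing_taxa)) {
    stop("fit lacks taxa children: ", paste(missing_taxa, collapse = ", "))
  }
  pred <- normalize_rows(raw[, taxa, drop = FALSE])
  obs <- normalize_rows(as.matrix(transitions$children[taxa]))
  mae <- rowMeans(abs(pred - obs))
  out <- data.frame(subject = transitions$subject,
                    target_day = transitions$target_day,
                    gap_days = transitions$gap_days,
                    mae = mae)
  attr(out, "predicted") <- pred
  attr(out, "observed") <- obs
  out
}

#' Leave-one-subject-out evaluation
#'
#' For each held-out subject, the network parameters are refit on the
#' remaining subjects' transitions (the structure stays fixed by default,
#' matching the protocol of learning only parameters per fold) and every
#' non-first sample of the held-out subject is predicted from its
#' predecessor.  Per-subject error is the mean of that subject's per-sample
#' mean absolute errors.
#'
#' @param cohort A `dbn_cohort`.
#' @param structure A `dbn_structure` learned on the full data (or any
#'   fixed structure).
#' @param priors A [dbn_priors()].
#' @param taxa Taxa for the error composition; default
#'   [select_taxa()] with the structure and `min_fraction`.
#' @param min_fraction Threshold passed to [select_taxa()].
#' @param relearn_structure Relearn the structure per fold as a
#'   sensitivity analysis (default `FALSE`).
#' @return List with `per_subject` (subject, n_predicted, mae) and
#'   `records` (all per-sample records).
#' @export
evaluate_loso <- function(cohort, structure, priors = dbn_priors(),
                          taxa = NULL, min_fraction = 0.01,
                          relearn_structure = FALSE) {
  subjects <- unique(cohort$meta$subject_id)
  if (length(subjects) < 2) stop("leave-one-subject-out needs >= 2 subjects")
  if (is.null(taxa)) taxa <- select_taxa(cohort, structure, min_fraction)
  tr <- build_transitions(cohort)
  per <- list(); recs <- list()
  for (s in subjects) {
    test_idx <- which(tr$subject == s)
    if (!length(test_idx)) {
      message("subject ", s, " has < 2 samples; excluded from evaluation")
      next
    }
    train <- subset_transitions(tr, which(tr$subject != s))
    st <- if (relearn_structure) {
      hill_climb(train, priors, children = structure$children)
    } else structure
    fs <- fit_dbn(st, train, priors)
    r <- prediction_records(fs, subset_transitions(tr, test_idx), taxa)
    recs[[s]] <- r
    per[[s]] <- data.frame(subject = s, n_predicted = nrow(r),
                           mae = mean(r$mae))
  }
  list(per_subject = do.call(rbind, c(per, list(make.row.names = FALSE))),
       records = do.call(rbind, c(recs, list(make.row.names = FALSE))))
}

#' k-fold cross-validation comparing two covariate sets
#'
#' Partitions subjects (not samples) into k folds.  For each fold and each
#' candidate variable set, the structure AND parameters are relearned on
#' the training subjects with candidate parents restricted to the taxa plus
#' that variable set, and held-out subjects' per-subject errors are
#' recorded.  The two variable sets are compared with a two-tailed paired
#' t-test on per-subject errors.
#'
#' @param cohort A `dbn_cohort`.
#' @param priors A [dbn_priors()].
#' @param k Number of folds (>= 2, <= number of subjects).
#' @param variable_sets Named list of exactly two character vectors of
#'   covariate names to allow as candidate parents (taxa are always
#'   candidates).
#' @param seed Seed controlling the fold assignment.
#' @param taxa Taxa for the error composition; default [select_taxa()] on
#'   the cohort with `min_fraction`.
#' @param min_fraction Threshold passed to [select_taxa()].
#' @return List with `per_subject` (one error column per variable set),
#'   `means` (mean per-person error per set), and `test` (the paired
#'   comparison from [compare_error_sets()]).
#' @export
evaluate_kfold <- function(cohort, priors = dbn_priors(), k = 5,
                           variable_sets, seed = 1, taxa = NULL,
                           min_fraction = 0.01) {
  stopifnot(length(variable_sets) == 2)
  if (is.null(names(variable_sets))) names(variable_sets) <- c("a", "b")
  subjects <- unique(cohort$meta$subject_id)
  if (k < 2) stop("k must be >= 2")
  if (k > length(subjects)) stop("k exceeds the number of subjects")
  if (is.null(taxa)) taxa <- select_taxa(cohort, NULL, min_fraction)
  tr <- build_transitions(cohort)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(subjects)))
  names(fold) <- subjects

  errs <- lapply(variable_sets, function(...) c())
  for (f in seq_len(k)) {
    test_subj <- subjects[fold == f]
    train <- subset_transitions(tr, which(!tr$subject %in% test_subj))
    test <- subset_transitions(tr, which(tr$subject %in% test_subj))
    if (!nrow(test$parents)) next
    for (nm in names(variable_sets)) {
      cand_parents <- c(tr$taxa, variable_sets[[nm]])
      st <- hill_climb(train, priors, children = tr$taxa,
                       parents = cand_parents)
      fs <- fit_dbn(st, train, priors)
      r <- prediction_records(fs, test, taxa)
      per <- tapply(r$mae, r$subject, mean)
      errs[[nm]] <- c(errs[[nm]], per)
    }
  }
  common <- Reduce(intersect, lapply(errs, names))
  per_subject <- data.frame(subject = common)
  for (nm in names(errs)) per_subject[[nm]] <- unname(errs[[nm]][common])
  test <- compare_error_sets(stats::setNames(per_subject[[2]], common),
                             stats::setNames(per_subject[[3]], common),
                             mode = "paired")
  list(per_subject = per_subject,
       means = vapply(errs, function(e) mean(e[common]), numeric(1)),
       test = test, fold = fold)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compare two error sets
#'
#' Paired mode: two-tailed paired t-test on per-subject error differences
#' after removing excluded subjects.  Grouped mode: splits one error vector
#' by a grouping value against a threshold (default: the median, e.g. of
#' inter-sample gaps; or supply the empirical mean of a reference model's
#' errors) and runs a two-sample two-tailed t-test.
#'
#' @param errors_a Named numeric vector of errors (names = subjects for
#'   paired mode).
#' @param errors_b Second error vector for paired mode (same names).
#' @param mode `"paired"` or `"grouped"`.
#' @param group Numeric vector (same length as `errors_a`) used to split in
#'   grouped mode.
#' @param threshold Split point for grouped mode; default `median(group)`.
#' @param exclusions Subject names to drop before testing.
#' @return List with `statistic`, `p.value`, `estimate`, `mode`, `n`.
#' @export
compare_error_sets <- function(errors_a, errors_b = NULL,
                               mode = c("paired", "grouped"),
                               group = NULL, threshold = NULL,
                               exclusions = NULL) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    stopifnot(!is.null(errors_b), length(errors_a) == length(errors_b))
    if (!is.null(exclusions)) {
      keep <- !(names(errors_a) %in% exclusions)
      errors_a <- errors_a[keep]
      errors_b <- errors_b[keep]
    }
    if (length(errors_a) < 3) stop("insufficient data: fewer than 3 pairs")
    d <- errors_a - errors_b
    if (all(abs(d) < .Machine$double.eps * 100)) {
      return(list(statistic = 0, p.value = 1, estimate = 0,
                  mode = mode, n = length(d)))
    }
    ht <- stats::t.test(errors_a, errors_b, paired = TRUE)
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         estimate = unname(ht$estimate), mode = mode, n = length(d))
  } else {
    stopifnot(!is.null(group), length(group) == length(errors_a))
    if (is.null(threshold)) threshold <- stats::median(group)
    lo <- errors_a[group <= threshold]
    hi <- errors_a[group > threshold]
    if (length(lo) < 2 || length(hi) < 2) {
      stop("insufficient data: a group has fewer than 2 records")
    }
    ht <- stats::t.test(lo, hi)
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         estimate = unname(diff(rev(ht$estimate))), mode = mode,
         n = length(errors_a), threshold = threshold,
         mean_low = mean(lo), mean_high = mean(hi))
  }
}
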