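## Iterative forward prediction: feed each normalized prediction back as
## the next input to project compositions from initial conditions only,
## plus the six-scenario synthetic initial-condition suite and its
## convergence diagnostic.

#' Trajectory configuration
#'
#' @param steps Number of forward steps (>= 1).
#' @param delta_t Days advanced per step (default 2, matching samples taken
#'   one or two days apart on average).
#' @param covariate_policy `"advance-clocks"`: day of life and
#'   post-conceptional age advance by `delta_t` per step (discrete
#'   covariates and antibiotics held at their initial values);
#'   `"hold-constant"`: all covariates frozen.
#' @param pca_unit Unit of the post-conceptional age covariate, used to
#'   advance it consistently with `delta_t` days.
#' @return List of class `trajectory_config`.
#' @export
trajectory_config <- function(steps = 20, delta_t = 2,
                              covariate_policy = c("advance-clocks",
                                                   "hold-constant"),
                              pca_unit = c("weeks", "days")) {
  stopifnot(steps >= 1, delta_t > 0)
  structure(list(steps = as.integer(steps), delta_t = delta_t,
                 covariate_policy = match.arg(covariate_policy),
                 pca_unit = match.arg(pca_unit)),
            class = "trajectory_config")
}

#' Initial-condition scenario
#'
#' @param name Scenario label.
#' @param profile Named numeric composition over the model taxa (will be
#'   normalized; must have positive total mass).
#' @param covariates Named list of initial covariate values; defaults
#'   emulate a preterm infant a few days after birth.
#' @return List of class `dbn_scenario`.
#' @export
scenario <- function(name, profile, covariates = default_covariates()) {
  stopifnot(is.numeric(profile), !is.null(names(profile)),
            all(profile >= 0), sum(profile) > 0)
  structure(list(name = name, profile = profile / sum(profile),
                 covariates = covariates),
            class = "dbn_scenario")
}

#' @rdname scenario
#' @param day_of_life,gestational_age,antibiotics,open_room Initial
#'   covariate values.
#' @param postconceptional_age Defaults to gestational age plus day of life
#'   in weeks.
#' @export
default_covariates <- function(day_of_life = 5, gestational_age = 28,
                               postconceptional_age = gestational_age +
                                 day_of_life / 7,
                               antibiotics = 0, open_room = "closed") {
  list(day_of_life = day_of_life, gestational_age = gestational_age,
       postconceptional_age = postconceptional_age,
       antibiotics = antibiotics, open_room = open_room)
}

#' The six bundled initial-condition scenarios
#'
#' 1. even split between the three dominant taxa; 2. the same with a trace
#' amount of every rare taxon; 3-5. scenario 2 with one dominant taxon
#' removed (Clostridia, Gammaproteobacteria, Bacilli respectively); 6. an
#' even split over the rare taxa only.
#'
#' @param taxa All model taxa.
#' @param dominant The three dominant taxa (must be in `taxa`).
#' @param trace Trace abundance given to each rare taxon in scenarios 2-5
#'   before renormalization.
#' @param covariates Shared initial covariates.
#' @return List of six [scenario()] objects.
#' @export
default_scenarios <- function(taxa,
                              dominant = c("Bacilli", "Clostridia",
                                           "Gammaproteobacteria"),
                              trace = 0.01,
                              covariates = default_covariates()) {
  stopifnot(all(dominant %in% taxa), length(dominant) == 3)
  rare <- setdiff(taxa, dominant)
  base <- stats::setNames(rep(0, length(taxa)), taxa)
  even3 <- base; even3[dominant] <- 1 / 3
  with_rare <- even3; with_rare[rare] <- trace
  drop1 <- function(tax) { p <- with_rare; p[tax] <- 0; p }
  rare_only <- base
  if (length(rare)) rare_only[rare] <- 1 / length(rare) else
    rare_only <- even3
  list(scenario("even-dominant", even3, covariates),
       scenario("dominant-plus-rare", with_rare, covariates),
       scenario("no-clostridia", drop1(dominant[2]), covariates),
       scenario("no-gammaproteobacteria", drop1(dominant[3]), covariates),
       scenario("no-bacilli", drop1(dominant[1]), covariates),
       scenario("rare-only", rare_only, covariates))
}

#' Iterative forward prediction
#'
#' Step 1 applies [predict_next()] and [normalize_prediction()] to the
#' initial state; each subsequent step feeds the previous normalized
#' prediction back as the taxa input.  Under the `advance-clocks` policy
#' the day-of-life and post-conceptional-age covariates advance by
#' `delta_t` days per step; discrete covariates and antibiotics are held.
#'
#' @param fit A [fit_dbn()] result.
#' @param initial A [scenario()] (or a named profile, wrapped
#'   automatically).
#' @param config A [trajectory_config()].
#' @return Matrix (`steps` x taxa) of predicted compositions; row `s` is
#'   the profile after `s` steps.
#' @export
iterative_predict <- function(fit, initial, config = trajectory_config()) {
  if (!inherits(initial, "dbn_scenario")) {
    initial <- scenario("initial", initial)
  }
  taxa <- fit$taxa
  missing_taxa <- setdiff(taxa, names(initial$profile))
  if (length(missing_taxa)) {
    stop("initial profile lacks taxa: ",
         paste(missing_taxa, collapse = ", "))
  }
  prof <- normalize_prediction(initial$profile, taxa)
  cov <- initial$covariates
  out <- matrix(NA_real_, config$steps, length(taxa),
                dimnames = list(NULL, taxa))
  for (s in seq_len(config$steps)) {
    state <- c(as.list(prof), cov)
    pred <- predict_next(fit, state)
    prof <- normalize_prediction(pred$continuous, taxa)
    out[s, ] <- prof
    if (config$covariate_policy == "advance-clocks") {
      cov$day_of_life <- cov$day_of_life + config$delta_t
      cov$postconceptional_age <- cov$postconceptional_age +
        if (config$pca_unit == "weeks") config$delta_t / 7 else
          config$delta_t
    }
  }
  out
}

max_pairwise_l1 <- function(profiles) {
  k <- nrow(profiles)
  best <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      best <- max(best, sum(abs(profiles[i, ] - profiles[j, ])))
    }
  }
  best
}

#' Run a suite of initial-condition scenarios
#'
#' Runs [iterative_predict()] for each scenario and summarizes convergence
#' as the maximum pairwise L1 distance between scenario profiles at each
#' step (plus the same metric at step 0, the initial conditions).
#'
#' @param fit A [fit_dbn()] result.
#' @param scenarios List of [scenario()] objects (>= 2); default: the six
#'   bundled scenarios over the fitted taxa.
#' @param config A [trajectory_config()].
#' @return List with `trajectories` (named list of step x taxa matrices)
#'   and `convergence` (data frame: step, max_pairwise_l1).
#' @export
scenario_suite <- function(fit, scenarios = NULL,
                           config = trajectory_config()) {
  if (is.null(scenarios)) scenarios <- default_scenarios(fit$taxa)
  stopifnot(length(scenarios) >= 2)
  trajs <- lapply(scenarios, iterative_predict, fit = fit, config = config)
  names(trajs) <- vapply(scenarios, `[[`, "", "name")
  taxa <- fit$taxa
  init <- t(vapply(scenarios,
                   function(sc) normalize_prediction(sc$profile, taxa),
                   numeric(length(taxa))))
  metric <- vapply(seq_len(config$steps), function(s) {
    max_pairwise_l1(t(vapply(trajs, function(m) m[s, ],
                             numeric(length(taxa)))))
  }, numeric(1))
  convergence <- data.frame(step = 0:config$steps,
                            max_pairwise_l1 = c(max_pairwise_l1(init),
                                                metric))
  list(trajectories = trajs, convergence = convergence)
}

#' Iterative per-subject evaluation
#'
#' Predicts each subject's trajectory from their first sample only: the
#' first observed sample seeds the state, and each subsequent observed
#' sample is predicted from the model's own previous (normalized)
#' prediction, with covariates taken from the observed metadata.  Errors
#' are mean absolute error over `taxa`, averaged per subject, comparable
#' with the one-step errors from [evaluate_loso()] / [prediction_records()].
#'
#' @param fit A [fit_dbn()] result.
#' @param cohort A `dbn_cohort`.
#' @param taxa Taxa for the error composition (default: the fit's taxa).
#' @return Data frame with `subject`, `n_predicted`, `mae`.
#' @export
evaluate_iterative <- function(fit, cohort, taxa = fit$taxa) {
  ab <- abundances(cohort)
  meta <- cohort$meta
  out <- list()
  for (s in unique(meta$subject_id)) {
    rows <- which(meta$subject_id == s)
    if (length(rows) < 2) next
    prof <- ab[rows[1], fit$taxa]
    maes <- numeric(0)
    for (j in seq_len(length(rows) - 1)) {
      src <- rows[j]; tgt <- rows[j + 1]
      state <- c(as.list(prof),
                 as.list(meta[src, COVARIATES, drop = FALSE]))
      pred <- normalize_prediction(predict_next(fit, state)$continuous,
                                   fit$taxa)
      pred_t <- drop(normalize_rows(matrix(pred[taxa], 1)))
      obs_t <- drop(normalize_rows(matrix(ab[tgt, taxa], 1)))
      maes <- c(maes, mean(abs(pred_t - obs_t)))
      prof <- pred
    }
    out[[s]] <- data.frame(subject = s, n_predicted = length(maes),
                           mae = mean(maes))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write trajectories as a long-format CSV
#'
#' @param trajectories Named list of step x taxa matrices from
#'   [scenario_suite()] or a single matrix from [iterative_predict()].
#' @param path Output file.
#' @export
write_trajectories <- function(trajectories, path) {
  if (is.matrix(trajectories)) trajectories <- list(trajectory = trajectories)
  rows <- lapply(names(trajectories), function(nm) {
    m <- trajectories[[nm]]
    data.frame(scenario = nm,
               step = rep(seq_len(nrow(m)), ncol(m)),
               taxon = rep(colnames(m), each = nrow(m)),
               abundance = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
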