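## Abruption detection: score each observed transition by the plug-in
## posterior likelihood of its target sample given its source sample,
## convert the -log10 likelihoods to z-scores, and flag records whose
## upper-tail normal p-value falls below alpha / m (m defaulting to the
## number of subjects, a subject-count correction for the dependence of
## repeated measures).

#' Negative log10 likelihood of each transition
#'
#' For each pair, sums the plug-in conditional log densities of all child
#' nodes (posterior-mean parameters) of the observed t + 1 values given the
#' observed t values, and returns the total on the -log10 scale.
#' Continuous children are evaluated on the relative-abundance scale;
#' discrete children contribute their log10 predictive probability.
#'
#' @param fit A [fit_dbn()] result.
#' @param transitions A `dbn_transitions`.
#' @param density `"plugin"` (posterior-mean parameters, the default) or
#'   `"predictive"` (full posterior-predictive Student-t, for sensitivity
#'   analysis).
#' @return Numeric vector, one value per transition.
#' @export
sample_neglog10_likelihood <- function(fit, transitions,
                                       density = c("plugin",
                                                   "predictive")) {
  -transition_log_density(fit, transitions, match.arg(density)) / log(10)
}

#' Scan transitions for abruption events
#'
#' Computes the -log10 likelihood of every included transition, converts
#' the values to z-scores against their empirical mean and standard
#' deviation, and flags records whose one-sided upper-tail normal p-value
#' is below `alpha / m`.  A subject is flagged when at least one of its
#' records is flagged.  Re-running with `exclusions` set to previously
#' flagged subjects implements the two-stage protocol (flag, remove,
#' rescan): excluded subjects' records do not enter the second-pass
#' mean/SD.
#'
#' @param fit A [fit_dbn()] result.
#' @param transitions A `dbn_transitions`.
#' @param alpha Significance level before correction (default 0.05).
#' @param m Correction divisor; defaults to the number of subjects present
#'   after exclusions.
#' @param exclusions Subjects removed before computing the score
#'   distribution.
#' @inheritParams sample_neglog10_likelihood
#' @return An object of class `abruption_report`: list with `records`
#'   (subject, target_day, neglog10_likelihood, z_score, flagged),
#'   `flagged_subjects`, `threshold_z`, `alpha`, `m`.
#' @export
abruption_scan <- function(fit, transitions, alpha = 0.05, m = NULL,
                           exclusions = NULL,
                           density = c("plugin", "predictive")) {
  keep <- !(transitions$subject %in% exclusions)
  if (!any(keep)) stop("no transitions remain after exclusions")
  tr <- subset_transitions(transitions, which(keep))
  nll <- sample_neglog10_likelihood(fit, tr, match.arg(density))
  mu <- mean(nll)
  sd_ <- stats::sd(nll)
  if (!is.finite(sd_) || sd_ == 0) {
    # identical records: z-scores are all zero, nothing can be flagged
    warning("degenerate likelihood distribution: zero variance across ",
            "records; no abruptions can be flagged")
    sd_ <- Inf
  }
  if (is.null(m)) m <- length(unique(tr$subject))
  z <- (nll - mu) / sd_
  pval <- stats::pnorm(z, lower.tail = FALSE)
  flagged <- pval < alpha / m
  records <- data.frame(subject = tr$subject,
                        target_day = tr$target_day,
                        gap_days = tr$gap_days,
                        neglog10_likelihood = nll,
                        z_score = z, p_value = pval, flagged = flagged)
  out <- list(records = records,
              flagged_subjects = sort(unique(tr$subject[flagged])),
              threshold_z = stats::qnorm(alpha / m, lower.tail = FALSE),
              alpha = alpha, m = m,
              mean_neglog10 = mu, sd_neglog10 = sd_)
  class(out) <- "abruption_report"
  out
}

#' @export
print.abruption_report <- function(x, ...) {
  cat(sprintf(
    "abruption_report: %d records, %d flagged (threshold p < %g / %d)\n",
    nrow(x$records), sum(x$records$flagged), x$alpha, x$m))
  if (length(x$flagged_subjects)) {
    cat("  flagged subjects:", paste(x$flagged_subjects, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Two-stage abruption protocol
#'
#' First scan, then exclude the flagged subjects and rescan the remainder,
#' mirroring the flag/remove/repeat procedure used to separate extreme
#' outliers from the next tier of unlikely transitions.
#'
#' @inheritParams abruption_scan
#' @return List with `first` and `second` abruption reports.
#' @export
abruption_scan_twostage <- function(fit, transitions, alpha = 0.05,
                                    m = NULL) {
  first <- abruption_scan(fit, transitions, alpha, m)
  second <- abruption_scan(fit, transitions, alpha, m,
                           exclusions = first$flagged_subjects)
  list(first = first, second = second)
}
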