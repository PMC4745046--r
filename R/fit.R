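## Parameter fitting and conditional densities.
##
## A fitted network carries, per continuous child and per discrete-parent
## configuration, the posterior-mean intercept, coefficient vector and
## residual variance under the conjugate prior; per discrete child it
## carries the Dirichlet prior mass and observed counts.  Configurations
## unobserved in training fall back to prior-only parameters (intercept 0,
## coefficients 0, variance sigma2), so densities are always defined.

# Sentinel label for the single configuration of a family with no
# discrete parents ("" cannot be used: empty names never match in R).
NO_CONFIG <- "(all)"

config_labels <- function(df, dparents, dlevels) {
  if (!length(dparents)) return(rep(NO_CONFIG, nrow(df)))
  cols <- lapply(dparents, function(v) {
    x <- df[[v]]
    if (is.null(x)) stop("incomplete evidence: missing parent '", v, "'")
    as.character(x)
  })
  do.call(paste, c(cols, sep = "."))
}

all_config_levels <- function(dlevels) {
  if (!length(dlevels)) return(NO_CONFIG)
  grid <- expand.grid(rev(dlevels), stringsAsFactors = FALSE)
  do.call(paste, c(rev(grid), sep = "."))
}

#' Fit network parameters
#'
#' Computes posterior parameters for every child of a structure from the
#' transition data.  Continuous children get, per discrete-parent
#' configuration, the posterior-mean regression coefficients and
#' posterior-mean residual variance of the conjugate normal-inverse-gamma
#' update; discrete children get the Dirichlet prior mass and per-cell
#' counts.
#'
#' @param structure A `dbn_structure`.
#' @param transitions A `dbn_transitions`.
#' @param priors A [dbn_priors()].
#' @return An object of class `dbn_fit` with elements `structure`,
#'   `priors`, `children` (per-child parameter records), `taxa` and
#'   `log_score` (the network score of the structure on this data).
#' @export
fit_dbn <- function(structure, transitions, priors = dbn_priors()) {
  validate_structure(structure)
  parent_kind <- node_kinds(transitions$parents)
  children <- list()
  for (ch in structure$children) {
    ps <- structure$parent_sets[[ch]]
    cparents <- ps[parent_kind[ps] == "continuous"]
    dparents <- ps[parent_kind[ps] == "discrete"]
    dlevels <- lapply(transitions$parents[dparents], levels)
    names(dlevels) <- dparents
    labels <- config_labels(transitions$parents, dparents, dlevels)
    lev <- all_config_levels(dlevels)
    y <- transitions$children[[ch]]
    if (is.numeric(y)) {
      X <- if (length(cparents)) {
        cbind(1, as.matrix(transitions$parents[cparents]))
      } else {
        matrix(1, nrow(transitions$parents), 1)
      }
      params <- lapply(lev, function(u) {
        i <- which(labels == u)
        post <- nig_posterior(y[i], X[i, , drop = FALSE],
                              priors$nu, priors$sigma2, priors$lambda)
        list(alpha = post$coef[1],
             beta = stats::setNames(post$coef[-1], cparents),
             sigma2 = post$sigma2, n = post$n,
             an = post$an, bn = post$bn, chol = post$chol)
      })
      names(params) <- lev
      children[[ch]] <- list(kind = "continuous", cparents = cparents,
                             dparents = dparents, dlevels = dlevels,
                             config_levels = lev, params = params)
    } else {
      y <- as.factor(y)
      states <- levels(y)
      a_cell <- priors$alpha_total / (length(lev) * length(states))
      counts <- matrix(0, length(lev), length(states),
                       dimnames = list(lev, states))
      tab <- table(factor(labels, levels = lev), y)
      counts[rownames(tab), colnames(tab)] <- as.numeric(tab)
      children[[ch]] <- list(kind = "discrete", cparents = character(0),
                             dparents = dparents, dlevels = dlevels,
                             config_levels = lev, states = states,
                             a_cell = a_cell, counts = counts)
    }
  }
  out <- list(structure = structure, priors = priors,
              children = children,
              taxa = intersect(transitions$taxa, structure$children),
              log_score = network_log_score(structure, transitions, priors))
  class(out) <- "dbn_fit"
  out
}

#' @export
print.dbn_fit <- function(x, ...) {
  cat(sprintf("dbn_fit: %d children, %d edges, log score %.3f\n",
              length(x$children),
              sum(lengths(x$structure$parent_sets)), x$log_score))
  invisible(x)
}

# Coerce parent evidence (named list or 1-row data frame) to a 1-row frame.
as_parent_row <- function(parent_values) {
  if (is.data.frame(parent_values)) {
    stopifnot(nrow(parent_values) == 1)
    return(parent_values)
  }
  if (!length(parent_values)) {
    return(as.data.frame(matrix(NA, 1, 0)))
  }
  as.data.frame(parent_values, optional = TRUE)
}

lookup_config <- function(rec, parent_row) {
  u <- config_labels(parent_row, rec$dparents, rec$dlevels)
  if (!u %in% rec$config_levels) {
    # unknown configuration: prior-only behaviour via the fallback level
    # cannot apply (levels enumerate the training factor space), so treat
    # as an error for continuous parents but allow prior-only discrete
    stop("unknown discrete-parent configuration: ", u)
  }
  u
}

#' Conditional log density of one child value
#'
#' Plug-in log density of an observed child value given a complete parent
#' assignment, using the posterior-mean parameters: a normal density at
#' `alpha(u) + beta(u) . v` for continuous children, the
#' Dirichlet-multinomial predictive probability for discrete children.
#'
#' @param fit A [fit_dbn()] result.
#' @param child Child node name.
#' @param value Observed value at t + 1 (numeric, or a state label).
#' @param parent_values Named list or 1-row data frame with every parent's
#'   value at time t; a missing parent raises an incomplete-evidence error.
#' @return Natural-log density (or log probability).
#' @export
conditional_log_density <- function(fit, child, value, parent_values) {
  rec <- fit$children[[child]]
  if (is.null(rec)) stop("unknown child node: ", child)
  row <- as_parent_row(parent_values)
  for (v in c(rec$cparents, rec$dparents)) {
    if (is.null(row[[v]]) || is.na(row[[v]])) {
      stop("incomplete evidence: missing parent '", v, "'")
    }
  }
  u <- lookup_config(rec, row)
  if (rec$kind == "continuous") {
    p <- rec$params[[u]]
    mu <- p$alpha + if (length(rec$cparents)) {
      sum(p$beta * as.numeric(row[rec$cparents]))
    } else 0
    stats::dnorm(as.numeric(value), mu, sqrt(p$sigma2), log = TRUE)
  } else {
    pr <- discrete_predictive(fit, child, row)
    z <- as.character(value)
    if (!z %in% names(pr)) stop("unknown state '", z, "' for ", child)
    log(pr[[z]])
  }
}

#' Posterior predictive distribution of a discrete child
#'
#' Probability vector proportional to `alpha[u, z] + n[u, z]`; an
#' unobserved configuration returns the prior-only (uniform, under the
#' symmetric prior) predictive.
#'
#' @param fit A [fit_dbn()] result.
#' @param child Name of a discrete child.
#' @param parent_config Named list or 1-row data frame assigning every
#'   discrete parent.
#' @return Named probability vector over the child's states (sums to 1).
#' @export
discrete_predictive <- function(fit, child, parent_config) {
  rec <- fit$children[[child]]
  if (is.null(rec) || rec$kind != "discrete") {
    stop("'", child, "' is not a discrete child of this fit")
  }
  row <- as_parent_row(parent_config)
  u <- config_labels(row, rec$dparents, rec$dlevels)
  nz <- if (u %in% rownames(rec$counts)) {
    rec$counts[u, ]
  } else {
    stats::setNames(rep(0, length(rec$states)), rec$states)
  }
  w <- rec$a_cell + nz
  w / sum(w)
}

# Vectorized conditional means of all continuous children over many rows.
predict_continuous <- function(fit, parents_df) {
  cont <- names(fit$children)[vapply(fit$children, `[[`, "", "kind") ==
                                "continuous"]
  out <- matrix(NA_real_, nrow(parents_df), length(cont),
                dimnames = list(NULL, cont))
  for (ch in cont) {
    rec <- fit$children[[ch]]
    labels <- config_labels(parents_df, rec$dparents, rec$dlevels)
    V <- if (length(rec$cparents)) {
      as.matrix(parents_df[rec$cparents])
    } else NULL
    for (u in unique(labels)) {
      i <- which(labels == u)
      p <- rec$params[[u]]
      if (is.null(p)) stop("unknown discrete-parent configuration: ", u)
      mu <- p$alpha + if (!is.null(V)) {
        drop(V[i, , drop = FALSE] %*% p$beta)
      } else 0
      out[i, ch] <- mu
    }
  }
  out
}

# Vectorized per-row total log density of all children (natural log).
# density = "plugin": normal at the posterior-mean parameters;
# density = "predictive": full posterior-predictive Student-t (heavier
# tails at small per-configuration sample sizes).
transition_log_density <- function(fit, transitions,
                                   density = c("plugin", "predictive")) {
  density <- match.arg(density)
  n <- nrow(transitions$parents)
  total <- numeric(n)
  for (ch in names(fit$children)) {
    rec <- fit$children[[ch]]
    labels <- config_labels(transitions$parents, rec$dparents, rec$dlevels)
    y <- transitions$children[[ch]]
    if (is.null(y)) stop("transitions lack child variable '", ch, "'")
    if (rec$kind == "continuous") {
      V <- if (length(rec$cparents)) {
        as.matrix(transitions$parents[rec$cparents])
      } else NULL
      for (u in unique(labels)) {
        i <- which(labels == u)
        p <- rec$params[[u]]
        if (is.null(p)) stop("unknown discrete-parent configuration: ", u)
        mu <- p$alpha + if (!is.null(V)) {
          drop(V[i, , drop = FALSE] %*% p$beta)
        } else 0
        if (density == "plugin") {
          total[i] <- total[i] +
            stats::dnorm(as.numeric(y[i]), mu, sqrt(p$sigma2), log = TRUE)
        } else {
          X <- if (!is.null(V)) {
            cbind(1, V[i, , drop = FALSE])
          } else {
            matrix(1, length(i), 1)
          }
          q <- forwardsolve(t(p$chol), t(X))
          scale2 <- (p$bn / p$an) * (1 + colSums(q^2))
          total[i] <- total[i] +
            stats::dt((as.numeric(y[i]) - mu) / sqrt(scale2),
                      df = 2 * p$an, log = TRUE) - 0.5 * log(scale2)
        }
      }
    } else {
      yc <- as.character(y)
      for (u in unique(labels)) {
        i <- which(labels == u)
        nz <- if (u %in% rownames(rec$counts)) rec$counts[u, ] else {
          stats::setNames(rep(0, length(rec$states)), rec$states)
        }
        w <- rec$a_cell + nz
        pr <- w / sum(w)
        total[i] <- total[i] + log(pr[yc[i]])
      }
    }
  }
  total
}

#' Serialize a fitted network to JSON
#'
#' Writes structure, priors, per-child parameters and the network score as
#' a single JSON document.
#'
#' @param fit A `dbn_fit`.
#' @param path Output file.
#' @export
write_dbn_json <- function(fit, path) {
  obj <- list(
    priors = unclass(fit$priors),
    structure = list(children = fit$structure$children,
                     parent_sets = fit$structure$parent_sets,
                     max_parents = fit$structure$max_parents),
    log_score = fit$log_score,
    children = lapply(fit$children, function(rec) {
      if (rec$kind == "continuous") {
        list(kind = rec$kind, cparents = rec$cparents,
             dparents = rec$dparents,
             params = lapply(rec$params, function(p) {
               list(alpha = p$alpha, beta = as.list(p$beta),
                    sigma2 = p$sigma2, n = p$n)
             }))
      } else {
        list(kind = rec$kind, dparents = rec$dparents,
             states = rec$states, a_cell = rec$a_cell,
             counts = as.data.frame(rec$counts))
      }
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
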