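# Independent oracles used by the unit and acceptance tests.  These
# deliberately avoid the package's closed-form code paths: the evidence
# oracle integrates the raw integrand on a grid, the structure oracle
# enumerates parent sets, and the regression oracle is ordinary least
# squares via lm().

# --- quadrature oracle for the continuous-family evidence ----------------
# log p(y | X) = log int N(y; X theta, s2 I) N(theta; 0, (s2/lambda) I)
#                        InvGamma(s2; nu/2, nu*sigma2/2) dtheta ds2
# Inner theta-integral: Simpson grid centred on the numerically located
# mode (the integrand is Gaussian in theta for fixed s2, so an 81-point
# grid over mode +/- 8 sd is essentially exact).  Outer s2-integral:
# adaptive quadrature on log(s2).
quad_log_evidence <- function(y, X, nu, sigma2, lambda = 1,
                              pts_per_dim = NULL) {
  n <- length(y)
  X <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
  d <- ncol(X)
  if (is.null(pts_per_dim)) pts_per_dim <- if (d >= 3) 61L else 81L
  log_inv_gamma <- function(s2, a, b) a * log(b) - lgamma(a) -
    (a + 1) * log(s2) - b / s2
  simpson_w <- function(m) {          # m odd
    c(1, rep(c(4, 2), (m - 3) / 2), 4, 1) / 3
  }
  # raw log-integrand in theta for fixed s2, vectorised over grid rows
  log_joint <- function(theta_mat, s2) {
    R <- matrix(y, n, nrow(theta_mat)) - X %*% t(theta_mat)
    (-n / 2) * log(2 * pi * s2) - colSums(R^2) / (2 * s2) +
      (-d / 2) * log(2 * pi * s2 / lambda) -
      rowSums(theta_mat^2) * lambda / (2 * s2)
  }
  inner_log <- function(s2) {
    neg <- function(th) -log_joint(matrix(th, 1), s2)
    opt <- stats::optim(rep(0, d), neg, method = "BFGS", hessian = TRUE)
    sds <- sqrt(diag(solve(opt$hessian)))
    grids <- lapply(seq_len(d), function(j) {
      seq(opt$par[j] - 8 * sds[j], opt$par[j] + 8 * sds[j],
          length.out = pts_per_dim)
    })
    ws <- lapply(grids, function(g) simpson_w(length(g)) * (g[2] - g[1]))
    pts <- as.matrix(expand.grid(grids))
    lv <- log_joint(pts, s2) + rowSums(log(as.matrix(expand.grid(ws))))
    mx <- max(lv)
    mx + log(sum(exp(lv - mx)))
  }

  a0 <- nu / 2
  b0 <- nu * sigma2 / 2
  offset <- inner_log(sigma2) + log_inv_gamma(sigma2, a0, b0)
  f <- function(u) {                  # u = log(s2)
    vapply(u, function(ui) {
      s2 <- exp(ui)
      exp(inner_log(s2) + log_inv_gamma(s2, a0, b0) + ui - offset)
    }, numeric(1))
  }
  int <- stats::integrate(f, lower = log(sigma2) - 14,
                          upper = log(sigma2) + 10,
                          rel.tol = 1e-8, subdivisions = 300L)
  offset + log(int$value)
}

# --- sequential (prequential) oracle for the same evidence ---------------
# Product of one-step posterior-predictive Student-t densities; an
# algebraically different factorization of the same marginal likelihood.
seq_log_evidence <- function(y, X, nu, sigma2, lam = 1) {
  X <- if (is.null(X)) matrix(1, length(y), 1) else cbind(1, X)
  d <- ncol(X)
  lambda <- diag(lam, d)
  eta <- rep(0, d)          # lambda %*% mean
  a <- nu / 2
  b <- nu * sigma2 / 2
  total <- 0
  for (i in seq_along(y)) {
    x <- X[i, ]
    m <- solve(lambda, eta)
    scale2 <- (b / a) * (1 + drop(t(x) %*% solve(lambda, x)))
    tval <- (y[i] - drop(crossprod(x, m))) / sqrt(scale2)
    total <- total + stats::dt(tval, df = 2 * a, log = TRUE) -
      0.5 * log(scale2)
    lambda_new <- lambda + tcrossprod(x)
    m_new <- solve(lambda_new, eta + x * y[i])
    b <- b + 0.5 * (y[i]^2 + drop(t(m) %*% lambda %*% m) -
                      drop(t(m_new) %*% lambda_new %*% m_new))
    a <- a + 0.5
    lambda <- lambda_new
    eta <- eta + x * y[i]
  }
  total
}

# --- exhaustive structure oracle -----------------------------------------
# The network score decomposes over children, so the global argmax is the
# per-child best parent subset; feasible for small candidate sets.
exhaustive_best_structure <- function(transitions, priors,
                                      children = NULL, parents = NULL) {
  if (is.null(children)) children <- sort(names(transitions$children))
  if (is.null(parents)) parents <- sort(names(transitions$parents))
  sets <- list()
  for (ch in children) {
    best <- character(0)
    best_score <- microdbn:::family_log_score(transitions, ch,
                                              character(0), priors)
    for (k in seq_len(min(priors$max_parents, length(parents)))) {
      combos <- utils::combn(parents, k, simplify = FALSE)
      for (ps in combos) {
        sc <- microdbn:::family_log_score(transitions, ch, ps, priors)
        if (sc > best_score + 1e-9) {
          best_score <- sc
          best <- sort(ps)
        }
      }
    }
    sets[[ch]] <- best
  }
  sets
}

# --- fixture builders ----------------------------------------------------

# Assemble a dbn_transitions directly from parent/child data frames.
make_transitions <- function(parents, children, subject = NULL) {
  n <- nrow(parents)
  structure(list(parents = parents, children = children,
                 subject = if (is.null(subject)) rep("S1", n) else subject,
                 gap_days = rep(1L, n), target_day = seq_len(n),
                 taxa = names(children)[vapply(children, is.numeric,
                                               logical(1))]),
            class = "dbn_transitions")
}

# k mutually independent zero-mean white-noise nodes at the fluctuation
# scale the model operates on (sd 0.05) -- unit-variance noise is not a
# plausible abundance fluctuation.
white_noise_transitions <- function(n = 500, k = 4, seed = 1,
                                    sd = 0.05) {
  set.seed(seed)
  mk <- function() as.data.frame(matrix(rnorm(n * k, 0, sd), n, k,
    dimnames = list(NULL, paste0("N", seq_len(k)))))
  make_transitions(mk(), mk())
}

# 4-node system with one planted edge N1 -> N2 (slope beta); the other
# children are independent noise.
planted4_transitions <- function(n = 500, beta = 0.8, sigma = 0.5,
                                 seed = 1) {
  set.seed(seed)
  parents <- as.data.frame(matrix(rnorm(n * 4), n, 4,
    dimnames = list(NULL, paste0("N", 1:4))))
  children <- as.data.frame(matrix(rnorm(n * 4), n, 4,
    dimnames = list(NULL, paste0("N", 1:4))))
  children$N2 <- beta * parents$N1 + rnorm(n, 0, sigma)
  make_transitions(parents, children)
}

# Tiny 1-subject cohort CSV on disk; returns the path.
toy_cohort_csv <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(subject_id = "A", day_of_life = c(3, 5, 6),
                   gestational_age = 28,
                   postconceptional_age = 28 + c(3, 5, 6) / 7,
                   antibiotics = 0, open_room = "closed",
                   Bacilli = c(80, 60, 20), Clostridia = c(20, 40, 80))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Small in-memory cohort with configurable subjects/samples.
toy_cohort <- function(n_subjects = 3, n_samples = 4, seed = 1,
                       taxa = c("Bacilli", "Clostridia", "unclassified")) {
  set.seed(seed)
  rows <- list(); counts <- list()
  for (s in seq_len(n_subjects)) {
    day <- cumsum(c(sample(3:5, 1), sample(1:2, n_samples - 1, TRUE)))
    ga <- runif(1, 24, 33)
    for (i in seq_len(n_samples)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = paste0("S", s), day_of_life = day[i],
        gestational_age = ga, postconceptional_age = ga + day[i] / 7,
        antibiotics = 0, open_room = sample(c("open", "closed"), 1))
      counts[[length(counts) + 1L]] <-
        stats::rmultinom(1, 1000, prob = rep(1, length(taxa)))[, 1]
    }
  }
  cm <- do.call(rbind, counts)
  colnames(cm) <- taxa
  as_cohort(do.call(rbind, rows), cm)
}
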