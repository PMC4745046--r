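## Conjugate marginal-likelihood (evidence) computations for the two
## conditional families used by the network score:
##   * continuous child | continuous parents, discrete-parent configuration:
##     Bayesian linear regression with a normal-inverse-gamma prior,
##   * discrete child | discrete parents: Dirichlet-multinomial.
## All scores are natural-log and decompose over discrete-parent
## configurations, which partition the rows.

# Normal-inverse-gamma log evidence for one configuration.
# X must already contain the intercept column.  Prior: coefficients ~
# N(0, sigma2_res/lambda * I) (ridge precision lambda per coefficient,
# scaled by the residual variance), sigma2_res ~ IG(nu/2, nu*sigma2/2).
nig_log_evidence <- function(y, X, nu, sigma2, lambda = 1) {
  n <- length(y)
  if (n == 0L) return(0)
  d <- ncol(X)
  lambda_n <- diag(lambda, d) + crossprod(X)
  ch <- chol(lambda_n)
  logdet_n <- 2 * sum(log(diag(ch)))
  xty <- crossprod(X, y)
  mu_n <- backsolve(ch, forwardsolve(t(ch), xty))
  a0 <- nu / 2
  an <- a0 + n / 2
  b0 <- nu * sigma2 / 2
  bn <- b0 + 0.5 * (sum(y * y) - sum(xty * mu_n))
  # bn > b0 > 0 mathematically; guard against rounding on near-exact fits
  bn <- max(bn, b0 * 1e-12, .Machine$double.xmin)
  -n / 2 * log(2 * pi) + 0.5 * (d * log(lambda) - logdet_n) +
    a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
}

# Posterior summaries for one configuration under the same prior.
# Returns posterior-mean coefficients and posterior-mean residual variance
# bn / (an - 1); an > 1 always holds in practice (nu >= 10 regimes), but a
# fallback to bn / an keeps tiny-nu experiments defined.
nig_posterior <- function(y, X, nu, sigma2, lambda = 1) {
  n <- length(y)
  d <- ncol(X)
  if (n == 0L) {
    return(list(coef = rep(0, d), sigma2 = sigma2, n = 0L,
                an = nu / 2, bn = nu * sigma2 / 2,
                chol = chol(diag(lambda, d))))
  }
  lambda_n <- diag(lambda, d) + crossprod(X)
  ch <- chol(lambda_n)
  xty <- crossprod(X, y)
  mu_n <- drop(backsolve(ch, forwardsolve(t(ch), xty)))
  a0 <- nu / 2
  an <- a0 + n / 2
  b0 <- nu * sigma2 / 2
  bn <- b0 + 0.5 * (sum(y * y) - sum(xty * mu_n))
  bn <- max(bn, .Machine$double.xmin)
  s2 <- if (an > 1) bn / (an - 1) else bn / an
  list(coef = mu_n, sigma2 = s2, n = n, an = an, bn = bn, chol = ch)
}

#' Log marginal likelihood of a continuous family
#'
#' Closed-form log evidence `log p(y | X, u)` of a conditional linear
#' Gaussian family: within each discrete-parent configuration `u` the child
#' is a linear regression on its continuous parents (plus intercept) with a
#' conjugate normal-inverse-gamma prior (see [dbn_priors()]), and the
#' coefficients and residual variance are integrated out analytically
#' (coefficient ridge precision `lambda`, variance prior
#' `IG(nu/2, nu*sigma2/2)`).
#' Contributions are summed across configurations, which partition the rows.
#'
#' @param y Numeric vector of child values (one per transition).
#' @param parents Numeric matrix of continuous-parent values
#'   (`length(y)` rows), or `NULL` for a parent-free family.
#' @param config Factor of discrete-parent configurations (one per row), or
#'   `NULL` when the family has no discrete parents.
#' @param priors A [dbn_priors()] object.
#' @return The log marginal likelihood (natural log).  Zero rows give 0
#'   (empty product).
#' @examples
#' pr <- dbn_priors()
#' y <- c(0.1, 0.3, 0.25, 0.4, 0.2)
#' x <- matrix(c(0.2, 0.25, 0.3, 0.35, 0.15), ncol = 1)
#' family_log_score_continuous(y, x, priors = pr)
#' @export
family_log_score_continuous <- function(y, parents = NULL, config = NULL,
                                        priors = dbn_priors()) {
  stopifnot(inherits(priors, "dbn_priors"))
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0L) return(0)
  if (is.null(parents)) {
    X <- matrix(1, n, 1)
  } else {
    parents <- as.matrix(parents)
    stopifnot(nrow(parents) == n)
    X <- cbind(1, parents)
  }
  if (is.null(config)) {
    return(nig_log_evidence(y, X, priors$nu, priors$sigma2,
                            priors$lambda))
  }
  config <- as.factor(config)
  stopifnot(length(config) == n)
  idx <- split(seq_len(n), config, drop = TRUE)
  sum(vapply(idx, function(i) {
    nig_log_evidence(y[i], X[i, , drop = FALSE], priors$nu,
                     priors$sigma2, priors$lambda)
  }, numeric(1)))
}

#' Log marginal likelihood of a discrete family
#'
#' Dirichlet-multinomial log evidence of a discrete child given its
#' (necessarily discrete) parents.  The prior mass `alpha_total` from
#' [dbn_priors()] is spread uniformly over all cells of the (parent
#' configuration x child state) table: each cell receives
#' `alpha_total / (n_configs * n_states)`.  Per configuration `u` with
#' prior row mass `A_u` and counts `n[u, z]` the contribution is
#' `log Gamma(A_u) - log Gamma(A_u + n_u) +
#'  sum_z [log Gamma(a_cell + n[u,z]) - log Gamma(a_cell)]`.
#'
#' @param y Factor of observed child states.  Unobserved levels keep prior
#'   mass only.
#' @param config Factor of discrete-parent configurations, or `NULL`.  Its
#'   level set (not just the observed levels) defines the number of
#'   configurations used to spread prior mass.
#' @param priors A [dbn_priors()] object.
#' @return Natural-log marginal likelihood; 0 for zero rows.
#' @examples
#' pr <- dbn_priors(alpha_total = 1)
#' y <- factor(c("a", "a", "a", "b"))
#' family_log_score_discrete(y, priors = pr)
#' # equals log[ G(1)/G(5) * G(3.5)/G(.5) * G(1.5)/G(.5) ]
#' @export
family_log_score_discrete <- function(y, config = NULL,
                                      priors = dbn_priors()) {
  stopifnot(inherits(priors, "dbn_priors"))
  y <- as.factor(y)
  n <- length(y)
  if (n == 0L) return(0)
  n_states <- nlevels(y)
  if (is.null(config)) {
    config <- factor(rep("", n))
  }
  config <- as.factor(config)
  stopifnot(length(config) == n)
  n_configs <- nlevels(config)
  a_cell <- priors$alpha_total / (n_configs * n_states)
  a_row <- a_cell * n_states
  tab <- table(config, y)   # observed-config rows only contribute
  total <- 0
  for (u in seq_len(nrow(tab))) {
    counts <- as.numeric(tab[u, ])
    n_u <- sum(counts)
    if (n_u == 0) next
    total <- total + lgamma(a_row) - lgamma(a_row + n_u) +
      sum(lgamma(a_cell + counts) - lgamma(a_cell))
  }
  total
}
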