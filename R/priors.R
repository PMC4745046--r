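#' Prior hyperparameters for conditional Gaussian network scoring
#'
#' Bundles the hyperparameters of the conjugate priors used to score and fit
#' two-slice networks.  Continuous children use a normal-inverse-gamma prior:
#' the residual variance has an inverse-gamma prior with shape `nu / 2` and
#' scale `nu * sigma2 / 2` (so `nu` is the prior equivalent sample size and
#' `sigma2` the prior assumed variance of each node), while the regression
#' coefficients (including the intercept) have prior mean 0 and a separate
#' ridge precision `lambda` per coefficient, scaled by the residual
#' variance.  Tying the coefficient precision to `nu` instead would shrink
#' slopes on proportion-scale predictors (sum of squares of order 1) by a
#' factor of ~`nu`, leaving most of the autoregressive signal in the
#' residual and producing spurious sibling edges; see the methods vignette.
#' Discrete children use a Dirichlet prior whose total mass `alpha_total`
#' is spread uniformly over all (parent configuration, child state) cells.
#'
#' Two regimes are bundled: the sparse regime (`nu = 10`, at most 3 parents
#' per child) imposes a strong complexity penalty; the dense regime
#' (`nu = 50`, at most 5 parents) admits more edges.
#'
#' @param nu Prior equivalent sample size (positive).
#' @param sigma2 Prior assumed residual variance (positive).
#' @param max_parents Maximum number of parents per child node (>= 1).
#' @param alpha_total Total Dirichlet prior mass for discrete children;
#'   defaults to `nu`.
#' @param lambda Ridge precision of the regression coefficients (default
#'   0.1, a weakly informative ridge: its prior slope standard deviation,
#'   `sqrt(sigma2_res / lambda)`, is several times the likelihood
#'   uncertainty for proportion-scale predictors, so fitted slopes are
#'   nearly unshrunk while edge admission still pays the Occam penalty
#'   `log((lambda + sum x^2) / lambda) / 2`).
#' @param regime Optional shortcut: `"sparse"` (nu = 10, 3 parents) or
#'   `"dense"` (nu = 50, 5 parents); overrides the other arguments.
#' @return An object of class `dbn_priors`.
#' @examples
#' dbn_priors()            # sparse regime defaults
#' dbn_priors(regime = "dense")
#' @export
dbn_priors <- function(nu = 10, sigma2 = 1, max_parents = 3,
                       alpha_total = nu, lambda = 0.1, regime = NULL) {
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("sparse", "dense"))
    if (regime == "sparse") {
      nu <- 10; sigma2 <- 1; max_parents <- 3
    } else {
      nu <- 50; sigma2 <- 1; max_parents <- 5
    }
    alpha_total <- nu
  }
  stopifnot(is.numeric(nu), length(nu) == 1, nu > 0,
            is.numeric(sigma2), length(sigma2) == 1, sigma2 > 0,
            is.numeric(max_parents), length(max_parents) == 1,
            max_parents >= 1,
            is.numeric(alpha_total), length(alpha_total) == 1,
            alpha_total > 0,
            is.numeric(lambda), length(lambda) == 1, lambda > 0)
  structure(list(nu = nu, sigma2 = sigma2,
                 max_parents = as.integer(max_parents),
                 alpha_total = alpha_total, lambda = lambda),
            class = "dbn_priors")
}

#' @param x A `dbn_priors` object.
#' @param ... Unused.
#' @rdname dbn_priors
#' @export
print.dbn_priors <- function(x, ...) {
  cat(sprintf(
    "CG network priors: nu = %g, sigma2 = %g, max_parents = %d, alpha_total = %g\n",
    x$nu, x$sigma2, x$max_parents, x$alpha_total))
  invisible(x)
}
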