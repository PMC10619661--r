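#' Shared Inter-GMM hyperparameters
#'
#' Constructs the prior shared by every agent in a naming game over a
#' K-component Gaussian mixture. Each mixture component of each agent carries a
#' Normal-Wishart prior: the component precision \eqn{\Lambda_k} is Wishart with
#' `nu` degrees of freedom and scale `beta_bar`, and the component mean
#' \eqn{\mu_k} given \eqn{\Lambda_k} is Gaussian with mean `m` and precision
#' \eqn{\bar\alpha \Lambda_k}. The prior over signs is the categorical
#' distribution `gamma`.
#'
#' `m` and `beta_bar` may be given in dimension-free form (a scalar `m`, a
#' scalar `beta_bar` meaning that scalar times the identity); they are expanded
#' to each agent's feature dimension when used. This lets one hyperparameter
#' object serve agents with different feature dimensionalities.
#'
#' The Wishart prior is proper only when `nu > F - 1` for feature dimension F.
#' Smaller `nu` (the classic weakly-informative `nu = 1` in F > 1) is accepted
#' here, but sampling component parameters *from the prior* then fails loudly;
#' posterior sampling is still well defined once a component holds at least
#' `F - nu + 1` observations (posterior degrees of freedom `nu + n_k`).
#'
#' @param K number of signs (mixture components) in the shared inventory.
#' @param gamma prior probability vector over the K signs; defaults to uniform.
#' @param m prior mean: scalar (broadcast) or numeric vector.
#' @param alpha_bar positive scalar scaling the mean precision.
#' @param nu Wishart degrees of freedom (> 0).
#' @param beta_bar Wishart scale: positive scalar (times identity) or a
#'   symmetric positive-definite matrix.
#' @return An object of class `inter_gmm_hyper`.
#' @examples
#' hy <- inter_gmm_hyper(K = 5, m = 0, alpha_bar = 1, nu = 1, beta_bar = 0.01)
#' hy$gamma
#' @export
inter_gmm_hyper <- function(K, gamma = NULL, m = 0, alpha_bar = 1, nu = 1,
                            beta_bar = 1) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  if (is.null(gamma)) gamma <- rep(1 / K, K)
  if (length(gamma) != K) {
    stop("`gamma` must have length K = ", K, ", got ", length(gamma))
  }
  if (any(gamma < 0) || abs(sum(gamma) - 1) > 1e-9) {
    stop("`gamma` must be a probability vector (non-negative, summing to 1)")
  }
  if (!is.numeric(alpha_bar) || length(alpha_bar) != 1L || alpha_bar <= 0) {
    stop("`alpha_bar` must be a positive scalar")
  }
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0) {
    stop("`nu` must be a positive scalar")
  }
  if (is.matrix(beta_bar)) {
    check_spd(beta_bar, "beta_bar")
  } else if (!is.numeric(beta_bar) || length(beta_bar) != 1L || beta_bar <= 0) {
    stop("scalar `beta_bar` must be positive")
  }
  structure(
    list(K = K, gamma = as.numeric(gamma), m = m, alpha_bar = alpha_bar,
         nu = nu, beta_bar = beta_bar),
    class = "inter_gmm_hyper"
  )
}

#' @export
print.inter_gmm_hyper <- function(x, ...) {
  cat("Inter-GMM hyperparameters\n")
  cat("  K =", x$K, " gamma =",
      if (stats::var(x$gamma) < 1e-12) sprintf("uniform 1/%d", x$K)
      else paste(signif(x$gamma, 3), collapse = " "), "\n")
  cat("  m =", paste(signif(x$m, 4), collapse = " "),
      " alpha_bar =", x$alpha_bar, " nu =", x$nu, "\n")
  cat("  beta_bar =",
      if (is.matrix(x$beta_bar)) sprintf("%dx%d matrix", nrow(x$beta_bar), ncol(x$beta_bar))
      else paste0(x$beta_bar, " (x identity)"), "\n")
  invisible(x)
}

check_spd <- function(mat, name) {
  if (nrow(mat) != ncol(mat) || max(abs(mat - t(mat))) > 1e-9) {
    stop("`", name, "` must be symmetric (tolerance 1e-9)")
  }
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`", name, "` must be positive definite")
  invisible(TRUE)
}

# Expand dimension-free hyperparameters to feature dimension F.
# Returns m (length-F vector), beta_bar (F x F), beta_inv (F x F) plus scalars.
expand_hyper <- function(hyper, F) {
  m <- hyper$m
  if (length(m) == 1L) m <- rep(as.numeric(m), F)
  if (length(m) != F) {
    stop("hyperparameter `m` has length ", length(m),
         " but the feature dimension is ", F)
  }
  bb <- hyper$beta_bar
  if (!is.matrix(bb)) bb <- diag(as.numeric(bb), F)
  if (nrow(bb) != F) {
    stop("hyperparameter `beta_bar` is ", nrow(bb), "x", ncol(bb),
         " but the feature dimension is ", F)
  }
  list(K = hyper$K, gamma = hyper$gamma, m = m, alpha_bar = hyper$alpha_bar,
       nu = hyper$nu, beta_bar = bb, beta_inv = chol2inv(chol(bb)))
}
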