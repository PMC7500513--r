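#' Piecewise learning predictor
#'
#' Two-stage learning curve on the latent probit scale: linear improvement
#' from trial 1 up to the breakpoint \code{tau} (the learning stage),
#' constant thereafter (the consolidation stage):
#' \code{intercept + slope * (min(t, tau) - 1)}.
#'
#' @param t trial number (>= 1). Vectorised.
#' @param tau breakpoint, in trial units (>= 1).
#' @param intercept latent level at trial 1.
#' @param slope learning rate per trial (non-negative in the fitted model).
#' @return latent predictor value(s).
#' @export
piecewise_predictor <- function(t, tau, intercept, slope) {
  intercept + slope * (pmin(t, tau) - 1)
}

#' Ordinal probit category probabilities
#'
#' Probability of each of the four PAS categories given a latent mean
#' \code{eta} and strictly increasing cutpoints:
#' \eqn{P(Y = k) = \Phi(\kappa_k - \eta) - \Phi(\kappa_{k-1} - \eta)} with
#' \eqn{\kappa_0 = -\infty}, \eqn{\kappa_4 = +\infty}.
#'
#' @param eta latent mean (scalar).
#' @param cutpoints numeric length-3, strictly increasing.
#' @return numeric length-4 summing to one.
#' @export
ordinal_probit_probs <- function(eta, cutpoints) {
  if (length(cutpoints) != 3L || any(diff(cutpoints) <= 0))
    stop("cutpoints must be 3 strictly increasing values")
  p <- diff(stats::pnorm(c(-Inf, cutpoints, Inf) - eta))
  as.numeric(p)
}

# P(l1 < Z1 <= u1, l2 < Z2 <= u2) for standard bivariate normal with
# correlation rho, by conditioning on Z1 and adaptive 1-D quadrature.
binorm_rect <- function(l1, u1, l2, u2, rho) {
  if (abs(rho) < 1e-12) {
    return((stats::pnorm(u1) - stats::pnorm(l1)) *
             (stats::pnorm(u2) - stats::pnorm(l2)))
  }
  s <- sqrt(1 - rho^2)
  f <- function(x)
    stats::dnorm(x) * (stats::pnorm((u2 - rho * x) / s) -
                         stats::pnorm((l2 - rho * x) / s))
  lo <- max(l1, -10); hi <- min(u1, 10)
  if (lo >= hi) return(0)
  stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

default_params <- function(md) {
  list(a = rep(0, md$n_individuals), b = rep(0, md$n_individuals),
       tau_s = rep(2, md$n_individuals), lambda_s = 0,
       c = rep(0, md$n_teams), lambda_g = 0,
       u = rep(0, md$n_individuals), v = rep(0, md$n_individuals),
       tau_p = rep(2, md$n_individuals),
       gamma_s = 0, gamma_g = 0, gamma_d = 0,
       cutpoints = c(-1, 0, 1), rho = 0)
}

#' Observed-data log-likelihood of the path model
#'
#' Sums three probit components: Bernoulli terms for individual success S
#' (latent predictor: piecewise learning curve plus the delay effect),
#' Bernoulli terms for joint success G (team intercept plus delay effect),
#' and ordinal terms for the observed PAS responses (piecewise learning
#' curve plus effects of S, G and D). When both members of a dyad have an
#' observed PAS in the same trial, their latent residuals are bivariate
#' normal with correlation \code{rho} and the pair contributes a bivariate
#' rectangle probability; a missing PAS contributes nothing.
#'
#' @param md a \code{\link{pc_model_data}}.
#' @param params list with elements \code{a, b, tau_s} (per individual),
#'   \code{lambda_s}, \code{c} (per team), \code{lambda_g}, \code{u, v,
#'   tau_p} (per individual), \code{gamma_s, gamma_g, gamma_d},
#'   \code{cutpoints} (length 3, increasing), \code{rho} in (-1, 1).
#' @return scalar log-likelihood.
#' @export
pc_log_likelihood <- function(md, params) {
  p <- utils::modifyList(default_params(md), params)
  if (!all(is.finite(unlist(p)))) stop("non-finite parameter value")
  if (any(diff(p$cutpoints) <= 0)) stop("cutpoints must be increasing")
  if (abs(p$rho) >= 1) stop("rho must lie in (-1, 1)")
  obs <- md$obs; trl <- md$trials
  eps <- 1e-12

  eta_s <- piecewise_predictor(obs$trial, p$tau_s[obs$individual],
                               p$a[obs$individual], p$b[obs$individual]) +
    p$lambda_s * obs$D
  ps <- pmin(pmax(stats::pnorm(eta_s), eps), 1 - eps)
  ll <- sum(ifelse(obs$S == 1L, log(ps), log1p(-ps)))

  eta_g <- p$c[trl$team] + p$lambda_g * trl$D
  pg <- pmin(pmax(stats::pnorm(eta_g), eps), 1 - eps)
  ll <- ll + sum(ifelse(trl$G == 1L, log(pg), log1p(-pg)))

  eta_y <- piecewise_predictor(obs$trial, p$tau_p[obs$individual],
                               p$u[obs$individual], p$v[obs$individual]) +
    p$gamma_s * obs$S + p$gamma_g * obs$G + p$gamma_d * obs$D
  kk <- c(-Inf, p$cutpoints, Inf)
  blocks <- pas_blocks(md)
  if (nrow(blocks$pairs)) {
    for (r in seq_len(nrow(blocks$pairs))) {
      i1 <- blocks$pairs[r, 1L]; i2 <- blocks$pairs[r, 2L]
      y1 <- obs$Y[i1]; y2 <- obs$Y[i2]
      pr <- binorm_rect(kk[y1] - eta_y[i1], kk[y1 + 1L] - eta_y[i1],
                        kk[y2] - eta_y[i2], kk[y2 + 1L] - eta_y[i2], p$rho)
      ll <- ll + log(max(pr, eps))
    }
  }
  for (i in blocks$singles) {
    y <- obs$Y[i]
    pr <- stats::pnorm(kk[y + 1L] - eta_y[i]) - stats::pnorm(kk[y] - eta_y[i])
    ll <- ll + log(max(pr, eps))
  }
  ll
}
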