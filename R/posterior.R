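#' Highest posterior density interval
#'
#' The narrowest interval containing a given fraction of the draws, computed
#' by scanning all contiguous windows of the sorted sample.
#'
#' @param x numeric vector of posterior draws (>= 100).
#' @param mass interval mass in (0, 1); default 0.95.
#' @return named numeric: \code{lower}, \code{upper}.
#' @export
hpdi <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 100) stop("need at least 100 draws for an HPDI")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(k + 1L):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Posterior summary table
#'
#' One row per reported parameter: the delay effects on individual and
#' joint success (lambda_s, lambda_g), the PAS effects of individual
#' success, joint success and delay (gamma_s, gamma_g, gamma_d), the
#' breakpoint hyper-means of the two learning curves (mu_tau_s, mu_tau_p),
#' and the residual within-dyad PAS correlation (rho); posterior mean, SD,
#' 95% HPDI bounds, split R-hat, effective sample size and a convergence
#' flag, at full precision.
#'
#' @param fit a \code{\link{pc_fit}}.
#' @param mass HPDI mass.
#' @return data frame.
#' @export
posterior_summary <- function(fit, mass = 0.95) {
  pm <- reported_parameters(fit$no_learning)
  keep <- c("lambda_s", "lambda_g", "gamma_s", "gamma_g", "gamma_d",
            "mu_tau_s", "mu_tau_p", "rho")
  pm <- pm[names(pm) %in% keep]
  dtab <- fit$diagnostics$table
  do.call(rbind, lapply(names(pm), function(nm) {
    x <- pc_draws(fit, nm)
    h <- hpdi(x, mass)
    i <- match(nm, dtab$parameter)
    data.frame(parameter = nm, mean = mean(x), sd = stats::sd(x),
               hpdi_lower = h[["lower"]], hpdi_upper = h[["upper"]],
               rhat = dtab$rhat[i], ess = dtab$ess[i],
               converged = dtab$rhat[i] <= 1.01 & dtab$ess[i] >= 400,
               stringsAsFactors = FALSE)
  }))
}

#' Posterior of the indirect delay -> joint success -> PAS effect
#'
#' The default contrast is the draw-wise product of the delay effect on
#' joint success (lambda_g) and the joint-success effect on PAS (gamma_g),
#' on the probit scale. The alternative \code{"categories"} contrast
#' propagates the pathway through the ordinal link: the difference in the
#' expected PAS category at a reference latent level when the joint-success
#' probability shifts from its D = 0 to its D = 1 value.
#'
#' @param fit a \code{\link{pc_fit}}.
#' @param type \code{"product"} (default) or \code{"categories"}.
#' @param eta_ref reference latent PAS level for the categories contrast.
#' @return numeric vector: one indirect-effect value per posterior draw.
#' @export
indirect_effect <- function(fit, type = c("product", "categories"),
                            eta_ref = 0) {
  type <- match.arg(type)
  lam_g <- pc_draws(fit, "lambda_g")
  gam_g <- pc_draws(fit, "gamma_g")
  if (type == "product") return(lam_g * gam_g)
  mu_c <- pc_draws(fit, "mu_c")
  k1 <- pc_draws(fit, "kappa1")
  k2 <- pc_draws(fit, "kappa2")
  k3 <- pc_draws(fit, "kappa3")
  vapply(seq_along(lam_g), function(i) {
    p1 <- stats::pnorm(mu_c[i] + lam_g[i])  # P(G=1 | D=1)
    p0 <- stats::pnorm(mu_c[i])             # P(G=1 | D=0)
    kk <- c(k1[i], k2[i], k3[i])
    ey <- function(pg) {
      pr <- pg * ordinal_probit_probs(eta_ref + gam_g[i], kk) +
        (1 - pg) * ordinal_probit_probs(eta_ref, kk)
      sum(pr * 1:4)
    }
    ey(p1) - ey(p0)
  }, numeric(1))
}
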