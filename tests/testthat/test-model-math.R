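test_that("the piecewise learning predictor plateaus at the breakpoint", {
  expect_equal(piecewise_predictor(5, 3, 0, 1), 2)
  expect_equal(piecewise_predictor(1:10, 4, 0.5, 0), rep(0.5, 10))
  expect_equal(piecewise_predictor(1, 7, -0.3, 0.2), -0.3)
  # constant for all t at or past the breakpoint
  expect_equal(piecewise_predictor(12, 4.5, 0, 0.3),
               piecewise_predictor(40, 4.5, 0, 0.3))
})

test_that("ordinal probit probabilities match the normal-CDF closed form", {
  p <- ordinal_probit_probs(0, c(-1, 0, 1))
  expect_equal(p, c(pnorm(-1), pnorm(0) - pnorm(-1), pnorm(1) - pnorm(0),
                    1 - pnorm(1)), tolerance = 1e-12)
  expect_equal(p[1], 0.1587, tolerance = 1e-3)
  expect_equal(ordinal_probit_probs(50, c(-1, 0, 1)), c(0, 0, 0, 1))
  set.seed(53)
  for (r in 1:50) {
    eta <- rnorm(1, 0, 2)
    kk <- sort(rnorm(3, 0, 2))
    if (any(diff(kk) == 0)) next
    pr <- ordinal_probit_probs(eta, kk)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    oracle <- diff(pnorm(c(-Inf, kk, Inf), mean = eta))
    expect_equal(pr, oracle, tolerance = 1e-12)
  }
  expect_error(ordinal_probit_probs(0, c(1, 0, -1)), "increasing")
})

test_that("larger latent means shift ordinal mass to higher categories", {
  kk <- c(-0.8, 0.3, 1.2)
  etas <- seq(-3, 3, by = 0.5)
  cum <- sapply(etas, function(e) cumsum(ordinal_probit_probs(e, kk))[1:3])
  # each cumulative probability is decreasing in eta (stochastic ordering)
  for (k in 1:3) expect_true(all(diff(cum[k, ]) < 0))
})

# a minimal one-team dataset: both players click in both trials
dyad_md <- function(Y = c(2L, 3L, 1L, 4L)) {
  obs <- data.frame(team = 1L, player = rep(1:2, 2),
                    individual = rep(1:2, 2), trial = rep(1:2, each = 2),
                    S = c(1L, 0L, 1L, 1L), G = c(0L, 0L, 1L, 1L),
                    D = c(0L, 0L, 1L, 1L), Y = Y)
  structure(list(obs = obs,
                 trials = data.frame(team = 1L, trial = 1:2,
                                     G = c(0L, 1L), D = c(0L, 1L)),
                 n_teams = 1L, n_individuals = 2L, t_max = 2L,
                 team_levels = 1L), class = "pc_model_data")
}

test_that("a single observation reduces to the analytic probit terms", {
  md <- dyad_md()
  md$obs <- md$obs[1, ]; md$trials <- md$trials[1, ]
  pars <- list(a = c(0.4, 0), b = c(0, 0), tau_s = c(2, 2), lambda_s = 0,
               c = -0.2, lambda_g = 0, u = c(0, 0), v = c(0, 0),
               tau_p = c(2, 2), gamma_s = 0, gamma_g = 0, gamma_d = 0,
               cutpoints = c(-1, 0, 1), rho = 0)
  ll <- pc_log_likelihood(md, pars)
  expected <- log(pnorm(0.4)) + log(1 - pnorm(-0.2)) +
    log(pnorm(0) - pnorm(-1))  # S = 1, G = 0, Y = 2 at eta 0
  expect_equal(ll, expected, tolerance = 1e-10)
})

test_that("with rho = 0 the likelihood is additive over observations", {
  md <- dyad_md()
  pars <- list(a = c(0.3, -0.1), b = c(0.2, 0.1), tau_s = c(1.5, 2),
               lambda_s = 0.7, c = 0.1, lambda_g = 1.0,
               u = c(0.2, -0.2), v = c(0.1, 0.05), tau_p = c(2, 2),
               gamma_s = -0.16, gamma_g = 0.69, gamma_d = 0.14,
               cutpoints = c(-1.2, 0.3, 1.2), rho = 0)
  ll1 <- pc_log_likelihood(md, pars)
  # duplicate the dyad as a second, identical team
  md2 <- md
  md2$obs <- rbind(md$obs, transform(md$obs, team = 2L,
                                     individual = individual + 2L))
  md2$trials <- rbind(md$trials, transform(md$trials, team = 2L))
  md2$n_teams <- 2L; md2$n_individuals <- 4L; md2$team_levels <- 1:2
  pars2 <- pars
  pars2$a <- rep(pars$a, 2); pars2$b <- rep(pars$b, 2)
  pars2$tau_s <- rep(pars$tau_s, 2); pars2$u <- rep(pars$u, 2)
  pars2$v <- rep(pars$v, 2); pars2$tau_p <- rep(pars$tau_p, 2)
  pars2$c <- rep(pars$c, 2)
  expect_equal(pc_log_likelihood(md2, pars2), 2 * ll1, tolerance = 1e-9)
})

test_that("correlated dyad PAS terms agree with 2-D quadrature", {
  md <- dyad_md()
  pars <- list(a = c(0.3, -0.1), b = c(0, 0), tau_s = c(2, 2),
               lambda_s = 0.7, c = 0.1, lambda_g = 1.0,
               u = c(0.2, -0.2), v = c(0, 0), tau_p = c(2, 2),
               gamma_s = -0.16, gamma_g = 0.69, gamma_d = 0.14,
               cutpoints = c(-1.2, 0.3, 1.2), rho = 0.5)
  ll <- pc_log_likelihood(md, pars)
  # independent oracle: trapezoid quadrature of the bivariate normal density
  # over each category rectangle
  bvn_rect_grid <- function(l1, u1, l2, u2, rho, n = 1001) {
    l1 <- max(l1, -8.5); u1 <- min(u1, 8.5)
    l2 <- max(l2, -8.5); u2 <- min(u2, 8.5)
    x <- seq(l1, u1, length.out = n); y <- seq(l2, u2, length.out = n)
    fx <- outer(x, y, function(a, b)
      exp(-(a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))) /
        (2 * pi * sqrt(1 - rho^2)))
    w <- rep(c(2, 4), length.out = n); w[c(1, n)] <- 1
    (t(w) %*% fx %*% w)[1, 1] * diff(x[1:2]) * diff(y[1:2]) / 9
  }
  eta <- function(i, S, G, D)
    pars$u[i] + pars$gamma_s * S + pars$gamma_g * G + pars$gamma_d * D
  kk <- c(-Inf, pars$cutpoints, Inf)
  oracle <- log(pnorm(0.3)) + log(1 - pnorm(-0.1)) +       # S trial 1
    log(pnorm(0.3 + 0.7)) + log(pnorm(-0.1 + 0.7)) +       # S trial 2 (D=1)
    log(1 - pnorm(0.1)) + log(pnorm(0.1 + 1.0)) +          # G terms
    log(bvn_rect_grid(kk[2] - eta(1, 1, 0, 0), kk[3] - eta(1, 1, 0, 0),
                      kk[3] - eta(2, 0, 0, 0), kk[4] - eta(2, 0, 0, 0), 0.5)) +
    log(bvn_rect_grid(kk[1] - eta(1, 1, 1, 1), kk[2] - eta(1, 1, 1, 1),
                      kk[4] - eta(2, 1, 1, 1), kk[5] - eta(2, 1, 1, 1), 0.5))
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("a missing PAS contributes nothing to the likelihood", {
  md_full <- dyad_md()
  md_miss <- dyad_md(Y = c(2L, NA_integer_, 1L, 4L))
  pars <- list(rho = 0.3, cutpoints = c(-1, 0, 1))
  ll_miss <- pc_log_likelihood(md_miss, pars)
  md_none <- dyad_md(Y = rep(NA_integer_, 4))
  ll_none <- pc_log_likelihood(md_none, pars)
  # with all latent means 0, the surviving terms are the trial-1 singleton
  # (Y = 2, now without its partner) and the trial-2 pair (Y = 1 and 4)
  p2 <- pnorm(0) - pnorm(-1)
  p_pair <- binorm_rect(-Inf, -1, 1, Inf, 0.3)
  expect_equal(ll_miss - ll_none, log(p2) + log(p_pair), tolerance = 1e-8)
})
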