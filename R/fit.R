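#' Prior settings for the path model
#'
#' Weakly informative defaults: Normal(0, 2.5^2) on regression effects and
#' hyper-means of intercepts, half-Normal(1) on random-effect SDs and on the
#' hyper-means of the (non-negative) learning slopes, Uniform(1, t_max) on
#' the breakpoint hyper-means with half-Normal(5) SDs, Uniform(-0.99, 0.99)
#' on the residual PAS correlation, and a diffuse ordered prior on the
#' cutpoints. The ordinal submodel is identified by fixing the latent
#' residual SD to 1 and the hyper-mean of the PAS intercepts to 0.
#'
#' @param effect_sd prior SD of regression effects (delay and path effects).
#' @param intercept_sd prior SD of intercept hyper-means.
#' @param re_sd_scale scale of the half-Normal priors on random-effect SDs.
#' @param slope_sd_scale scale of the half-Normal priors on slope hyper-means
#'   and SDs.
#' @param tau_sd_scale scale of the half-Normal prior on breakpoint SDs.
#' @param cutpoint_sd prior SD of the first cutpoint and of the positive
#'   increments between cutpoints.
#' @return a list of class \code{pc_priors}.
#' @export
pc_priors <- function(effect_sd = 2.5, intercept_sd = 2.5, re_sd_scale = 1,
                      slope_sd_scale = 1, tau_sd_scale = 5,
                      cutpoint_sd = 3) {
  structure(list(effect_sd = effect_sd, intercept_sd = intercept_sd,
                 re_sd_scale = re_sd_scale, slope_sd_scale = slope_sd_scale,
                 tau_sd_scale = tau_sd_scale, cutpoint_sd = cutpoint_sd),
            class = "pc_priors")
}

#' MCMC settings
#'
#' @param chains number of chains (>= 2).
#' @param adapt adaptation iterations.
#' @param burnin burn-in iterations discarded after adaptation.
#' @param iterations retained sampling iterations per chain.
#' @param thin thinning interval.
#' @return a list of class \code{pc_mcmc}.
#' @export
pc_mcmc_config <- function(chains = 2, adapt = 500, burnin = 500,
                           iterations = 1500, thin = 1) {
  if (chains < 2) stop("need at least 2 chains for convergence diagnostics")
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 burnin = as.integer(burnin),
                 iterations = as.integer(iterations),
                 thin = as.integer(thin)), class = "pc_mcmc")
}

pc_jags_model <- function(priors, no_learning = FALSE) {
  pe <- 1 / priors$effect_sd^2
  pi_ <- 1 / priors$intercept_sd^2
  pre <- 1 / priors$re_sd_scale^2
  psl <- 1 / priors$slope_sd_scale^2
  pta <- 1 / priors$tau_sd_scale^2
  pk <- 1 / priors$cutpoint_sd^2
  learn_s <- if (no_learning) "0" else
    "b[indS[k]] * (min(tS[k], tauS[indS[k]]) - 1)"
  learn_p <- function(ind, t) {
    if (no_learning) "0" else
      sprintf("v[%s] * (min(%s, tauP[%s]) - 1)", ind, t, ind)
  }
  re_learning <- if (no_learning) "
    for (i in 1:NI) {
      a[i] ~ dnorm(mu_a, pow(sig_a, -2))
      u[i] ~ dnorm(0, pow(sig_u, -2))
    }
    mu_tauS <- 1; mu_tauP <- 1
  " else sprintf("
    for (i in 1:NI) {
      a[i] ~ dnorm(mu_a, pow(sig_a, -2))
      b[i] ~ dnorm(mu_b, pow(sig_b, -2)) T(0,)
      tauS[i] ~ dnorm(mu_tauS, pow(sig_tauS, -2)) T(1, Tmax)
      u[i] ~ dnorm(0, pow(sig_u, -2))
      v[i] ~ dnorm(mu_v, pow(sig_v, -2)) T(0,)
      tauP[i] ~ dnorm(mu_tauP, pow(sig_tauP, -2)) T(1, Tmax)
    }
    mu_b ~ dnorm(0, %g) T(0,)
    mu_v ~ dnorm(0, %g) T(0,)
    mu_tauS ~ dunif(1, Tmax)
    mu_tauP ~ dunif(1, Tmax)
    sig_b ~ dnorm(0, %g) T(0,)
    sig_v ~ dnorm(0, %g) T(0,)
    sig_tauS ~ dnorm(0, %g) T(0,)
    sig_tauP ~ dnorm(0, %g) T(0,)
  ", psl, psl, psl, psl, pta, pta)

  sprintf("
model {
  # individual success: piecewise learning + delay effect
  for (k in 1:NS) {
    etaS[k] <- a[indS[k]] + %s + lamS * DS[k]
    pS[k] <- max(1.0E-7, min(1 - 1.0E-7, phi(etaS[k])))
    S[k] ~ dbern(pS[k])
  }
  # joint success: team intercept + delay effect
  for (k in 1:NG) {
    etaG[k] <- c[teamG[k]] + lamG * DG[k]
    pG[k] <- max(1.0E-7, min(1 - 1.0E-7, phi(etaG[k])))
    G[k] ~ dbern(pG[k])
  }
  # PAS, dyad pairs: correlated latent bivariate normal, thresholded
  for (p in 1:NP) {
    muP[p, 1] <- u[indP1[p]] + %s + gamS * SP1[p] + gamG * GP[p] + gamD * DP[p]
    muP[p, 2] <- u[indP2[p]] + %s + gamS * SP2[p] + gamG * GP[p] + gamD * DP[p]
    zP[p, 1:2] ~ dmnorm(muP[p, 1:2], Om[1:2, 1:2])
    Y1[p] ~ dinterval(zP[p, 1], kappa[1:3])
    Y2[p] ~ dinterval(zP[p, 2], kappa[1:3])
  }
  # PAS, unpaired observations
  for (s in 1:NQ) {
    muQ[s] <- u[indQ[s]] + %s + gamS * SQ[s] + gamG * GQ[s] + gamD * DQ[s]
    zQ[s] ~ dnorm(muQ[s], 1)
    Yq[s] ~ dinterval(zQ[s], kappa[1:3])
  }
  %s
  for (j in 1:NJ) { c[j] ~ dnorm(mu_c, pow(sig_c, -2)) }
  lamS ~ dnorm(0, %g)
  lamG ~ dnorm(0, %g)
  gamS ~ dnorm(0, %g)
  gamG ~ dnorm(0, %g)
  gamD ~ dnorm(0, %g)
  mu_a ~ dnorm(0, %g)
  mu_c ~ dnorm(0, %g)
  sig_a ~ dnorm(0, %g) T(0,)
  sig_c ~ dnorm(0, %g) T(0,)
  sig_u ~ dnorm(0, %g) T(0,)
  rho ~ dunif(-0.99, 0.99)
  Om[1, 1] <- 1 / (1 - rho * rho)
  Om[2, 2] <- 1 / (1 - rho * rho)
  Om[1, 2] <- -rho / (1 - rho * rho)
  Om[2, 1] <- -rho / (1 - rho * rho)
  kappa[1] ~ dnorm(0, %g)
  dk2 ~ dnorm(0, %g) T(0,)
  dk3 ~ dnorm(0, %g) T(0,)
  kappa[2] <- kappa[1] + dk2
  kappa[3] <- kappa[2] + dk3
}",
          learn_s,
          learn_p("indP1[p]", "tP[p]"), learn_p("indP2[p]", "tP[p]"),
          learn_p("indQ[s]", "tQ[s]"),
          re_learning,
          pe, pe, pe, pe, pe, pi_, pi_, pre, pre, pre, pk, pk, pk)
}

pc_jags_data <- function(md) {
  obs <- md$obs; trl <- md$trials
  blocks <- pas_blocks(md)
  pr <- blocks$pairs
  sg <- blocks$singles
  dat <- list(
    NS = nrow(obs), NG = nrow(trl), NI = md$n_individuals, NJ = md$n_teams,
    NP = nrow(pr), NQ = length(sg), Tmax = md$t_max,
    indS = obs$individual, tS = obs$trial, DS = obs$D, S = obs$S,
    teamG = trl$team, DG = trl$D, G = trl$G,
    indP1 = obs$individual[pr[, 1L]], indP2 = obs$individual[pr[, 2L]],
    tP = obs$trial[pr[, 1L]],
    SP1 = obs$S[pr[, 1L]], SP2 = obs$S[pr[, 2L]],
    GP = obs$G[pr[, 1L]], DP = obs$D[pr[, 1L]],
    Y1 = obs$Y[pr[, 1L]] - 1L, Y2 = obs$Y[pr[, 2L]] - 1L,
    indQ = obs$individual[sg], tQ = obs$trial[sg],
    SQ = obs$S[sg], GQ = obs$G[sg], DQ = obs$D[sg],
    Yq = obs$Y[sg] - 1L)
  # drop empty blocks: JAGS rejects zero-length loops' data vectors
  if (dat$NP == 0L)
    dat[c("indP1", "indP2", "tP", "SP1", "SP2", "GP", "DP", "Y1", "Y2")] <- NULL
  if (dat$NQ == 0L)
    dat[c("indQ", "tQ", "SQ", "GQ", "DQ", "Yq")] <- NULL
  dat
}

# latent z initial value consistent with an observed category under the
# initial cutpoints (-1, 0, 1)
z_init_for <- function(y) c(-1.5, -0.5, 0.5, 1.5)[y]

pc_jags_inits <- function(md, mcmc, seed, no_learning) {
  dat <- pc_jags_data(md)
  lapply(seq_len(mcmc$chains), function(ch) {
    ini <- list(
      lamS = 0, lamG = 0, gamS = 0, gamG = 0, gamD = 0,
      mu_a = 0, mu_c = 0, sig_a = 0.5, sig_c = 0.5, sig_u = 0.5,
      a = rep(0, md$n_individuals), c = rep(0, md$n_teams),
      u = rep(0, md$n_individuals),
      rho = 0, kappa = c(-1, NA, NA), dk2 = 1, dk3 = 1,
      .RNG.name = "base::Wichmann-Hill",
      .RNG.seed = (as.integer(seed) %% 100000L) * 1000L + ch)
    if (!no_learning) {
      # overdispersed breakpoint starting points: odd chains start early,
      # even chains late, so split R-hat flags poor traversal honestly
      tau0 <- if (ch %% 2L == 1L) 2 else
        min(md$t_max - 1, max(2, md$t_max / 2))
      ini$b <- rep(0.05, md$n_individuals)
      ini$v <- rep(0.05, md$n_individuals)
      ini$tauS <- rep(tau0, md$n_individuals)
      ini$tauP <- rep(tau0, md$n_individuals)
      ini$mu_b <- 0.05; ini$mu_v <- 0.05
      ini$mu_tauS <- tau0; ini$mu_tauP <- tau0
      ini$sig_b <- 0.2; ini$sig_v <- 0.2
      ini$sig_tauS <- 2; ini$sig_tauP <- 2
    }
    if (!is.null(dat$Y1)) {
      z <- cbind(z_init_for(dat$Y1 + 1L), z_init_for(dat$Y2 + 1L))
      z[is.na(z)] <- 0
      ini$zP <- z
    }
    if (!is.null(dat$Yq)) {
      zq <- z_init_for(dat$Yq + 1L)
      zq[is.na(zq)] <- 0
      ini$zQ <- zq
    }
    ini
  })
}

#' Fit the hierarchical Bayesian path model
#'
#' Samples the posterior of the path model by MCMC (Gibbs sampling via
#' JAGS). The model comprises a binary probit submodel for individual
#' success with a piecewise learning curve (individual intercepts, slopes
#' and breakpoints) and an inter-click delay effect; a binary probit
#' submodel for joint success with team intercepts and a delay effect; and
#' an ordinal probit submodel for the PAS responses with its own piecewise
#' learning curve, effects of individual success, joint success and delay,
#' three free cutpoints, and a residual correlation between the two dyad
#' members' latent PAS variables.
#'
#' @param md a \code{\link{pc_model_data}} with at least 2 teams.
#' @param priors a \code{\link{pc_priors}}.
#' @param mcmc a \code{\link{pc_mcmc_config}}.
#' @param seed integer; fixes all sampler randomness (reproducible draws).
#' @param no_learning if \code{TRUE}, fixes all learning slopes to zero,
#'   reducing the model to a plain hierarchical probit (used for
#'   cross-checks against independent probit fits).
#' @param monitor extra node names to monitor besides the reported
#'   parameters.
#' @param quiet suppress JAGS progress output.
#' @return object of class \code{pc_fit}: \code{draws} (a
#'   \code{coda::mcmc.list}), \code{diagnostics} (split R-hat and effective
#'   sample size per reported parameter, a convergence flag, and whether
#'   the sampler's adaptation phase completed within \code{mcmc$adapt}),
#'   \code{seed}, \code{mcmc}, \code{priors}, \code{no_learning}, and the
#'   parameter name map.
#' @export
pc_fit <- function(md, priors = pc_priors(), mcmc = pc_mcmc_config(),
                   seed = 1L, no_learning = FALSE, monitor = character(),
                   quiet = TRUE) {
  stopifnot(inherits(md, "pc_model_data"))
  if (md$n_teams < 2) stop("need at least 2 teams to fit the model")
  if (all(md$obs$S == 1L) || all(md$obs$S == 0L))
    warning("degenerate data: individual success has no variation; ",
            "the fit is prior-dominated")
  model_str <- pc_jags_model(priors, no_learning)
  dat <- pc_jags_data(md)
  if (no_learning)  # trial numbers and bounds only enter the learning terms
    dat[intersect(c("tS", "tP", "tQ", "Tmax"), names(dat))] <- NULL
  inits <- pc_jags_inits(md, mcmc, seed, no_learning)
  params <- c("lamS", "lamG", "gamS", "gamG", "gamD", "rho", "kappa",
              "mu_a", "mu_c", "sig_a", "sig_c", "sig_u")
  if (!no_learning)
    params <- c(params, "mu_tauS", "mu_tauP", "mu_b", "mu_v",
                "sig_b", "sig_v", "sig_tauS", "sig_tauP")
  params <- union(params, monitor)
  adapted <- TRUE
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model_str), data = dat,
                      inits = inits, n.chains = mcmc$chains,
                      n.adapt = mcmc$adapt, quiet = quiet),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        adapted <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (mcmc$burnin > 0)
    update(jm, mcmc$burnin, progress.bar = if (quiet) "none" else "text")
  draws <- rjags::coda.samples(jm, params, n.iter = mcmc$iterations,
                               thin = mcmc$thin,
                               progress.bar = if (quiet) "none" else "text")
  diag <- pc_diagnostics(draws, reported_parameters(no_learning))
  diag$adaptation_complete <- adapted
  structure(list(draws = draws, diagnostics = diag, seed = as.integer(seed),
                 mcmc = mcmc, priors = priors, no_learning = no_learning,
                 n_obs = nrow(md$obs), n_teams = md$n_teams),
            class = "pc_fit")
}

# canonical (report) names -> JAGS node names
param_map <- function() {
  c(lambda_s = "lamS", lambda_g = "lamG", gamma_s = "gamS",
    gamma_g = "gamG", gamma_d = "gamD", mu_tau_s = "mu_tauS",
    mu_tau_p = "mu_tauP", rho = "rho",
    kappa1 = "kappa[1]", kappa2 = "kappa[2]", kappa3 = "kappa[3]",
    mu_a = "mu_a", mu_c = "mu_c")
}

reported_parameters <- function(no_learning = FALSE) {
  pm <- param_map()
  if (no_learning) pm <- pm[!names(pm) %in% c("mu_tau_s", "mu_tau_p")]
  pm
}

#' @export
print.pc_fit <- function(x, ...) {
  cat("<pc_fit>", x$n_obs, "observations,", x$n_teams, "teams;",
      length(x$draws), "chains x", nrow(x$draws[[1]]), "draws\n")
  if (!x$diagnostics$converged)
    cat("convergence warning:",
        paste(x$diagnostics$flagged, collapse = ", "), "\n")
  print(posterior_summary(x))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param fit a \code{pc_fit}.
#' @param parameter canonical name (e.g. \code{"gamma_g"}) or JAGS node
#'   name.
#' @return numeric vector of pooled posterior draws.
#' @export
pc_draws <- function(fit, parameter) {
  pm <- param_map()
  node <- if (parameter %in% names(pm)) pm[[parameter]] else parameter
  mat <- as.matrix(fit$draws)
  if (!node %in% colnames(mat)) stop("unknown parameter: ", parameter)
  as.numeric(mat[, node])
}

split_rhat <- function(chains_mat) {
  # chains_mat: iterations x chains; split each chain in half
  n <- nrow(chains_mat)
  half <- floor(n / 2)
  sub <- cbind(chains_mat[seq_len(half), , drop = FALSE],
               chains_mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

pc_diagnostics <- function(draws, pm) {
  mat_list <- lapply(draws, as.matrix)
  out <- do.call(rbind, lapply(names(pm), function(nm) {
    node <- pm[[nm]]
    if (!node %in% colnames(mat_list[[1]])) return(NULL)
    cm <- sapply(mat_list, function(m) m[, node])
    data.frame(parameter = nm, rhat = split_rhat(cm),
               ess = as.numeric(coda::effectiveSize(
                 coda::as.mcmc.list(lapply(seq_len(ncol(cm)), function(i)
                   coda::mcmc(cm[, i]))))),
               stringsAsFactors = FALSE)
  }))
  flagged <- out$parameter[out$rhat > 1.01 | out$ess < 400]
  list(table = out, converged = length(flagged) == 0L, flagged = flagged)
}
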