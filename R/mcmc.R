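#' MCMC configuration
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param seeds Optional integer seeds, one per chain.
#' @param save_states Store latent-state and rate draws (needed for
#'   posterior predictive checks, tLTRE and projections).
#' @return An `imm_mcmc_config` object; element `draws_per_chain` gives the
#'   retained draw count `floor((n_iter - n_burn) / thin)`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 6000L, n_burn = 1000L,
                        thin = 5L, seeds = NULL, save_states = TRUE) {
  stopifnot(n_burn < n_iter, thin >= 1L, n_chains >= 1L)
  if (is.null(seeds)) seeds <- seq_len(n_chains)
  stopifnot(length(seeds) == n_chains)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seeds = as.integer(seeds), save_states = save_states,
                 draws_per_chain = (as.integer(n_iter) - as.integer(n_burn)) %/%
                   as.integer(thin)),
            class = "imm_mcmc_config")
}

#' Total retained draws implied by a configuration
#' @param config An `imm_mcmc_config`.
#' @return Integer: chains times retained draws per chain.
#' @export
n_retained <- function(config) config$n_chains * config$draws_per_chain

# ---- flattening to the C++ core ---------------------------------------------

imm_data_to_cpp <- function(data) {
  T_ <- data$n_years
  y <- data$y
  y[!is.na(y) & y <= 0] <- NA_real_
  list(G = 4L, Gf = 3L, T = T_,
       y = matrix(as.numeric(y), 4L, T_),
       jobs = matrix(as.numeric(data$jobs), 4L, T_),
       x = as.numeric(data$covs$x),
       storms = matrix(as.numeric(data$covs$storms), 4L, T_ - 1L),
       h = as.integer(data$covs$h),
       marr_counts = data$marr$counts,
       marr_g = as.integer(data$marr$rel$group_i - 1L),
       marr_a = as.integer(ifelse(data$marr$rel$age == "J", 0L, 1L)),
       marr_r = as.integer(data$marr$rel$year - 1L),
       f_age = as.integer(ifelse(imm_flows()$age == "J", 0L, 1L)),
       f_from = as.integer(imm_flows()$from_i - 1L),
       f_to = as.integer(imm_flows()$to_i - 1L))
}

imm_spec_to_cpp <- function(spec) {
  list(initA_lo = as.numeric(spec$initA_bounds[, 1]),
       initA_hi = as.numeric(spec$initA_bounds[, 2]),
       apsi_max = spec$alpha_psi_max,
       bg_sd = normal_prior_sd(spec$beta_gamma_scale, spec$normal_reading),
       mu_sd = normal_prior_sd(spec$mu_scale, spec$normal_reading),
       lam_rate = spec$lambda_rate,
       sg_max = spec$sigma_gamma_max,
       sphi_max = spec$sigma_phi_max,
       spsi_max = spec$sigma_psi_max,
       sp_max = spec$sigma_p_max,
       tau_a = spec$tau_prior[["shape"]],
       tau_b = spec$tau_prior[["rate"]],
       laplace_sq = spec$laplace_scale == "inv_lambda_sq",
       tau_is_var = spec$tau_reading == "variance")
}

hyper_to_init <- function(hyper, latent) {
  list(alpha_gamma = hyper$alpha_gamma,
       beta_gamma = as.numeric(hyper$beta_gamma),
       sigma_gamma = hyper$sigma_gamma,
       eps_gamma = as.numeric(hyper$eps_gamma),
       alpha_phiJ = hyper$alpha_phiJ,
       beta_stormJ = hyper$beta_stormJ,
       huntJ = as.numeric(hyper$huntJ),
       alpha_phiA = hyper$alpha_phiA,
       beta_stormA = hyper$beta_stormA,
       huntA = as.numeric(hyper$huntA),
       mu_beta = hyper$mu_beta,
       lambda_beta = hyper$lambda_beta,
       mu_hunt = as.numeric(hyper$mu_hunt),
       lambda_hunt = as.numeric(hyper$lambda_hunt),
       sigma_phiJ = hyper$sigma_phiJ,
       sigma_phiA = hyper$sigma_phiA,
       eps_phiJ = as.numeric(hyper$eps_phiJ),
       eps_phiA = as.numeric(hyper$eps_phiA),
       alpha_psi = as.numeric(hyper$alpha_psi),
       sigma_psi = hyper$sigma_psi,
       eps_psi = as.numeric(hyper$eps_psi),
       alpha_p = hyper$alpha_p,
       sigma_p = hyper$sigma_p,
       eps_p = as.numeric(hyper$eps_p),
       tau_y = hyper$tau_y,
       A1 = as.numeric(latent$A[, 1]),
       J = as.numeric(latent$J),
       N1 = as.numeric(latent$N1),
       Nad = as.numeric(latent$Nad),
       I = as.numeric(latent$I))
}

# draw a hyperparameter set from the priors (year effects jittered small so
# that the variance conditionals are non-degenerate at the start)
draw_hyper_from_prior <- function(spec) {
  T_ <- spec$n_years
  nf <- nrow(spec$flows)
  bsd <- normal_prior_sd(spec$beta_gamma_scale, spec$normal_reading)
  msd <- normal_prior_sd(spec$mu_scale, spec$normal_reading)
  mu_beta <- stats::rnorm(2, 0, msd)
  lambda_beta <- stats::rexp(2, spec$lambda_rate)
  mu_hunt <- matrix(stats::rnorm(4, 0, msd), 2, 2)
  lambda_hunt <- matrix(stats::rexp(4, spec$lambda_rate), 2, 2)
  rlap <- function(n, mu, b) mu + sample(c(-1, 1), n, TRUE) * stats::rexp(n, 1 / b)
  bJ <- laplace_b(lambda_beta[1], spec$laplace_scale)
  bA <- laplace_b(lambda_beta[2], spec$laplace_scale)
  # cap Laplace scales during initialisation so starting effects stay sane
  bJ <- min(bJ, 1); bA <- min(bA, 1)
  huntJ <- matrix(0, 3, 2); huntA <- matrix(0, 4, 2)
  for (h in 1:2) {
    huntJ[, h] <- rlap(3, mu_hunt[1, h],
                       min(laplace_b(lambda_hunt[1, h], spec$laplace_scale), 1))
    huntA[, h] <- rlap(4, mu_hunt[2, h],
                       min(laplace_b(lambda_hunt[2, h], spec$laplace_scale), 1))
  }
  imm_hyper(
    n_years = T_,
    alpha_gamma = stats::runif(4, 0.02, 0.6),
    beta_gamma = matrix(stats::rnorm(16, 0, min(bsd, 0.5)), 4, 4),
    sigma_gamma = stats::runif(1, 0.1, 0.6),
    alpha_phiJ = stats::runif(3, 0.4, 0.95),
    alpha_phiA = stats::runif(4, 0.4, 0.97),
    beta_stormJ = rlap(3, mu_beta[1], bJ) * 0.3,
    beta_stormA = rlap(4, mu_beta[2], bA) * 0.3,
    huntJ = huntJ * 0.3, huntA = huntA * 0.3,
    mu_beta = mu_beta, lambda_beta = lambda_beta,
    mu_hunt = mu_hunt, lambda_hunt = lambda_hunt,
    sigma_phiJ = stats::runif(1, 0.1, 0.5),
    sigma_phiA = stats::runif(1, 0.1, 0.5),
    alpha_psi = stats::runif(nrow(spec$flows), 0.005, spec$alpha_psi_max * 0.8),
    sigma_psi = stats::runif(1, 0.1, 0.5),
    alpha_p = c(stats::runif(3, 0.3, 0.97), stats::runif(1, 0.05, 0.8)),
    sigma_p = stats::runif(1, 0.1, 0.5),
    tau_y = stats::runif(1, 0.001, 0.05),
    eps_gamma = matrix(stats::rnorm(4 * T_, 0, 0.05), 4, T_),
    eps_phiJ = matrix(stats::rnorm(3 * (T_ - 1), 0, 0.05), 3, T_ - 1),
    eps_phiA = matrix(stats::rnorm(4 * (T_ - 1), 0, 0.05), 4, T_ - 1),
    eps_psi = matrix(stats::rnorm(nf * (T_ - 1), 0, 0.05), nf, T_ - 1),
    eps_p = matrix(stats::rnorm(4 * (T_ - 1), 0, 0.05), 4, T_ - 1)
  )
}

# data-driven latent initial values satisfying all support constraints
init_latents <- function(data, spec) {
  T_ <- data$n_years
  y <- data$y
  for (i in 1:4) y[i, ] <- interpolate_counts(y[i, ])
  jobs <- data$jobs
  J <- matrix(0, 4, T_); N1 <- matrix(0, 4, T_)
  Nad <- matrix(0, 4, T_); I <- matrix(0, 4, T_)
  J[] <- ifelse(is.na(jobs), pmax(0, round_half_up(0.1 * y)), jobs)
  Atarget <- round_half_up(y) - J
  Atarget[Atarget < 1] <- 1
  A1 <- pmin(pmax(Atarget[, 1], spec$initA_bounds[, 1]), spec$initA_bounds[, 2])
  A_prev <- A1
  for (t in 2:T_) {
    N1[, t] <- pmin(J[, t - 1], round_half_up(0.5 * J[, t - 1]))
    Nad[, t] <- pmin(A_prev, round_half_up(0.8 * A_prev))
    I[, t] <- pmax(0, Atarget[, t] - N1[, t] - Nad[, t])
    A_prev <- N1[, t] + Nad[, t] + I[, t]
  }
  imm_states(J, N1, Nad, I, A1)
}

#' Fit by MCMC
#'
#' Generic entry point. The method for `imm_data` runs the compiled adaptive
#' Metropolis-within-Gibbs sampler on the integrated metapopulation
#' posterior; the method for plain functions runs the same adaptive scalar
#' random-walk scheme ([amwg()]) on an arbitrary log-target, which is how
#' the sampler machinery is validated against closed-form posteriors.
#'
#' @param x An `imm_data` object, or a log-posterior function.
#' @param ... Passed to methods.
#' @return An `imm_fit` (for `imm_data`) or a draws matrix (for functions).
#' @export
fit_mcmc <- function(x, ...) UseMethod("fit_mcmc")

#' @rdname fit_mcmc
#' @param spec An `imm_spec` object.
#' @param config An `imm_mcmc_config` object.
#' @param init_tries Prior re-draws allowed before giving up on a finite
#'   starting posterior.
#' @param init_pool Prior draws scored per chain; the highest-posterior one
#'   starts the chain (overdispersed but feasible initialisation).
#' @export
fit_mcmc.imm_data <- function(x, spec = imm_spec(x$n_years),
                              config = mcmc_config(), init_tries = 1000L,
                              init_pool = 25L, ...) {
  dat <- imm_data_to_cpp(x)
  sp <- imm_spec_to_cpp(spec)
  latent <- init_latents(x, spec)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seeds[ch])
    best <- NULL; best_lp <- -Inf; tries <- 0L
    while (tries < init_tries && (is.null(best) || tries < init_pool)) {
      tries <- tries + 1L
      cand <- hyper_to_init(draw_hyper_from_prior(spec), latent)
      lp <- imm_lp_cpp(dat, sp, cand)
      if (is.finite(lp) && lp > best_lp) { best <- cand; best_lp <- lp }
    }
    if (is.null(best)) {
      stop("no finite initial posterior after ", init_tries,
           " prior draws; last lp = ", best_lp)
    }
    res <- imm_mcmc_cpp(dat, sp,
                        list(n_iter = config$n_iter, n_burn = config$n_burn,
                             thin = config$thin,
                             save_states = config$save_states),
                        best)
    if (!isTRUE(res$ok)) stop("sampler could not start from a finite state")
    colnames(res$pars) <- imm_par_names()
    chains[[ch]] <- res
  }
  structure(list(chains = chains, config = config, spec = spec,
                 n_years = x$n_years, par_names = imm_par_names()),
            class = "imm_fit")
}

#' @rdname fit_mcmc
#' @param init Numeric vector of starting values (function method).
#' @export
fit_mcmc.function <- function(x, init, config = mcmc_config(n_chains = 1L), ...) {
  amwg(x, init, n_iter = config$n_iter, n_burn = config$n_burn,
       thin = config$thin, seed = config$seeds[1])
}

#' Parameter names of the monitored hyperparameters
#' @return Character vector matching the columns of the draw matrices.
#' @export
imm_par_names <- function() {
  g <- imm_groups()
  covn <- c("gdd_winter", "gdd_stage", "gdd_breed", "snow_breed")
  flows <- imm_flows()
  c(paste0("alpha_gamma[", g, "]"),
    paste0("beta_gamma[", rep(g, 4), ",", rep(covn, each = 4), "]"),
    "sigma_gamma",
    paste0("alpha_phiJ[", g[1:3], "]"),
    paste0("beta_stormJ[", g[1:3], "]"),
    paste0("huntJ[", rep(g[1:3], 2), ",", rep(1:2, each = 3), "]"),
    paste0("alpha_phiA[", g, "]"),
    paste0("beta_stormA[", g, "]"),
    paste0("huntA[", rep(g, 2), ",", rep(1:2, each = 4), "]"),
    paste0("mu_beta[", c("J", "A"), "]"),
    paste0("lambda_beta[", c("J", "A"), "]"),
    paste0("mu_hunt[", rep(c("J", "A"), 2), ",", rep(1:2, each = 2), "]"),
    paste0("lambda_hunt[", rep(c("J", "A"), 2), ",", rep(1:2, each = 2), "]"),
    "sigma_phiJ", "sigma_phiA",
    paste0("alpha_psi[", flows$age, ",", flows$from, ">", flows$to, "]"),
    "sigma_psi",
    paste0("alpha_p[", g, "]"),
    "sigma_p", "tau_y")
}

#' Adaptive scalar Metropolis sampler for an arbitrary log target
#'
#' Componentwise Gaussian random walk with Robbins-Monro adaptation of each
#' step size towards 0.44 acceptance. Used directly for small analytic
#' targets; the compiled integrated-model sampler applies the same scheme.
#'
#' @param log_post Function mapping a parameter vector to a log density.
#' @param init Numeric starting vector (finite log density required).
#' @param n_iter,n_burn,thin Schedule.
#' @param seed Optional RNG seed.
#' @return Matrix of retained draws (rows) by parameters (columns).
#' @export
amwg <- function(log_post, init, n_iter = 5000L, n_burn = 1000L, thin = 1L,
                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  x <- init
  lp <- log_post(x)
  if (!is.finite(lp)) stop("initial log posterior is not finite")
  ls <- rep(log(0.5), d)
  cnt <- rep(0, d)
  nkeep <- (n_iter - n_burn) %/% thin
  out <- matrix(NA_real_, nkeep, d)
  keep <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(d)) {
      prop <- x
      prop[j] <- x[j] + exp(ls[j]) * stats::rnorm(1)
      lpp <- log_post(prop)
      a <- if (!is.finite(lpp)) 0 else min(1, exp(lpp - lp))
      if (stats::runif(1) < a) { x <- prop; lp <- lpp }
      cnt[j] <- cnt[j] + 1
      ls[j] <- ls[j] + (a - 0.44) / cnt[j]^0.6
    }
    if (it > n_burn && (it - n_burn) %% thin == 0 && keep < nkeep) {
      keep <- keep + 1L
      out[keep, ] <- x
    }
  }
  out
}

#' Combined hyperparameter draws
#'
#' @param fit An `imm_fit`.
#' @return Matrix of all chains' retained draws, named columns.
#' @export
fit_draws <- function(fit) {
  do.call(rbind, lapply(fit$chains, function(ch) ch$pars))
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic two-part PSRF from chain means and within-chain variances; values
#' at or above 1.1 flag non-convergence.
#'
#' @param draws An `imm_fit`, or a list of draw matrices (one per chain,
#'   equal dimensions).
#' @return Named vector of R-hat values with attribute `"flagged"` listing
#'   parameters with R-hat >= 1.1.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "imm_fit")) draws <- lapply(draws$chains, `[[`, "pars")
  if (is.matrix(draws[[1]]) == FALSE) draws <- lapply(draws, as.matrix)
  m <- length(draws)
  if (m < 2L) stop("Gelman-Rubin needs at least two chains")
  n <- nrow(draws[[1]])
  P <- ncol(draws[[1]])
  rhat <- numeric(P)
  for (p in seq_len(P)) {
    ch <- vapply(draws, function(d) d[, p], numeric(n))
    mns <- colMeans(ch)
    B <- n * stats::var(mns)
    W <- mean(apply(ch, 2, stats::var))
    if (W <= 0) { rhat[p] <- 1; next }
    vhat <- (n - 1) / n * W + B / n
    rhat[p] <- sqrt(vhat / W)
  }
  names(rhat) <- colnames(draws[[1]]) %||% paste0("par", seq_len(P))
  attr(rhat, "flagged") <- names(rhat)[rhat >= 1.1]
  rhat
}

#' Posterior medians and equal-tailed credible intervals
#'
#' @param draws Draw matrix (rows draws, columns parameters) or `imm_fit`.
#' @param levels Credible levels, default 0.90 (0.95 also conventional).
#' @return data.frame with the median and one lower/upper pair per level.
#' @export
summarize_draws <- function(draws, levels = 0.90) {
  if (inherits(draws, "imm_fit")) draws <- fit_draws(draws)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) == 0L) stop("no draws to summarize")
  out <- data.frame(parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
                    median = apply(draws, 2, stats::median))
  for (lv in levels) {
    a <- (1 - lv) / 2
    q <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    out[[paste0("lower", format(100 * lv))]] <- q[1, ]
    out[[paste0("upper", format(100 * lv))]] <- q[2, ]
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild an imm_rates object from stored draw `k` of chain `ch`
fit_rates <- function(fit, ch, k) {
  T_ <- fit$n_years
  G <- 4L
  nint <- T_ - 1L
  chn <- fit$chains[[ch]]
  flows <- imm_flows()
  nf <- nrow(flows)
  psiJ <- array(0, c(G, G, nint)); psiA <- array(0, c(G, G, nint))
  psi <- matrix(chn$psi[k, ], nf, nint)
  for (f in seq_len(nf)) {
    if (flows$age[f] == "J") psiJ[flows$from_i[f], flows$to_i[f], ] <- psi[f, ]
    else psiA[flows$from_i[f], flows$to_i[f], ] <- psi[f, ]
  }
  structure(list(gamma = matrix(chn$gamma[k, ], G, T_),
                 phiJ = matrix(chn$phiJ[k, ], G, nint),
                 phiA = matrix(chn$phiA[k, ], G, nint),
                 psiJ = psiJ, psiA = psiA,
                 p = matrix(chn$p[k, ], G, nint),
                 n_years = T_), class = "imm_rates")
}

fit_states <- function(fit, ch, k) {
  T_ <- fit$n_years
  chn <- fit$chains[[ch]]
  J <- matrix(chn$J[k, ], 4, T_)
  N1 <- matrix(chn$N1[k, ], 4, T_)
  Nad <- matrix(chn$Nad[k, ], 4, T_)
  I <- matrix(chn$I[k, ], 4, T_)
  A <- matrix(chn$A[k, ], 4, T_)
  structure(list(J = J, N1 = N1, Nad = Nad, I = I, A = A, Ntot = J + A,
                 n_years = T_), class = "imm_states")
}

# iterate over a subsample of retained draws across chains
draw_index <- function(fit, n_draws = NULL) {
  idx <- do.call(rbind, lapply(seq_along(fit$chains), function(ch) {
    cbind(ch, seq_len(fit$chains[[ch]]$n_kept))
  }))
  if (!is.null(n_draws) && n_draws < nrow(idx)) {
    idx <- idx[round(seq(1, nrow(idx), length.out = n_draws)), , drop = FALSE]
  }
  idx
}

#' Posterior predictive checks
#'
#' Replicates each data set from the fitted model along the posterior draws
#' and compares a discrepancy statistic between observed and replicated
#' data. Implemented statistics: Freeman-Tukey for counts
#' (`"freeman_tukey_counts"`), Freeman-Tukey for juvenile counts
#' (`"freeman_tukey_juveniles"`) and Pearson chi-square on m-array cells by
#' release group (`"marray_chisq_by_group"`).
#'
#' @param fit An `imm_fit` with saved states.
#' @param data The `imm_data` the model was fitted to.
#' @param statistic One of the statistic names above.
#' @param n_draws Number of posterior draws used (subsampled evenly).
#' @return An `imm_ppc` object: list with the per-draw observed and
#'   replicated statistics and the Bayesian p-value(s)
#'   `Pr(T_rep >= T_obs)`. For the m-array statistic the p-value is a named
#'   vector (one per release group plus `"combined"`).
#' @export
posterior_predictive_check <- function(fit, data,
                                       statistic = c("freeman_tukey_counts",
                                                     "freeman_tukey_juveniles",
                                                     "marray_chisq_by_group"),
                                       n_draws = 200L) {
  statistic <- match.arg(statistic)
  idx <- draw_index(fit, n_draws)
  nd <- nrow(idx)
  if (statistic == "freeman_tukey_counts") {
    obs <- rep(NA_real_, nd); rep_ <- rep(NA_real_, nd)
    ok <- !is.na(data$y) & data$y > 0
    for (k in seq_len(nd)) {
      st <- fit_states(fit, idx[k, 1], idx[k, 2])
      tau <- fit$chains[[idx[k, 1]]]$pars[idx[k, 2], "tau_y"]
      sdlog <- if (fit$spec$tau_reading == "variance") sqrt(tau) else 1 / sqrt(tau)
      mu <- st$Ntot * exp(sdlog^2 / 2)
      yrep <- matrix(stats::rlnorm(sum(ok), log(st$Ntot[ok]), sdlog), ncol = 1)
      obs[k] <- sum((sqrt(data$y[ok]) - sqrt(mu[ok]))^2)
      rep_[k] <- sum((sqrt(yrep) - sqrt(mu[ok]))^2)
    }
    p <- mean(rep_ >= obs)
  } else if (statistic == "freeman_tukey_juveniles") {
    obs <- rep(NA_real_, nd); rep_ <- rep(NA_real_, nd)
    ok <- !is.na(data$jobs)
    for (k in seq_len(nd)) {
      st <- fit_states(fit, idx[k, 1], idx[k, 2])
      lam <- st$J[ok]
      jrep <- stats::rpois(length(lam), lam)
      obs[k] <- sum((sqrt(data$jobs[ok]) - sqrt(lam))^2)
      rep_[k] <- sum((sqrt(jrep) - sqrt(lam))^2)
    }
    p <- mean(rep_ >= obs)
  } else {
    marr <- data$marr
    R <- nrow(marr$counts)
    groups <- marr$rel$group_i
    a01 <- as.integer(ifelse(marr$rel$age == "J", 0L, 1L))
    obs <- matrix(0, nd, 4); rep_ <- matrix(0, nd, 4)
    for (k in seq_len(nd)) {
      rates <- fit_rates(fit, idx[k, 1], idx[k, 2])
      prmat <- marray_rows_probs_cpp(fit$n_years,
                                     as.integer(marr$rel$group_i), a01,
                                     as.integer(marr$rel$year),
                                     rates$phiJ, rates$phiA,
                                     as.numeric(rates$psiJ),
                                     as.numeric(rates$psiA), rates$p)
      for (r in seq_len(R)) {
        n <- marr$releases[r]
        if (n == 0) next
        pr <- prmat[r, ]
        e <- n * pr
        # standard minimum-expected-count rule: cells with tiny expectations
        # make the Pearson statistic explode on single rare events
        use <- e >= 0.5
        x2o <- sum((marr$counts[r, use] - e[use])^2 / e[use])
        sim <- as.numeric(stats::rmultinom(1, n, pr))
        x2r <- sum((sim[use] - e[use])^2 / e[use])
        g <- groups[r]
        obs[k, g] <- obs[k, g] + x2o
        rep_[k, g] <- rep_[k, g] + x2r
      }
    }
    p <- c(colMeans(rep_ >= obs), combined = mean(rowSums(rep_) >= rowSums(obs)))
    names(p)[1:4] <- imm_groups()
  }
  structure(list(statistic = statistic, observed = obs, replicated = rep_,
                 p_value = p), class = "imm_ppc")
}
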