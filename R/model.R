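#' Demographic rates implied by hyperparameters and covariates
#'
#' Applies the model's link functions: log-linear fecundity with four
#' standardized environmental covariates, logit-linear survival with a storm
#' covariate and hunting-period intercepts, and logit-scale year deviations
#' around dispersal and resighting means. Elsewhere juvenile survival is not
#' separately estimable (no juvenile capture histories exist there) and is
#' derived as the logit-scale mean of the focal groups' juvenile survival.
#'
#' @param hyper An `imm_hyper` object.
#' @param covs An `imm_covs` object (see [compute_covariates()] or
#'   [sim_covariates()]).
#' @return An `imm_rates` object: list with matrices `gamma` (G x T),
#'   `phiJ`, `phiA` (G x T-1), `p` (G x T-1, resighting at occasions
#'   2..T) and arrays `psiJ`, `psiA` (G x G x T-1, zero diagonal).
#' @export
rates_from_hyper <- function(hyper, covs) {
  G <- 4L
  T_ <- hyper$n_years
  stopifnot(dim(covs$x)[2] == T_, ncol(covs$storms) == T_ - 1L,
            length(covs$h) == T_ - 1L)
  gamma <- matrix(0, G, T_, dimnames = list(imm_groups(), NULL))
  for (i in seq_len(G)) {
    eta <- log(hyper$alpha_gamma[i]) +
      covs$x[i, , ] %*% hyper$beta_gamma[i, ] + hyper$eps_gamma[i, ]
    gamma[i, ] <- exp(eta)
  }
  hunt_term <- function(hmat, i, h) ifelse(h == 0L, 0, hmat[i, pmax(h, 1L)])
  phiJ <- matrix(0, G, T_ - 1L, dimnames = list(imm_groups(), NULL))
  lphiJ_focal <- matrix(0, 3L, T_ - 1L)
  for (i in 1:3) {
    lphiJ_focal[i, ] <- logit(hyper$alpha_phiJ[i]) +
      hyper$beta_stormJ[i] * covs$storms[i, ] +
      hunt_term(hyper$huntJ, i, covs$h) + hyper$eps_phiJ[i, ]
    phiJ[i, ] <- invlogit(lphiJ_focal[i, ])
  }
  phiJ[4L, ] <- invlogit(colMeans(lphiJ_focal))
  phiA <- matrix(0, G, T_ - 1L, dimnames = list(imm_groups(), NULL))
  for (i in seq_len(G)) {
    phiA[i, ] <- invlogit(logit(hyper$alpha_phiA[i]) +
                            hyper$beta_stormA[i] * covs$storms[i, ] +
                            hunt_term(hyper$huntA, i, covs$h) +
                            hyper$eps_phiA[i, ])
  }
  flows <- imm_flows()
  psiJ <- array(0, dim = c(G, G, T_ - 1L))
  psiA <- array(0, dim = c(G, G, T_ - 1L))
  for (f in seq_len(nrow(flows))) {
    v <- invlogit(logit(hyper$alpha_psi[f]) + hyper$eps_psi[f, ])
    if (flows$age[f] == "J") {
      psiJ[flows$from_i[f], flows$to_i[f], ] <- v
    } else {
      psiA[flows$from_i[f], flows$to_i[f], ] <- v
    }
  }
  p <- matrix(0, G, T_ - 1L, dimnames = list(imm_groups(), NULL))
  for (i in seq_len(G)) {
    p[i, ] <- invlogit(logit(hyper$alpha_p[i]) + hyper$eps_p[i, ])
  }
  structure(list(gamma = gamma, phiJ = phiJ, phiA = phiA,
                 psiJ = psiJ, psiA = psiA, p = p, n_years = T_),
            class = "imm_rates")
}

#' Fecundity linear predictor
#'
#' Per-capita production of young for group `i` in year `t`:
#' `gamma = exp(log(alpha) + sum(beta * x) + eps)`. The Uniform(0,1)
#' intercept is the natural-scale among-year mean and enters the log link as
#' `log(alpha)` (an additive (0,1) log-scale intercept would force
#' `gamma >= 1`, an order of magnitude above observed production).
#'
#' @inheritParams rates_from_hyper
#' @param i Group index (1..4).
#' @param t Year index (1..T).
#' @return Fecundity `gamma[i, t] > 0`.
#' @export
fecundity_linpred <- function(hyper, covs, i, t) {
  a <- hyper$alpha_gamma[i]
  if (a <= 0 || a >= 1) stop("fecundity intercept outside (0,1)")
  exp(log(a) + sum(covs$x[i, t, ] * hyper$beta_gamma[i, ]) +
        hyper$eps_gamma[i, t])
}

#' Survival linear predictor
#'
#' Apparent survival over the interval from winter `t` to `t + 1` on the
#' inverse-logit scale, with a standardized storm covariate and
#' hunting-period intercepts (baseline period contributes 0).
#'
#' @inheritParams fecundity_linpred
#' @param age `"J"` (juvenile; focal groups only) or `"A"` (adult).
#' @return Survival probability in (0,1).
#' @export
survival_linpred <- function(hyper, covs, i, t, age) {
  if (!age %in% c("J", "A")) stop("unknown age class: ", age)
  h <- covs$h[t]
  if (age == "J") {
    if (i > 3L) stop("Elsewhere juvenile survival is derived, not estimated")
    a <- hyper$alpha_phiJ[i]
    if (a <= 0 || a >= 1) stop("survival intercept outside (0,1)")
    eta <- logit(a) + hyper$beta_stormJ[i] * covs$storms[i, t] +
      (if (h > 0L) hyper$huntJ[i, h] else 0) + hyper$eps_phiJ[i, t]
  } else {
    a <- hyper$alpha_phiA[i]
    if (a <= 0 || a >= 1) stop("survival intercept outside (0,1)")
    eta <- logit(a) + hyper$beta_stormA[i] * covs$storms[i, t] +
      (if (h > 0L) hyper$huntA[i, h] else 0) + hyper$eps_phiA[i, t]
  }
  invlogit(eta)
}

#' Movement and resighting probabilities for one interval
#'
#' Dispersal probabilities for the interval from winter `t` to `t + 1`
#' (logit-scale year deviations around flow-specific means) and resighting
#' probabilities at occasion `t + 1`. Rows are not renormalized; proposals
#' implying a row sum of movement probabilities at or above one are invalid
#' and rejected during inference.
#'
#' @inheritParams fecundity_linpred
#' @param t Interval index (1..T-1).
#' @return List with `psiJ`, `psiA` (G x G matrices, zero diagonal) and `p`
#'   (length-G resighting probabilities at occasion `t + 1`).
#' @export
movement_detection <- function(hyper, t) {
  if (any(hyper$alpha_psi < 0) || any(hyper$alpha_psi >= 1)) {
    stop("dispersal mean outside support")
  }
  G <- 4L
  flows <- imm_flows()
  psiJ <- matrix(0, G, G)
  psiA <- matrix(0, G, G)
  for (f in seq_len(nrow(flows))) {
    v <- invlogit(logit(hyper$alpha_psi[f]) + hyper$eps_psi[f, t])
    if (flows$age[f] == "J") psiJ[flows$from_i[f], flows$to_i[f]] <- v
    else psiA[flows$from_i[f], flows$to_i[f]] <- v
  }
  p <- invlogit(logit(hyper$alpha_p) + hyper$eps_p[, t])
  list(psiJ = psiJ, psiA = psiA, p = p)
}

#' Expected next state of the process model
#'
#' One step of the stage-structured expectation: expected returning
#' second-winter birds, returning older adults and immigrants from current
#' juveniles and adults, and expected juveniles produced by next year's
#' adults. No juvenile flow leaves the Elsewhere group.
#'
#' @param J,A Length-G current juvenile and adult abundances.
#' @param rates_t List with `gamma_next` (length-G fecundity of the target
#'   year), `phiJ`, `phiA` (length-G survival over the interval) and `psiJ`,
#'   `psiA` (G x G movement matrices for the interval).
#' @return List with expected `N1`, `Nad`, `I`, `A`, `J`, `Ntot` of the next
#'   year.
#' @export
process_expectation <- function(J, A, rates_t) {
  G <- length(J)
  outJ <- rowSums(rates_t$psiJ)
  outA <- rowSums(rates_t$psiA)
  N1 <- rates_t$phiJ * (1 - outJ) * J
  Nad <- rates_t$phiA * (1 - outA) * A
  inflow <- colSums(rates_t$psiJ * (rates_t$phiJ * J)) +
    colSums(rates_t$psiA * (rates_t$phiA * A))
  A_next <- N1 + Nad + inflow
  J_next <- A_next * rates_t$gamma_next
  list(J = J_next, N1 = N1, Nad = Nad, I = inflow, A = A_next,
       Ntot = J_next + A_next)
}

#' Latent state container
#'
#' @param J,N1,Nad,I G x T integer matrices; columns 1 of `N1`, `Nad`, `I`
#'   are ignored (the first winter has only initial adults and juveniles).
#' @param initA Length-G initial adult abundances.
#' @return `imm_states` object with derived `A` and `Ntot`.
#' @export
imm_states <- function(J, N1, Nad, I, initA) {
  G <- nrow(J); T_ <- ncol(J)
  A <- cbind(initA, N1[, -1, drop = FALSE] + Nad[, -1, drop = FALSE] +
               I[, -1, drop = FALSE])
  dimnames(A) <- NULL
  structure(list(J = J, N1 = N1, Nad = Nad, I = I, A = A,
                 Ntot = J + A, n_years = T_), class = "imm_states")
}

#' Log-density of the latent process model
#'
#' Poisson recruitment, Binomial survival-and-fidelity of juveniles and
#' adults, and Poisson immigration given the expected inflow sum.
#'
#' @param latent An `imm_states` object.
#' @param rates An `imm_rates` object.
#' @return Scalar log-density (may be `-Inf`).
#' @export
process_logdensity <- function(latent, rates) {
  T_ <- latent$n_years
  lp <- sum(stats::dpois(latent$J[, 1], latent$A[, 1] * rates$gamma[, 1],
                         log = TRUE))
  for (t in 2:T_) {
    it <- t - 1L
    outJ <- rowSums(rates$psiJ[, , it])
    outA <- rowSums(rates$psiA[, , it])
    piJ <- rates$phiJ[, it] * (1 - outJ)
    piA <- rates$phiA[, it] * (1 - outA)
    inflow <- colSums(rates$psiJ[, , it] * (rates$phiJ[, it] * latent$J[, it])) +
      colSums(rates$psiA[, , it] * (rates$phiA[, it] * latent$A[, it]))
    lp <- lp +
      sum(stats::dbinom(latent$N1[, t], latent$J[, it], piJ, log = TRUE)) +
      sum(stats::dbinom(latent$Nad[, t], latent$A[, it], piA, log = TRUE)) +
      sum(stats::dpois(latent$I[, t], inflow, log = TRUE)) +
      sum(stats::dpois(latent$J[, t], latent$A[, t] * rates$gamma[, t],
                       log = TRUE))
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Lognormal count-observation log-likelihood
#'
#' Counts are linked to true total subpopulation size by
#' `y ~ logNormal(log(Ntot), tau_y)`, with `tau_y` read as the log-scale
#' variance by default (precision reading available via the model spec).
#' `NA` counts are skipped; non-positive counts on modelled cells are an
#' error.
#'
#' @param y Observed counts (matrix or vector; `NA` allowed).
#' @param Ntot True total sizes, same shape.
#' @param tau_y Positive observation parameter.
#' @param reading `"variance"` or `"precision"`.
#' @return Scalar log-likelihood.
#' @export
loglik_counts <- function(y, Ntot, tau_y, reading = "variance") {
  if (tau_y <= 0) stop("tau_y must be positive")
  ok <- !is.na(y)
  y <- y[ok]; Ntot <- Ntot[ok]
  if (any(y <= 0)) stop("non-positive count on a modelled cell")
  if (any(Ntot <= 0)) return(-Inf)
  sdlog <- if (reading == "variance") sqrt(tau_y) else 1 / sqrt(tau_y)
  sum(stats::dlnorm(y, meanlog = log(Ntot), sdlog = sdlog, log = TRUE))
}

#' Poisson juvenile-count log-likelihood
#'
#' `Jobs ~ Poisson(J)`; `NA` cells (years without fecundity sampling) are
#' skipped, so production in those years is informed only by the process
#' model and the counts.
#'
#' @param Jobs Observed juvenile counts (`NA` allowed).
#' @param J True juvenile abundances, same shape.
#' @return Scalar log-likelihood (`-Inf` if `Jobs > 0` where `J = 0`).
#' @export
loglik_juveniles <- function(Jobs, J) {
  ok <- !is.na(Jobs)
  Jobs <- Jobs[ok]; J <- J[ok]
  if (any(Jobs < 0) || any(Jobs != floor(Jobs))) {
    stop("juvenile counts must be non-negative integers")
  }
  sum(stats::dpois(Jobs, J, log = TRUE))
}

# column index of resighting cell (group j, occasion u) in the m-array layout
marray_col <- function(j, u, G = 4L) (u - 2L) * G + j

#' Multistate m-array cell probabilities for one release cohort
#'
#' First-resighting probabilities for birds released in `group` at age `age`
#' in year `year`: the probability of each (group, occasion) first-resighting
#' cell is a survive-and-move path sum with non-detection at intermediate
#' occasions; juvenile rates apply only to the first interval after a
#' juvenile release, after which birds are adults. The last cell is the
#' never-seen probability.
#'
#' @param rates An `imm_rates` object.
#' @param group Release group index (1..4) or code.
#' @param age `"J"` or `"A"`.
#' @param year Release year (1..T; a release in year T is never resighted).
#' @return Probability vector of length `G * (T - 1) + 1` over resighting
#'   cells (group fastest, occasions 2..T) plus the never-seen cell; sums
#'   to 1.
#' @export
marray_cell_probs <- function(rates, group, age, year) {
  G <- 4L
  T_ <- rates$n_years
  if (is.character(group)) group <- match(group, imm_groups())
  if (!age %in% c("J", "A")) stop("unknown age class: ", age)
  if (age == "J" && group > 3L) stop("no juvenile releases in the Elsewhere group")
  probs <- numeric(G * (T_ - 1L) + 1L)
  if (year >= T_) {
    probs[length(probs)] <- 1
    return(probs)
  }
  q <- numeric(G)
  q[group] <- 1
  for (u in (year + 1L):T_) {
    it <- u - 1L
    juvenile_step <- (age == "J" && u == year + 1L)
    phi <- if (juvenile_step) rates$phiJ[, it] else rates$phiA[, it]
    psi <- if (juvenile_step) rates$psiJ[, , it] else rates$psiA[, , it]
    M <- psi * phi
    diag(M) <- phi * (1 - rowSums(psi))
    q <- as.numeric(t(M) %*% q)
    det_p <- rates$p[, it]
    probs[marray_col(seq_len(G), u)] <- q * det_p
    q <- q * (1 - det_p)
  }
  probs[length(probs)] <- 1 - sum(probs)
  probs
}

#' Multinomial m-array log-likelihood
#'
#' Sums, over release rows, the multinomial log-likelihood of first
#' resightings given the model's cell probabilities. Multinomial
#' normalisation constants are dropped, so absolute values are comparable
#' only within a fixed data set.
#'
#' @param marr An `imm_marray` object (see [marray_from_histories()]).
#' @param rates An `imm_rates` object.
#' @return Scalar log-likelihood (`-Inf` if any positive count sits on a
#'   zero-probability cell).
#' @export
loglik_marray <- function(marr, rates) {
  lp <- 0
  for (r in seq_len(nrow(marr$counts))) {
    m <- marr$counts[r, ]
    nz <- which(m > 0)
    if (!length(nz)) next
    pr <- marray_cell_probs(rates, marr$rel$group_i[r], marr$rel$age[r],
                            marr$rel$year[r])[nz]
    if (any(pr <= 0)) return(-Inf)
    lp <- lp + sum(m[nz] * log(pr))
  }
  lp
}

dlaplace_log <- function(x, mu, b) -log(2 * b) - abs(x - mu) / b

#' Log prior density of the hyperparameters and initial abundances
#'
#' Sums the stated prior densities: discrete-uniform initial adults with
#' group-specific bounds, Uniform probability-scale intercepts, Normal
#' fecundity covariate effects, Laplace-shrunk storm and hunting effects with
#' Normal shrinkage means and Exponential Laplace rates, Uniform year-effect
#' standard deviations, Uniform(0, 0.2) dispersal means, an InverseGamma
#' count-observation parameter, and the Normal year-effect densities given
#' their standard deviations. Returns `-Inf` outside any support.
#'
#' @param hyper An `imm_hyper` object.
#' @param initA Length-4 initial adult abundances.
#' @param spec An `imm_spec` object.
#' @return Scalar log prior density.
#' @export
log_prior <- function(hyper, initA, spec = imm_spec(hyper$n_years)) {
  lp <- 0
  bounds <- spec$initA_bounds
  for (i in 1:4) {
    if (initA[i] < bounds[i, 1] || initA[i] > bounds[i, 2] ||
        initA[i] != floor(initA[i])) return(-Inf)
    lp <- lp - log(bounds[i, 2] - bounds[i, 1] + 1)
  }
  unif <- function(x, lo, hi) {
    if (any(x <= lo) || any(x >= hi)) return(NA_real_)
    -length(x) * log(hi - lo)
  }
  u_terms <- c(unif(hyper$alpha_gamma, 0, 1),
               unif(hyper$alpha_phiJ, 0, 1),
               unif(hyper$alpha_phiA, 0, 1),
               unif(hyper$alpha_p, 0, 1),
               unif(hyper$alpha_psi, 0, spec$alpha_psi_max),
               unif(hyper$sigma_gamma, 0, spec$sigma_gamma_max),
               unif(hyper$sigma_phiJ, 0, spec$sigma_phi_max),
               unif(hyper$sigma_phiA, 0, spec$sigma_phi_max),
               unif(hyper$sigma_psi, 0, spec$sigma_psi_max),
               unif(hyper$sigma_p, 0, spec$sigma_p_max))
  if (any(is.na(u_terms))) return(-Inf)
  lp <- lp + sum(u_terms)
  bsd <- normal_prior_sd(spec$beta_gamma_scale, spec$normal_reading)
  lp <- lp + sum(stats::dnorm(hyper$beta_gamma, 0, bsd, log = TRUE))
  msd <- normal_prior_sd(spec$mu_scale, spec$normal_reading)
  lp <- lp + sum(stats::dnorm(c(hyper$mu_beta, hyper$mu_hunt), 0, msd,
                              log = TRUE))
  lams <- c(hyper$lambda_beta, hyper$lambda_hunt)
  if (any(lams <= 0)) return(-Inf)
  lp <- lp + sum(stats::dexp(lams, spec$lambda_rate, log = TRUE))
  bJ <- laplace_b(hyper$lambda_beta[1], spec$laplace_scale)
  bA <- laplace_b(hyper$lambda_beta[2], spec$laplace_scale)
  lp <- lp + sum(dlaplace_log(hyper$beta_stormJ, hyper$mu_beta[1], bJ)) +
    sum(dlaplace_log(hyper$beta_stormA, hyper$mu_beta[2], bA))
  for (a in 1:2) for (h in 1:2) {
    b <- laplace_b(hyper$lambda_hunt[a, h], spec$laplace_scale)
    hu <- if (a == 1) hyper$huntJ[, h] else hyper$huntA[, h]
    lp <- lp + sum(dlaplace_log(hu, hyper$mu_hunt[a, h], b))
  }
  if (hyper$tau_y <= 0) return(-Inf)
  a0 <- spec$tau_prior[["shape"]]; b0 <- spec$tau_prior[["rate"]]
  lp <- lp + a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(hyper$tau_y) -
    b0 / hyper$tau_y
  # year effects given their standard deviations
  for (nm in c("gamma", "phiJ", "phiA", "psi", "p")) {
    eps <- hyper[[paste0("eps_", nm)]]
    sig <- hyper[[paste0("sigma_", nm)]]
    if (sig <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(eps, 0, sig, log = TRUE))
  }
  unname(lp)
}

#' Joint log posterior of the integrated metapopulation model
#'
#' Sum of the log prior, the latent process log-density and the three
#' component log-likelihoods (counts, juvenile counts, m-array). Any
#' non-finite component makes the joint `-Inf`. Dispersal rows whose movement
#' probabilities sum to one or more are invalid (`-Inf`).
#'
#' @param hyper An `imm_hyper` object.
#' @param latent An `imm_states` object.
#' @param data An `imm_data` object.
#' @param spec An `imm_spec` object.
#' @return Scalar log posterior density (up to constants dropped in the
#'   m-array likelihood).
#' @export
joint_log_posterior <- function(hyper, latent, data,
                                spec = imm_spec(hyper$n_years)) {
  lp <- log_prior(hyper, latent$A[, 1], spec)
  if (!is.finite(lp)) return(-Inf)
  rates <- rates_from_hyper(hyper, data$covs)
  for (it in seq_len(hyper$n_years - 1L)) {
    if (any(rowSums(rates$psiJ[, , it]) >= 1) ||
        any(rowSums(rates$psiA[, , it]) >= 1)) return(-Inf)
  }
  lp <- lp + process_logdensity(latent, rates)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + loglik_counts(data$y, latent$Ntot, hyper$tau_y, spec$tau_reading)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + loglik_juveniles(data$jobs, latent$J)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + loglik_marray(data$marr, rates)
  lp
}

#' Observed-data container
#'
#' @param y G x T count matrix (`NA` allowed).
#' @param jobs G x T juvenile-count matrix (`NA` allowed).
#' @param marr An `imm_marray` object.
#' @param covs An `imm_covs` object.
#' @param years Optional calendar year labels.
#' @return An `imm_data` object.
#' @export
imm_data <- function(y, jobs, marr, covs, years = NULL) {
  stopifnot(nrow(y) == 4L, all(dim(jobs) == dim(y)))
  stopifnot(dim(covs$x)[2] == ncol(y))
  structure(list(y = y, jobs = jobs, marr = marr, covs = covs,
                 years = years, n_years = ncol(y)), class = "imm_data")
}
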