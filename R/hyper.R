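#' Model specification: priors and structural settings
#'
#' Collects prior settings and parameterisation switches for the integrated
#' metapopulation model. Defaults follow the hierarchical prior set used for
#' the wintering-goose system: discrete-uniform initial adult abundances with
#' group-specific bounds, Uniform(0,1) probability-scale intercepts for
#' fecundity, survival and resighting, Uniform(0,0.2) dispersal means,
#' Normal shrinkage means with Exponential(0.1) Laplace rates for
#' group-specific storm and hunting effects, and an InverseGamma(0.01, 0.01)
#' prior on the lognormal count-observation variance.
#'
#' @param n_years Number of winters T.
#' @param first_year Calendar year label of the first winter (its autumn
#'   year), default 1983.
#' @param initA_bounds 4x2 matrix of discrete-uniform bounds for initial
#'   adult abundance per group (rows ordered as [imm_groups()]).
#' @param alpha_psi_max Upper bound of the Uniform prior on dispersal means.
#' @param beta_gamma_scale Second parameter of the Normal prior on fecundity
#'   covariate effects (interpreted per `normal_reading`), default 10.
#' @param mu_scale Second parameter of the Normal prior on shrinkage means.
#' @param lambda_rate Rate of the Exponential prior on Laplace rate
#'   parameters, default 0.1.
#' @param sigma_gamma_max,sigma_phi_max,sigma_psi_max,sigma_p_max Upper
#'   bounds of the Uniform priors on year-effect standard deviations.
#' @param tau_prior Shape and rate of the InverseGamma prior on the count
#'   observation parameter.
#' @param tau_reading `"variance"` (default) treats the count-observation
#'   parameter as the log-scale variance; `"precision"` as a log-scale
#'   precision.
#' @param normal_reading Interpretation of the second Normal-prior parameter:
#'   `"variance"` (default), `"sd"` or `"precision"`.
#' @param laplace_scale `"inv_lambda_sq"` (default) sets the Laplace scale to
#'   1/lambda^2; `"inv_lambda"` to 1/lambda.
#' @return An object of class `imm_spec`.
#' @export
imm_spec <- function(n_years = 39L,
                     first_year = 1983L,
                     initA_bounds = rbind(W = c(1000, 4000),
                                          Is = c(1000, 4000),
                                          LK = c(1, 400),
                                          E = c(1000, 7500)),
                     alpha_psi_max = 0.2,
                     beta_gamma_scale = 10,
                     mu_scale = 1,
                     lambda_rate = 0.1,
                     sigma_gamma_max = 10,
                     sigma_phi_max = 10,
                     sigma_psi_max = 1,
                     sigma_p_max = 10,
                     tau_prior = c(shape = 0.01, rate = 0.01),
                     tau_reading = c("variance", "precision"),
                     normal_reading = c("variance", "sd", "precision"),
                     laplace_scale = c("inv_lambda_sq", "inv_lambda")) {
  tau_reading <- match.arg(tau_reading)
  normal_reading <- match.arg(normal_reading)
  laplace_scale <- match.arg(laplace_scale)
  stopifnot(n_years >= 3L, nrow(initA_bounds) == 4L, ncol(initA_bounds) == 2L,
            all(initA_bounds[, 2] >= initA_bounds[, 1]))
  structure(list(
    n_years = as.integer(n_years),
    first_year = as.integer(first_year),
    groups = imm_groups(),
    n_focal = imm_n_focal(),
    flows = imm_flows(),
    initA_bounds = initA_bounds,
    alpha_psi_max = alpha_psi_max,
    beta_gamma_scale = beta_gamma_scale,
    mu_scale = mu_scale,
    lambda_rate = lambda_rate,
    sigma_gamma_max = sigma_gamma_max,
    sigma_phi_max = sigma_phi_max,
    sigma_psi_max = sigma_psi_max,
    sigma_p_max = sigma_p_max,
    tau_prior = tau_prior,
    tau_reading = tau_reading,
    normal_reading = normal_reading,
    laplace_scale = laplace_scale
  ), class = "imm_spec")
}

# standard deviation implied by a Normal prior's second parameter
normal_prior_sd <- function(scale, reading) {
  switch(reading,
         variance = sqrt(scale),
         sd = scale,
         precision = 1 / sqrt(scale))
}

# Laplace scale b implied by rate lambda
laplace_b <- function(lambda, reading) {
  switch(reading, inv_lambda_sq = 1 / lambda^2, inv_lambda = 1 / lambda)
}

#' Construct a hyperparameter set
#'
#' Bundles every top-level parameter of the integrated metapopulation model:
#' probability-scale intercepts, covariate and hunting effects, shrinkage
#' parameters, year-effect standard deviations and realised year effects, and
#' the count-observation variance. Any component not supplied defaults to
#' zero effects and the intercepts of a demographically plausible goose
#' metapopulation.
#'
#' @param n_years Number of winters T (year effects are sized from this).
#' @param alpha_gamma Length-4 fecundity intercepts in (0,1).
#' @param beta_gamma 4x4 matrix of fecundity covariate effects (groups x
#'   covariates gdd_winter, gdd_stage, gdd_breed, snow_breed).
#' @param sigma_gamma Fecundity year-effect sd.
#' @param alpha_phiJ Length-3 focal juvenile survival intercepts in (0,1).
#' @param alpha_phiA Length-4 adult survival intercepts in (0,1).
#' @param beta_stormJ,beta_stormA Storm effects on juvenile (focal only) and
#'   adult survival.
#' @param huntJ 3x2 matrix of juvenile hunting-period effects (levels 1, 2).
#' @param huntA 4x2 matrix of adult hunting-period effects.
#' @param mu_beta,lambda_beta Length-2 shrinkage mean and Laplace rate for
#'   storm effects (juvenile, adult).
#' @param mu_hunt,lambda_hunt 2x2 matrices (age x level) of shrinkage means
#'   and Laplace rates for hunting effects.
#' @param sigma_phiJ,sigma_phiA Survival year-effect sds.
#' @param alpha_psi Dispersal means per flow (ordered as [imm_flows()]),
#'   each in (0, alpha_psi_max).
#' @param sigma_psi Dispersal year-effect sd.
#' @param alpha_p Length-4 resighting intercepts in (0,1).
#' @param sigma_p Resighting year-effect sd.
#' @param tau_y Count-observation parameter (log-scale variance by default).
#' @param eps_gamma,eps_phiJ,eps_phiA,eps_psi,eps_p Optional realised year
#'   effects; default 0 (they are drawn by [draw_rates()] when simulating).
#' @return An object of class `imm_hyper`.
#' @export
imm_hyper <- function(n_years = 39L,
                      alpha_gamma = c(0.11, 0.15, 0.10, 0.14),
                      beta_gamma = NULL,
                      sigma_gamma = 0.3,
                      alpha_phiJ = c(0.74, 0.84, 0.76),
                      alpha_phiA = c(0.79, 0.86, 0.86, 0.89),
                      beta_stormJ = c(-0.14, 0, 0),
                      beta_stormA = c(0.07, 0, 0.12, 0),
                      huntJ = rbind(c(0, 0.16), c(0, -0.38), c(0, 0)),
                      huntA = rbind(c(0.43, 0), c(0, -0.29),
                                    c(0, -0.34), c(0.27, -0.45)),
                      mu_beta = c(0, 0),
                      lambda_beta = c(2, 2),
                      mu_hunt = matrix(0, 2, 2),
                      lambda_hunt = matrix(2, 2, 2),
                      sigma_phiJ = 0.25,
                      sigma_phiA = 0.25,
                      alpha_psi = NULL,
                      sigma_psi = 0.3,
                      alpha_p = c(0.90, 0.89, 0.92, 0.28),
                      sigma_p = 0.3,
                      tau_y = 0.0025,
                      eps_gamma = NULL, eps_phiJ = NULL, eps_phiA = NULL,
                      eps_psi = NULL, eps_p = NULL) {
  T_ <- as.integer(n_years)
  flows <- imm_flows()
  if (is.null(beta_gamma)) {
    beta_gamma <- matrix(0, 4, 4, dimnames = list(
      imm_groups(), c("gdd_winter", "gdd_stage", "gdd_breed", "snow_breed")))
    beta_gamma["W", "gdd_winter"] <- 0.16
    beta_gamma["LK", "gdd_winter"] <- -0.26
    beta_gamma["Is", "gdd_stage"] <- -0.19
    beta_gamma["LK", "gdd_stage"] <- -0.27
    beta_gamma["E", "gdd_stage"] <- -0.21
    beta_gamma["E", "snow_breed"] <- -0.15
  }
  if (is.null(alpha_psi)) {
    alpha_psi <- default_alpha_psi(flows)
  }
  zmat <- function(x, nr) if (is.null(x)) matrix(0, nr, 0) else x
  blank <- function(x, nr, nc) if (is.null(x)) matrix(0, nr, nc) else as.matrix(x)
  h <- structure(list(
    n_years = T_,
    alpha_gamma = alpha_gamma,
    beta_gamma = as.matrix(beta_gamma),
    sigma_gamma = sigma_gamma,
    eps_gamma = blank(eps_gamma, 4, T_),
    alpha_phiJ = alpha_phiJ,
    alpha_phiA = alpha_phiA,
    beta_stormJ = beta_stormJ,
    beta_stormA = beta_stormA,
    huntJ = as.matrix(huntJ),
    huntA = as.matrix(huntA),
    mu_beta = mu_beta,
    lambda_beta = lambda_beta,
    mu_hunt = as.matrix(mu_hunt),
    lambda_hunt = as.matrix(lambda_hunt),
    sigma_phiJ = sigma_phiJ,
    sigma_phiA = sigma_phiA,
    eps_phiJ = blank(eps_phiJ, 3, T_ - 1L),
    eps_phiA = blank(eps_phiA, 4, T_ - 1L),
    alpha_psi = alpha_psi,
    sigma_psi = sigma_psi,
    eps_psi = blank(eps_psi, nrow(flows), T_ - 1L),
    alpha_p = alpha_p,
    sigma_p = sigma_p,
    eps_p = blank(eps_p, 4, T_ - 1L),
    tau_y = tau_y
  ), class = "imm_hyper")
  validate_hyper(h)
  h
}

default_alpha_psi <- function(flows = imm_flows()) {
  key <- paste(flows$age, flows$from, flows$to)
  val <- rep(0.01, nrow(flows))
  set <- function(age, from, to, v) {
    val[key == paste(age, from, to)] <<- v
  }
  # adult dispersal means: Elsewhere feeds W and Is; modest exchange among
  # focal groups; magnitudes consistent with ~14-15% of birds moving per year
  set("A", "E", "W", 0.05); set("A", "E", "Is", 0.03); set("A", "E", "LK", 0.005)
  set("A", "W", "E", 0.02); set("A", "Is", "E", 0.03); set("A", "LK", "E", 0.02)
  set("A", "W", "Is", 0.01); set("A", "Is", "W", 0.03)
  set("A", "LK", "W", 0.02); set("A", "W", "LK", 0.005)
  set("A", "Is", "LK", 0.005); set("A", "LK", "Is", 0.02)
  set("J", "W", "Is", 0.02); set("J", "Is", "W", 0.03); set("J", "LK", "W", 0.02)
  set("J", "W", "E", 0.02); set("J", "Is", "E", 0.03); set("J", "LK", "E", 0.02)
  names(val) <- key
  val
}

validate_hyper <- function(h) {
  stopifnot(
    length(h$alpha_gamma) == 4L, all(h$alpha_gamma > 0 & h$alpha_gamma < 1),
    length(h$alpha_phiJ) == 3L, all(h$alpha_phiJ > 0 & h$alpha_phiJ < 1),
    length(h$alpha_phiA) == 4L, all(h$alpha_phiA > 0 & h$alpha_phiA < 1),
    all(h$alpha_psi >= 0 & h$alpha_psi < 1),
    length(h$alpha_p) == 4L, all(h$alpha_p > 0 & h$alpha_p < 1),
    h$sigma_gamma >= 0, h$sigma_phiJ >= 0, h$sigma_phiA >= 0,
    h$sigma_psi >= 0, h$sigma_p >= 0, h$tau_y > 0,
    all(dim(h$beta_gamma) == c(4L, 4L)),
    all(dim(h$huntJ) == c(3L, 2L)), all(dim(h$huntA) == c(4L, 2L))
  )
  invisible(h)
}
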