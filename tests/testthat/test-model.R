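# Likelihoods, linear predictors and priors of the integrated model.

covs0 <- function(T_ = 6) {
  # covariates at their mean, baseline hunting period
  new_covs(x = array(0, c(4, T_, 4)), storms = matrix(0, 4, T_ - 1),
           h = rep(0L, T_ - 1))
}

hyper0 <- function(T_ = 6, ...) {
  imm_hyper(n_years = T_, beta_gamma = matrix(0, 4, 4),
            beta_stormJ = rep(0, 3), beta_stormA = rep(0, 4),
            huntJ = matrix(0, 3, 2), huntA = matrix(0, 4, 2), ...)
}

test_that("fecundity linear predictor applies the log link", {
  h <- hyper0(alpha_gamma = rep(0.12, 4))
  cv <- covs0()
  expect_equal(fecundity_linpred(h, cv, 1, 3), 0.12)
  h$eps_gamma[2, 4] <- 0.5
  expect_equal(fecundity_linpred(h, cv, 2, 4), 0.12 * exp(0.5))
  h2 <- hyper0(alpha_gamma = rep(0.1, 4))
  h2$beta_gamma[1, 1] <- 0.2
  cv$x[1, 2, 1] <- 1
  expect_equal(fecundity_linpred(h2, cv, 1, 2), 0.1 * exp(0.2),
               tolerance = 1e-12)
  expect_equal(0.1 * exp(0.2), 0.1221, tolerance = 1e-3)
  h2$alpha_gamma[1] <- 1.5
  expect_error(fecundity_linpred(h2, cv, 1, 1), "\\(0,1\\)")
})

test_that("survival linear predictor is logit-linear with hunting intercepts", {
  h <- hyper0(alpha_phiA = rep(0.8, 4), alpha_phiJ = rep(0.7, 3))
  cv <- covs0()
  expect_equal(survival_linpred(h, cv, 2, 3, "A"), 0.8)
  expect_equal(survival_linpred(h, cv, 1, 1, "J"), 0.7)
  # +0.43 on the logit of 0.8 (hunting level 1)
  h$huntA[1, 1] <- 0.43
  cv1 <- covs0()
  cv1$h[2] <- 1L
  got <- survival_linpred(h, cv1, 1, 2, "A")
  expect_equal(got, plogis(qlogis(0.8) + 0.43), tolerance = 1e-12)
  expect_equal(got, 0.860, tolerance = 1e-3)
  # monotone decreasing in storms when the effect is negative
  h2 <- hyper0(alpha_phiJ = rep(0.7, 3))
  h2$beta_stormJ[1] <- -0.3
  vals <- sapply(c(-1, 0, 1, 2), function(s) {
    cv2 <- covs0()
    cv2$storms[1, 2] <- s
    survival_linpred(h2, cv2, 1, 2, "J")
  })
  expect_true(all(diff(vals) < 0))
  expect_error(survival_linpred(h, covs0(), 1, 1, "B"), "unknown age")
  expect_error(survival_linpred(h, covs0(), 4, 1, "J"), "derived")
})

test_that("movement and detection draw from logit-scale year deviations", {
  h <- hyper0()
  md <- movement_detection(h, 2)
  fl <- imm_flows()
  for (f in seq_len(nrow(fl))) {
    m <- if (fl$age[f] == "J") md$psiJ else md$psiA
    expect_equal(m[fl$from_i[f], fl$to_i[f]], as.numeric(h$alpha_psi[f]))
  }
  expect_true(all(diag(md$psiJ) == 0) && all(diag(md$psiA) == 0))
  # no juvenile dispersal out of Elsewhere
  expect_equal(md$psiJ[4, ], rep(0, 4))
  expect_equal(md$p, h$alpha_p)
  # fidelity stays in (0, 1]
  expect_true(all(1 - rowSums(md$psiJ) > 0 & 1 - rowSums(md$psiJ) <= 1))
  h$alpha_psi[1] <- 1.2
  expect_error(movement_detection(h, 1), "support")
})

test_that("process expectation matches hand-computed two-group dynamics", {
  # identity limit: no mortality, no movement, no future recruitment
  r0 <- list(gamma_next = rep(0, 4), phiJ = rep(1, 4), phiA = rep(1, 4),
             psiJ = matrix(0, 4, 4), psiA = matrix(0, 4, 4))
  J <- c(100, 50, 10, 80); A <- c(1000, 600, 100, 900)
  e <- process_expectation(J, A, r0)
  expect_equal(e$A, J + A)
  expect_equal(e$I, rep(0, 4))
  # two-group toy with hand-computed expectations
  psiA <- matrix(0, 4, 4); psiA[1, 2] <- psiA[2, 1] <- 0.1
  rt <- list(gamma_next = rep(0.1, 4), phiJ = rep(0.7, 4),
             phiA = rep(0.8, 4), psiJ = matrix(0, 4, 4), psiA = psiA)
  J <- c(100, 0, 0, 0); A <- c(1000, 500, 0, 0)
  e <- process_expectation(J, A, rt)
  expect_equal(e$N1[1], 0.7 * 100)
  expect_equal(e$Nad[1], 0.8 * 0.9 * 1000)
  expect_equal(e$I[1], 0.8 * 0.1 * 500)  # adults moving 2 -> 1
  expect_equal(e$I[2], 0.8 * 0.1 * 1000)
  expect_equal(e$A[1], 70 + 720 + 40)
  expect_equal(e$J[1], 0.1 * 830)
  # conservation with survival one and no recruitment
  rc <- list(gamma_next = rep(0, 4), phiJ = rep(1, 4), phiA = rep(1, 4),
             psiJ = matrix(0.05, 4, 4) - diag(0.05, 4), psiA = matrix(0.08, 4, 4) - diag(0.08, 4))
  e2 <- process_expectation(J, A, rc)
  expect_equal(sum(e2$Ntot), sum(J + A), tolerance = 1e-9)
})

test_that("lognormal count likelihood matches a closed-form oracle", {
  # independently coded density: f(y) = exp(-(log y - log N)^2 / (2 tau)) /
  # (y sqrt(2 pi tau))
  oracle <- function(y, N, tau) {
    -log(y) - 0.5 * log(2 * pi * tau) - (log(y) - log(N))^2 / (2 * tau)
  }
  y <- c(120.3, 88, 405.7); N <- c(110, 95, 400); tau <- 0.04
  expect_equal(loglik_counts(y, N, tau), sum(oracle(y, N, tau)),
               tolerance = 1e-12)
  # unimodality in |log y - log N|
  devs <- c(0.01, 0.1, 0.4, 1)
  lls <- sapply(devs, function(d) loglik_counts(100 * exp(d), 100, 0.04))
  expect_true(all(diff(lls) < 0))
  # scale equivariance: scaling y and N by c changes log density by -log(c)
  expect_equal(loglik_counts(3 * 120, 3 * 110, 0.04),
               loglik_counts(120, 110, 0.04) - log(3), tolerance = 1e-12)
  # NA cells are skipped; non-positive modelled counts refuse
  expect_equal(loglik_counts(c(NA, 120), c(50, 110), 0.04),
               loglik_counts(120, 110, 0.04))
  expect_error(loglik_counts(c(0, 120), c(50, 110), 0.04), "non-positive")
  # precision reading inverts the variance
  expect_equal(loglik_counts(120, 110, 25, reading = "precision"),
               loglik_counts(120, 110, 1 / 25), tolerance = 1e-12)
})

test_that("Poisson juvenile likelihood handles boundary intensities", {
  expect_equal(loglik_juveniles(0, 5), -5)
  expect_equal(loglik_juveniles(2, 2), 2 * log(2) - 2 - log(2))
  expect_equal(loglik_juveniles(2, 2), -1.3069, tolerance = 1e-4)
  expect_equal(loglik_juveniles(3, 0), -Inf)
  expect_equal(loglik_juveniles(0, 0), 0)
  expect_equal(loglik_juveniles(c(NA, 4), c(9, 4)), dpois(4, 4, log = TRUE))
  expect_error(loglik_juveniles(2.5, 3), "integers")
})

test_that("m-array cell probabilities are proper and match closed forms", {
  # death certain: all mass in the never-seen cell
  r <- const_rates(T_ = 4, phiJ = 0, phiA = 0)
  pr <- marray_cell_probs(r, 1, "A", 1)
  expect_equal(pr[length(pr)], 1)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # one interval, certain detection: cell(j) = phi * psi exactly
  r2 <- const_rates(T_ = 2, phiA = 0.8, psiA = 0.05, p = 1)
  pr2 <- marray_cell_probs(r2, 1, "A", 1)
  expect_equal(pr2[marray_col(2, 2)], 0.8 * 0.05)
  expect_equal(pr2[marray_col(1, 2)], 0.8 * (1 - 3 * 0.05))
  expect_equal(pr2[length(pr2)], 1 - 0.8, tolerance = 1e-12)
  # release in the final year is never resighted
  pr3 <- marray_cell_probs(const_rates(T_ = 3), 2, "A", 3)
  expect_equal(pr3[length(pr3)], 1)
  # rows sum to one for random rates, both ages, all release years
  set.seed(11)
  rr <- draw_rates(imm_hyper(6), sim_covariates(6, seed = 3))
  for (g in 1:3) for (a in c("J", "A")) for (yr in 1:5) {
    expect_equal(sum(marray_cell_probs(rr, g, a, yr)), 1, tolerance = 1e-12)
  }
  expect_error(marray_cell_probs(rr, 4, "J", 1), "Elsewhere")
})

test_that("m-array cell probabilities equal exhaustive path enumeration", {
  # 4 years, random year-varying rates, juvenile and adult releases: the
  # recursion must agree with brute-force enumeration over all trajectories
  set.seed(12)
  rr <- draw_rates(imm_hyper(4, sigma_psi = 0.4, sigma_p = 0.4),
                   sim_covariates(4, seed = 5))
  for (g in 1:3) for (a in c("J", "A")) for (yr in 1:3) {
    expect_equal(marray_cell_probs(rr, g, a, yr),
                 marray_probs_bruteforce(rr, g, a, yr), tolerance = 1e-10)
  }
  expect_equal(marray_cell_probs(rr, 4, "A", 2),
               marray_probs_bruteforce(rr, 4, "A", 2), tolerance = 1e-10)
})

test_that("multinomial m-array likelihood sums count-weighted log cells", {
  T_ <- 3
  r <- const_rates(T_ = T_, phiA = 1, psiA = 0, p = 1)
  # all birds resighted at home next year with certainty: log-lik 0
  counts <- matrix(0L, 1, 4 * (T_ - 1) + 1)
  counts[1, marray_col(1, 2)] <- 7L
  marr <- immeta:::new_marray(counts, data.frame(group_i = 1L, age = "A",
                                                 year = 1L), T_)
  expect_equal(loglik_marray(marr, r), 0)
  # single row, hand arithmetic on two cells
  r2 <- const_rates(T_ = 2, phiA = 0.75 / (1 - 3 * 0.01), psiA = 0.01, p = 1)
  pr <- marray_cell_probs(r2, 1, "A", 1)
  counts2 <- matrix(0L, 1, 5)
  counts2[1, marray_col(1, 2)] <- 3L
  counts2[1, 5] <- 1L
  marr2 <- immeta:::new_marray(counts2, data.frame(group_i = 1L, age = "A",
                                                   year = 1L), 2L)
  expect_equal(loglik_marray(marr2, r2),
               3 * log(pr[marray_col(1, 2)]) + log(pr[5]), tolerance = 1e-12)
  # row order invariance
  sim <- tiny_sim()
  marr3 <- sim$data$marr
  ll1 <- loglik_marray(marr3, sim$truth$rates)
  perm <- sample(nrow(marr3$counts))
  marr4 <- immeta:::new_marray(marr3$counts[perm, ], marr3$rel[perm, ],
                               marr3$n_years)
  expect_equal(loglik_marray(marr4, sim$truth$rates), ll1, tolerance = 1e-10)
  # positive count on an impossible cell
  rdead <- const_rates(T_ = 2, phiA = 0)
  expect_equal(loglik_marray(marr2, rdead), -Inf)
})

test_that("log prior matches the stated densities and supports", {
  spec <- imm_spec(6)
  h <- hyper0()
  initA <- c(2000, 2000, 200, 2000)
  lp <- log_prior(h, initA, spec)
  expect_true(is.finite(lp))
  # discrete-uniform initial abundance: Pr = 1/3001 per group (W range)
  h2 <- h
  lp2 <- log_prior(h2, c(1000, 2000, 200, 2000), spec)
  expect_equal(lp2, lp) # flat within support
  expect_equal(log_prior(h, c(5000, 2000, 200, 2000), spec), -Inf)
  # alpha_psi outside Uniform(0, 0.2)
  h3 <- h
  h3$alpha_psi[2] <- 0.3
  expect_equal(log_prior(h3, initA, spec), -Inf)
  # Laplace density at its location is log(1/(2b))
  h4 <- h
  h4$mu_beta <- c(0, 0)
  h4$lambda_beta <- c(2, 2) # b = 1/4
  h4$beta_stormJ <- rep(0, 3)
  b <- 1 / 4
  delta <- log_prior(h4, initA, spec) -
    {
      h5 <- h4
      h5$beta_stormJ <- c(0.5, 0, 0)
      log_prior(h5, initA, spec)
    }
  expect_equal(delta, 0.5 / b, tolerance = 1e-12) # |x - mu|/b difference
  # moving one initial abundance out of a group-specific range
  expect_equal(log_prior(h, c(2000, 2000, 500, 2000), spec), -Inf)
  # explicit discrete-uniform mass: widening W's range by replacing spec
  spec2 <- imm_spec(6, initA_bounds = rbind(W = c(1000, 4000),
                                            Is = c(1000, 4000),
                                            LK = c(1, 400),
                                            E = c(1000, 7500)))
  expect_equal(log_prior(h, initA, spec2) - log_prior(h, initA, spec), 0)
})

test_that("joint posterior is the sum of its components", {
  sim <- tiny_sim()
  spec <- imm_spec(10)
  h <- sim$truth$hyper
  lat <- sim$truth$states
  data <- sim$data
  rates <- rates_from_hyper(h, data$covs)
  total <- joint_log_posterior(h, lat, data, spec)
  parts <- log_prior(h, lat$A[, 1], spec) +
    process_logdensity(lat, rates) +
    loglik_counts(data$y, lat$Ntot, h$tau_y) +
    loglik_juveniles(data$jobs, lat$J) +
    loglik_marray(data$marr, rates)
  expect_equal(total, parts, tolerance = 1e-10)
  expect_true(is.finite(total))
  # monotone in a single component: improving the count fit cannot lower it
  h_bad <- h
  h_bad$tau_y <- h$tau_y * 1e4
  expect_false(identical(total, joint_log_posterior(h_bad, lat, data, spec)))
})

test_that("batch cell probabilities equal the per-row reference", {
  sim <- tiny_sim()
  r <- sim$truth$rates
  marr <- sim$data$marr
  prmat <- immeta:::marray_rows_probs_cpp(
    r$n_years, as.integer(marr$rel$group_i),
    as.integer(ifelse(marr$rel$age == "J", 0L, 1L)),
    as.integer(marr$rel$year), r$phiJ, r$phiA,
    as.numeric(r$psiJ), as.numeric(r$psiA), r$p)
  for (k in sample(nrow(prmat), 10)) {
    expect_equal(prmat[k, ],
                 marray_cell_probs(r, marr$rel$group_i[k], marr$rel$age[k],
                                   marr$rel$year[k]), tolerance = 1e-12)
  }
})

test_that("compiled joint posterior agrees with the R reference", {
  sim <- tiny_sim()
  spec <- imm_spec(10)
  lpR <- joint_log_posterior(sim$truth$hyper, sim$truth$states, sim$data, spec)
  lpC <- immeta:::imm_lp_cpp(immeta:::imm_data_to_cpp(sim$data),
                             immeta:::imm_spec_to_cpp(spec),
                             immeta:::hyper_to_init(sim$truth$hyper,
                                                    sim$truth$states))
  expect_equal(lpC, lpR, tolerance = 1e-8)
  # and at a second, perturbed point
  h2 <- sim$truth$hyper
  h2$alpha_phiA <- plogis(qlogis(h2$alpha_phiA) + 0.2)
  h2$eps_psi <- h2$eps_psi * 0.5
  h2$tau_y <- 0.01
  lpR2 <- joint_log_posterior(h2, sim$truth$states, sim$data, spec)
  lpC2 <- immeta:::imm_lp_cpp(immeta:::imm_data_to_cpp(sim$data),
                              immeta:::imm_spec_to_cpp(spec),
                              immeta:::hyper_to_init(h2, sim$truth$states))
  expect_equal(lpC2, lpR2, tolerance = 1e-8)
})
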