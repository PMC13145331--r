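test_that("realised growth is the element-wise ratio of successive totals", {
  expect_equal(realized_growth(c(100, 110)), 1.1)
  expect_equal(realized_growth(rep(250, 6)), rep(1, 5))
  m <- rbind(c(10, 20, 40), c(8, 4, 2))
  expect_equal(realized_growth(m), rbind(c(2, 2), c(0.5, 0.5)))
  expect_equal(ncol(realized_growth(matrix(1:12, 2))), 5)
  expect_error(realized_growth(c(10, 0, 5)), "zero total")
})

# build a theta series with chosen temporal variation around a realistic mean
make_theta <- function(n_years = 30, jitter = NULL, seed = 1) {
  set.seed(seed)
  base <- c(gamma = 0.12, phiJ = 0.75, phiA = 0.85, fidJ = 0.95, fidA = 0.93,
            iota_a = 0.02, iota_b = 0.04, iota_c = 0.01,
            piJ = 0.10, piN1 = 0.07, piNad = 0.73, piI = 0.10)
  th <- matrix(rep(base, each = n_years), n_years, length(base),
               dimnames = list(NULL, names(base)))
  if (!is.null(jitter)) {
    for (nm in names(jitter)) {
      th[, nm] <- th[, nm] + rnorm(n_years, 0, jitter[[nm]])
    }
  }
  th
}

test_that("tLTRE contributions vanish for time-constant parameters", {
  res <- tltre_core(make_theta())
  expect_equal(unname(res$contributions), rep(0, 12))
  expect_equal(res$var_lambda, 0)
})

test_that("tLTRE matches the analytic single-parameter case", {
  th <- make_theta(jitter = list(gamma = 0.012), seed = 2)
  res <- tltre_core(th)
  s <- immeta:::lambda_sensitivity(colMeans(th))
  analytic <- s[["gamma"]]^2 * var(th[, "gamma"])
  expect_equal(res$contributions[["gamma"]], analytic, tolerance = 1e-10)
  # all other parameters contribute nothing
  expect_equal(sum(abs(res$contributions)) - abs(res$contributions[["gamma"]]),
               0)
  # and the single contribution explains Var(lambda) to first order
  expect_equal(res$total, res$var_lambda, tolerance = 0.01 * res$var_lambda)
})

test_that("tLTRE contributions sum to the variance of growth to first order", {
  jit <- list(gamma = 0.01, phiJ = 0.02, phiA = 0.02, fidA = 0.01,
              iota_a = 0.002, piJ = 0.005, piNad = 0.005)
  th <- make_theta(n_years = 60, jitter = jit, seed = 3)
  res <- tltre_core(th)
  expect_lt(abs(res$total - res$var_lambda) / res$var_lambda, 0.10)
  # the approximation becomes exact as the perturbations shrink
  rel_err <- sapply(c(1, 0.3, 0.1), function(sc) {
    th2 <- make_theta(n_years = 60, jitter = lapply(jit, `*`, sc), seed = 4)
    r <- tltre_core(th2)
    abs(r$total - r$var_lambda) / r$var_lambda
  })
  expect_lt(rel_err[3], rel_err[1] + 1e-12)
  expect_lt(rel_err[3], 0.02)
})

test_that("analytic sensitivities agree with central finite differences", {
  th <- colMeans(make_theta(jitter = list(gamma = 0.01, phiA = 0.02), seed = 5))
  s <- immeta:::lambda_sensitivity(th)
  eps <- 1e-6
  for (k in names(th)) {
    up <- th; up[k] <- up[k] + eps
    dn <- th; dn[k] <- dn[k] - eps
    num <- (lambda_from_theta(matrix(up, 1, dimnames = list(NULL, names(th)))) -
              lambda_from_theta(matrix(dn, 1, dimnames = list(NULL, names(th))))) /
      (2 * eps)
    expect_equal(s[[k]], as.numeric(num), tolerance = 1e-6)
  }
})

test_that("tLTRE over posterior draws runs on simulator truth", {
  sim <- tiny_sim()
  fit <- make_truth_fit(sim$truth$rates, sim$truth$states)
  lt <- tltre_decompose(fit, "W", n_draws = 1)
  expect_s3_class(lt, "imm_ltre")
  # percentages sum to 100 within rounding for the single draw
  expect_equal(sum(lt$pct[1, ]), 100, tolerance = 1e-9)
  expect_error(tltre_decompose(fit, "E"), "focal")
})

test_that("per-year contributions attribute growth changes to first order", {
  # single-parameter change between two years: contribution = sens * delta
  th <- make_theta(n_years = 3)
  th[2, "gamma"] <- th[2, "gamma"] + 0.004
  lam <- lambda_from_theta(th)
  mid <- (th[1, ] + th[2, ]) / 2
  s <- immeta:::lambda_sensitivity(mid)
  expect_equal(s[["gamma"]] * 0.004, lam[2] - lam[1],
               tolerance = abs(lam[2] - lam[1]) * 0.01)
  # telescoping: summed contributions track delta lambda on a truth fit
  sim <- tiny_sim()
  fit <- make_truth_fit(sim$truth$rates, sim$truth$states)
  dl <- delta_lambda_contributions(fit, "W", n_draws = 1)
  th_series <- immeta:::theta_series(sim$truth$rates, sim$truth$states, 1)
  lam_series <- lambda_from_theta(th_series)
  expect_equal(unname(rowSums(dl$contributions)), unname(diff(lam_series)),
               tolerance = 0.1 * max(abs(diff(lam_series))))
  expect_equal(nrow(dl$table), nrow(th_series) - 1)
})

test_that("dominant drivers are counted with ties split", {
  cm <- cbind(a = c(1, 1, 0.2), b = c(0.5, 0.2, 0.8))
  dd <- dominant_driver_summary(cm)
  expect_equal(dd$pct_years[dd$driver == "a"], 200 / 3, tolerance = 1e-12)
  expect_equal(sum(dd$pct_years), 100)
  # one driver always largest
  one <- cbind(a = rep(2, 5), b = rep(1, 5))
  expect_equal(dominant_driver_summary(one)$pct_years, c(100, 0))
  # alternating drivers over ten years
  alt <- cbind(a = rep(c(3, 1), 5), b = rep(c(1, 3), 5))
  expect_equal(dominant_driver_summary(alt)$pct_years, c(50, 50))
  # exact tie splits equally
  tie <- cbind(a = 1, b = 1)
  expect_equal(dominant_driver_summary(tie)$pct_years, c(50, 50))
  expect_error(dominant_driver_summary(cm[0, , drop = FALSE]), "non-empty")
})

test_that("net immigration rates match hand arithmetic and antisymmetry", {
  T_ <- 6
  # constructed rates: only E -> W adult flow, constant states
  r <- const_rates(T_ = T_, gamma = 0, phiA = 1, phiJ = 1)
  r$psiA[4, 1, ] <- 0.13 / 4000 * 100 # placeholder, overwritten below
  r$psiA[, , ] <- 0
  r$psiA[4, 1, ] <- 0.13 * 100 / (1 * 4000)
  J <- matrix(0, 4, T_); N1 <- matrix(0, 4, T_); I <- matrix(0, 4, T_)
  Nad <- matrix(0, 4, T_)
  A <- matrix(rep(c(100, 200, 50, 4000), T_), 4, T_)
  st <- structure(list(J = J, N1 = N1, Nad = Nad, I = I, A = A, Ntot = J + A,
                       n_years = T_), class = "imm_states")
  fit <- make_truth_fit(r, st)
  ni <- net_immigration(fit, n_draws = 1)
  # inflow to W: phi * psi * A_E = 1 * (13/4000) * 4000 = 13 per year on 100
  expect_equal(ni$pairwise$inet[ni$pairwise$from == "E" &
                                  ni$pairwise$to == "W"], 0.13,
               tolerance = 1e-9)
  # overall equals the sum of pairwise rates
  for (g in imm_groups()) {
    expect_equal(ni$overall$inet[ni$overall$group == g],
                 sum(ni$pairwise$inet[ni$pairwise$to == g]), tolerance = 1e-12)
  }
  # symmetric flows between identical groups cancel exactly
  r2 <- const_rates(T_ = T_, gamma = 0, phiA = 0.9)
  r2$psiA[1, 2, ] <- 0.05; r2$psiA[2, 1, ] <- 0.05
  A2 <- matrix(500, 4, T_)
  st2 <- structure(list(J = J, N1 = N1, Nad = Nad, I = I, A = A2,
                        Ntot = J + A2, n_years = T_), class = "imm_states")
  ni2 <- net_immigration(make_truth_fit(r2, st2), n_draws = 1)
  expect_equal(ni2$overall$inet[1:2], c(0, 0), tolerance = 1e-12)
  # antisymmetry scaled by adult abundance between a pair of groups
  pd <- ni$pair_draws[1, , ]
  expect_equal(pd[4, 1] * A[1, 1], -pd[1, 4] * A[4, 1], tolerance = 1e-9)
})

test_that("scenario projections reproduce the expectation recursion", {
  sim <- tiny_sim()
  r <- sim$truth$rates
  st <- sim$truth$states
  pr <- project_core(r, st$J[, 1], st$A[, 1], "both")
  # oracle: iterate the one-step process expectation
  J <- st$J[, 1]; A <- st$A[, 1]
  for (t in 1:(r$n_years - 1)) {
    e <- process_expectation(J, A, list(gamma_next = r$gamma[, t + 1],
                                        phiJ = r$phiJ[, t], phiA = r$phiA[, t],
                                        psiJ = r$psiJ[, , t],
                                        psiA = r$psiA[, , t]))
    J <- e$J; A <- e$A
  }
  expect_equal(pr$Ntot[, r$n_years], unname(J + A), tolerance = 1e-9)
  # removing immigration cannot help when every inflow is positive
  pr_em <- project_core(r, st$J[, 1], st$A[, 1], "emigration_only")
  expect_true(all(pr_em$Ntot <= pr$Ntot + 1e-9))
  growth <- function(p, i) exp(mean(log(p$lambda[i, ])))
  for (i in 1:3) expect_lte(growth(pr_em, i), growth(pr, i) + 1e-12)
})

test_that("no-movement growth converges to the two-stage matrix eigenvalue", {
  gam <- 0.12; pJ <- 0.72; pA <- 0.86
  r <- const_rates(T_ = 60, gamma = gam, phiJ = pJ, phiA = pA,
                   psiJ = 0.02, psiA = 0.03)
  pr <- project_core(r, rep(50, 4), rep(500, 4), "no_movement")
  lam_inf <- pr$lambda[1, 59]
  M <- rbind(c(gam * pJ, gam * pA), c(pJ, pA))
  expect_equal(lam_inf, max(Re(eigen(M)$values)), tolerance = 1e-9)
})

test_that("projection over draws summarises growth and correlation", {
  sim <- tiny_sim()
  fit <- make_truth_fit(sim$truth$rates, sim$truth$states)
  pr <- project_scenarios(fit, "both", n_draws = 1)
  expect_s3_class(pr, "imm_projection")
  # on simulator truth the expected trajectory tracks the realised one
  expect_true(all(pr$summary$r[1:3] > 0.9))
  expect_true(all(pr$summary$pr_r_pos[1:3] == 1))
  expect_error(project_scenarios(fit, "teleportation"), "arg")
})
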