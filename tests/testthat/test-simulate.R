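test_that("drawn rates collapse to intercepts without noise and reproduce seeds", {
  h0 <- imm_hyper(8, beta_gamma = matrix(0, 4, 4), beta_stormJ = rep(0, 3),
                  beta_stormA = rep(0, 4), huntJ = matrix(0, 3, 2),
                  huntA = matrix(0, 4, 2), sigma_gamma = 0, sigma_phiJ = 0,
                  sigma_phiA = 0, sigma_psi = 0, sigma_p = 0)
  r <- draw_rates(h0, sim_covariates(8, seed = 1))
  expect_equal(unique(as.numeric(r$gamma[1, ])), h0$alpha_gamma[1])
  expect_equal(unique(as.numeric(r$phiA[3, ])), h0$alpha_phiA[3])
  expect_equal(unique(as.numeric(r$p[4, ])), h0$alpha_p[4])
  # same seed, same output; different seed, different output
  cv <- sim_covariates(8, seed = 2)
  h <- imm_hyper(8)
  r1 <- draw_rates(h, cv, seed = 9)
  r2 <- draw_rates(h, cv, seed = 9)
  r3 <- draw_rates(h, cv, seed = 10)
  expect_identical(r1$gamma, r2$gamma)
  expect_false(identical(r1$gamma, r3$gamma))
  # rates live in their supports
  expect_true(all(r1$phiJ > 0 & r1$phiJ < 1))
  expect_true(all(r1$gamma > 0))
  h_bad <- imm_hyper(8)
  h_bad$alpha_psi[1] <- 0.5
  expect_error(draw_rates(h_bad, cv), "support")
})

test_that("year-effect dispersion matches its standard deviation at scale", {
  # Monte-Carlo check: sd of logit adult survival over many simulated years
  T_ <- 10000L
  h <- imm_hyper(T_, beta_gamma = matrix(0, 4, 4), beta_stormA = rep(0, 4),
                 huntA = matrix(0, 4, 2), sigma_phiA = 0.25)
  cv <- new_covs(x = array(0, c(4, T_, 4)), storms = matrix(0, 4, T_ - 1),
                 h = rep(0L, T_ - 1))
  r <- draw_rates(h, cv, seed = 5)
  emp <- sd(qlogis(r$phiA[2, ]))
  expect_equal(emp, 0.25, tolerance = 0.02)
})

test_that("simulated states satisfy the accounting identities", {
  sim <- tiny_sim()
  st <- sim$truth$states
  expect_equal(st$A[, -1], st$N1[, -1] + st$Nad[, -1] + st$I[, -1])
  expect_equal(st$Ntot, st$J + st$A)
  expect_true(all(st$J >= 0 & st$N1 >= 0 & st$Nad >= 0 & st$I >= 0))
  # binomial supports: survivors never exceed their source stage
  T_ <- st$n_years
  expect_true(all(st$N1[, 2:T_] <= st$J[, 1:(T_ - 1)]))
  expect_true(all(st$Nad[, 2:T_] <= st$A[, 1:(T_ - 1)]))
})

test_that("deterministic limits of the state simulation hold", {
  # no recruitment, full survival, no movement: totals frozen
  r <- const_rates(T_ = 6, gamma = 0, phiJ = 1, phiA = 1, psiJ = 0, psiA = 0)
  st <- simulate_states(r, c(100, 200, 50, 300), process_noise = FALSE)
  expect_equal(st$Ntot, matrix(rep(c(100, 200, 50, 300), 6), 4, 6))
  # no movement anywhere: immigrants identically zero
  r2 <- const_rates(T_ = 6, gamma = 0.1, phiJ = 0.7, phiA = 0.85)
  st2 <- simulate_states(r2, c(100, 200, 50, 300), seed = 3)
  expect_equal(st2$I[, -1], matrix(0, 4, 5))
})

test_that("mean simulated trajectory matches the expectation recursion", {
  set.seed(21)
  T_ <- 5
  r <- draw_rates(imm_hyper(T_, sigma_gamma = 0, sigma_phiJ = 0,
                            sigma_phiA = 0, sigma_psi = 0, sigma_p = 0),
                  sim_covariates(T_, seed = 4))
  init <- c(400, 300, 120, 500)
  # oracle: the transition means are linear in the state, so the expected
  # trajectory is the iterated one-step expectation
  J <- init * r$gamma[, 1]
  A <- init
  for (t in 1:(T_ - 1)) {
    e <- process_expectation(J, A, list(gamma_next = r$gamma[, t + 1],
                                        phiJ = r$phiJ[, t], phiA = r$phiA[, t],
                                        psiJ = r$psiJ[, , t], psiA = r$psiA[, , t]))
    J <- e$J; A <- e$A
  }
  nrep <- 500
  finals <- matrix(0, nrep, 4)
  for (k in seq_len(nrep)) {
    st <- simulate_states(r, init)
    finals[k, ] <- st$Ntot[, T_]
  }
  mc_mean <- colMeans(finals)
  mc_se <- apply(finals, 2, sd) / sqrt(nrep)
  expect_true(all(abs(mc_mean - (J + A)) <= 3 * mc_se + 1e-9))
})

test_that("observations follow the stated observation models", {
  sim <- tiny_sim()
  st <- sim$truth$states
  # vanishing observation noise recovers the truth
  o0 <- simulate_observations(st, tau_y = 1e-12, seed = 1)
  expect_equal(o0$y, st$Ntot, tolerance = 1e-4, ignore_attr = TRUE)
  # Poisson juvenile counts are unbiased
  lam <- 37
  stJ <- st
  stJ$J[] <- lam
  draws <- replicate(40, {
    simulate_observations(stJ, 0.0025)$jobs
  })
  n <- length(stJ$J) * 40
  expect_equal(mean(draws), lam, tolerance = 3 * sqrt(lam / n) / lam)
  # seeded reproducibility
  o1 <- simulate_observations(st, 0.0025, seed = 9)
  o2 <- simulate_observations(st, 0.0025, seed = 9)
  expect_identical(o1, o2)
  # zero totals are flagged and emitted as the zero sentinel
  st0 <- st
  st0$Ntot[2, 3] <- 0
  o3 <- simulate_observations(st0, 0.0025, seed = 2)
  expect_equal(o3$y[2, 3], 0)
  expect_true(attr(o3$y, "zero_total")[2, 3])
})

test_that("capture histories follow the movement-survival-detection chain", {
  # certainty limit: every bird resighted at its release group every year
  r <- const_rates(T_ = 5, phiJ = 1, phiA = 1, psiJ = 0, psiA = 0, p = 1)
  rel <- data.frame(group_i = c(1L, 2L), age = c("A", "J"), year = c(1L, 2L),
                    n = c(3L, 2L))
  hi <- simulate_histories(r, rel, seed = 1)
  expect_equal(hi$hist[1, ], c(1L, 1L, 1L, 1L, 1L))
  expect_equal(hi$hist[4, ], c(0L, 2L, 2L, 2L, 2L))
  # blind observer: marking occasion only
  r0 <- const_rates(T_ = 5, p = 0)
  hi0 <- simulate_histories(r0, rel, seed = 2)
  expect_equal(sum(hi0$hist > 0), nrow(hi0$hist))
  # juvenile releases outside focal groups refuse
  expect_error(simulate_histories(r, data.frame(group_i = 4L, age = "J",
                                                year = 1L, n = 1L)),
               "focal")
})

test_that("empirical first-interval survival matches the juvenile rate", {
  r <- const_rates(T_ = 3, phiJ = 0.7, phiA = 0.9, psiJ = 0, psiA = 0, p = 1)
  n <- 10000L
  hi <- simulate_histories(r, data.frame(group_i = 1L, age = "J", year = 1L,
                                         n = n), seed = 8)
  alive2 <- mean(hi$hist[, 2] > 0) # p = 1, so resighted iff alive
  expect_lt(abs(alive2 - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("m-array construction matches hand enumeration", {
  T_ <- 4
  hist <- rbind(c(1L, 1L, 0L, 2L),   # adult, marked g1 y1; seen y2 g1, y4 g2
                c(1L, 0L, 0L, 0L),   # adult, marked g1 y1; never seen again
                c(0L, 2L, 3L, 0L))   # juvenile, marked g2 y2; seen y3 g3
  histories <- structure(list(hist = hist, group0 = c(1L, 1L, 2L),
                              age0 = c("A", "A", "J"), year0 = c(1L, 1L, 2L),
                              n_years = T_), class = "imm_histories")
  ma <- marray_from_histories(histories)
  expect_equal(ma$releases, rowSums(ma$counts))
  key <- paste(ma$rel$group_i, ma$rel$age, ma$rel$year)
  ncell <- 4 * (T_ - 1) + 1
  # row (1, A, 1): one first resighting at (1,2), one never seen
  r1 <- ma$counts[key == "1 A 1", ]
  expect_equal(sum(r1), 2)
  expect_equal(r1[marray_col(1, 2)], 1L)
  expect_equal(r1[ncell], 1L)
  # re-release of bird 1 at (1, A, 2): next resighting (2, 4)
  r2 <- ma$counts[key == "1 A 2", ]
  expect_equal(r2[marray_col(2, 4)], 1L)
  expect_equal(sum(r2), 1)
  # juvenile release row and its adult re-release, never seen afterwards
  r3 <- ma$counts[key == "2 J 2", ]
  expect_equal(r3[marray_col(3, 3)], 1L)
  r4 <- ma$counts[key == "3 A 3", ]
  expect_equal(r4[ncell], 1L)
  # resighting the bird marked in year 4 creates no new release row
  expect_false(any(ma$rel$year >= T_))
  # malformed: resighting before marking
  bad <- histories
  bad$hist[3, 1] <- 2L
  expect_error(marray_from_histories(bad), "before marking")
})

test_that("all-unseen histories put full mass in the never-seen column", {
  T_ <- 5
  hist <- matrix(0L, 4, T_)
  hist[, 2] <- 1L # all marked g1 year 2, never resighted
  histories <- structure(list(hist = hist, group0 = rep(1L, 4),
                              age0 = rep("A", 4), year0 = rep(2L, 4),
                              n_years = T_), class = "imm_histories")
  ma <- marray_from_histories(histories)
  expect_equal(nrow(ma$counts), 1L)
  expect_equal(ma$counts[1, 4 * (T_ - 1) + 1], 4L)
})

test_that("simulated m-array frequencies converge to the cell probabilities", {
  set.seed(33)
  T_ <- 4
  r <- draw_rates(imm_hyper(T_, sigma_psi = 0.2), sim_covariates(T_, seed = 6))
  n <- 20000L
  hi <- simulate_histories(r, data.frame(group_i = 2L, age = "J", year = 1L,
                                         n = n), seed = 12)
  ma <- marray_from_histories(hi)
  row <- which(ma$rel$group_i == 2 & ma$rel$age == "J" & ma$rel$year == 1)
  emp <- ma$counts[row, ] / n
  pr <- marray_cell_probs(r, 2, "J", 1)
  # each cell within 4 binomial standard errors (plus slack for empty cells)
  se <- sqrt(pr * (1 - pr) / n)
  expect_true(all(abs(emp - pr) <= 4 * se + 1e-4))
})

test_that("a full synthetic data set is coherent and reproducible", {
  sim1 <- simulate_dataset(sim_config(n_years = 8, seed = 77))
  sim2 <- simulate_dataset(sim_config(n_years = 8, seed = 77))
  expect_identical(sim1$data$y, sim2$data$y)
  expect_identical(sim1$data$marr$counts, sim2$data$marr$counts)
  expect_s3_class(sim1$data, "imm_data")
  # the m-array only contains juvenile rows for focal groups
  expect_true(all(sim1$data$marr$rel$group_i[sim1$data$marr$rel$age == "J"] <= 3))
  # joint posterior at the generating values is finite
  expect_true(is.finite(joint_log_posterior(sim1$truth$hyper,
                                            sim1$truth$states, sim1$data,
                                            imm_spec(8))))
})
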