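#' Synthetic standardized covariates
#'
#' Generates a covariate set with the structure the model expects: four
#' standardized fecundity covariates and a standardized storm covariate per
#' group-year (independent standard normals re-standardized within group),
#' plus the hunting-period index implied by the calendar years. Emulates the
#' marginal structure of the real covariates (standardized within group,
#' step-pattern hunting periods); it does not emulate among-group or serial
#' correlation of real weather.
#'
#' @param n_years Number of winters T.
#' @param first_year Calendar label of the first winter, default 1983.
#' @param seed Optional RNG seed.
#' @return An `imm_covs` object.
#' @export
sim_covariates <- function(n_years = 39L, first_year = 1983L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- 4L
  covn <- c("gdd_winter", "gdd_stage", "gdd_breed", "snow_breed")
  x <- array(stats::rnorm(G * n_years * 4), dim = c(G, n_years, 4),
             dimnames = list(imm_groups(), NULL, covn))
  for (i in seq_len(G)) for (k in 1:4) x[i, , k] <- standardize(x[i, , k])
  storms <- matrix(stats::rnorm(G * (n_years - 1L)), G, n_years - 1L)
  for (i in seq_len(G)) storms[i, ] <- standardize(storms[i, ])
  years <- first_year + seq_len(n_years) - 1L
  new_covs(x = x, storms = storms, h = hunting_period(years[-1]))
}

#' Draw demographic rates from hyperparameters
#'
#' Draws the year effects from their Normal distributions and applies the
#' model's link functions to produce full rate trajectories. With all
#' standard deviations zero the rates are constant at their intercepts
#' (covariates at their mean), which gives the deterministic limit used in
#' several tests.
#'
#' @param hyper An `imm_hyper` object (intercepts, effects, sds).
#' @param covs An `imm_covs` object; defaults to simulated covariates.
#' @param seed Optional RNG seed.
#' @return An `imm_rates` object; the drawn year effects are attached as
#'   attribute `"hyper"` (an `imm_hyper` with `eps_*` filled in).
#' @export
draw_rates <- function(hyper, covs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T_ <- hyper$n_years
  if (is.null(covs)) covs <- sim_covariates(T_)
  validate_hyper(hyper)
  if (any(hyper$alpha_psi >= 0.2 + 1e-12)) {
    stop("dispersal mean outside its prior support [0, 0.2]")
  }
  nf <- nrow(imm_flows())
  h <- hyper
  h$eps_gamma <- matrix(stats::rnorm(4 * T_, 0, hyper$sigma_gamma), 4, T_)
  h$eps_phiJ <- matrix(stats::rnorm(3 * (T_ - 1L), 0, hyper$sigma_phiJ), 3, T_ - 1L)
  h$eps_phiA <- matrix(stats::rnorm(4 * (T_ - 1L), 0, hyper$sigma_phiA), 4, T_ - 1L)
  h$eps_psi <- matrix(stats::rnorm(nf * (T_ - 1L), 0, hyper$sigma_psi), nf, T_ - 1L)
  h$eps_p <- matrix(stats::rnorm(4 * (T_ - 1L), 0, hyper$sigma_p), 4, T_ - 1L)
  rates <- rates_from_hyper(h, covs)
  for (it in seq_len(T_ - 1L)) {
    if (any(rowSums(rates$psiJ[, , it]) >= 1) ||
        any(rowSums(rates$psiA[, , it]) >= 1)) {
      stop("drawn movement probabilities sum to >= 1 for a group")
    }
  }
  attr(rates, "hyper") <- h
  attr(rates, "covs") <- covs
  rates
}

#' Simulate latent states
#'
#' Runs the stage-structured process model forward: Poisson recruitment,
#' Binomial survival-and-fidelity, Poisson immigration. With
#' `process_noise = FALSE` the expectations are propagated (rounded half-up),
#' giving the deterministic limit.
#'
#' @param rates An `imm_rates` object.
#' @param init_A Length-4 initial adult abundances.
#' @param seed Optional RNG seed.
#' @param process_noise Draw stochastic transitions (default) or propagate
#'   rounded expectations.
#' @return An `imm_states` object.
#' @export
simulate_states <- function(rates, init_A, seed = NULL, process_noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (any(init_A < 0)) stop("initial adult abundances must be non-negative")
  G <- 4L
  T_ <- rates$n_years
  J <- N1 <- Nad <- I <- matrix(0, G, T_)
  A <- matrix(0, G, T_)
  A[, 1] <- init_A
  draw_pois <- function(lam) if (process_noise) stats::rpois(length(lam), lam) else round_half_up(lam)
  draw_bin <- function(n, p) if (process_noise) stats::rbinom(length(n), n, p) else round_half_up(n * p)
  J[, 1] <- draw_pois(A[, 1] * rates$gamma[, 1])
  for (t in 2:T_) {
    it <- t - 1L
    outJ <- rowSums(rates$psiJ[, , it])
    outA <- rowSums(rates$psiA[, , it])
    N1[, t] <- draw_bin(J[, it], rates$phiJ[, it] * (1 - outJ))
    Nad[, t] <- draw_bin(A[, it], rates$phiA[, it] * (1 - outA))
    inflow <- colSums(rates$psiJ[, , it] * (rates$phiJ[, it] * J[, it])) +
      colSums(rates$psiA[, , it] * (rates$phiA[, it] * A[, it]))
    I[, t] <- draw_pois(inflow)
    A[, t] <- N1[, t] + Nad[, t] + I[, t]
    J[, t] <- draw_pois(A[, t] * rates$gamma[, t])
  }
  imm_states(J, N1, Nad, I, init_A)
}

#' Simulate count and juvenile-count observations
#'
#' Counts are lognormal around the true totals with log-scale variance
#' `tau_y`; juvenile counts are Poisson around true juvenile abundance. A
#' zero true total cannot produce a lognormal count: such cells emit the
#' sentinel `y = 0` and are flagged in the `"zero_total"` attribute.
#'
#' @param states An `imm_states` object.
#' @param tau_y Log-scale observation variance.
#' @param seed Optional RNG seed.
#' @return List with matrices `y` and `jobs`; `y` carries the
#'   `"zero_total"` flag matrix as an attribute.
#' @export
simulate_observations <- function(states, tau_y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(tau_y)
  zero <- states$Ntot == 0
  y <- matrix(0, nrow(states$Ntot), ncol(states$Ntot))
  y[!zero] <- stats::rlnorm(sum(!zero), meanlog = log(states$Ntot[!zero]),
                            sdlog = sdlog)
  attr(y, "zero_total") <- zero
  jobs <- matrix(stats::rpois(length(states$J), states$J),
                 nrow(states$J), ncol(states$J))
  list(y = y, jobs = jobs)
}

#' Default release schedule
#'
#' Newly marked birds per (group, age, year): by default 30 juveniles and 30
#' adults in each focal group in every release year, none in Elsewhere
#' (birds are marked at focal sites only; Elsewhere release rows arise from
#' re-releases after resighting there).
#'
#' @param n_years Number of winters T (releases occur in years 1..T-1).
#' @param n_juv,n_ad Releases per focal group-year.
#' @return data.frame with columns `group_i`, `age`, `year`, `n`.
#' @export
default_releases <- function(n_years = 39L, n_juv = 30L, n_ad = 30L) {
  grid <- expand.grid(group_i = 1:3, age = c("J", "A"),
                      year = seq_len(n_years - 1L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- ifelse(grid$age == "J", n_juv, n_ad)
  grid
}

#' Simulate individual capture-resighting histories
#'
#' Each released bird moves among groups and survives according to the
#' age-specific rates (juvenile rates for the first interval after a juvenile
#' release only) and is resighted at its current group with that group's
#' resighting probability. Histories record the marking occasion and all
#' resightings.
#'
#' @param rates An `imm_rates` object.
#' @param releases Release schedule (see [default_releases()]).
#' @param seed Optional RNG seed.
#' @return An `imm_histories` object: list with integer matrix `hist`
#'   (individuals x occasions; value = group index when detected, 0
#'   otherwise; the marking occasion counts as detected), and vectors
#'   `group0`, `age0`, `year0`.
#' @export
simulate_histories <- function(rates, releases, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- 4L
  T_ <- rates$n_years
  if (any(releases$n < 0)) stop("release counts must be non-negative")
  if (any(releases$age == "J" & releases$group_i > 3L)) {
    stop("juvenile releases are only allowed in focal groups")
  }
  n_ind <- sum(releases$n)
  hist <- matrix(0L, n_ind, T_)
  group0 <- integer(n_ind); age0 <- character(n_ind); year0 <- integer(n_ind)
  row <- 0L
  for (k in seq_len(nrow(releases))) {
    nk <- releases$n[k]
    if (nk == 0L) next
    g0 <- releases$group_i[k]; a0 <- releases$age[k]; r0 <- releases$year[k]
    for (b in seq_len(nk)) {
      row <- row + 1L
      group0[row] <- g0; age0[row] <- a0; year0[row] <- r0
      hist[row, r0] <- g0
      s <- g0
      if (r0 >= T_) next
      for (u in (r0 + 1L):T_) {
        it <- u - 1L
        juvenile_step <- (a0 == "J" && u == r0 + 1L)
        phi <- if (juvenile_step) rates$phiJ[s, it] else rates$phiA[s, it]
        if (stats::runif(1) >= phi) break
        psi <- if (juvenile_step) rates$psiJ[s, , it] else rates$psiA[s, , it]
        dest <- c(psi, 1 - sum(psi))
        pick <- sample.int(G + 1L, 1L, prob = dest)
        if (pick <= G) s <- pick
        if (stats::runif(1) < rates$p[s, it]) hist[row, u] <- s
      }
    }
  }
  structure(list(hist = hist, group0 = group0, age0 = age0, year0 = year0,
                 n_years = T_), class = "imm_histories")
}

#' Build a multistate m-array from individual histories
#'
#' Summarises first resightings per release cohort: one row per (release
#' group, age, release year), columns over (resighting group, occasion) plus
#' a never-seen cell. After each resighting before the final occasion the
#' bird re-enters the corresponding adult release row, so rows sum to their
#' release totals by construction.
#'
#' @param histories An `imm_histories` object.
#' @return An `imm_marray` object: list with integer matrix `counts`
#'   (rows x cells), data.frame `rel` (`group_i`, `age`, `year`), vector
#'   `releases` (row totals) and `n_years`.
#' @export
marray_from_histories <- function(histories) {
  G <- 4L
  T_ <- histories$n_years
  hist <- histories$hist
  rel_key <- function(g, a, r) paste(g, a, r, sep = ".")
  rows <- new.env(parent = emptyenv())
  ncell <- G * (T_ - 1L) + 1L
  add <- function(g, a, r, cell) {
    k <- rel_key(g, a, r)
    cur <- if (is.null(rows[[k]])) integer(ncell) else rows[[k]]
    cur[cell] <- cur[cell] + 1L
    rows[[k]] <- cur
  }
  for (i in seq_len(nrow(hist))) {
    r <- histories$year0[i]
    g <- histories$group0[i]
    a <- histories$age0[i]
    seen <- which(hist[i, ] > 0L)
    if (length(seen) && min(seen) < r) stop("resighting before marking for individual ", i)
    seen <- seen[seen > r]
    for (u in seen) {
      j <- hist[i, u]
      add(g, a, r, marray_col(j, u))
      if (u >= T_) { r <- NA_integer_; break }
      g <- j; a <- "A"; r <- u
    }
    if (!is.na(r)) add(g, a, r, ncell)
  }
  keys <- ls(rows)
  parts <- do.call(rbind, strsplit(keys, ".", fixed = TRUE))
  rel <- data.frame(group_i = as.integer(parts[, 1]), age = parts[, 2],
                    year = as.integer(parts[, 3]), stringsAsFactors = FALSE)
  ord <- order(rel$age, rel$group_i, rel$year)
  counts <- do.call(rbind, lapply(keys, function(k) rows[[k]]))
  counts <- counts[ord, , drop = FALSE]
  rel <- rel[ord, , drop = FALSE]
  rownames(rel) <- NULL
  new_marray(counts, rel, T_)
}

new_marray <- function(counts, rel, n_years) {
  structure(list(counts = counts, rel = rel,
                 releases = rowSums(counts), n_years = n_years),
            class = "imm_marray")
}

#' Simulation configuration for the default synthetic scenario
#'
#' The default scenario mirrors the magnitudes of the wintering-goose system:
#' four groups over 39 winters, low fecundity (about 0.1-0.15 young per
#' adult), high adult survival (0.79-0.89), high focal resighting
#' probabilities (about 0.9) with low Elsewhere resighting (about 0.28),
#' dispersal means well below the 0.2 prior cap, initial abundances at the
#' estimated 1983/84 sizes, and 30 juvenile plus 30 adult releases per focal
#' group-year.
#'
#' @param n_years Number of winters.
#' @param hyper An `imm_hyper` object of true parameter values.
#' @param init_A True initial adult abundances.
#' @param releases Release schedule.
#' @param seed RNG seed for the whole simulation.
#' @param process_noise Logical; `FALSE` propagates expectations.
#' @return List of class `imm_sim_config`.
#' @export
sim_config <- function(n_years = 39L,
                       hyper = imm_hyper(n_years),
                       init_A = c(3320, 2428, 157, 3987),
                       releases = default_releases(n_years),
                       seed = 1L,
                       process_noise = TRUE) {
  structure(list(n_years = as.integer(n_years), hyper = hyper,
                 init_A = init_A, releases = releases, seed = seed,
                 process_noise = process_noise),
            class = "imm_sim_config")
}

#' Simulate a complete synthetic data set
#'
#' Draws rates, latent states, observations and capture histories under one
#' configuration and packages them as an `imm_data` object plus the full
#' simulation truth.
#'
#' @param config An `imm_sim_config` object.
#' @return List with `data` (an `imm_data`), and `truth` (list: `rates`,
#'   `states`, `hyper` with realised year effects, `init_A`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  covs <- sim_covariates(config$n_years)
  rates <- draw_rates(config$hyper, covs)
  states <- simulate_states(rates, config$init_A,
                            process_noise = config$process_noise)
  obs <- simulate_observations(states, config$hyper$tau_y)
  histories <- simulate_histories(rates, config$releases)
  marr <- marray_from_histories(histories)
  data <- imm_data(y = obs$y, jobs = obs$jobs, marr = marr, covs = covs)
  list(data = data,
       truth = list(rates = rates, states = states,
                    hyper = attr(rates, "hyper"), init_A = config$init_A,
                    histories = histories))
}
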