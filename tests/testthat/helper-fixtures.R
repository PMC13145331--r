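# Small shared fixtures built in code. Everything is seeded so the suite is
# reproducible.

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_years = 10, seed = 42,
                                            releases = default_releases(10)))
    }
    cache
  }
})

# constant-rate object for hand-checkable scenarios
const_rates <- function(T_ = 5, gamma = 0.1, phiJ = 0.7, phiA = 0.85,
                        psiJ = 0, psiA = 0, p = 0.9) {
  G <- 4
  gam <- matrix(gamma, G, T_)
  pj <- matrix(phiJ, G, T_ - 1)
  pa <- matrix(phiA, G, T_ - 1)
  aJ <- array(0, c(G, G, T_ - 1))
  aA <- array(0, c(G, G, T_ - 1))
  fl <- imm_flows()
  for (f in seq_len(nrow(fl))) {
    if (fl$age[f] == "J") aJ[fl$from_i[f], fl$to_i[f], ] <- psiJ
    else aA[fl$from_i[f], fl$to_i[f], ] <- psiA
  }
  pm <- matrix(p, G, T_ - 1)
  structure(list(gamma = gam, phiJ = pj, phiA = pa, psiJ = aJ, psiA = aA,
                 p = pm, n_years = T_), class = "imm_rates")
}

# wrap exact rate/state trajectories (e.g. simulator truth) as a one-draw
# imm_fit so the post-fit analyses can be checked against closed-form oracles
make_truth_fit <- function(rates, states, tau_y = 0.0025,
                           spec = imm_spec(rates$n_years)) {
  T_ <- rates$n_years
  fl <- imm_flows()
  nf <- nrow(fl)
  psi <- matrix(0, nf, T_ - 1)
  for (f in seq_len(nf)) {
    arr <- if (fl$age[f] == "J") rates$psiJ else rates$psiA
    psi[f, ] <- arr[fl$from_i[f], fl$to_i[f], ]
  }
  pars <- matrix(tau_y, 1, length(imm_par_names()),
                 dimnames = list(NULL, imm_par_names()))
  chain <- list(pars = pars,
                gamma = matrix(as.numeric(rates$gamma), 1),
                phiJ = matrix(as.numeric(rates$phiJ), 1),
                phiA = matrix(as.numeric(rates$phiA), 1),
                p = matrix(as.numeric(rates$p), 1),
                psi = matrix(as.numeric(psi), 1),
                J = matrix(as.numeric(states$J), 1),
                N1 = matrix(as.numeric(states$N1), 1),
                Nad = matrix(as.numeric(states$Nad), 1),
                I = matrix(as.numeric(states$I), 1),
                A = matrix(as.numeric(states$A), 1),
                n_kept = 1L)
  structure(list(chains = list(chain), spec = spec, n_years = T_,
                 par_names = imm_par_names(),
                 config = mcmc_config(n_chains = 1, n_iter = 10, n_burn = 5,
                                      thin = 1)),
            class = "imm_fit")
}

# exhaustive-path oracle for multistate m-array cell probabilities: sums the
# probability of every (site trajectory, detection pattern) ending in a
# first resighting at (j, u), or in no resighting at all
marray_probs_bruteforce <- function(rates, group, age, year) {
  G <- 4
  T_ <- rates$n_years
  ncell <- G * (T_ - 1) + 1
  probs <- numeric(ncell)
  if (year >= T_) {
    probs[ncell] <- 1
    return(probs)
  }
  recurse <- function(state, u, prob, first) {
    # `state` = current group at occasion u (alive), prob = path probability
    if (u == T_) {
      probs[ncell] <<- probs[ncell] + prob
      return(invisible())
    }
    t <- u # interval u -> u+1
    juv <- (age == "J" && first)
    phi <- if (juv) rates$phiJ[state, t] else rates$phiA[state, t]
    psi <- if (juv) rates$psiJ[state, , t] else rates$psiA[state, , t]
    # death
    probs[ncell] <<- probs[ncell] + prob * (1 - phi)
    for (dest in 1:G) {
      move <- if (dest == state) 1 - sum(psi) else psi[dest]
      if (move <= 0) next
      pr2 <- prob * phi * move
      pdet <- rates$p[dest, t]
      # detected at u+1: first resighting, path ends here
      probs[(u + 1 - 2) * G + dest] <<- probs[(u + 1 - 2) * G + dest] +
        pr2 * pdet
      # not detected: continue as adult
      recurse(dest, u + 1, pr2 * (1 - pdet), FALSE)
    }
  }
  recurse(group, year, 1, TRUE)
  probs
}
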