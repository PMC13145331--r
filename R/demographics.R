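#' Realised growth rates
#'
#' Element-wise annual growth `lambda[, t] = Ntot[, t + 1] / Ntot[, t]`.
#'
#' @param Ntot Group-by-year matrix (or vector) of positive total sizes.
#' @return Matrix (or vector) of growth rates, one fewer column.
#' @export
realized_growth <- function(Ntot) {
  vec <- is.null(dim(Ntot))
  m <- if (vec) matrix(Ntot, nrow = 1) else Ntot
  if (ncol(m) < 2L) stop("need at least two years")
  if (any(m == 0)) {
    bad <- which(m == 0, arr.ind = TRUE)[1, ]
    stop("zero total size at group ", bad[1], ", year ", bad[2])
  }
  lam <- m[, -1, drop = FALSE] / m[, -ncol(m), drop = FALSE]
  if (vec) drop(lam) else lam
}

# names of the demographic parameters entering the growth-rate expression
# for a focal group with three movement sources
theta_names <- function(sources) {
  c("gamma", "phiJ", "phiA", "fidJ", "fidA",
    paste0("iota_", sources), "piJ", "piN1", "piNad", "piI")
}

#' Growth rate implied by the demographic parameter vector
#'
#' The realised growth of a focal subpopulation is expressed as
#' `lambda_t = (1 + gamma_{t+1}) * (phiJ * fidJ * piJ +
#'   phiA * fidA * (piN1 + piNad + piI) + sum(iota_s))`,
#' where `pi*` are stage proportions of the current total, `fid*` are
#' fidelity probabilities (one minus total emigration) and `iota_s` is the
#' expected adult-equivalent immigrant flow from source `s` arriving next
#' winter per current total.
#'
#' @param theta Matrix (years x parameters) with columns named as in the
#'   tLTRE decomposition (`gamma`, `phiJ`, `phiA`, `fidJ`, `fidA`,
#'   `iota_*`, `piJ`, `piN1`, `piNad`, `piI`).
#' @return Numeric vector of per-year growth rates.
#' @export
lambda_from_theta <- function(theta) {
  iota <- theta[, grepl("^iota_", colnames(theta)), drop = FALSE]
  piA <- theta[, "piN1"] + theta[, "piNad"] + theta[, "piI"]
  (1 + theta[, "gamma"]) *
    (theta[, "phiJ"] * theta[, "fidJ"] * theta[, "piJ"] +
       theta[, "phiA"] * theta[, "fidA"] * piA +
       rowSums(iota))
}

# analytic gradient of lambda_from_theta at a parameter vector
lambda_sensitivity <- function(th) {
  iota_idx <- grepl("^iota_", names(th))
  piA <- th[["piN1"]] + th[["piNad"]] + th[["piI"]]
  B <- th[["phiJ"]] * th[["fidJ"]] * th[["piJ"]] +
    th[["phiA"]] * th[["fidA"]] * piA + sum(th[iota_idx])
  g1 <- 1 + th[["gamma"]]
  s <- numeric(length(th))
  names(s) <- names(th)
  s["gamma"] <- B
  s["phiJ"] <- g1 * th[["fidJ"]] * th[["piJ"]]
  s["fidJ"] <- g1 * th[["phiJ"]] * th[["piJ"]]
  s["phiA"] <- g1 * th[["fidA"]] * piA
  s["fidA"] <- g1 * th[["phiA"]] * piA
  s[iota_idx] <- g1
  s["piJ"] <- g1 * th[["phiJ"]] * th[["fidJ"]]
  s["piN1"] <- s["piNad"] <- s["piI"] <- g1 * th[["phiA"]] * th[["fidA"]]
  s
}

#' Transient LTRE decomposition of one demographic series
#'
#' First-order decomposition of the temporal variance of the realised growth
#' rate into contributions of the demographic parameters:
#' `contribution_k = sum_j s_k s_j Cov_t(theta_k, theta_j)` with
#' sensitivities `s` evaluated at the temporal means. Contributions sum to
#' the first-order approximation of `Var_t(lambda)`.
#'
#' @param theta Matrix (years x parameters), columns named as in
#'   [lambda_from_theta()].
#' @return List with `contributions` (absolute), `pct` (percent of the
#'   summed contributions), `total` (their sum), `var_lambda` (realised
#'   variance of the growth series) and `sens` (the sensitivity vector).
#' @export
tltre_core <- function(theta) {
  if (nrow(theta) < 2L) stop("need at least two years")
  mu <- colMeans(theta)
  s <- lambda_sensitivity(mu)
  if (any(!is.finite(s))) stop("non-finite sensitivities")
  V <- stats::cov(theta)
  contr <- as.numeric(s %*% V) * s # s_k * sum_j V_kj s_j
  names(contr) <- colnames(theta)
  tot <- sum(contr)
  lam <- lambda_from_theta(theta)
  pct <- if (tot > 0) 100 * contr / tot else contr * 0
  list(contributions = contr, pct = pct, total = tot,
       var_lambda = stats::var(lam), sens = s)
}

# theta series (years 2..T-1) for one focal group from one posterior draw
theta_series <- function(rates, states, group) {
  T_ <- rates$n_years
  i <- group
  src <- setdiff(1:4, i)
  ts <- 2:(T_ - 1L)
  Nt <- states$Ntot[i, ts]
  iota <- sapply(src, function(s) {
    (rates$phiJ[s, ts] * rates$psiJ[s, i, ts] * states$J[s, ts] +
       rates$phiA[s, ts] * rates$psiA[s, i, ts] * states$A[s, ts]) / Nt
  })
  th <- cbind(gamma = rates$gamma[i, ts + 1L],
              phiJ = rates$phiJ[i, ts],
              phiA = rates$phiA[i, ts],
              fidJ = 1 - apply(rates$psiJ[i, , ts, drop = FALSE], 3, sum),
              fidA = 1 - apply(rates$psiA[i, , ts, drop = FALSE], 3, sum),
              iota,
              piJ = states$J[i, ts] / Nt,
              piN1 = states$N1[i, ts] / Nt,
              piNad = states$Nad[i, ts] / Nt,
              piI = states$I[i, ts] / Nt)
  colnames(th) <- theta_names(imm_groups()[src])
  th
}

#' Transient LTRE decomposition over posterior draws
#'
#' Runs [tltre_core()] on the demographic series of each posterior draw for
#' one focal subpopulation (the first winter is dropped because its adult
#' stage composition is not defined). Not available for the Elsewhere group,
#' whose juvenile survival and emigration are not estimated.
#'
#' @param fit An `imm_fit` with saved states.
#' @param group Focal group index (1..3) or code.
#' @param n_draws Posterior draws used (subsampled evenly).
#' @return An `imm_ltre` object: list with `summary` (data.frame of median
#'   and 90% CRI of absolute and percent contributions), draw matrices
#'   `contributions` and `pct`, and vectors `total`, `var_lambda`.
#' @export
tltre_decompose <- function(fit, group, n_draws = 400L) {
  if (is.character(group)) group <- match(group, imm_groups())
  if (is.na(group) || group > 3L) {
    stop("tLTRE is computed for focal groups only")
  }
  idx <- draw_index(fit, n_draws)
  nd <- nrow(idx)
  first <- tltre_core(theta_series(fit_rates(fit, idx[1, 1], idx[1, 2]),
                                   fit_states(fit, idx[1, 1], idx[1, 2]), group))
  K <- length(first$contributions)
  contr <- matrix(NA_real_, nd, K, dimnames = list(NULL, names(first$contributions)))
  pct <- contr
  total <- numeric(nd); vlam <- numeric(nd)
  for (k in seq_len(nd)) {
    res <- tltre_core(theta_series(fit_rates(fit, idx[k, 1], idx[k, 2]),
                                   fit_states(fit, idx[k, 1], idx[k, 2]), group))
    contr[k, ] <- res$contributions
    pct[k, ] <- res$pct
    total[k] <- res$total
    vlam[k] <- res$var_lambda
  }
  qs <- function(m) t(apply(m, 2, stats::quantile, probs = c(0.5, 0.05, 0.95)))
  sa <- qs(contr); sp <- qs(pct)
  summary <- data.frame(parameter = colnames(contr),
                        contribution = sa[, 1], lower90 = sa[, 2], upper90 = sa[, 3],
                        pct = sp[, 1], pct_lower90 = sp[, 2], pct_upper90 = sp[, 3])
  rownames(summary) <- NULL
  structure(list(group = imm_groups()[group], summary = summary,
                 contributions = contr, pct = pct, total = total,
                 var_lambda = vlam), class = "imm_ltre")
}

#' Per-year contributions to changes in growth rate
#'
#' First-order attribution of year-to-year changes in the realised growth
#' rate: the contribution of parameter `k` to `delta lambda_t` is
#' `(theta_{k,t+1} - theta_{k,t})` times the sensitivity evaluated at the
#' midpoint. Years where `|delta lambda| > 0.1` are flagged and the dominant
#' driver (largest absolute contribution) reported.
#'
#' @param fit An `imm_fit` with saved states.
#' @param group Focal group index (1..3) or code.
#' @param n_draws Posterior draws used.
#' @return An `imm_dlambda` object: list with `table` (per year-pair:
#'   median `delta_lambda`, flag, dominant driver) and the median per-year
#'   contribution matrix `contributions`.
#' @export
delta_lambda_contributions <- function(fit, group, n_draws = 400L) {
  if (is.character(group)) group <- match(group, imm_groups())
  if (is.na(group) || group > 3L) stop("available for focal groups only")
  if (fit$n_years < 4L) stop("need at least three modelled intervals")
  idx <- draw_index(fit, n_draws)
  nd <- nrow(idx)
  th0 <- theta_series(fit_rates(fit, idx[1, 1], idx[1, 2]),
                      fit_states(fit, idx[1, 1], idx[1, 2]), group)
  ny <- nrow(th0) - 1L
  K <- ncol(th0)
  contr <- array(NA_real_, c(nd, ny, K))
  dlam <- matrix(NA_real_, nd, ny)
  for (k in seq_len(nd)) {
    th <- theta_series(fit_rates(fit, idx[k, 1], idx[k, 2]),
                       fit_states(fit, idx[k, 1], idx[k, 2]), group)
    lam <- lambda_from_theta(th)
    dlam[k, ] <- diff(lam)
    for (t in seq_len(ny)) {
      mid <- (th[t, ] + th[t + 1L, ]) / 2
      s <- lambda_sensitivity(mid)
      contr[k, t, ] <- (th[t + 1L, ] - th[t, ]) * s
    }
  }
  med <- apply(contr, c(2, 3), stats::median)
  colnames(med) <- colnames(th0)
  dl <- apply(dlam, 2, stats::median)
  dom <- colnames(med)[apply(abs(med), 1, which.max)]
  tab <- data.frame(interval = seq_len(ny) + 1L, delta_lambda = dl,
                    large_change = abs(dl) > 0.1, dominant = dom)
  structure(list(group = imm_groups()[group], table = tab,
                 contributions = med, dlam_draws = dlam),
            class = "imm_dlambda")
}

#' Dominant-driver fractions
#'
#' Fraction of years in which each demographic parameter has the largest
#' absolute contribution; exact ties split equally.
#'
#' @param contributions Years-by-parameters matrix of contributions.
#' @return data.frame with per-driver percentages summing to 100.
#' @export
dominant_driver_summary <- function(contributions) {
  if (is.null(dim(contributions)) || nrow(contributions) == 0L) {
    stop("need a non-empty contribution matrix")
  }
  K <- ncol(contributions)
  share <- numeric(K)
  for (t in seq_len(nrow(contributions))) {
    a <- abs(contributions[t, ])
    win <- which(a == max(a))
    share[win] <- share[win] + 1 / length(win)
  }
  data.frame(driver = colnames(contributions) %||% paste0("theta", seq_len(K)),
             pct_years = 100 * share / nrow(contributions))
}

#' Net immigration rates and source-sink classification
#'
#' For each ordered group pair, the annual net adult immigration rate is
#' `(expected adult immigrants s to i at t+1 - expected adult emigrants i to
#' s at t+1) / A_{i,t}`, averaged over years; the overall rate per group is
#' the sum over sources. Immigration is computed for adults only so focal
#' groups and Elsewhere are comparable. Groups whose 90% interval lies above
#' (below) zero are classified sinks receiving net immigration (sources with
#' net emigration).
#'
#' @param fit An `imm_fit` with saved states.
#' @param n_draws Posterior draws used.
#' @return An `imm_sourcesink` object: list with `pairwise` (data.frame of
#'   median/CRI per ordered pair), `overall` (per group with
#'   classification), and the per-draw matrices.
#' @export
net_immigration <- function(fit, n_draws = 400L) {
  idx <- draw_index(fit, n_draws)
  nd <- nrow(idx)
  G <- 4L
  pair <- array(NA_real_, c(nd, G, G))
  for (k in seq_len(nd)) {
    rates <- fit_rates(fit, idx[k, 1], idx[k, 2])
    st <- fit_states(fit, idx[k, 1], idx[k, 2])
    ts <- seq_len(fit$n_years - 1L)
    for (i in seq_len(G)) {
      Ai <- st$A[i, ts]
      if (any(Ai == 0)) {
        warning("zero adult abundance; skipping affected years")
      }
      keep <- Ai > 0
      for (s in seq_len(G)) {
        if (s == i) next
        inn <- rates$phiA[s, ts] * rates$psiA[s, i, ts] * st$A[s, ts]
        out <- rates$phiA[i, ts] * rates$psiA[i, s, ts] * Ai
        pair[k, s, i] <- mean(((inn - out) / Ai)[keep])
      }
    }
  }
  overall <- apply(pair, c(1, 3), sum, na.rm = TRUE)
  qs <- function(x) stats::quantile(x, c(0.5, 0.05, 0.95), names = FALSE)
  pw <- do.call(rbind, lapply(seq_len(G), function(s) {
    do.call(rbind, lapply(seq_len(G), function(i) {
      if (s == i) return(NULL)
      q <- qs(pair[, s, i])
      data.frame(from = imm_groups()[s], to = imm_groups()[i],
                 inet = q[1], lower90 = q[2], upper90 = q[3])
    }))
  }))
  ov <- do.call(rbind, lapply(seq_len(G), function(i) {
    q <- qs(overall[, i])
    cls <- if (q[2] > 0) "sink (net immigration)" else
      if (q[3] < 0) "source (net emigration)" else "neutral"
    data.frame(group = imm_groups()[i], inet = q[1], lower90 = q[2],
               upper90 = q[3], class = cls)
  }))
  rownames(pw) <- rownames(ov) <- NULL
  structure(list(pairwise = pw, overall = ov, pair_draws = pair,
                 overall_draws = overall), class = "imm_sourcesink")
}

#' Deterministic projection of the metapopulation under a movement scenario
#'
#' Iterates the expected stage dynamics of all four groups jointly from an
#' initial state with year-specific rates, switching immigration (inflow
#' terms) and emigration (outflow losses) on or off. With both movement
#' terms on, the projection is exactly the iterated process expectation.
#'
#' @param rates An `imm_rates` object.
#' @param init_J,init_A Length-4 initial juvenile and adult abundances.
#' @param scenario One of `"both"`, `"emigration_only"`,
#'   `"immigration_only"`, `"no_movement"`.
#' @return List with matrices `J`, `A`, `Ntot` (G x T) and `lambda`
#'   (G x T-1).
#' @export
project_core <- function(rates, init_J, init_A,
                         scenario = c("both", "emigration_only",
                                      "immigration_only", "no_movement")) {
  scenario <- match.arg(scenario)
  emig <- scenario %in% c("both", "emigration_only")
  immig <- scenario %in% c("both", "immigration_only")
  G <- 4L
  T_ <- rates$n_years
  J <- A <- matrix(0, G, T_)
  J[, 1] <- init_J; A[, 1] <- init_A
  for (t in seq_len(T_ - 1L)) {
    outJ <- if (emig) rowSums(rates$psiJ[, , t]) else 0
    outA <- if (emig) rowSums(rates$psiA[, , t]) else 0
    ret <- rates$phiJ[, t] * (1 - outJ) * J[, t] +
      rates$phiA[, t] * (1 - outA) * A[, t]
    inflow <- if (immig) {
      colSums(rates$psiJ[, , t] * (rates$phiJ[, t] * J[, t])) +
        colSums(rates$psiA[, , t] * (rates$phiA[, t] * A[, t]))
    } else 0
    A[, t + 1L] <- ret + inflow
    J[, t + 1L] <- A[, t + 1L] * rates$gamma[, t + 1L]
  }
  Ntot <- J + A
  list(J = J, A = A, Ntot = Ntot,
       lambda = Ntot[, -1, drop = FALSE] / Ntot[, -T_, drop = FALSE])
}

#' Movement-scenario projections over posterior draws
#'
#' For each posterior draw, projects the metapopulation deterministically
#' from the estimated first-winter state under a movement scenario, and
#' summarises the among-year geometric-mean growth rate and the Pearson
#' correlation between projected and estimated totals per focal group.
#'
#' @param fit An `imm_fit` with saved states.
#' @param scenario Scenario name (see [project_core()]).
#' @param n_draws Posterior draws used.
#' @return An `imm_projection` object: list with `summary` (per group:
#'   median and 90% CRI of the geometric-mean growth, median correlation,
#'   `Pr(r > 0)`), and per-draw matrices `growth`, `correlation`.
#' @export
project_scenarios <- function(fit, scenario = "both", n_draws = 400L) {
  scenario <- match.arg(scenario, c("both", "emigration_only",
                                    "immigration_only", "no_movement"))
  idx <- draw_index(fit, n_draws)
  nd <- nrow(idx)
  G <- 4L
  growth <- matrix(NA_real_, nd, G)
  corr <- matrix(NA_real_, nd, G)
  for (k in seq_len(nd)) {
    rates <- fit_rates(fit, idx[k, 1], idx[k, 2])
    st <- fit_states(fit, idx[k, 1], idx[k, 2])
    pr <- project_core(rates, st$J[, 1], st$A[, 1], scenario)
    for (i in seq_len(G)) {
      growth[k, i] <- exp(mean(log(pr$lambda[i, ])))
      corr[k, i] <- suppressWarnings(stats::cor(pr$Ntot[i, ], st$Ntot[i, ]))
    }
  }
  qs <- function(x) stats::quantile(x, c(0.5, 0.05, 0.95), names = FALSE)
  summary <- do.call(rbind, lapply(seq_len(G), function(i) {
    q <- qs(growth[, i])
    data.frame(group = imm_groups()[i], growth = q[1], lower90 = q[2],
               upper90 = q[3],
               r = stats::median(corr[, i], na.rm = TRUE),
               pr_r_pos = mean(corr[, i] > 0, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  structure(list(scenario = scenario, summary = summary, growth = growth,
                 correlation = corr), class = "imm_projection")
}
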