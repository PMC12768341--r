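# Population simulation: cell-to-cell variability and the stability retry rule.
#
# Normal biological variability is emulated by multiplying every kinetic rate
# parameter and every initial concentration by an independent truncated-normal
# factor (mean 1, sd `variation`, truncated at 2 sd).  The same factors are
# used for a member's basal steady state and for any drug simulation run on
# that member.

# truncated-normal multiplicative factors, mean 1
.ox_rfactors <- function(n, variation, trunc_sd = 2) {
  if (variation == 0) return(rep(1, n))
  z <- stats::rnorm(n)
  bad <- abs(z) > trunc_sd
  while (any(bad)) {
    z[bad] <- stats::rnorm(sum(bad))
    bad <- abs(z) > trunc_sd
  }
  1 + variation * z
}

# kinetic constants subject to population variability (beyond the 8 x's)
.ox_varied_kin <- c("a_ANT", "a_PiC", "a_Kuni", "a_KHE",
                    "rho_nadh", "rho_qh2", "k_clear_m", "k_diff", "k_clear_c")

# draw a perturbed (params, init) pair
.ox_perturb <- function(params, init, variation) {
  fx <- .ox_rfactors(length(params$x), variation)
  params$x <- params$x * fx
  fk <- .ox_rfactors(length(.ox_varied_kin), variation)
  for (i in seq_along(.ox_varied_kin))
    params$kin[[.ox_varied_kin[i]]] <- params$kin[[.ox_varied_kin[i]]] * fk[i]
  fi <- .ox_rfactors(length(init), variation)
  init <- init * fi
  list(params = params, init = init)
}

# 4th-decimal nudge: add one unit in the 4th significant decimal place,
# e.g. 0.009 -> 0.009001
.ox_nudge <- function(p) p + 10^(floor(log10(abs(p))) - 3)

#' Run a population of simulations with parameter variability
#'
#' Simulates `n` population members, each with every rate parameter and
#' initial concentration independently scaled by a truncated-normal factor
#' (mean 1, sd `variation`).  If three or more members of the population are
#' numerically unstable, the impairment-adjusted parameter named in
#' `nudge_param` is varied in its 4th significant decimal (e.g. 0.009 to
#' 0.009001) and the whole population is rerun, until stability is maintained
#' or the retry budget is exhausted.
#'
#' @param params Center [ox_params()] parameter set.
#' @param protocol [drug_protocol()] applied to every member (default: none,
#'   i.e. basal steady states only).
#' @param n Number of members (>= 1).
#' @param variation Fractional sd of the variability factors, in \[0, 0.5\].
#' @param seed Integer seed; the population is fully reproducible given it.
#' @param duration,dt Passed to [ox_simulate()] when a protocol is given.
#' @param nudge_param Optional name of the impairment-adjusted parameter to
#'   nudge under the stability retry rule.
#' @param max_retries Retry budget for the nudge rule.
#' @return A list with `members` (per-member list with `params`, `init`,
#'   `steady`, and `trajectory` when a protocol was given), `unstable`
#'   (indices of unstable members), `nudged` (number of nudges applied) and
#'   `params` (possibly nudged center parameters).
#' @export
ox_population <- function(params, protocol = NULL, n = 50, variation = 0.2,
                          seed = 1, duration = 4800, dt = 30,
                          nudge_param = NULL, max_retries = 20) {
  stopifnot(n >= 1, variation >= 0, variation <= 0.5)
  base_init <- ox_pc_state(params)
  for (attempt in 0:max_retries) {
    set.seed(seed)
    members <- vector("list", n)
    unstable <- integer()
    for (i in seq_len(n)) {
      pert <- .ox_perturb(params, base_init, variation)
      ss <- tryCatch(ox_steady_state(pert$params, pert$init),
                     error = function(e) list(status = "numerically-unstable"))
      memb <- list(params = pert$params, init = pert$init, steady = ss)
      if (ss$status != "ok") {
        unstable <- c(unstable, i)
      } else if (!is.null(protocol)) {
        tr <- ox_simulate(pert$params, protocol, duration = duration,
                          init = ss$state, dt = dt)
        memb$trajectory <- tr
        if (tr$status != "ok") unstable <- c(unstable, i)
      }
      members[[i]] <- memb
    }
    if (length(unstable) < 3 || is.null(nudge_param))
      return(list(members = members, unstable = unstable,
                  nudged = attempt, params = params))
    params$x[[nudge_param]] <- .ox_nudge(params$x[[nudge_param]])
  }
  stop("population numerically unstable after ", max_retries,
       " retries; unstable members: ", paste(unstable, collapse = ", "))
}

#' Run a population of full trajectories
#'
#' Convenience wrapper around [ox_population()] returning just the member
#' trajectories for a protocol (empty protocol: constant trajectories from
#' each member's steady state).
#'
#' @inheritParams ox_population
#' @return List of `ox_trajectory` objects.
#' @export
population_trajectories <- function(params, protocol = drug_protocol(), n = 50,
                                    variation = 0.2, seed = 1,
                                    duration = 4800, dt = 30,
                                    nudge_param = NULL) {
  pop <- ox_population(params, protocol = protocol, n = n,
                       variation = variation, seed = seed,
                       duration = duration, dt = dt,
                       nudge_param = nudge_param)
  lapply(pop$members, function(m) {
    if (!is.null(m$trajectory)) m$trajectory
    else structure(list(times = numeric(), state = NULL, fluxes = NULL,
                        status = m$steady$status, params_final = m$params),
                   class = "ox_trajectory")
  })
}
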