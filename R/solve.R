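# Integration and steady-state solvers.

.ox_rtol <- 1e-8
.ox_atol <- 1e-12
.ox_ss_tol <- 1e-8
.ox_ss_tmax <- 1e4

# normalized residual: |dy/dt| scaled by the state magnitude (with a floor of
# 1% of the typical PC magnitude so near-zero pools do not dominate)
.ox_resid <- function(state, params) {
  d <- ox_derivatives(state, params)
  typ <- ox_pc_state(params)
  denom <- pmax(abs(state), 0.01 * abs(typ))
  max(abs(d) / denom)
}

# damped Newton iteration on the reduced non-clamped states, in variables
# scaled by the typical PC magnitudes.  The five conserved pairs (NADH/NAD,
# QH2/Q, cytc red/ox, matrix and cytosolic adenine pools) make the full
# Jacobian singular, so one member of each pair is eliminated via its pool
# total (taken from the input state).
.ox_newton <- function(state, params, tol = .ox_ss_tol, max_iter = 40) {
  nm <- ox_state_names()
  pairs <- list(c("nadh_m", "nad_m"), c("qh2", "q"), c("cred", "cox"),
                c("atp_m", "adp_m"), c("atp_c", "adp_c"))
  totals <- vapply(pairs, function(pr) state[[pr[1]]] + state[[pr[2]]], 0)
  # total exchangeable phosphate (volume-weighted) is also conserved:
  # W_m (atp_m + pi_m) + V_c (atp_c + pi_c)
  W_m <- params$consts$W_m
  V_c <- params$consts$V_c
  p_tot <- W_m * (state[["atp_m"]] + state[["pi_m"]]) +
    V_c * (state[["atp_c"]] + state[["pi_c"]])
  dep <- c(match(vapply(pairs, `[`, "", 2), nm), match("pi_c", nm))
  free <- setdiff(seq_along(state), c(.ox_clamped(), dep))
  typ <- pmax(abs(ox_pc_state(params)), 1e-12)
  y <- state
  z <- y / typ
  fullstate <- function(z) {
    yy <- z * typ
    names(yy) <- nm
    for (k in seq_along(pairs))
      yy[[pairs[[k]][2]]] <- totals[k] - yy[[pairs[[k]][1]]]
    yy[["pi_c"]] <- (p_tot - W_m * (yy[["atp_m"]] + yy[["pi_m"]]) -
                       V_c * yy[["atp_c"]]) / V_c
    yy
  }
  fscaled <- function(z) ox_derivatives(fullstate(z), params) / typ
  rnorm_of <- function(z, f) max(abs(f[free]) / pmax(abs(z[free]), 0.01))
  f <- fscaled(z)
  for (iter in seq_len(max_iter)) {
    r <- rnorm_of(z, f)
    if (r < tol)
      return(list(state = fullstate(z), ok = TRUE, resid = r))
    Jm <- matrix(0, length(free), length(free))
    for (j in seq_along(free)) {
      h <- 1e-6 * max(abs(z[free[j]]), 0.01)
      zp <- z; zp[free[j]] <- zp[free[j]] + h
      zm <- z; zm[free[j]] <- zm[free[j]] - h
      Jm[, j] <- (fscaled(zp)[free] - fscaled(zm)[free]) / (2 * h)
    }
    step <- tryCatch(solve(Jm, -f[free]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(state = fullstate(z), ok = FALSE, resid = r))
    alpha <- 1
    improved <- FALSE
    f_norm <- sum(f[free]^2)
    for (ls in 1:15) {
      zc <- z
      zc[free] <- z[free] + alpha * step
      yc <- fullstate(zc)
      # positivity: concentrations (incl. eliminated pool partners) must stay
      # positive; dpsi is unconstrained
      if (all(yc[-1] > 0) && all(is.finite(yc))) {
        fc <- tryCatch(fscaled(zc), error = function(e) NULL)
        if (!is.null(fc) && all(is.finite(fc))) {
          fc_norm <- sum(fc[free]^2)
          if (fc_norm < f_norm * (1 - 1e-4 * alpha) || fc_norm < (tol * 0.01)^2) {
            z <- zc; f <- fc; improved <- TRUE
            break
          }
        }
      }
      alpha <- alpha / 2
    }
    if (!improved) {
      r <- rnorm_of(z, f)
      return(list(state = fullstate(z), ok = r < tol, resid = r))
    }
  }
  r <- rnorm_of(z, f)
  list(state = fullstate(z), ok = r < tol, resid = r)
}

# one integration segment with the compiled model (stiff BDF via vode, with
# an lsoda retry); returns the deSolve matrix or NULL on failure
.ox_lsoda <- function(init, times, params) {
  pv <- .ox_parvec(params)
  y0 <- unname(init[ox_state_names()])
  run <- function(solver) tryCatch(suppressWarnings(
    solver(y = y0, times = times, func = "ox_derivs", parms = pv,
           dllname = "oxphosim", initfunc = "ox_init",
           nout = 18, rtol = .ox_rtol, atol = .ox_atol, maxsteps = 200000)
  ), error = function(e) NULL)
  good <- function(out) !is.null(out) && attr(out, "istate")[1] > 0 &&
    all(is.finite(out))
  out <- run(deSolve::vode)
  if (!good(out)) out <- run(deSolve::lsoda)
  if (!good(out)) return(NULL)
  out
}

#' Run the model to its basal steady state
#'
#' Finds the steady state of the model for a given parameter set: a damped
#' Newton iteration (finite-difference Jacobian on the 19 non-clamped states)
#' polishes the solution after an initial relaxation integration, so the
#' returned state satisfies a maximum normalized derivative below `tol`.
#' Integration is capped at `tmax` model-seconds.
#'
#' @param params An [ox_params()] object.
#' @param init Initial state (default: the designed physiological state).
#' @param tol Steady-state tolerance on max |d(state)/dt| / |state| (1/s).
#' @param tmax Maximum integration time in model-seconds before giving up.
#' @return A list with elements `state` (named state vector), `status`
#'   (`"ok"` or `"numerically-unstable"`), `resid` (the achieved normalized
#'   residual) and `fluxes` (fluxes at the returned state).
#' @export
ox_steady_state <- function(params, init = ox_pc_state(params),
                            tol = .ox_ss_tol, tmax = .ox_ss_tmax) {
  init <- init[ox_state_names()]
  if (any(!is.finite(init)) || any(init[-1] <= 0))
    stop("initial state must be finite with positive concentrations")
  y <- init
  status <- "numerically-unstable"
  resid <- .ox_resid(init, params)
  if (resid < tol) {
    # already a steady state (within tolerance): fixed point, return as-is
    status <- "ok"
  } else {
    # relax by integration into the physiological basin, then polish with
    # Newton; keep integrating in growing chunks if the polish has not yet
    # converged
    t_done <- 0
    chunk <- 1000
    y_int <- init
    while (t_done < tmax) {
      seg <- .ox_lsoda(y_int, c(0, chunk), params)
      if (is.null(seg)) break
      y_int <- seg[nrow(seg), 1 + seq_len(22)]
      names(y_int) <- ox_state_names()
      t_done <- t_done + chunk
      chunk <- min(2 * chunk, max(tmax - t_done, 0))
      ns <- .ox_newton(y_int, params, tol)
      if (ns$ok && all(ns$state[-1] > 0)) {
        y <- ns$state; status <- "ok"; resid <- ns$resid
        break
      }
      resid <- ns$resid
      if (chunk <= 0) break
    }
  }
  fl <- if (status == "ok") ox_fluxes(y, params) else
    rep(NA_real_, length(ox_flux_names()))
  if (status == "ok" && any(y[-1] < 0)) status <- "numerically-unstable"
  list(state = y, status = status, resid = resid,
       fluxes = stats::setNames(fl, ox_flux_names()))
}

#' Simulate the model under a drug protocol
#'
#' Integrates the model with the stiff solver (lsoda, rtol 1e-8, atol 1e-10),
#' applying each protocol event at its scheduled time by modifying the target
#' parameter and continuing the integration from the current state (state is
#' continuous across events).
#'
#' @param params An [ox_params()] object.
#' @param protocol A [drug_protocol()] (possibly empty).
#' @param duration Total simulated time, s.
#' @param init Initial state; defaults to the basal steady state for `params`.
#' @param dt Output time step, s.
#' @return An object of class `ox_trajectory`: list with `times`, `state`
#'   (time x 22 matrix), `fluxes` (time x 18 matrix), `status` (`"ok"` or
#'   `"numerically-unstable"`), and `params_final` (parameters after all
#'   events).
#' @export
ox_simulate <- function(params, protocol = drug_protocol(), duration = 3600,
                        init = NULL, dt = 30) {
  stopifnot(inherits(params, "ox_params"))
  events <- if (length(protocol$events))
    protocol$events[order(vapply(protocol$events, `[[`, 0, "time"))] else list()
  ev_times <- vapply(events, `[[`, 0, "time")
  if (length(ev_times) && (any(ev_times < 0) || any(ev_times > duration)))
    stop("protocol events must fall within [0, duration]")
  if (is.null(init)) {
    ss <- ox_steady_state(params)
    if (ss$status != "ok")
      return(structure(list(times = numeric(), state = NULL, fluxes = NULL,
                            status = "numerically-unstable",
                            params_final = params),
                       class = "ox_trajectory"))
    init <- ss$state
  }
  breaks <- unique(c(0, ev_times, duration))
  p <- params
  y <- init[ox_state_names()]
  all_t <- c()
  all_s <- NULL
  all_f <- NULL
  status <- "ok"
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    # apply events scheduled at t0
    for (ev in events) {
      if (ev$time == t0) p <- apply_event(p, ev)
    }
    if (t1 > t0) {
      times <- unique(c(seq(t0, t1, by = dt), t1))
      seg <- .ox_lsoda(y, times, params = p)
      if (is.null(seg)) { status <- "numerically-unstable"; break }
      keep <- if (i == 1) seq_len(nrow(seg)) else -1
      all_t <- c(all_t, seg[keep, 1])
      all_s <- rbind(all_s, seg[keep, 1 + seq_len(22), drop = FALSE])
      all_f <- rbind(all_f, seg[keep, 23 + seq_len(18), drop = FALSE])
      y <- seg[nrow(seg), 1 + seq_len(22)]
      names(y) <- ox_state_names()
    }
  }
  if (!is.null(all_s)) colnames(all_s) <- ox_state_names()
  if (!is.null(all_f)) colnames(all_f) <- ox_flux_names()
  structure(list(times = all_t, state = all_s, fluxes = all_f,
                 status = status, params_final = p),
            class = "ox_trajectory")
}

#' @export
print.ox_trajectory <- function(x, ...) {
  cat("<ox_trajectory> ", length(x$times), " time points, status: ",
      x$status, "\n", sep = "")
  invisible(x)
}

#' Export a trajectory as a tidy data frame / CSV
#'
#' @param traj An `ox_trajectory`.
#' @param path Optional CSV path; if given the tidy table is also written.
#' @return Data frame with columns `time`, `variable`, `value` (states and
#'   fluxes stacked).
#' @export
ox_trajectory_tidy <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "ox_trajectory"))
  wide <- cbind(traj$state, traj$fluxes)
  df <- data.frame(
    time = rep(traj$times, times = ncol(wide)),
    variable = rep(colnames(wide), each = length(traj$times)),
    value = as.vector(wide),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
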