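# Surface-hopping molecular dynamics.  Nuclei follow velocity Verlet on the
# active adiabatic surface; electronic amplitudes are propagated with the
# time-dependent coupling v.k01 (exact two-level exponential over 50
# substeps per nuclear step); hops follow Tully's fewest-switches
# probability, with energy-conserving velocity rescaling along the NACV
# direction (frustrated hops leave velocities unchanged).  The Zhu-Nakamura
# branch attempts hops only at local minima of the adiabatic gap, with a
# transition probability built from the gap history alone and uniform
# velocity rescaling.  No decoherence correction is applied.

kinetic_energy <- function(vel, masses) {
  0.5 * sum(masses * rowSums(vel^2)) * dann_constants$kin
}

maxwell_velocities <- function(masses, T) {
  n <- length(masses)
  sd_v <- sqrt(dann_constants$kB * T * dann_constants$acc / masses)
  v <- matrix(rnorm(3 * n), n, 3) * sd_v
  # remove centre-of-mass drift
  v - matrix(colSums(v * masses) / sum(masses), n, 3, byrow = TRUE)
}

#' Sample thermal initial conditions with a Nose-Hoover thermostat
#'
#' Runs ground-state NVT dynamics from a basin minimum and returns
#' decorrelated position/velocity snapshots.  At `T = 0` the snapshots are
#' the minimum itself with zero velocities.
#'
#' @param model a potential model
#' @param geometry0 starting geometry near a ground-state minimum
#' @param T temperature (K)
#' @param n number of snapshots
#' @param seed RNG seed
#' @param dt timestep (fs)
#' @param decorrelation decorrelation interval between snapshots (fs)
#' @param burn_in equilibration time before the first snapshot (fs)
#' @param tau thermostat time constant (fs)
#' @return list of [geometry()] objects carrying velocities
#' @export
sample_initial_conditions <- function(model, geometry0, T = 300, n = 100,
                                      seed = 1, dt = 0.5, decorrelation = 30,
                                      burn_in = 300, tau = 25) {
  set.seed(seed)
  g <- geometry0
  masses <- g$masses
  natom <- length(g$z)
  if (T <= 0) {
    g$vel <- matrix(0, natom, 3)
    return(replicate(n, g, simplify = FALSE))
  }
  vel <- maxwell_velocities(masses, T)
  pos <- g$pos
  nf <- 3 * natom
  kbt <- dann_constants$kB * T
  Q <- nf * kbt * tau^2               # thermostat mass, kcal/mol * fs^2
  xi <- 0
  force_at <- function(p) {
    gg <- g; gg$pos <- p
    direct_forces(model, gg, states = 0L)[["0"]]
  }
  f <- force_at(pos)
  acc <- f * dann_constants$acc / masses
  n_burn <- ceiling(burn_in / dt)
  n_dec <- max(1L, round(decorrelation / dt))
  snaps <- vector("list", n)
  total <- n_burn + n * n_dec
  k <- 0L
  for (step in seq_len(total)) {
    vel <- vel + 0.5 * dt * (acc - xi * vel)
    pos <- pos + dt * vel
    ke <- kinetic_energy(vel, masses)
    xi <- xi + dt * (2 * ke - nf * kbt) / Q
    f <- force_at(pos)
    if (!all(is.finite(f))) stop("thermostat divergence: non-finite force")
    acc <- f * dann_constants$acc / masses
    vel <- (vel + 0.5 * dt * acc) / (1 + 0.5 * dt * xi)
    if (step > n_burn && (step - n_burn) %% n_dec == 0L) {
      k <- k + 1L
      gg <- g; gg$pos <- pos; gg$vel <- vel
      snaps[[k]] <- gg
    }
  }
  snaps[seq_len(k)]
}

#' Create a surface-hopping trajectory state
#'
#' @param geom a [geometry()] carrying velocities
#' @param model a potential model
#' @param active initial active surface (0 or 1)
#' @param deg_tol degeneracy tolerance for couplings (kcal/mol)
#' @return a `dann_traj_state`
#' @export
trajectory_state <- function(geom, model, active = 1L, deg_tol = 1e-6) {
  if (is.null(geom$vel)) stop("initial geometry must carry velocities")
  ev <- adiabatic_eval(model, geom, deg_tol = deg_tol)
  structure(list(t = 0, geom = geom, active = as.integer(active),
                 c = { cc <- complex(2); cc[active + 1L] <- 1 + 0i; cc },
                 eval = ev, prev_eval = NULL, vka = 0, gap_hist = ev$gap,
                 deg_tol = deg_tol),
            class = "dann_traj_state")
}

#' One velocity-Verlet step on the active surface
#'
#' Advances positions and velocities by `dt` using the active adiabatic
#' force, carrying eigenvector sign continuity into the new evaluation.
#' Hop logic is separate (see [fssh_hop()] / [zn_hop()]).
#'
#' @param state a `dann_traj_state`
#' @param model a potential model
#' @param dt timestep (fs)
#' @return the advanced state
#' @export
verlet_step <- function(state, model, dt) {
  if (dt <= 0) stop("dt must be positive")
  g <- state$geom
  masses <- g$masses
  ev <- state$eval
  f <- ev$forces[[state$active + 1L]]
  if (!all(is.finite(f))) stop("non-finite force")
  acc <- f * dann_constants$acc / masses
  # coupling at step start (for the electronic propagation)
  state$vka <- if (!is.null(ev$k01_defined) && ev$k01_defined)
    sum(g$vel * ev$k01) else 0
  g$vel <- g$vel + 0.5 * dt * acc
  g$pos <- g$pos + dt * g$vel
  ev2 <- adiabatic_eval(model, g, prev_u = ev$u, deg_tol = state$deg_tol)
  f2 <- ev2$forces[[state$active + 1L]]
  if (!all(is.finite(f2))) stop("non-finite force")
  g$vel <- g$vel + 0.5 * dt * f2 * dann_constants$acc / masses
  state$geom <- g
  state$prev_eval <- ev
  state$eval <- ev2
  state$t <- state$t + dt
  state$gap_hist <- c(tail(state$gap_hist, 2), ev2$gap)
  state
}

.hop_event <- function(state, to, accepted, core) {
  cnnc <- if (!is.null(core)) rad2deg(dihedral_cpp(state$geom$pos, core)) else NA_real_
  structure(list(time = state$t, geometry = state$geom,
                 from_state = state$active, to_state = to,
                 cnnc_at_hop = cnnc, accepted = accepted),
            class = "dann_hop")
}

# energy-conserving rescale along `dir` (N x 3); NULL dir = uniform scaling.
# Returns updated velocities or NULL if frustrated.
.rescale_velocities <- function(vel, masses, dE, dir = NULL) {
  if (is.null(dir)) {
    ke <- kinetic_energy(vel, masses)
    if (ke <= dE) return(NULL)
    return(vel * sqrt(1 - dE / ke))
  }
  A <- 0.5 * sum(rowSums(dir^2) / masses) * dann_constants$kin
  B <- sum(vel * dir) * dann_constants$kin
  disc <- B^2 - 4 * A * dE
  if (!is.finite(disc) || disc < 0) return(NULL)
  roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
  gam <- roots[which.min(abs(roots))]
  vel + gam * dir / masses
}

#' Fewest-switches hop attempt after a Verlet step
#'
#' Propagates the two electronic amplitudes across the step just taken
#' (linear interpolation of energies and coupling, exact two-level
#' exponential substeps), accumulates Tully's switching probability, and
#' attempts a stochastic hop.  Accepted hops rescale velocities along the
#' NACV direction to conserve total energy; hops that cannot be paid for
#' kinetically are recorded as frustrated and leave velocities unchanged.
#'
#' @param state a `dann_traj_state` advanced by [verlet_step()]
#' @param model a potential model
#' @param dt the timestep just taken (fs)
#' @param nsub electronic substeps per nuclear step
#' @param core optional CNNC indices for hop-geometry bookkeeping
#' @return list with `state` and `hop` (a `dann_hop` or `NULL`)
#' @export
fssh_hop <- function(state, model, dt, nsub = 50L, core = NULL) {
  if (is.null(state$prev_eval)) stop("call verlet_step before fssh_hop")
  ev1 <- state$prev_eval; ev2 <- state$eval
  vkb <- if (ev2$k01_defined) sum(state$geom$vel * ev2$k01) else 0
  pr <- propagate_tdse_cpp(state$c, ev1$energies[1], ev2$energies[1],
                           ev1$energies[2], ev2$energies[2],
                           state$vka, vkb, dt, as.integer(nsub), state$active)
  state$c <- as.complex(pr$c)
  g_hop <- min(max(pr$g_hop, 0), 1)
  hop <- NULL
  if (g_hop > 0 && runif(1) < g_hop) {
    to <- 1L - state$active
    dE <- ev2$energies[to + 1L] - ev2$energies[state$active + 1L]
    dir <- if (ev2$k01_defined && sum(ev2$k01^2) > 0) {
      k <- ev2$k01; k / sqrt(sum(k^2))
    } else NULL                         # uniform rescale at near-degeneracy
    newv <- .rescale_velocities(state$geom$vel, state$geom$masses, dE, dir)
    if (is.null(newv)) {
      hop <- .hop_event(state, to, FALSE, core)
    } else {
      state$geom$vel <- newv
      hop <- .hop_event(state, to, TRUE, core)
      state$active <- to
      # forces on the new surface for the next step
      state$eval <- adiabatic_eval(model, state$geom, prev_u = ev2$u,
                                   deg_tol = state$deg_tol)
    }
  }
  list(state = state, hop = hop)
}

#' Zhu-Nakamura hop attempt at a local gap minimum
#'
#' Uses only the adiabatic gap along the trajectory: when the last three
#' steps bracket a local minimum of the S0/S1 gap, a Landau-Zener-type
#' transition probability `exp(-(pi/2 hbar) sqrt(dE^3 / (d2 dE/dt2)))` is
#' evaluated from the gap and its discrete second time-derivative at the
#' minimum.  Accepted hops rescale all velocities uniformly (no NACV is
#' available to this scheme).
#'
#' @inheritParams fssh_hop
#' @return list with `state` and `hop`
#' @export
zn_hop <- function(state, model, dt, core = NULL) {
  h <- state$gap_hist
  hop <- NULL
  if (length(h) == 3 && h[2] < h[1] && h[2] < h[3]) {
    curv <- (h[3] - 2 * h[2] + h[1]) / dt^2
    if (curv > 1e-12) {
      p <- exp(-(pi / (2 * dann_constants$hbar)) * sqrt(max(h[2], 0)^3 / curv))
      if (runif(1) < p) {
        to <- 1L - state$active
        ev2 <- state$eval
        dE <- ev2$energies[to + 1L] - ev2$energies[state$active + 1L]
        newv <- .rescale_velocities(state$geom$vel, state$geom$masses, dE, NULL)
        if (is.null(newv)) {
          hop <- .hop_event(state, to, FALSE, core)
        } else {
          state$geom$vel <- newv
          hop <- .hop_event(state, to, TRUE, core)
          state$active <- to
          state$eval <- adiabatic_eval(model, state$geom, prev_u = ev2$u,
                                       deg_tol = state$deg_tol)
        }
      }
    }
  }
  list(state = state, hop = hop)
}

#' Run one surface-hopping trajectory
#'
#' Vertically excites a thermal geometry to S1, propagates surface-hopping
#' dynamics until the horizon, and, after an accepted hop to S0, runs a
#' ground-state relaxation window before classifying the final isomer via
#' the CNNC dihedral (|CNNC| < 90 deg is cis).
#'
#' @param init a [geometry()] with velocities (thermal snapshot)
#' @param model a potential model
#' @param scheme "fs" (fewest switches) or "zn" (Zhu-Nakamura)
#' @param horizon propagation horizon (fs)
#' @param seed RNG seed for the hop draws
#' @param dt nuclear timestep (fs)
#' @param nsub electronic substeps per nuclear step
#' @param relax ground-state relaxation window after the hop (fs)
#' @param stride store every `stride`-th frame
#' @param core CNNC core indices; defaults to `model$core`
#' @param deg_tol degeneracy tolerance (kcal/mol)
#' @return a `dann_trajectory` with frames, hop events, final isomer,
#'   S1 residence time and flags
#' @export
run_trajectory <- function(init, model, scheme = c("fs", "zn"), horizon = 2000,
                           seed = 1, dt = 0.5, nsub = 50L, relax = 200,
                           stride = 10L, core = NULL, deg_tol = 1e-6) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (is.null(core)) core <- model$core
  initial_isomer <- if (!is.null(core)) .isomer_from_cnnc(init$pos, core)
                    else init$isomer
  state <- trajectory_state(init, model, active = 1L, deg_tol = deg_tol)
  frames <- list(.traj_frame(state))
  hops <- list()
  reached_ground <- FALSE
  s1_exit <- NA_real_
  aborted <- FALSE
  nstep <- ceiling(horizon / dt)
  for (step in seq_len(nstep)) {
    state <- tryCatch(verlet_step(state, model, dt), error = function(e) e)
    if (inherits(state, "error")) { aborted <- TRUE; break }
    res <- if (scheme == "fs") fssh_hop(state, model, dt, nsub, core)
           else zn_hop(state, model, dt, core)
    state <- res$state
    if (!is.null(res$hop)) {
      hops[[length(hops) + 1L]] <- res$hop
      if (res$hop$accepted && state$active == 0L) {
        reached_ground <- TRUE
        s1_exit <- state$t
      }
    }
    if (step %% stride == 0L) frames[[length(frames) + 1L]] <- .traj_frame(state)
    if (reached_ground) break
  }
  if (reached_ground && !aborted) {
    nrel <- ceiling(relax / dt)
    for (step in seq_len(nrel)) {
      state <- tryCatch(verlet_step(state, model, dt), error = function(e) e)
      if (inherits(state, "error")) { aborted <- TRUE; break }
      if (step %% stride == 0L) frames[[length(frames) + 1L]] <- .traj_frame(state)
    }
  }
  # trajectories that never reach S0 keep their initial isomer: the final
  # isomer is only defined after ground-state relaxation
  final_isomer <- if (!aborted && reached_ground && !is.null(core))
    .isomer_from_cnnc(state$geom$pos, core) else initial_isomer
  structure(list(frames = frames, hops = hops, final_isomer = final_isomer,
                 initial_isomer = initial_isomer,
                 reached_ground = reached_ground, s1_exit_time = s1_exit,
                 horizon = horizon, aborted = aborted,
                 final_state = if (inherits(state, "error")) NULL else state),
            class = "dann_trajectory")
}

.traj_frame <- function(state) {
  list(t = state$t, z = state$geom$z, pos = state$geom$pos,
       active = state$active, e0 = state$eval$energies[1],
       e1 = state$eval$energies[2])
}

#' @export
print.dann_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dann_trajectory: %d frames, %d hop attempts, %s -> %s, ground=%s, S1 exit=%s fs>\n",
    length(x$frames), length(x$hops), x$initial_isomer, x$final_isomer,
    x$reached_ground, format(x$s1_exit_time)))
  invisible(x)
}

#' Summarize a surface-hopping ensemble
#'
#' Computes the isomerization quantum yield (fraction of trajectories
#' ending in the other isomer), its bootstrap standard deviation, the
#' excited-state lifetime from a single-exponential fit to the S1 survival
#' curve (censored maximum likelihood), the fraction reaching the ground
#' state by the horizon, and planar/rotational pathway fractions over the
#' trajectories that hopped.
#'
#' @param results list of trajectory records: each needs `final_isomer`,
#'   `initial_isomer`, `reached_ground`, `s1_exit_time`, `horizon`,
#'   `aborted`, and optionally `hops`
#' @param n_boot bootstrap resamples for the yield standard deviation
#' @param seed RNG seed for the bootstrap
#' @param planar_threshold |CNNC| threshold (degrees) separating planar
#'   from rotational hops
#' @return an `EnsembleSummary` list
#' @export
summarize_ensemble <- function(results, n_boot = 1000, seed = 1,
                               planar_threshold = 150) {
  if (length(results) == 0) stop("no trajectories")
  ok <- !vapply(results, function(r) isTRUE(r$aborted), logical(1))
  if (!any(ok)) stop("all trajectories aborted")
  res <- results[ok]
  reactive <- vapply(res, function(r) r$final_isomer != r$initial_isomer,
                     logical(1))
  yield <- mean(reactive)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    mean(reactive[sample.int(length(reactive), replace = TRUE)]), numeric(1))
  yield_sd <- sqrt(mean((boots - mean(boots))^2))
  exits <- vapply(res, function(r)
    if (is.null(r$s1_exit_time)) NA_real_ else r$s1_exit_time, numeric(1))
  horizons <- vapply(res, function(r) r$horizon, numeric(1))
  n_event <- sum(!is.na(exits))
  lifetime <- if (n_event > 0)
    (sum(exits, na.rm = TRUE) + sum(horizons[is.na(exits)])) / n_event
  else NA_real_
  lifetime_se <- if (n_event > 0) lifetime / sqrt(n_event) else NA_real_
  # pathway fractions from the first accepted hop of each hopped trajectory
  pathways <- unlist(lapply(res, function(r) {
    if (is.null(r$hops)) return(NULL)
    acc <- Filter(function(h) isTRUE(h$accepted), r$hops)
    if (length(acc) == 0) return(NULL)
    classify_hop_pathway(acc[[1]], planar_threshold)
  }))
  frac_planar <- if (length(pathways)) mean(pathways == "planar") else NA_real_
  structure(list(n_traj = length(res), yield = yield, yield_sd = yield_sd,
                 lifetime_fs = lifetime, lifetime_se = lifetime_se,
                 frac_ground_by_horizon = mean(vapply(res, function(r)
                   isTRUE(r$reached_ground), logical(1))),
                 frac_planar = frac_planar,
                 frac_rotational = if (is.na(frac_planar)) NA_real_
                                   else 1 - frac_planar,
                 abort_frac = mean(!ok)),
            class = "dann_ensemble_summary")
}

#' @export
print.dann_ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "<ensemble: n=%d, yield=%.3f +/- %.3f, lifetime=%.1f fs, ground by horizon=%.2f>\n",
    x$n_traj, x$yield, x$yield_sd, x$lifetime_fs, x$frac_ground_by_horizon))
  invisible(x)
}
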