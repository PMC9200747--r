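# Trajectory and screening observables.

#' Signed CNNC dihedral angle
#'
#' Standard right-hand-rule dihedral of the four-atom C-N=N-C core, in
#' degrees in (-180, 180].  Invariant under rigid rotation/translation and
#' negated by reflection.
#'
#' @param geom a [geometry()] or an N x 3 position matrix
#' @param core integer vector of the four core atom indices
#' @return angle in degrees
#' @export
cnnc_dihedral <- function(geom, core) {
  pos <- if (inherits(geom, "dann_geometry")) geom$pos else as.matrix(geom)
  core <- as.integer(core)
  if (length(core) != 4 || anyDuplicated(core)) stop("core must be 4 distinct indices")
  for (trip in list(core[1:3], core[2:4])) {
    u <- pos[trip[1], ] - pos[trip[2], ]
    v <- pos[trip[3], ] - pos[trip[2], ]
    s2 <- sum(pracma_cross(u, v)^2) / (sum(u^2) * sum(v^2))
    if (s2 < 1e-12) stop("collinear atoms: dihedral undefined")
  }
  phi <- rad2deg(dihedral_cpp(pos, core))
  if (phi <= -180) phi <- phi + 360
  phi
}

#' Classify a hop as planar or rotational
#'
#' Hops with |CNNC| at or above the planar threshold happen at the planar
#' (non-reactive) intersection; the rest happen along the twisted
#' (reactive) seam.
#'
#' @param hop a `dann_hop` event (with `cnnc_at_hop` in degrees)
#' @param planar_threshold |CNNC| threshold in degrees (default 150)
#' @return "planar" or "rotational"
#' @export
classify_hop_pathway <- function(hop, planar_threshold = 150) {
  cnnc <- if (is.list(hop)) hop$cnnc_at_hop else hop
  if (is.na(cnnc)) stop("hop carries no CNNC angle")
  if (abs(cnnc) >= planar_threshold) "planar" else "rotational"
}

#' Thermally averaged S0 -> S1 gap
#'
#' Arithmetic mean of the predicted adiabatic gap over ground-state MD
#' snapshots, in eV.  Thermal averaging typically blueshifts the gap
#' relative to the single minimum geometry.
#'
#' @param model a potential model
#' @param snapshots list of [geometry()] snapshots
#' @return mean gap in eV
#' @export
thermal_mean_gap <- function(model, snapshots) {
  if (length(snapshots) == 0) stop("need at least one snapshot")
  gaps <- vapply(snapshots, function(g) {
    sol <- adiabatize(model_diabatic(model, g, gradient = FALSE)$d)
    sol$energies[2] - sol$energies[1]
  }, numeric(1))
  mean(gaps) / dann_constants$ev_to_kcal
}

#' Isomeric stability from thermal ensembles
#'
#' Median ground-state energy difference between the two isomers' thermal
#' ensembles, signed so that a negative value means the queried isomer is
#' the more stable one (E_trans - E_cis for trans, E_cis - E_trans for
#' cis).  The median suppresses outlier geometries.
#'
#' @param model a potential model
#' @param snapshots_cis,snapshots_trans ground-state MD snapshots
#' @param isomer which isomer the stability is quoted for
#' @return stability in eV
#' @export
isomer_stability <- function(model, snapshots_cis, snapshots_trans,
                             isomer = c("cis", "trans")) {
  isomer <- match.arg(isomer)
  if (length(snapshots_cis) == 0 || length(snapshots_trans) == 0)
    stop("both snapshot sets must be non-empty")
  e0 <- function(snaps) vapply(snaps, function(g)
    adiabatize(model_diabatic(model, g, gradient = FALSE)$d)$energies[1],
    numeric(1))
  med_c <- median(e0(snapshots_cis))
  med_t <- median(e0(snapshots_trans))
  diff_kcal <- if (isomer == "trans") med_t - med_c else med_c - med_t
  diff_kcal / dann_constants$ev_to_kcal
}

#' Screen a set of molecules for photoswitch observables
#'
#' For each molecule and isomer: thermally averaged gap, isomeric
#' stability, isomerization quantum yield with bootstrap standard
#' deviation, and the fraction of trajectories reaching the ground state
#' by the horizon.  Models wrapping the analytic oracle use the fast
#' compiled ensemble path; learned models use the generic engine.
#'
#' @param models named list of potential models, one per molecule (each
#'   with a `core` field); oracle-backed models may carry `spec`
#' @param n_traj trajectories per isomer
#' @param T temperature (K)
#' @param horizon NAMD horizon (fs)
#' @param n_snap thermal snapshots for gap/stability averages
#' @param seed base RNG seed
#' @param scheme hopping scheme
#' @param path optional CSV output path
#' @return data.frame of screening records (one row per molecule x isomer)
#' @export
screening_report <- function(models, n_traj = 200, T = 300, horizon = 2000,
                             n_snap = 60, seed = 1, scheme = c("fs", "zn"),
                             path = NULL) {
  scheme <- match.arg(scheme)
  rows <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    id <- names(models)[mi]
    if (is.null(id) || !nzchar(id)) id <- paste0("mol", mi)
    snaps <- list()
    mins <- list()
    for (iso in c("cis", "trans")) {
      mins[[iso]] <- if (!is.null(model$spec))
        oracle_min_geometry(model$spec, iso)
      else stop("screening needs basin geometries; provide oracle-backed models")
      snaps[[iso]] <- sample_initial_conditions(model, mins[[iso]], T = T,
                                                n = n_snap, seed = seed + mi)
    }
    for (iso in c("cis", "trans")) {
      yld <- .screen_yield(model, iso, n_traj, T, horizon, seed + 31 * mi, scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, isomer = iso,
        mean_gap_eV = thermal_mean_gap(model, snaps[[iso]]),
        stability_eV = isomer_stability(model, snaps$cis, snaps$trans, iso),
        yield = yld$yield, yield_sd = yld$sd,
        frac_ground = yld$frac_ground, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

.screen_yield <- function(model, isomer, n_traj, T, horizon, seed, scheme) {
  if (!is.null(model$spec) && inherits(model, "dann_oracle")) {
    bf <- brute_force_yield(model$spec, isomer, n_traj = n_traj, scheme = scheme,
                            seed = seed, T = T, horizon = horizon,
                            n_pool = min(500, n_traj))
    boots <- {
      set.seed(seed)
      r <- bf$reactive
      vapply(seq_len(200), function(i)
        mean(r[sample.int(length(r), replace = TRUE)]), numeric(1))
    }
    return(list(yield = bf$yield, sd = sd(boots), frac_ground = bf$frac_ground))
  }
  gmin <- oracle_min_geometry(model$spec, isomer)
  snaps <- sample_initial_conditions(model, gmin, T = T, n = n_traj, seed = seed)
  results <- lapply(seq_len(n_traj), function(k)
    run_trajectory(snaps[[k]], model, scheme = scheme, horizon = horizon,
                   seed = seed + k))
  s <- summarize_ensemble(results, n_boot = 200, seed = seed)
  list(yield = s$yield, sd = s$yield_sd, frac_ground = s$frac_ground_by_horizon)
}
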