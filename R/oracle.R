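# Analytic 3-state diabatic oracle: a stand-in reference method with exact
# labels.  The molecule is an azo-rotor (R-N=N-R with methyl-like caps): the
# three diagonal diabatic elements are trigonometric polynomials of the
# central CNNC torsion phi plus state-specific harmonic terms in the two
# CNN/NNC bends, the 0-1 coupling is an odd-harmonic cosine of phi that
# vanishes at the 90-degree crossing, and every remaining coordinate is held
# by a harmonic bath shared by all diagonals (so it never affects gaps).
# With the default parameters d22 is the cis ground diabat, d00 the trans
# ground diabat and d11 the trans excited diabat; d00 and d11 cross at
# phi = 90 deg where the coupling vanishes, giving a true rotational conical
# intersection whose seam is a curve in (phi, alpha1, alpha2): the gap
# vanishes only where both the crossing and the bend-balance conditions
# hold (codimension 2).  A smooth polynomial dip in d11 near phi = 180 deg
# produces a removable planar near-degeneracy on the trans side.

#' Construct an oracle specification
#'
#' Returns the full parameter set of the analytic diabatic rotor: the
#' molecular template (an azomethane-like CH3-N=N-CH3 rotor), torsional
#' profiles of the diagonal diabats, bend stiffness and centers, coupling
#' profile, planar-dip parameters and the harmonic bath.  All energies are
#' kcal/mol, angles degrees at this interface.
#'
#' @param g01 amplitude of the 0-1 diabatic coupling `g01 * cos(phi)`
#'   (kcal/mol)
#' @param dip_amp depth of the smooth planar dip in d11 near phi = 180 deg
#' @param bend_k harmonic bend stiffness (kcal/mol/rad^2), all states
#' @param bend_center_excited bend center of the excited diabat d11
#'   (degrees); the offset from the 120-degree ground-state center is what
#'   makes the intersection seam codimension 2
#' @param diag_cos optional 3 x 3 matrix of cosine coefficients for the
#'   diagonal profiles (rows d00, d11, d22; columns cos(0), cos(phi),
#'   cos(2 phi))
#' @return an object of class `dann_oracle_spec`
#' @export
oracle_spec <- function(g01 = 5, dip_amp = 20, bend_k = 80,
                        bend_center_excited = 130, diag_cos = NULL) {
  mol <- .build_rotor_template()
  if (is.null(diag_cos)) {
    diag_cos <- rbind(c(27.5, 27.5, 0),   # d00: trans ground diabat
                      c(42.5, 17.5, 15),  # d11: trans excited diabat
                      c(41.0, -29.0, 0))  # d22: cis ground diabat
  }
  spec <- list(
    z = mol$z, core = mol$core, masses = atomic_masses(mol$z),
    diag_cos = diag_cos,
    dip_amp = c(0, dip_amp, 0), dip_pow = 8L,
    bend_k = rep(bend_k, 3),
    bend_c = deg2rad(c(120, bend_center_excited, 120)),
    coup_cos = rbind(c(0, g01, 0), c(0, 0, 0), c(0, 0, 0)),
    bath = mol$bath,
    pos_trans = mol$pos_trans, pos_cis = mol$pos_cis
  )
  class(spec) <- "dann_oracle_spec"
  spec
}

#' @export
print.dann_oracle_spec <- function(x, ...) {
  cat(sprintf("<oracle spec: %d-atom azo rotor, g01=%.3g, dip=%.3g kcal/mol>\n",
              length(x$z), x$coup_cos[1, 2], x$dip_amp[2]))
  invisible(x)
}

# NeRF atom placement: position D given A-B-C, bond r(C-D), angle B-C-D,
# dihedral A-B-C-D (radians)
.place_nerf <- function(a, b, c, r, theta, phi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d_local <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  c + cbind(bc, m, n) %*% d_local
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Build the CH3-N=N-CH3 template in both basins plus the bath term lists.
.build_rotor_template <- function() {
  z <- c(6L, 7L, 7L, 6L, rep(1L, 6))
  core <- c(1L, 2L, 3L, 4L)
  d_nn <- 1.25; d_cn <- 1.47; d_ch <- 1.09
  a_cnn <- deg2rad(120); a_hcn <- deg2rad(109.47)
  build <- function(phi_deg) {
    pos <- matrix(0, 10, 3)
    pos[2, ] <- c(0, 0, 0)
    pos[3, ] <- c(d_nn, 0, 0)
    pos[1, ] <- c(d_cn * cos(a_cnn), d_cn * sin(a_cnn), 0)  # angle C1-N2-N3 = 120
    pos[4, ] <- .place_nerf(pos[1, ], pos[2, ], pos[3, ], d_cn, a_cnn,
                            deg2rad(phi_deg))
    for (j in 1:3)
      pos[4 + j, ] <- .place_nerf(pos[3, ], pos[2, ], pos[1, ], d_ch, a_hcn,
                                  deg2rad(c(60, 180, 300)[j]))
    for (j in 1:3)
      pos[7 + j, ] <- .place_nerf(pos[2, ], pos[3, ], pos[4, ], d_ch, a_hcn,
                                  deg2rad(c(60, 180, 300)[j]))
    pos
  }
  bond_idx <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(1, 6), c(1, 7),
                    c(4, 8), c(4, 9), c(4, 10))
  bond_r0 <- c(d_cn, d_nn, d_cn, rep(d_ch, 6))
  bond_k <- c(320, 500, 320, rep(340, 6))
  ang_idx <- rbind(c(5, 1, 2), c(6, 1, 2), c(7, 1, 2), c(5, 1, 6), c(5, 1, 7),
                   c(6, 1, 7),
                   c(8, 4, 3), c(9, 4, 3), c(10, 4, 3), c(8, 4, 9), c(8, 4, 10),
                   c(9, 4, 10))
  ang_t0 <- rep(a_hcn, 12)
  ang_k <- rep(40, 12)
  tor_idx <- rbind(c(5, 1, 2, 3), c(6, 1, 2, 3), c(7, 1, 2, 3),
                   c(8, 4, 3, 2), c(9, 4, 3, 2), c(10, 4, 3, 2))
  list(z = z, core = core,
       bath = list(bond_idx = bond_idx, bond_r0 = bond_r0, bond_k = bond_k,
                   ang_idx = ang_idx, ang_t0 = ang_t0, ang_k = ang_k,
                   tor_idx = tor_idx, tor_k = rep(0.2, 6), tor_n = rep(3L, 6),
                   tor_d = rep(0, 6)),
       pos_trans = build(180), pos_cis = build(0))
}

#' Evaluate the oracle diabatic Hamiltonian
#'
#' Exact diabatic matrix and analytic element gradients at a geometry; the
#' surface is infinitely differentiable away from undefined dihedrals
#' (collinear core atoms).
#'
#' @param spec an [oracle_spec()]
#' @param geom a [geometry()] with the oracle's atom ordering
#' @return list with `d` (3x3) and `grad` (3 x 3 x N x 3 array)
#' @export
oracle_hd <- function(spec, geom) {
  pos <- if (inherits(geom, "dann_geometry")) geom$pos else as.matrix(geom)
  .check_core_collinear(spec, pos)
  oracle_eval_cpp(unclass(spec), pos, gradient = TRUE)
}

.check_core_collinear <- function(spec, pos) {
  for (trip in list(spec$core[1:3], spec$core[2:4])) {
    u <- pos[trip[1], ] - pos[trip[2], ]
    v <- pos[trip[3], ] - pos[trip[2], ]
    s <- sqrt(sum(pracma_cross(u, v)^2)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    if (s < 1e-6) stop("collinear core atoms: dihedral undefined")
  }
  invisible(NULL)
}

#' Wrap an oracle spec as a potential model
#'
#' The oracle satisfies the same PotentialModel contract as the learned
#' backbones, so the full dynamics/analysis stack can run directly on the
#' exact surface.
#'
#' @param spec an [oracle_spec()]
#' @return a `dann_model`
#' @export
oracle_model <- function(spec) {
  structure(list(spec = spec, core = spec$core, counter = new_model_counter()),
            class = c("dann_oracle", "dann_model"))
}

#' @export
model_diabatic_impl.dann_oracle <- function(model, geom, gradient) {
  pos <- geom$pos
  .check_core_collinear(model$spec, pos)
  res <- oracle_eval_cpp(unclass(model$spec), pos, gradient = gradient)
  if (!gradient) res$grad <- NULL
  res
}

#' @export
model_grad_combo_impl.dann_oracle <- function(model, geom, w) {
  res <- oracle_eval_cpp(unclass(model$spec), geom$pos, gradient = TRUE)
  n <- nrow(geom$pos)
  G <- matrix(res$grad, nrow = 9)
  matrix(as.vector(w) %*% G, n, 3)
}

#' Exact labels from the oracle
#'
#' Routes the analytic diabatic matrix through the same adiabatization and
#' rotated-gradient code used for learned models, so oracle labels satisfy
#' every invariant of the diabatic head by construction.
#'
#' @param spec an [oracle_spec()]
#' @param geom a [geometry()]
#' @param provenance provenance tag for the resulting frame
#' @return a [labeled_frame()]
#' @export
oracle_labels <- function(spec, geom, provenance = "normal_mode") {
  hd <- oracle_hd(spec, geom)
  sol <- adiabatize(hd$d)
  der <- rotated_gradient(hd, sol)
  g2 <- geom
  g2$isomer <- .isomer_from_cnnc(geom$pos, spec$core)
  labeled_frame(g2, e0 = sol$energies[1], e1 = sol$energies[2],
                f0 = der$forces[[1]], f1 = der$forces[[2]],
                h01 = der$h[["01"]], provenance = provenance)
}

.isomer_from_cnnc <- function(pos, core) {
  phi <- rad2deg(dihedral_cpp(pos, core))
  if (abs(phi) < 90) "cis" else "trans"
}

#' Relaxed basin geometry of the oracle ground state
#'
#' @param spec an [oracle_spec()]
#' @param isomer "cis" or "trans"
#' @return a [geometry()] at the optimized minimum
#' @export
oracle_min_geometry <- function(spec, isomer = c("cis", "trans")) {
  isomer <- match.arg(isomer)
  pos0 <- if (isomer == "cis") spec$pos_cis else spec$pos_trans
  n <- nrow(pos0)
  fn <- function(x) {
    d <- oracle_eval_cpp(unclass(spec), matrix(x, n, 3), gradient = FALSE)$d
    adiabatize(d)$energies[1]
  }
  gr <- function(x) {
    pos <- matrix(x, n, 3)
    res <- oracle_eval_cpp(unclass(spec), pos, gradient = TRUE)
    sol <- adiabatize(res$d)
    G <- matrix(res$grad, nrow = 9)
    w <- as.vector(outer(sol$u[, 1], sol$u[, 1]))
    as.vector(matrix(w %*% G, n, 3))
  }
  opt <- optim(as.vector(pos0), fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  geometry(spec$z, matrix(opt$par, n, 3), isomer = isomer)
}

#' Locate an exact point on the conical-intersection seam
#'
#' Minimizes the squared S0/S1 gap over the full geometry starting from a
#' twisted, bend-opened guess; with the default spec this converges to a
#' true zero of the gap (machine precision) at phi ~ 90 deg.
#'
#' @param spec an [oracle_spec()]
#' @return a [geometry()] with S1 - S0 below 1e-8 kcal/mol
#' @export
oracle_ci_geometry <- function(spec) {
  # start from a twisted geometry with bends between the two centers
  pos0 <- .twisted_guess(spec)
  n <- nrow(pos0)
  gap_objective <- function(bias) {
    fn <- function(x) {
      d <- oracle_eval_cpp(unclass(spec), matrix(x, n, 3), gradient = FALSE)$d
      sol <- adiabatize(d)
      (sol$energies[2] - sol$energies[1])^2 + bias * sol$energies[1]
    }
    gr <- function(x) {
      pos <- matrix(x, n, 3)
      res <- oracle_eval_cpp(unclass(spec), pos, gradient = TRUE)
      sol <- adiabatize(res$d)
      G <- matrix(res$grad, nrow = 9)
      gap <- sol$energies[2] - sol$energies[1]
      wgap <- as.vector(outer(sol$u[, 2], sol$u[, 2]) -
                          outer(sol$u[, 1], sol$u[, 1]))
      out <- 2 * gap * matrix(wgap %*% G, n, 3)
      if (bias > 0) {
        w0 <- as.vector(outer(sol$u[, 1], sol$u[, 1]))
        out <- out + bias * matrix(w0 %*% G, n, 3)
      }
      as.vector(out)
    }
    list(fn = fn, gr = gr)
  }
  # phase 1: gap^2 with a light energy bias keeps the search on the low-energy
  # part of the seam; phase 2 polishes the pure gap^2 to a true zero
  ob1 <- gap_objective(1e-3)
  opt <- optim(as.vector(pos0), ob1$fn, ob1$gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  ob2 <- gap_objective(0)
  for (i in 1:5) {
    opt <- optim(opt$par, ob2$fn, ob2$gr, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-20))
    if (ob2$fn(opt$par) < 1e-18) break
  }
  geometry(spec$z, matrix(opt$par, n, 3), isomer = "unknown")
}

.twisted_guess <- function(spec) {
  mol <- .build_rotor_template()
  d_cn <- 1.47
  pos <- mol$pos_trans
  # rebuild C4 at phi = 90 with bends at the midpoint of the two centers
  a_mid <- (spec$bend_c[1] + spec$bend_c[2]) / 2
  pos[4, ] <- .place_nerf(pos[1, ], pos[2, ], pos[3, ], d_cn, a_mid, pi / 2)
  # C1 angle likewise: rebuild C1 against N3-N2 axis
  pos[1, ] <- c(d_cn * cos(a_mid), d_cn * sin(a_mid), 0)
  for (j in 1:3)
    pos[4 + j, ] <- .place_nerf(pos[3, ], pos[2, ], pos[1, ], 1.09,
                                deg2rad(109.47), deg2rad(c(60, 180, 300)[j]))
  for (j in 1:3)
    pos[7 + j, ] <- .place_nerf(pos[2, ], pos[3, ], pos[4, ], 1.09,
                                deg2rad(109.47), deg2rad(c(60, 180, 300)[j]))
  pos
}

#' Generate oracle geometries
#'
#' Three sampling modes: `normal_mode` draws classical harmonic thermal
#' displacements along the mass-weighted normal modes of a basin minimum at
#' temperature `T`; `rot_inv` lays a grid over the central torsion
#' phi in \[0, 360) deg while cycling symmetric/asymmetric bend offsets that
#' cross the intersection seam; `basin` returns relaxed minima.
#'
#' @param spec an [oracle_spec()]
#' @param mode one of "normal_mode", "rot_inv", "basin"
#' @param n number of geometries
#' @param T temperature in K (normal_mode)
#' @param seed RNG seed
#' @param isomer basin for normal_mode/basin modes
#' @return list of [geometry()] objects
#' @export
generate_geometries <- function(spec, mode = c("normal_mode", "rot_inv", "basin"),
                                n = 100, T = 300, seed = 1,
                                isomer = c("cis", "trans")) {
  mode <- match.arg(mode)
  isomer <- match.arg(isomer)
  set.seed(seed)
  if (mode == "basin") {
    gmin <- oracle_min_geometry(spec, isomer)
    return(replicate(n, gmin, simplify = FALSE))
  }
  if (mode == "rot_inv") {
    phis <- seq(0, 360, length.out = n + 1)[seq_len(n)]
    bend_sets <- rbind(c(0, 0), c(8, 8), c(8, -8), c(-8, 8), c(12, 12))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      bo <- bend_sets[((i - 1) %% nrow(bend_sets)) + 1, ]
      pos <- .rotor_at(spec, phis[i], 120 + bo[1], 120 + bo[2])
      out[[i]] <- geometry(spec$z, pos,
                           isomer = .isomer_from_cnnc(pos, spec$core))
    }
    return(out)
  }
  # normal-mode sampling
  gmin <- oracle_min_geometry(spec, isomer)
  nm <- .normal_modes(spec, gmin)
  natom <- length(spec$z)
  lapply(seq_len(n), function(i) {
    q <- rnorm(length(nm$lambda), sd = sqrt(dann_constants$kB * T / nm$lambda))
    dx <- nm$modes %*% q                 # mass-weighted displacement
    pos <- gmin$pos + matrix(dx / sqrt(rep(spec$masses, each = 3)), natom, 3,
                             byrow = TRUE)
    geometry(spec$z, pos, isomer = gmin$isomer)
  })
}

# rebuild the rotor at given torsion / bend angles (degrees)
.rotor_at <- function(spec, phi_deg, a1_deg = 120, a2_deg = 120) {
  mol <- .build_rotor_template()
  d_cn <- 1.47
  pos <- mol$pos_trans
  pos[1, ] <- c(d_cn * cos(deg2rad(a1_deg)), d_cn * sin(deg2rad(a1_deg)), 0)
  pos[4, ] <- .place_nerf(pos[1, ], pos[2, ], pos[3, ], d_cn, deg2rad(a2_deg),
                          deg2rad(phi_deg))
  for (j in 1:3)
    pos[4 + j, ] <- .place_nerf(pos[3, ], pos[2, ], pos[1, ], 1.09,
                                deg2rad(109.47), deg2rad(c(60, 180, 300)[j]))
  for (j in 1:3)
    pos[7 + j, ] <- .place_nerf(pos[2, ], pos[3, ], pos[4, ], 1.09,
                                deg2rad(109.47), deg2rad(c(60, 180, 300)[j]))
  pos
}

# mass-weighted harmonic analysis at a minimum; drops the 6 softest modes
# (translation/rotation)
.normal_modes <- function(spec, gmin, step = 1e-4) {
  n <- length(spec$z)
  dof <- 3 * n
  grad_at <- function(pos) {
    res <- oracle_eval_cpp(unclass(spec), pos, gradient = TRUE)
    sol <- adiabatize(res$d)
    G <- matrix(res$grad, nrow = 9)
    w <- as.vector(outer(sol$u[, 1], sol$u[, 1]))
    as.vector(t(matrix(w %*% G, n, 3)))   # atom-major x1 y1 z1 ...
  }
  H <- matrix(0, dof, dof)
  for (j in seq_len(dof)) {
    pp <- gmin$pos; pm <- gmin$pos
    atom <- ceiling(j / 3); xyz <- ((j - 1) %% 3) + 1
    pp[atom, xyz] <- pp[atom, xyz] + step
    pm[atom, xyz] <- pm[atom, xyz] - step
    H[, j] <- (grad_at(pp) - grad_at(pm)) / (2 * step)
  }
  H <- (H + t(H)) / 2
  msq <- sqrt(rep(spec$masses, each = 3))
  Hmw <- H / outer(msq, msq)
  es <- eigen(Hmw, symmetric = TRUE)
  keep <- order(abs(es$values))[-(1:6)]          # drop trans/rot
  keep <- keep[es$values[keep] > 0]
  list(lambda = es$values[keep], modes = es$vectors[, keep, drop = FALSE])
}

# ---------------------------------------------------------------------------
# brute-force reference yields
# ---------------------------------------------------------------------------

.oracle_cache <- new.env(parent = emptyenv())

.spec_key <- function(spec, ...) {
  extras <- paste(format(unlist(list(...)), digits = 15), collapse = ",")
  nums <- unlist(spec[c("diag_cos", "dip_amp", "dip_pow", "bend_k", "bend_c",
                        "coup_cos")])
  paste(paste(format(nums, digits = 15), collapse = ","), extras, sep = "|")
}

#' Brute-force surface-hopping quantum yield on the oracle surface
#'
#' Runs a large ensemble of surface-hopping trajectories directly on the
#' analytic surfaces (no learned model) from thermal initial conditions and
#' returns the isomerization quantum yield with its binomial standard
#' error.  Results are cached by (spec, isomer, scheme, seed, n).
#'
#' @param spec an [oracle_spec()]
#' @param isomer starting isomer
#' @param n_traj ensemble size (>= 1000; reference work uses >= 10000)
#' @param scheme "fs" (fewest switches) or "zn" (gap-minimum Zhu-Nakamura)
#' @param seed RNG seed
#' @param T temperature (K) of the initial thermal ensemble
#' @param horizon trajectory horizon in fs
#' @param n_pool size of the NVT position pool resampled for initial
#'   conditions (velocities are redrawn from Maxwell-Boltzmann)
#' @return list with `yield`, `se`, `n`, `frac_ground`, `abort_frac`
#' @export
brute_force_yield <- function(spec, isomer = "cis", n_traj = 10000,
                              scheme = c("fs", "zn"), seed = 1, T = 300,
                              horizon = 2000, n_pool = 1000) {
  scheme <- match.arg(scheme)
  key <- .spec_key(spec, isomer, n_traj, scheme, seed, T, horizon, n_pool)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  ens <- .oracle_thermal_ensemble(spec, isomer, n_traj, T, seed, n_pool)
  res <- oracle_ensemble_cpp(unclass(spec), ens$pos, ens$vel, spec$masses,
                             dt = 0.5, nsub = 50, horizon = horizon, relax = 200,
                             scheme = if (scheme == "fs") 0L else 1L,
                             deg_tol = 1e-6, seed = as.integer(seed %% .Machine$integer.max))
  start_cis <- isomer == "cis"
  ok <- !res$aborted
  reactive <- (res$final_cis == 1) != start_cis
  p <- mean(reactive[ok])
  out <- list(yield = p, se = sqrt(p * (1 - p) / sum(ok)), n = sum(ok),
              frac_ground = mean(res$reached_ground[ok]),
              abort_frac = mean(res$aborted),
              s1_exit = res$s1_exit[ok], reactive = reactive[ok])
  .oracle_cache[[key]] <- out
  out
}

# NVT position pool + Maxwell-Boltzmann velocities, flattened for the C++
# ensemble runner (rows: trajectories; cols: x1 y1 z1 x2 ...)
.oracle_thermal_ensemble <- function(spec, isomer, n_traj, T, seed, n_pool) {
  model <- oracle_model(spec)
  gmin <- oracle_min_geometry(spec, isomer)
  snaps <- sample_initial_conditions(model, gmin, T = T,
                                     n = min(n_pool, n_traj), seed = seed)
  set.seed(seed + 7)
  natom <- length(spec$z)
  idx <- sample.int(length(snaps), n_traj, replace = n_traj > length(snaps))
  pos <- matrix(0, n_traj, 3 * natom)
  vel <- matrix(0, n_traj, 3 * natom)
  sd_v <- sqrt(dann_constants$kB * T / spec$masses * dann_constants$acc)
  for (k in seq_len(n_traj)) {
    pos[k, ] <- as.vector(t(snaps[[idx[k]]]$pos))
    vel[k, ] <- as.vector(t(matrix(rnorm(3 * natom), natom, 3) * sd_v))
  }
  list(pos = pos, vel = vel)
}

#' A small family of oracle rotors with varied torsional profiles
#'
#' Five rotors sharing the same molecular template but differing in the
#' excited-state torsional torque (d00 amplitude) or the steepness of the
#' cis ground diabat (d22), which controls the post-hop branching and
#' spreads the isomerization quantum yields over a wide range.
#'
#' @param n number of family members (up to 5)
#' @return named list of [oracle_spec()]s
#' @export
oracle_family <- function(n = 5) {
  base <- rbind(c(27.5, 27.5, 0), c(42.5, 17.5, 15), c(41, -29, 0))
  alter <- function(row, val) { m <- base; m[row, ] <- val; m }
  specs <- list(
    fast_torque = alter(1, c(37.5, 37.5, 0)),
    mid_torque = alter(1, c(32.5, 32.5, 0)),
    soft_cis_pull = alter(3, c(33, -21, 0)),
    base = base,
    steep_cis_pull = alter(3, c(61, -49, 0)))
  lapply(specs[seq_len(n)], function(dc) oracle_spec(diag_cos = dc))
}
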