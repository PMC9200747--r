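harmonic_model <- function(kap = 2, R0) {
  custom_model(function(pos) {
    n <- nrow(pos)
    d <- diag(c(0.5 * kap * sum((pos - R0)^2), 1e3, 2e3))
    grad <- array(0, c(3, 3, n, 3))
    grad[1, 1, , ] <- kap * (pos - R0)
    list(d = d, grad = grad)
  })
}

test_that("verlet propagation: uniform motion, NVE stability, reversibility", {
  R0 <- rbind(c(0, 0, 0), c(2, 0, 0))
  # zero-force region: R += V dt
  free <- custom_model(function(pos)
    list(d = diag(c(0, 10, 20)), grad = array(0, c(3, 3, nrow(pos), 3))))
  g <- geometry(c(6L, 6L), R0, vel = rbind(c(0.01, 0, 0), c(0, -0.02, 0)))
  st <- trajectory_state(g, free, active = 0L)
  st <- verlet_step(st, free, 2)
  expect_equal(st$geom$pos, R0 + 2 * g$vel, tolerance = 1e-12)
  # harmonic surface: energy drift < 1e-4 kcal/mol over 1000 steps at 0.5 fs
  hm <- harmonic_model(2, R0)
  set.seed(1)
  g <- geometry(c(6L, 6L), R0 + matrix(rnorm(6, sd = 0.05), 2, 3),
                vel = matrix(rnorm(6, sd = 0.002), 2, 3))
  st <- trajectory_state(g, hm, active = 0L)
  etot <- function(s) s$eval$energies[1] +
    dann:::kinetic_energy(s$geom$vel, s$geom$masses)
  e0 <- etot(st)
  drift <- 0
  for (k in 1:1000) {
    st <- verlet_step(st, hm, 0.5)
    drift <- max(drift, abs(etot(st) - e0))
  }
  expect_lt(drift, 1e-4)
  # time reversal returns to the start
  start <- st$geom$pos
  for (k in 1:100) st <- verlet_step(st, hm, 0.5)
  st$geom$vel <- -st$geom$vel
  for (k in 1:100) st <- verlet_step(st, hm, 0.5)
  expect_lt(max(abs(st$geom$pos - start)), 1e-8)
})

test_that("Nose-Hoover sampling equipartitions and respects the T -> 0 limit", {
  om <- fx_oracle_model()
  gmin <- fx_cis_min()
  snaps <- sample_initial_conditions(om, gmin, T = 300, n = 120, seed = 5)
  ke <- vapply(snaps, function(s)
    dann:::kinetic_energy(s$vel, s$masses), 0)
  target <- 30 * dann_constants$kB * 300 / 2
  expect_lt(abs(mean(ke) / target - 1), 0.05)
  # fixed seed reproduces the snapshot set
  snaps2 <- sample_initial_conditions(om, gmin, T = 300, n = 3, seed = 7)
  snaps3 <- sample_initial_conditions(om, gmin, T = 300, n = 3, seed = 7)
  expect_identical(snaps2[[3]]$pos, snaps3[[3]]$pos)
  # T = 0: zero velocities, positions at the minimum
  cold <- sample_initial_conditions(om, gmin, T = 0, n = 2, seed = 1)
  expect_equal(cold[[1]]$vel, matrix(0, 10, 3))
  expect_equal(cold[[2]]$pos, gmin$pos)
})

test_that("zero coupling freezes the amplitudes and forbids hops", {
  free <- custom_model(function(pos) {
    n <- nrow(pos)
    grad <- array(0, c(3, 3, n, 3))
    grad[1, 1, 1, 1] <- 0.5
    grad[2, 2, 1, 1] <- -0.5
    list(d = diag(c(0, 5, 50)), grad = grad)
  })
  g <- geometry(c(6L, 6L), rbind(c(0, 0, 0), c(3, 0, 0)),
                vel = rbind(c(0.01, 0, 0), c(0, 0, 0)))
  st <- trajectory_state(g, free, active = 1L)
  set.seed(2)
  for (k in 1:200) {
    st <- verlet_step(st, free, 0.5)
    r <- fssh_hop(st, free, 0.5)
    st <- r$state
    expect_null(r$hop)
  }
  expect_equal(Mod(st$c[2])^2, 1, tolerance = 1e-10)
})

test_that("electronic norm is conserved and accepted hops conserve total energy", {
  om <- fx_oracle_model()
  snaps <- sample_initial_conditions(om, fx_cis_min(), T = 300, n = 1, seed = 9)
  st <- trajectory_state(snaps[[1]], om, active = 1L)
  etot <- function(s) s$eval$energies[s$active + 1] +
    dann:::kinetic_energy(s$geom$vel, s$geom$masses)
  set.seed(9)
  norm_err <- 0
  hop_seen <- FALSE
  for (k in 1:1000) {
    st <- verlet_step(st, om, 0.5)
    e_before <- etot(st)
    r <- fssh_hop(st, om, 0.5)
    st <- r$state
    norm_err <- max(norm_err, abs(sum(Mod(st$c)^2) - 1))
    if (!is.null(r$hop) && r$hop$accepted) {
      expect_lt(abs(etot(st) - e_before), 1e-8)
      hop_seen <- TRUE
      break
    }
  }
  expect_lt(norm_err, 1e-6)
  expect_true(hop_seen)   # cis photodynamics hops within ~0.5 ps
})

test_that("Zhu-Nakamura hops only fire at gap minima and vanish for huge gaps", {
  om <- fx_oracle_model()
  # strictly monotone gap history -> no attempt regardless of RNG
  g <- fx_geom(seed = 12)
  g$vel <- matrix(0, 10, 3)
  st <- trajectory_state(g, om, active = 1L)
  st$gap_hist <- c(10, 8, 6)
  set.seed(1)
  expect_null(zn_hop(st, om, 0.5)$hop)
  # huge gap at a minimum: transition probability below 1e-6
  st$gap_hist <- c(60.001, 60, 60.001)
  p <- exp(-(pi / (2 * dann_constants$hbar)) *
             sqrt(60^3 / ((0.002) / 0.25)))
  expect_lt(p, 1e-6)
  hops <- 0
  set.seed(2)
  for (k in 1:200) {
    st2 <- st
    if (!is.null(zn_hop(st2, om, 0.5)$hop)) hops <- hops + 1
  }
  expect_identical(hops, 0)
})

test_that("frustrated hops leave velocities unchanged and are recorded", {
  # force an upward hop attempt with negligible kinetic energy
  vel0 <- matrix(0, 2, 3)
  deep <- custom_model(function(pos) {
    n <- nrow(pos)
    d <- matrix(0, 3, 3); d[2, 2] <- 50; d[3, 3] <- 100
    d[1, 2] <- d[2, 1] <- 1
    grad <- array(0, c(3, 3, n, 3))
    grad[1, 2, 1, 1] <- grad[2, 1, 1, 1] <- 0.4
    list(d = d, grad = grad)
  })
  g <- geometry(c(6L, 6L), rbind(c(0, 0, 0), c(3, 0, 0)), vel = vel0)
  st <- trajectory_state(g, deep, active = 0L)
  newv <- dann:::.rescale_velocities(vel0, g$masses, dE = 50,
                                     dir = matrix(c(1, 0, 0, 0, 0, 0), 2, 3))
  expect_null(newv)          # cannot pay the energy cost
  ok <- dann:::.rescale_velocities(matrix(c(0.2, 0, 0, 0, 0, 0), 2, 3),
                                   g$masses, dE = 10, dir = NULL)
  ke_before <- dann:::kinetic_energy(matrix(c(0.2, 0, 0, 0, 0, 0), 2, 3),
                                     g$masses)
  expect_equal(dann:::kinetic_energy(ok, g$masses), ke_before - 10,
               tolerance = 1e-10)
})

test_that("ensemble summaries: yields, bootstrap, censored-exponential lifetime", {
  mk <- function(final, init = "cis", exit = NA, hops = NULL)
    list(final_isomer = final, initial_isomer = init, reached_ground = !is.na(exit),
         s1_exit_time = exit, horizon = 1000, aborted = FALSE, hops = hops)
  all_reactive <- replicate(40, mk("trans", exit = 100), simplify = FALSE)
  s <- summarize_ensemble(all_reactive, n_boot = 200, seed = 1)
  expect_equal(s$yield, 1)
  expect_equal(s$yield_sd, 0)
  expect_equal(s$frac_ground_by_horizon, 1)
  # known-exponential lifetime recovery
  set.seed(4)
  exits <- rexp(5000, rate = 1 / 50)
  res <- lapply(exits, function(t) mk("trans", exit = t))
  s2 <- summarize_ensemble(res, n_boot = 10, seed = 1)
  expect_lt(abs(s2$lifetime_fs - 50), 2)
  # bootstrap sd of a Bernoulli sample approaches sqrt(p(1-p)/n)
  set.seed(5)
  outc <- runif(1000) < 0.3
  res3 <- lapply(outc, function(r) mk(if (r) "trans" else "cis"))
  s3 <- summarize_ensemble(res3, n_boot = 1000, seed = 2)
  p <- s3$yield
  expect_lt(abs(s3$yield_sd / sqrt(p * (1 - p) / 1000) - 1), 0.1)
  expect_error(summarize_ensemble(list()), "no trajectories")
  ab <- mk("cis"); ab$aborted <- TRUE
  expect_error(summarize_ensemble(list(ab)), "aborted")
})

test_that("coupling-free trajectories never reach the ground state deterministically", {
  spec0 <- oracle_spec(g01 = 0)
  om0 <- oracle_model(spec0)
  snaps <- sample_initial_conditions(om0, oracle_min_geometry(spec0, "cis"),
                                     T = 300, n = 1, seed = 3)
  tr <- run_trajectory(snaps[[1]], om0, scheme = "fs", horizon = 100, seed = 1)
  expect_false(tr$reached_ground)
  expect_identical(tr$final_isomer, tr$initial_isomer)
  tr2 <- run_trajectory(snaps[[1]], om0, scheme = "fs", horizon = 100, seed = 1)
  expect_identical(tr$frames[[length(tr$frames)]]$pos,
                   tr2$frames[[length(tr2$frames)]]$pos)
})
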