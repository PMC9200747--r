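test_that("the CNNC dihedral follows the right-hand convention and its symmetries", {
  spec <- fx_spec()
  expect_equal(cnnc_dihedral(geometry(spec$z, spec$pos_trans), spec$core), 180)
  expect_equal(cnnc_dihedral(geometry(spec$z, spec$pos_cis), spec$core), 0,
               tolerance = 1e-8)
  g <- geometry(spec$z, dann:::.rotor_at(spec, 63))
  expect_equal(cnnc_dihedral(g, spec$core), 63, tolerance = 1e-6)
  # mirror image negates, rigid rotation/translation preserves
  gm <- g; gm$pos[, 3] <- -gm$pos[, 3]
  expect_equal(cnnc_dihedral(gm, spec$core), -63, tolerance = 1e-6)
  gr <- dann:::rotate_geometry(g, dann:::random_rotation())
  gr$pos <- gr$pos + 5
  expect_equal(cnnc_dihedral(gr, spec$core), 63, tolerance = 1e-6)
  lin <- geometry(c(6L, 7L, 7L, 6L),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(cnnc_dihedral(lin, 1:4), "collinear")
  expect_error(cnnc_dihedral(g, c(1, 2, 2, 4)), "distinct")
})

test_that("hops are classified planar or rotational by the |CNNC| threshold", {
  expect_identical(classify_hop_pathway(list(cnnc_at_hop = 178)), "planar")
  expect_identical(classify_hop_pathway(list(cnnc_at_hop = -160)), "planar")
  expect_identical(classify_hop_pathway(list(cnnc_at_hop = 95)), "rotational")
  expect_identical(classify_hop_pathway(list(cnnc_at_hop = 95),
                                        planar_threshold = 90), "planar")
  hops <- lapply(c(178, -170, 95, 40, 88), function(x) list(cnnc_at_hop = x))
  cl <- vapply(hops, classify_hop_pathway, "")
  expect_equal(mean(cl == "planar") + mean(cl == "rotational"), 1)
})

test_that("thermal averaging shifts the gap consistently across ensembles", {
  om <- fx_oracle_model()
  spec <- fx_spec()
  gmin <- fx_cis_min()
  # constant-gap model: the average is that constant for any snapshots
  const <- custom_model(function(pos)
    list(d = diag(c(0, 23.060548, 99)), grad = array(0, c(3, 3, nrow(pos), 3))))
  snaps1 <- list(fx_geom(seed = 41), fx_geom(seed = 42))
  expect_equal(thermal_mean_gap(const, snaps1), 1)
  expect_equal(thermal_mean_gap(const, snaps1[1]), 1)
  # oracle at 300 K: the thermal average differs measurably from the single
  # minimum-geometry gap, and two independent thermal ensembles (NVT
  # dynamics vs harmonic normal-mode sampling) agree on the shifted value
  snaps <- sample_initial_conditions(om, gmin, T = 300, n = 60, seed = 6)
  nm_snaps <- generate_geometries(spec, "normal_mode", n = 200, T = 300,
                                  seed = 7, isomer = "cis")
  gap_min <- {
    s <- adiabatize(model_diabatic(om, gmin, FALSE)$d)
    (s$energies[2] - s$energies[1]) / dann_constants$ev_to_kcal
  }
  g_nvt <- thermal_mean_gap(om, snaps)
  g_nm <- thermal_mean_gap(om, nm_snaps)
  expect_gt(abs(g_nvt - gap_min), 0.005)      # thermal shift is resolved
  expect_lt(abs(g_nvt - g_nm), 0.02)          # ensembles agree on it
  expect_error(thermal_mean_gap(om, list()), "snapshot")
})

test_that("isomeric stability is a signed median with the quoted convention", {
  shift <- 0.66 * dann_constants$ev_to_kcal
  mk_const <- function(e0) custom_model(function(pos)
    list(d = diag(c(e0, e0 + 40, 1e4)), grad = array(0, c(3, 3, nrow(pos), 3))))
  g <- fx_geom(seed = 43)
  snaps <- replicate(7, g, simplify = FALSE)
  # identical distributions: zero stability
  m_eq <- mk_const(5)
  expect_equal(isomer_stability(m_eq, snaps, snaps, "cis"), 0)
  # trans lower by 0.66 eV: trans stability -0.66, cis +0.66
  m_iso <- custom_model(function(pos) {
    phi <- abs(dann:::dihedral_cpp(pos, c(1L, 2L, 3L, 4L)))
    e0 <- if (phi > pi / 2) 0 else shift
    list(d = diag(c(e0, e0 + 40, 1e4)), grad = array(0, c(3, 3, nrow(pos), 3)))
  })
  spec <- fx_spec()
  s_cis <- replicate(5, geometry(spec$z, spec$pos_cis), simplify = FALSE)
  s_trans <- replicate(5, geometry(spec$z, spec$pos_trans), simplify = FALSE)
  expect_equal(isomer_stability(m_iso, s_cis, s_trans, "trans"), -0.66,
               tolerance = 1e-10)
  expect_equal(isomer_stability(m_iso, s_cis, s_trans, "cis"), 0.66,
               tolerance = 1e-10)
  expect_error(isomer_stability(m_iso, list(), s_trans, "cis"), "non-empty")
})

test_that("one outlier in an odd sample leaves the median stability unchanged", {
  # 101 snapshots, one absurd outlier: median moves by zero
  vals <- c(rep(10, 50), rep(12, 50), 1e6)
  expect_equal(median(vals), median(c(rep(10, 50), rep(12, 51))))
})

test_that("screening reproduces the brute-force yield ranking of the rotor family", {
  fam <- oracle_family(3)   # fast_torque, mid_torque, soft_cis_pull
  bf <- vapply(fam, function(sp)
    brute_force_yield(sp, "cis", n_traj = 400, scheme = "fs", seed = 11,
                      n_pool = 120)$yield, 0)
  models <- lapply(fam, oracle_model)
  rep1 <- screening_report(models, n_traj = 250, T = 300, horizon = 2000,
                           n_snap = 20, seed = 21)
  expect_equal(nrow(rep1), 6)                       # cis + trans per molecule
  expect_true(all(rep1$yield >= 0 & rep1$yield <= 1))
  expect_true(all(rep1$mean_gap_eV > 0))
  cis <- rep1[rep1$isomer == "cis", ]
  expect_identical(order(cis$yield), order(bf))     # Spearman rho = 1
  # deterministic given the seed
  rep2 <- screening_report(models, n_traj = 250, T = 300, horizon = 2000,
                           n_snap = 20, seed = 21)
  expect_identical(rep1, rep2)
  # stability signs: cis rotor less stable than trans for the base profile
  base_row <- rep1[rep1$id == "soft_cis_pull", ]
  expect_gt(base_row$stability_eV[base_row$isomer == "cis"], 0)
  expect_lt(base_row$stability_eV[base_row$isomer == "trans"], 0)
})

test_that("bootstrap yield uncertainty matches the binomial law at n = 1000", {
  set.seed(12)
  reactive <- runif(1000) < 0.4
  res <- lapply(reactive, function(r)
    list(final_isomer = if (r) "trans" else "cis", initial_isomer = "cis",
         reached_ground = TRUE, s1_exit_time = 50, horizon = 1000,
         aborted = FALSE, hops = NULL))
  s <- summarize_ensemble(res, n_boot = 1000, seed = 3)
  expect_lt(abs(s$yield_sd / sqrt(s$yield * (1 - s$yield) / 1000) - 1), 0.1)
})
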