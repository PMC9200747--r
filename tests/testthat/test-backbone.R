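mpnn_small <- function(seed = 4)
  mpnn_model(n_feats = 8L, n_interactions = 2L, cutoff = 4, n_rbf = 6L,
             n_readout = 6L, seed = seed)

test_that("scalar features are invariant and vector features equivariant under rotation", {
  mm <- mpnn_small()
  g <- fx_geom(seed = 2)
  R <- dann:::random_rotation()
  fA <- encode(g, mm)
  fB <- encode(dann:::rotate_geometry(g, R), mm)
  expect_lt(max(abs(fA$s - fB$s)), 1e-10)
  for (f in seq_len(dim(fA$v)[2]))
    expect_lt(max(abs(fA$v[, f, ] %*% t(R) - fB$v[, f, ])), 1e-10)
  # diabatic elements invariant, gradients rotate with the geometry
  hdA <- model_diabatic(mm, g, gradient = TRUE)
  hdB <- model_diabatic(mm, dann:::rotate_geometry(g, R), gradient = TRUE)
  expect_equal(hdA$d, hdB$d, tolerance = 1e-10)
  for (i in 1:2) {
    gA <- hdA$grad[1, 1, i, ]
    gB <- hdB$grad[1, 1, i, ]
    expect_equal(as.vector(R %*% gA), gB, tolerance = 1e-9)
  }
})

test_that("permuting identical atoms permutes features and leaves outputs unchanged", {
  mm <- mpnn_small()
  g <- fx_geom(seed = 3)
  perm <- seq_along(g$z)
  perm[c(5, 6)] <- c(6, 5)              # swap two hydrogens
  g2 <- geometry(g$z[perm], g$pos[perm, ])
  fA <- encode(g, mm)
  fB <- encode(g2, mm)
  expect_equal(fA$s[perm, ], fB$s, tolerance = 1e-11)
  expect_equal(model_diabatic(mm, g, FALSE)$d,
               model_diabatic(mm, g2, FALSE)$d, tolerance = 1e-11)
})

test_that("atoms beyond the cutoff keep their bare element embedding", {
  mm <- mpnn_small()
  g <- geometry(c(6L, 6L), rbind(c(0, 0, 0), c(100, 0, 0)))
  f <- encode(g, mm)
  # both atoms identical element and no neighbors: identical features
  expect_equal(f$s[1, ], f$s[2, ], tolerance = 1e-12)
  expect_equal(f$v, array(0, dim(f$v)))
  g3 <- geometry(c(6L, 6L), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  f3 <- encode(g3, mm)
  expect_gt(max(abs(f3$s[1, ] - f$s[1, ])), 1e-6)  # neighbors do change features
})

test_that("diabatic readout is size-extensive over non-interacting replicas", {
  mm <- mpnn_small()
  g <- fx_geom(seed = 5)
  d1 <- readout_diabatic(g, mm)$d
  g2 <- geometry(c(g$z, g$z), rbind(g$pos, g$pos + 500))
  d2 <- readout_diabatic(g2, mm)$d
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
  expect_true(max(abs(d1 - t(d1))) == 0)
})

test_that("perturbations beyond the interaction range leave local contributions unchanged", {
  mm <- mpnn_small()          # 2 rounds x 4 A cutoff -> horizon 8 A
  z <- c(6L, 6L, 6L)
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(20, 0, 0))
  d_ref <- model_diabatic(mm, geometry(z, pos), FALSE)$d
  pos2 <- pos; pos2[3, ] <- pos2[3, ] + c(1, 2, -1)   # still beyond range
  d_mov <- model_diabatic(mm, geometry(z, pos2), FALSE)$d
  expect_equal(d_mov, d_ref, tolerance = 1e-12)
})

test_that("freshly initialized models are deterministic given the seed", {
  g <- fx_geom(seed = 6)
  expect_identical(model_diabatic(mpnn_small(9), g, FALSE)$d,
                   model_diabatic(mpnn_small(9), g, FALSE)$d)
  expect_false(isTRUE(all.equal(model_diabatic(mpnn_small(9), g, FALSE)$d,
                                model_diabatic(mpnn_small(10), g, FALSE)$d)))
  expect_error(encode(geometry(c(6L, 6L), rbind(c(0, 0, 0), c(1, 0, 0)))[c()],
                      mpnn_small()))
})

test_that("both backbones have analytic gradients matching finite differences", {
  g <- fx_geom(seed = 7)
  spec <- fx_spec()
  dm <- dense_model(geometry(spec$z, spec$pos_trans), hidden = 12,
                    seed = 3, core = spec$core)
  for (model in list(dm, mpnn_small())) {
    res <- model_diabatic(model, g, gradient = TRUE)
    h <- 1e-6
    set.seed(8)
    for (probe in 1:8) {
      i <- sample(10, 1); x <- sample(3, 1)
      gp <- g; gp$pos[i, x] <- gp$pos[i, x] + h
      gm <- g; gm$pos[i, x] <- gm$pos[i, x] - h
      fd <- (model_diabatic(model, gp, FALSE)$d -
               model_diabatic(model, gm, FALSE)$d) / (2 * h)
      expect_lt(max(abs(fd - res$grad[, , i, x])), 1e-7)
    }
    # combo gradient equals the weighted sum of element gradients
    w <- rand_sym3(); w <- (w + t(w)) / 2
    combo <- model_grad_combo(model, g, w)
    ref <- matrix(0, 10, 3)
    for (a in 1:3) for (b in 1:3) ref <- ref + w[a, b] * res$grad[a, b, , ]
    expect_equal(combo, ref, tolerance = 1e-9)
  }
})

test_that("descriptor-model checkpoints round-trip through JSON", {
  spec <- fx_spec()
  dm <- dense_model(geometry(spec$z, spec$pos_trans), hidden = 10, seed = 5,
                    core = spec$core)
  g <- fx_geom(seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(dm, path)
  dm2 <- load_model(path)
  expect_equal(model_diabatic(dm2, g, TRUE), model_diabatic(dm, g, TRUE),
               tolerance = 1e-12)
  expect_identical(dm2$torsion_order, dm$torsion_order)
})
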