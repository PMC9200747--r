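test_that("adiabatize reproduces closed-form eigensystems", {
  sol <- adiabatize(diag(c(0, 10, 50)))
  expect_equal(sol$energies, c(0, 10, 50))
  expect_equal(sol$u, diag(3))
  d <- rbind(c(0, 3, 0), c(3, 0, 0), c(0, 0, 100))
  sol <- adiabatize(d)
  expect_equal(sol$energies, c(-3, 3, 100))
  expect_error(adiabatize(matrix(rnorm(9), 3)), "symmetric")
})

test_that("eigenvalues agree with an independent characteristic-polynomial solver", {
  set.seed(11)
  for (i in 1:50) {
    d <- rand_sym3()
    sol <- adiabatize(d)
    # char poly: det(d - x I) = -x^3 + tr x^2 - m2 x + det
    tr <- sum(diag(d))
    m2 <- sum(diag(d)[c(1, 1, 2)] * diag(d)[c(2, 3, 3)]) -
      d[1, 2]^2 - d[1, 3]^2 - d[2, 3]^2
    roots <- sort(Re(polyroot(c(det(d), -m2, tr, -1))))
    expect_equal(sol$energies, roots, tolerance = 1e-9)
    # reconstruction to 1e-10 relative
    rec <- sol$u %*% diag(sol$energies) %*% t(sol$u)
    expect_lt(max(abs(rec - d)) / max(abs(d)), 1e-10)
    # sign convention: largest-magnitude entry of each column positive
    for (c in 1:3) expect_gte(sol$u[which.max(abs(sol$u[, c])), c], 0)
  }
})

test_that("rotated gradient gives Hellmann-Feynman forces on diagonal models", {
  n <- 4
  grad0 <- array(0, c(3, 3, n, 3))
  sol <- adiabatize(diag(c(1, 2, 3)))
  der <- rotated_gradient(list(d = diag(c(1, 2, 3)), grad = grad0), sol)
  for (s in 1:3) expect_equal(der$forces[[s]], matrix(0, n, 3))
  expect_equal(der$h[["01"]], matrix(0, n, 3))
  # harmonic diagonal model: d_nn = 0.5 * kap_n |R - R0|^2 -> f_n = -kap_n (R - R0)
  set.seed(2)
  R0 <- matrix(rnorm(n * 3), n, 3)
  R <- R0 + matrix(rnorm(n * 3, sd = 0.1), n, 3)
  kap <- c(1, 2, 5)
  d <- diag(0.5 * kap * sum((R - R0)^2))
  grad <- array(0, c(3, 3, n, 3))
  for (s in 1:3) grad[s, s, , ] <- kap[s] * (R - R0)
  der <- rotated_gradient(list(d = d, grad = grad), adiabatize(d))
  ord <- order(diag(d))
  for (s in 1:3)
    expect_equal(der$forces[[s]], -kap[ord[s]] * (R - R0), tolerance = 1e-12)
})

test_that("rotated-gradient forces match finite differences on the oracle", {
  spec <- fx_spec()
  set.seed(5)
  for (rep in 1:4) {
    g <- fx_geom(seed = 20 + rep)
    hd <- oracle_hd(spec, g)
    sol <- adiabatize(hd$d)
    der <- rotated_gradient(hd, sol)
    h <- 1e-4
    for (probe in 1:6) {
      i <- sample(10, 1); x <- sample(3, 1)
      gp <- g; gp$pos[i, x] <- gp$pos[i, x] + h
      gm <- g; gm$pos[i, x] <- gm$pos[i, x] - h
      ep <- adiabatize(oracle_hd(spec, gp)$d)$energies
      em <- adiabatize(oracle_hd(spec, gm)$d)$energies
      for (s in 1:2)
        expect_lt(abs(-(ep[s] - em[s]) / (2 * h) - der$forces[[s]][i, x]), 1e-4)
    }
  }
})

test_that("derivative coupling obeys k = h / gap and is flagged at degeneracy", {
  spec <- fx_spec()
  g <- fx_geom(seed = 31)
  hd <- oracle_hd(spec, g)
  sol <- adiabatize(hd$d)
  der <- rotated_gradient(hd, sol)
  gap <- sol$energies[2] - sol$energies[1]
  expect_true(der$k_defined[["01"]])
  expect_equal(der$k[["01"]] * gap, der$h[["01"]], tolerance = 1e-12)
  # at a true degeneracy the division is refused, h still returned
  ci <- oracle_ci_geometry(spec)
  hd_ci <- oracle_hd(spec, ci)
  der_ci <- rotated_gradient(hd_ci, adiabatize(hd_ci$d))
  expect_false(der_ci$k_defined[["01"]])
  expect_true(all(is.finite(der_ci$h[["01"]])))
})

test_that("direct forces agree with the rotated route and count 2 vs 6 gradients", {
  om <- fx_oracle_model()
  errs <- numeric(0)
  for (rep in 1:20) {
    g <- fx_geom(seed = 40 + rep, sd = 0.03)
    hd <- model_diabatic(om, g, gradient = TRUE)
    der <- rotated_gradient(hd, adiabatize(hd$d))
    fd <- direct_forces(om, g, states = c(0L, 1L))
    errs <- c(errs, max(abs(fd[["0"]] - der$forces[[1]])),
              max(abs(fd[["1"]] - der$forces[[2]])))
  }
  expect_lt(max(errs), 1e-6)
  # instrumented gradient counters
  g <- fx_geom(seed = 77)
  reset_grad_counter(om)
  invisible(direct_forces(om, g, states = c(0L, 1L)))
  expect_identical(grad_counter(om), 2L)
  reset_grad_counter(om)
  invisible(model_diabatic(om, g, gradient = TRUE))
  expect_identical(grad_counter(om), 6L)
  expect_error(direct_forces(om, g, states = 3L), "0..2")
})

test_that("branching plane is recovered for a linear two-state model", {
  # d11 - d00 = a*x, d01 = b*y: g along x of atom 1, h along y of atom 1
  a <- 4; b <- 2
  model <- custom_model(function(pos) {
    n <- nrow(pos)
    x <- pos[1, 1]; y <- pos[1, 2]
    d <- matrix(0, 3, 3)
    d[2, 2] <- a * x
    d[1, 2] <- d[2, 1] <- b * y
    d[3, 3] <- 1e4
    grad <- array(0, c(3, 3, n, 3))
    grad[2, 2, 1, 1] <- a
    grad[1, 2, 1, 2] <- grad[2, 1, 1, 2] <- b
    list(d = d, grad = grad)
  })
  # on the x-axis the coupling vanishes and the gap gradient is pure x,
  # while the coupling gradient is pure y
  g0 <- geometry(c(6L, 6L), rbind(c(0.001, 0, 0), c(5, 0, 0)))
  bp <- branching_plane(model, g0)
  expect_equal(abs(bp$g[1, 1]), 1, tolerance = 1e-6)
  expect_equal(abs(bp$h_dir[1, 2]), 1, tolerance = 1e-6)
  # swapping the two state labels at most flips the sign of g
  ev <- dann:::adiabatic_eval(model, g0)
  g_swapped <- -(ev$forces[[1]] - ev$forces[[2]])   # grad(E0 - E1)
  g_swapped <- g_swapped / sqrt(sum(g_swapped^2))
  expect_equal(abs(sum(bp$g * g_swapped)), 1, tolerance = 1e-9)
  # far from the seam the vectors are refused
  gfar <- geometry(c(6L, 6L), rbind(c(3, 3, 0), c(5, 0, 0)))
  expect_error(branching_plane(model, gfar), "window")
  # scan: n = 1 equals the origin evaluation; around the exact crossing the
  # linear-coupling gap is symmetric under (x, y) -> (-x, -y)
  sc1 <- scan_branching_plane(model, bp, extent = 0.01, n = 1L)
  ev0 <- adiabatize(model_diabatic(model, g0, FALSE)$d)
  expect_equal(sc1$gap, ev0$energies[2] - ev0$energies[1], tolerance = 1e-12)
  origin0 <- geometry(c(6L, 6L), rbind(c(0, 0, 0), c(5, 0, 0)))
  bp0 <- bp; bp0$origin <- origin0
  sc <- scan_branching_plane(model, bp0, extent = 0.05, n = 5L)
  inv <- sc[order(-sc$x, -sc$y), ]
  expect_equal(sc$gap, inv$gap, tolerance = 1e-9)
})

test_that("the oracle CI shows a linear cone and smooth diabats across the seam", {
  spec <- fx_spec()
  om <- fx_oracle_model()
  ci <- oracle_ci_geometry(spec)
  sol <- adiabatize(oracle_hd(spec, ci)$d)
  expect_lt(sol$energies[2] - sol$energies[1], 1e-8)
  bp <- branching_plane(om, ci)
  lams <- seq(0.002, 0.01, length.out = 5)
  for (dir in list(bp$g, bp$h_dir)) {
    for (sgn in c(-1, 1)) {
      ls <- sgn * lams
      gaps <- vapply(ls, function(l) {
        g2 <- ci; g2$pos <- g2$pos + l * dir
        s <- adiabatize(model_diabatic(om, g2, FALSE)$d)
        s$energies[2] - s$energies[1]
      }, 0)
      expect_gte(summary(lm(gaps ~ abs(ls)))$r.squared, 0.999)
    }
  }
  # scan minimum at the origin for an exact CI origin
  sc <- scan_branching_plane(om, bp, extent = 0.01, n = 5L)
  expect_lte(sc$gap[sc$x == 0 & sc$y == 0], min(sc$gap) + 1e-12)
  # diabatic elements stay smooth across the seam while the gap kinks
  h <- 2e-3
  line <- seq(-5, 5) * h
  vals <- vapply(line, function(l) {
    g2 <- ci; g2$pos <- g2$pos + l * bp$g
    hd <- model_diabatic(om, g2, FALSE)
    s <- adiabatize(hd$d)
    c(hd$d[1, 1], hd$d[2, 2], hd$d[1, 2], s$energies[2] - s$energies[1])
  }, numeric(4))
  d2 <- function(v) max(abs(diff(diff(v)))) / h^2
  expect_gt(d2(vals[4, ]), 50 * max(d2(vals[1, ]), d2(vals[2, ]), d2(vals[3, ])))
})

test_that("near the seam h stays bounded while k diverges as the inverse gap", {
  spec <- fx_spec()
  om <- fx_oracle_model()
  ci <- oracle_ci_geometry(spec)
  bp <- branching_plane(om, ci)
  hnorms <- c(); knorms <- c(); gaps <- c()
  for (l in c(0.05, 0.01, 0.002)) {
    g2 <- ci; g2$pos <- g2$pos + l * bp$g
    ev <- adiabatic_eval(om, g2)
    gaps <- c(gaps, ev$gap)
    hnorms <- c(hnorms, sqrt(sum(ev$h01^2)))
    knorms <- c(knorms, sqrt(sum(ev$k01^2)))
    expect_equal(sqrt(sum((ev$k01 * ev$gap)^2)), sqrt(sum(ev$h01^2)),
                 tolerance = 1e-10)
  }
  expect_lt(max(hnorms) / min(hnorms), 3)      # h bounded
  expect_gt(knorms[3] / knorms[1], 10)         # k diverges as gap shrinks
  expect_true(all(diff(gaps) < 0))
})
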