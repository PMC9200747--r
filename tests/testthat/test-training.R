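mk_pred <- function(fr, de = 0, df = 0, dh = NULL) {
  list(e0 = fr$e0 + de, e1 = fr$e1 + de, f0 = fr$f0 + df, f1 = fr$f1 + df,
       h01 = if (is.null(dh)) fr$h01 else fr$h01 + dh,
       d = diag(c(fr$e0, fr$e1, fr$e1 + 50)))
}

test_that("loss terms reproduce their closed-form values", {
  fr <- fx_frames(n_nm = 3, n_rot = 2)[[1]]
  w <- loss_weights(w_energy = 1, w_force = 0, w_gap = 1, w_ref = 1,
                    w_nacv = 1)
  # exact predictions: every term zero
  pred <- mk_pred(fr)
  pred$d <- if (fr$geometry$isomer == "cis")
    diag(c(fr$e1, 0, fr$e0)) else diag(c(fr$e0, fr$e1, 99))
  lt <- loss_total(pred, fr, w)
  expect_equal(lt$total, 0)
  # both energies off by +1: 1.0 per state, gap term 0
  pred1 <- mk_pred(fr, de = 1)
  expect_equal(loss_core(pred1, fr, w), 2)
  w2 <- loss_weights(w_energy = 2, w_force = 0, w_gap = 2, w_ref = 2,
                     w_nacv = 2)
  expect_equal(loss_core(pred1, fr, w2), 2 * loss_core(pred1, fr, w))
  # trans reference: d00 = E0 + 2, d11 = E1 -> 4 w_ref
  g_t <- fr$geometry; g_t$isomer <- "trans"
  fr_t <- fr; fr_t$geometry <- g_t
  pred_t <- mk_pred(fr_t)
  pred_t$d <- diag(c(fr$e0 + 2, fr$e1, 99))
  expect_equal(loss_ref(pred_t, fr_t, w), 4)
  # cis reference zero case
  g_c <- fr$geometry; g_c$isomer <- "cis"
  fr_c <- fr; fr_c$geometry <- g_c
  pred_c <- mk_pred(fr_c)
  pred_c$d <- diag(c(fr$e1, 77, fr$e0))
  expect_equal(loss_ref(pred_c, fr_c, w), 0)
  # unknown isomer contributes nothing
  g_u <- fr$geometry; g_u$isomer <- "unknown"
  fr_u <- fr; fr_u$geometry <- g_u
  expect_equal(loss_ref(mk_pred(fr_u), fr_u, w), 0)
})

test_that("the NACV loss is phase-resolved and atom-normalized", {
  fr <- fx_frames(n_nm = 3, n_rot = 2)[[2]]
  w <- loss_weights(w_nacv = 1)
  expect_equal(loss_nacv(mk_pred(fr), fr, w), 0)
  flipped <- mk_pred(fr); flipped$h01 <- -fr$h01
  expect_equal(loss_nacv(flipped, fr, w), 0)
  bumped <- mk_pred(fr)
  bumped$h01[4, ] <- bumped$h01[4, ] + c(1, 0, 0)   # unit vector on one atom
  expect_equal(loss_nacv(bumped, fr, w), 1 / n_atoms(fr$geometry))
  # absent labels are skipped
  fr2 <- fr; fr2$h01 <- NULL
  expect_equal(loss_nacv(mk_pred(fr), fr2, w), 0)
})

test_that("the total loss is the exact sum of its three terms", {
  frames <- fx_frames(n_nm = 4, n_rot = 3)
  w <- loss_weights()
  spec <- fx_spec()
  dm <- dense_model(frames[[1]]$geometry, hidden = 8, seed = 2,
                    core = spec$core)
  for (fr in frames[1:5]) {
    pred <- model_predict(dm, fr)
    lt <- loss_total(pred, fr, w)
    expect_equal(lt$total, lt$core + lt$ref + lt$nacv, tolerance = 1e-12)
  }
})

test_that("analytic parameter gradients match finite differences", {
  frames <- fx_frames(n_nm = 4, n_rot = 3)[c(1, 5, 9)]
  spec <- fx_spec()
  dm <- dense_model(frames[[1]]$geometry, hidden = 6, seed = 7,
                    core = spec$core)
  mk_data <- function() lapply(frames, function(fr) {
    dd <- dann:::dense_descriptors(dm, fr$geometry, jacobian = TRUE)
    list(D = dd$D, J = dd$J, e0 = fr$e0, e1 = fr$e1,
         f0 = as.vector(t(fr$f0)), f1 = as.vector(t(fr$f1)),
         h01 = as.vector(t(fr$h01)), iso = fr$geometry$isomer,
         natom = n_atoms(fr$geometry))
  })
  data <- mk_data()
  Dmat <- do.call(rbind, lapply(data, `[[`, "D"))
  theta <- dann:::dense_flatten(dm$params)
  # energy-type terms are exact by Hellmann-Feynman: full FD agreement
  w_e <- loss_weights(w_energy = 1, w_force = 0, w_gap = 0.7, w_ref = 0.4,
                      w_nacv = 0)
  lg <- dann:::.dense_loss_grad(dm, data, Dmat, 1:3, w_e)
  set.seed(3)
  for (j in sample(length(theta), 20)) {
    h <- 1e-6
    m <- dm
    tp <- theta; tp[j] <- tp[j] + h
    m$params <- dann:::dense_unflatten(dm, tp)
    lp <- dann:::.dense_loss_grad(m, data, Dmat, 1:3, w_e, grad = FALSE)$loss$total
    tm <- theta; tm[j] <- tm[j] - h
    m$params <- dann:::dense_unflatten(dm, tm)
    lm_ <- dann:::.dense_loss_grad(m, data, Dmat, 1:3, w_e, grad = FALSE)$loss$total
    expect_equal(lg$grad[j], (lp - lm_) / (2 * h), tolerance = 1e-4)
  }
  # force/NACV terms hold the adiabatic rotation fixed per step, so they are
  # checked against finite differences of the frozen-rotation loss
  w_v <- loss_weights(w_energy = 0, w_force = 0.3, w_gap = 0, w_ref = 0,
                      w_nacv = 0.5)
  fr1 <- data[[1]]
  fw0 <- dann:::dense_forward(dm, fr1$D)
  eg0 <- dann:::.eig6(fw0$y)
  frozen_loss <- function(params) {
    fw <- dann:::dense_forward(list(params = params), fr1$D)
    sp_ <- 1 - fw$h^2
    predP <- function(c6) {
      q <- as.vector(crossprod(params$W2, c6)) * sp_
      gd <- as.vector(crossprod(params$W1, q)) +
        as.vector(crossprod(params$W3, c6))
      as.vector(crossprod(fr1$J, gd))
    }
    u <- eg0$u
    c6h <- c(u[1, 1] * u[1, 2], u[2, 1] * u[2, 2], u[3, 1] * u[3, 2],
             u[1, 1] * u[2, 2] + u[2, 1] * u[1, 2],
             u[1, 1] * u[3, 2] + u[3, 1] * u[1, 2],
             u[2, 1] * u[3, 2] + u[3, 1] * u[2, 2])
    dof <- length(fr1$f0)
    P0 <- predP(eg0$a0); P1 <- predP(eg0$a1); Ph <- predP(c6h)
    sgn <- if (sum((Ph - fr1$h01)^2) <= sum((Ph + fr1$h01)^2)) 1 else -1
    w_v$w_force * (sum(((-P0) - fr1$f0)^2) + sum(((-P1) - fr1$f1)^2)) / dof +
      w_v$w_nacv * sum((Ph - sgn * fr1$h01)^2) / fr1$natom
  }
  vt <- dann:::.dense_vector_terms(dm$params, fr1, eg0, fw0$h, fr1$D, w_v,
                                   grad = TRUE)
  gan <- c(as.vector(vt$gW1), vt$gb1, as.vector(vt$gW2), as.vector(vt$gW3),
           rep(0, 6))
  set.seed(4)
  for (j in sample(length(theta) - 6, 20)) {   # b2 does not enter P
    h <- 1e-6
    tp <- theta; tp[j] <- tp[j] + h
    lp <- frozen_loss(dann:::dense_unflatten(dm, tp))
    tm <- theta; tm[j] <- tm[j] - h
    lm_ <- frozen_loss(dann:::dense_unflatten(dm, tm))
    expect_equal(gan[j], (lp - lm_) / (2 * h), tolerance = 1e-4)
  }
})

test_that("one optimization step on one frame lowers that frame's loss", {
  frames <- fx_frames(n_nm = 4, n_rot = 3)[3]
  spec <- fx_spec()
  dm <- dense_model(frames[[1]]$geometry, hidden = 8, seed = 4,
                    core = spec$core)
  w <- loss_weights()
  data <- lapply(frames, function(fr) {
    dd <- dann:::dense_descriptors(dm, fr$geometry, jacobian = TRUE)
    list(D = dd$D, J = dd$J, e0 = fr$e0, e1 = fr$e1,
         f0 = as.vector(t(fr$f0)), f1 = as.vector(t(fr$f1)),
         h01 = as.vector(t(fr$h01)), iso = fr$geometry$isomer, natom = 10)
  })
  Dmat <- matrix(data[[1]]$D, 1)
  lg <- dann:::.dense_loss_grad(dm, data, Dmat, 1L, w)
  theta <- dann:::dense_flatten(dm$params) - 1e-6 * lg$grad
  dm$params <- dann:::dense_unflatten(dm, theta)
  after <- dann:::.dense_loss_grad(dm, data, Dmat, 1L, w, grad = FALSE)
  expect_lt(after$loss$total, lg$loss$total)
})

test_that("training is deterministic and restores the best checkpoint", {
  frames <- fx_frames(n_nm = 15, n_rot = 10)
  spec <- fx_spec()
  w <- loss_weights(w_force = 0, w_nacv = 0)
  cfg <- train_config(epochs = 30, seed = 5, patience = 30)
  r1 <- train_model(frames, dense_model(frames[[1]]$geometry, hidden = 12,
                                        seed = 5, core = spec$core),
                    w = w, cfg = cfg)
  r2 <- train_model(frames, dense_model(frames[[1]]$geometry, hidden = 12,
                                        seed = 5, core = spec$core),
                    w = w, cfg = cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
  expect_true(all(c("loss_core", "loss_ref", "loss_nacv", "val_total",
                    "val_gap_mae") %in% names(r1$history)))
  # validation loss of the kept model equals the best epoch's
  expect_equal(min(r1$history$val_total),
               r1$history$val_total[which.min(r1$history$val_total)])
})

test_that("training on matching-capacity data drives the validation gap down", {
  frames <- fx_frames(n_nm = 25, n_rot = 25)
  spec <- fx_spec()
  r <- train_model(frames, dense_model(frames[[1]]$geometry, hidden = 24,
                                       seed = 6, core = spec$core),
                   w = loss_weights(w_force = 0, w_nacv = 0),
                   cfg = train_config(epochs = 120, seed = 6, patience = 120))
  h <- r$history
  expect_lt(tail(h$val_gap_mae, 1), h$val_gap_mae[1] / 2)
  # constant-label degenerate problem: model collapses to the constant
  gsame <- frames[[1]]
  const_frames <- replicate(20, gsame, simplify = FALSE)
  rc <- train_model(const_frames,
                    dense_model(gsame$geometry, hidden = 6, seed = 7),
                    w = loss_weights(w_force = 0, w_nacv = 0, w_ref = 0),
                    cfg = train_config(epochs = 60, seed = 7, patience = 60))
  expect_lt(tail(rc$history$val_total, 1), 1e-6)
})

test_that("committee training uses distinct seeds unless forced identical", {
  frames <- fx_frames(n_nm = 10, n_rot = 8)
  spec <- fx_spec()
  fac <- function(seed) dense_model(frames[[1]]$geometry, hidden = 10,
                                    seed = seed, core = spec$core)
  cfg <- train_config(epochs = 15, seed = 8, patience = 15)
  w <- loss_weights(w_force = 0, w_nacv = 0)
  expect_error(train_committee(frames, n = 1, cfg = cfg), ">= 2")
  comm <- train_committee(frames, n = 2, cfg = cfg, model_factory = fac, w = w)
  expect_false(identical(comm[[1]]$params, comm[[2]]$params))
  g <- fx_geom(seed = 30)
  expect_gt(committee_variance(comm, g)$total, 0)
  same <- train_committee(frames, n = 2, cfg = cfg, model_factory = fac,
                          w = w, seeds = c(8, 8))
  expect_identical(same[[1]]$params, same[[2]]$params)
  expect_equal(committee_variance(same, g)$total, 0)
})
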