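# The diabatic training loss and optimizer.  The total loss is the exact
# sum of three terms: a core term (MSE on adiabatic energies, forces and
# the S0/S1 gap), a reference term tying diabatic diagonal elements to the
# labeled adiabatic energies by isomer basin, and a sign-resolved NACV term
# on the rotated off-diagonal h01.  For the descriptor backbone all
# gradients, including the force/NACV terms (mixed second derivatives),
# are analytic; for the message-passing backbone the energy-type terms are
# trained and the vector terms are skipped with a warning.  Loss gradients
# treat the diagonalizer as locally constant (exact for the energy terms
# by Hellmann-Feynman).

#' Loss weights for the diabatic loss
#'
#' @param w_energy,w_force,w_gap,w_ref,w_nacv non-negative term weights
#' @return a `dann_loss_weights` list
#' @export
loss_weights <- function(w_energy = 1, w_force = 0.1, w_gap = 1, w_ref = 0.2,
                         w_nacv = 0.05) {
  w <- list(w_energy = w_energy, w_force = w_force, w_gap = w_gap,
            w_ref = w_ref, w_nacv = w_nacv)
  if (any(unlist(w) < 0)) stop("weights must be non-negative")
  if (all(unlist(w) == 0)) stop("at least one weight must be positive")
  structure(w, class = "dann_loss_weights")
}

#' Predictions of a model on one frame
#'
#' @param model a potential model
#' @param frame a [labeled_frame()]
#' @return list with e0, e1, f0, f1, h01 and the diabatic matrix d
#' @export
model_predict <- function(model, frame) {
  ev <- adiabatic_eval(model, frame$geometry)
  list(e0 = ev$energies[1], e1 = ev$energies[2], f0 = ev$forces[[1]],
       f1 = ev$forces[[2]], h01 = ev$h01, d = ev$d)
}

#' Core loss: adiabatic energies, forces and gap
#'
#' Weighted sum of squared errors on E0 and E1, mean-squared errors on the
#' force matrices, and the squared gap error; zero iff all match.
#'
#' @param pred prediction list from [model_predict()]
#' @param frame a [labeled_frame()]
#' @param w a [loss_weights()]
#' @return non-negative scalar
#' @export
loss_core <- function(pred, frame, w) {
  if (!all(dim(pred$f0) == dim(frame$f0))) stop("force shape mismatch")
  w$w_energy * ((pred$e0 - frame$e0)^2 + (pred$e1 - frame$e1)^2) +
    w$w_gap * ((pred$e1 - pred$e0) - (frame$e1 - frame$e0))^2 +
    w$w_force * (mean((pred$f0 - frame$f0)^2) + mean((pred$f1 - frame$f1)^2))
}

#' Reference-geometry loss
#'
#' Ties the diabatic diagonal to the labeled adiabatic energies according
#' to the isomer basin: trans frames penalize (E0 - d00)^2 + (E1 - d11)^2,
#' cis frames (E0 - d22)^2 + (E1 - d00)^2; frames with unknown isomer
#' contribute zero.
#'
#' @inheritParams loss_core
#' @return non-negative scalar
#' @export
loss_ref <- function(pred, frame, w) {
  iso <- frame$geometry$isomer
  if (iso == "trans")
    w$w_ref * ((frame$e0 - pred$d[1, 1])^2 + (frame$e1 - pred$d[2, 2])^2)
  else if (iso == "cis")
    w$w_ref * ((frame$e0 - pred$d[3, 3])^2 + (frame$e1 - pred$d[1, 1])^2)
  else 0
}

#' Sign-resolved NACV loss
#'
#' The overall phase of a reference NACV is arbitrary, so the mismatch is
#' minimized over the label sign per frame: min over s in {+1, -1} of
#' ||pred - s * label||^2 / N.  Frames without h01 contribute zero.
#'
#' @inheritParams loss_core
#' @return non-negative scalar
#' @export
loss_nacv <- function(pred, frame, w) {
  if (is.null(frame$h01)) return(0)
  n <- nrow(frame$h01)
  w$w_nacv * min(sum((pred$h01 - frame$h01)^2),
                 sum((pred$h01 + frame$h01)^2)) / n
}

#' Total diabatic loss (core + reference + NACV)
#'
#' @inheritParams loss_core
#' @return list with `total` and the three terms
#' @export
loss_total <- function(pred, frame, w) {
  lc <- loss_core(pred, frame, w)
  lr <- loss_ref(pred, frame, w)
  ln <- loss_nacv(pred, frame, w)
  list(total = lc + lr + ln, core = lc, ref = lr, nacv = ln)
}

#' Training configuration
#'
#' @param epochs maximum epochs
#' @param lr,lr_final initial and final learning rate (exponential decay)
#' @param batch_size minibatch size (0 = full batch)
#' @param seed RNG seed (recorded in the checkpoint)
#' @param val_split validation fraction in (0, 1)
#' @param patience early-stop patience in epochs
#' @return a `dann_train_config`
#' @export
train_config <- function(epochs = 400, lr = 0.03, lr_final = 0.003,
                         batch_size = 0L, seed = 1, val_split = 0.1,
                         patience = 60, vec_subsample = 500L) {
  if (val_split <= 0 || val_split >= 1) stop("val_split must be in (0,1)")
  structure(list(epochs = as.integer(epochs), lr = lr, lr_final = lr_final,
                 batch_size = as.integer(batch_size), seed = seed,
                 val_split = val_split, patience = as.integer(patience),
                 vec_subsample = as.integer(vec_subsample)),
            class = "dann_train_config")
}

# ---------------------------------------------------------------------------
# Adam
# ---------------------------------------------------------------------------

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = state)
}

# ---------------------------------------------------------------------------
# training
# ---------------------------------------------------------------------------

#' Train a model on labeled frames with the diabatic loss
#'
#' Splits the frames into train/validation sets, minimizes the total
#' diabatic loss with Adam, and restores the parameters with the best
#' validation loss.  The history records every loss term per epoch.  Runs
#' are deterministic given the seed and data.
#'
#' @param frames list of [labeled_frame()]s (>= 2)
#' @param model a potential model (descriptor or message-passing backbone)
#' @param w a [loss_weights()]
#' @param cfg a [train_config()]
#' @param val_frames optional fixed validation frames; when supplied, all of
#'   `frames` are used for training and the split is skipped (useful when a
#'   stable model-selection criterion is needed across retrains)
#' @return list with `model` (best checkpoint) and `history` (data.frame)
#' @export
train_model <- function(frames, model, w = loss_weights(), cfg = train_config(),
                        val_frames = NULL) {
  if (length(frames) < 2) stop("need at least 2 frames")
  UseMethod("train_model", model)
}

.train_split <- function(nf, cfg) {
  n_val <- max(1L, round(cfg$val_split * nf))
  val_idx <- sample.int(nf, n_val)
  list(train = setdiff(seq_len(nf), val_idx), val = val_idx)
}

.eig6 <- function(yrow) {
  sol <- adiabatize(.y_to_d(yrow))
  a <- function(nn) {
    u <- sol$u[, nn]
    c(u[1]^2, u[2]^2, u[3]^2, 2 * u[1] * u[2], 2 * u[1] * u[3], 2 * u[2] * u[3])
  }
  list(E = sol$energies, u = sol$u, a0 = a(1), a1 = a(2))
}

#' @export
train_model.dann_dense <- function(frames, model, w = loss_weights(),
                                   cfg = train_config(), val_frames = NULL) {
  set.seed(cfg$seed)
  if (!is.null(val_frames)) {
    n_tr <- length(frames)
    frames <- c(frames, val_frames)
    sp <- list(train = seq_len(n_tr), val = n_tr + seq_along(val_frames))
  }
  nf <- length(frames)
  if (is.null(val_frames)) sp <- .train_split(nf, cfg)
  data <- lapply(frames, function(fr) {
    dd <- dense_descriptors(model, fr$geometry,
                            jacobian = (w$w_force > 0 || w$w_nacv > 0))
    list(D = dd$D, J = dd$J, e0 = fr$e0, e1 = fr$e1,
         f0 = as.vector(t(fr$f0)), f1 = as.vector(t(fr$f1)),
         h01 = if (is.null(fr$h01)) NULL else as.vector(t(fr$h01)),
         iso = fr$geometry$isomer, natom = n_atoms(fr$geometry))
  })
  Dmat <- do.call(rbind, lapply(data, `[[`, "D"))
  if (!isTRUE(model$initialized)) {
    model$params$b2 <- .init_output_bias(data)
  }
  theta <- dense_flatten(model$params)
  opt <- adam_new(length(theta))
  best <- list(val = Inf, theta = theta, epoch = 0)
  hist <- vector("list", cfg$epochs)
  n_bad <- 0
  for (ep in seq_len(cfg$epochs)) {
    lr <- cfg$lr * (cfg$lr_final / cfg$lr)^((ep - 1) / max(cfg$epochs - 1, 1))
    idx <- if (cfg$batch_size > 0)
      sample(sp$train, min(cfg$batch_size, length(sp$train))) else sp$train
    model$params <- dense_unflatten(model, theta)
    vec_idx <- if (cfg$vec_subsample > 0 && cfg$vec_subsample < length(idx))
      sample(idx, cfg$vec_subsample) else idx
    lg <- .dense_loss_grad(model, data, Dmat, idx, w, vec_idx = vec_idx)
    if (!is.finite(lg$loss$total))
      stop(sprintf("divergent loss at epoch %d (total=%g)", ep, lg$loss$total))
    st <- adam_step(opt, theta, lg$grad, lr)
    theta <- st$theta; opt <- st$state
    model$params <- dense_unflatten(model, theta)
    val <- .dense_loss_grad(model, data, Dmat, sp$val, w, grad = FALSE)
    hist[[ep]] <- data.frame(epoch = ep, loss_core = lg$loss$core,
                             loss_ref = lg$loss$ref, loss_nacv = lg$loss$nacv,
                             loss_total = lg$loss$total,
                             val_total = val$loss$total,
                             val_gap_mae = val$gap_mae)
    if (val$loss$total < best$val - 1e-12) {
      best <- list(val = val$loss$total, theta = theta, epoch = ep)
      n_bad <- 0
    } else {
      n_bad <- n_bad + 1
      if (n_bad >= cfg$patience) break
    }
  }
  model$params <- dense_unflatten(model, best$theta)
  model$initialized <- TRUE
  model$seed <- cfg$seed
  list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null,
                                                            logical(1))]))
}

.init_output_bias <- function(data) {
  iso <- vapply(data, `[[`, "", "iso")
  e0 <- vapply(data, `[[`, 0, "e0")
  e1 <- vapply(data, `[[`, 0, "e1")
  pick <- function(v, default) if (length(v)) mean(v) else default
  c(pick(c(e0[iso == "trans"], e1[iso == "cis"]), mean(e0)),   # d00
    pick(e1[iso == "trans"], mean(e1)),                        # d11
    pick(e0[iso == "cis"], mean(e0)),                          # d22
    0, 0, 0)
}

# Loss and analytic parameter gradient over the frames in `idx`.  The
# force/NACV terms may be estimated on a subsample (`vec_idx`) for speed;
# the estimate stays unbiased because the subsample is redrawn per epoch.
.dense_loss_grad <- function(model, data, Dmat, idx, w, grad = TRUE,
                             vec_idx = idx) {
  p <- model$params
  Dm <- Dmat[idx, , drop = FALSE]
  Z1 <- sweep(Dm %*% t(p$W1), 2, p$b1, "+")
  H <- tanh(Z1)
  Y <- sweep(H %*% t(p$W2) + Dm %*% t(p$W3), 2, p$b2, "+")
  nb <- length(idx)
  dLdY <- matrix(0, nb, 6)
  loss_core_s <- 0; loss_ref_s <- 0; loss_nacv_s <- 0
  gap_err <- numeric(nb)
  gW1 <- if (grad) matrix(0, nrow(p$W1), ncol(p$W1))
  gb1 <- if (grad) numeric(length(p$b1))
  gW2 <- if (grad) matrix(0, 6, ncol(p$W2))
  gW3 <- if (grad) matrix(0, 6, ncol(p$W3))
  vec_set <- rep(FALSE, length(data))
  vec_set[vec_idx] <- TRUE
  vfac <- nb / max(length(vec_idx), 1L)   # rescale subsampled vector terms
  for (b in seq_len(nb)) {
    fr <- data[[idx[b]]]
    eg <- .eig6(Y[b, ])
    E0 <- eg$E[1]; E1 <- eg$E[2]
    gap_err[b] <- abs((E1 - E0) - (fr$e1 - fr$e0))
    r0 <- E0 - fr$e0; r1 <- E1 - fr$e1
    rg <- (E1 - E0) - (fr$e1 - fr$e0)
    loss_core_s <- loss_core_s + w$w_energy * (r0^2 + r1^2) + w$w_gap * rg^2
    dLdY[b, ] <- dLdY[b, ] + 2 * w$w_energy * (r0 * eg$a0 + r1 * eg$a1) +
      2 * w$w_gap * rg * (eg$a1 - eg$a0)
    if (fr$iso == "trans") {
      rr0 <- fr$e0 - Y[b, 1]; rr1 <- fr$e1 - Y[b, 2]
      loss_ref_s <- loss_ref_s + w$w_ref * (rr0^2 + rr1^2)
      dLdY[b, 1] <- dLdY[b, 1] - 2 * w$w_ref * rr0
      dLdY[b, 2] <- dLdY[b, 2] - 2 * w$w_ref * rr1
    } else if (fr$iso == "cis") {
      rr0 <- fr$e0 - Y[b, 3]; rr1 <- fr$e1 - Y[b, 1]
      loss_ref_s <- loss_ref_s + w$w_ref * (rr0^2 + rr1^2)
      dLdY[b, 3] <- dLdY[b, 3] - 2 * w$w_ref * rr0
      dLdY[b, 1] <- dLdY[b, 1] - 2 * w$w_ref * rr1
    }
    if ((w$w_force > 0 || w$w_nacv > 0) && !is.null(fr$J) && vec_set[idx[b]]) {
      res <- .dense_vector_terms(p, fr, eg, H[b, ], fr$D, w, grad)
      loss_core_s <- loss_core_s + vfac * res$loss_force
      loss_nacv_s <- loss_nacv_s + vfac * res$loss_nacv
      if (grad) {
        gW1 <- gW1 + vfac * res$gW1; gb1 <- gb1 + vfac * res$gb1
        gW2 <- gW2 + vfac * res$gW2; gW3 <- gW3 + vfac * res$gW3
      }
    }
  }
  loss <- list(core = loss_core_s / nb, ref = loss_ref_s / nb,
               nacv = loss_nacv_s / nb)
  loss$total <- loss$core + loss$ref + loss$nacv
  out <- list(loss = loss, gap_mae = mean(gap_err))
  if (grad) {
    gW2 <- gW2 + crossprod(dLdY, H)
    gW3 <- gW3 + crossprod(dLdY, Dm)
    gb2 <- colSums(dLdY)
    dH <- dLdY %*% p$W2
    dZ1 <- dH * (1 - H^2)
    gW1 <- gW1 + crossprod(dZ1, Dm)
    gb1 <- gb1 + colSums(dZ1)
    out$grad <- c(as.vector(gW1), gb1, as.vector(gW2), as.vector(gW3), gb2) / nb
  }
  out
}

# Force and NACV loss terms with analytic parameter gradients for the
# descriptor net.  The combo-gradient prediction is P(c6) = J^T W1^T q
# with q = (W2^T c6) * s', s' = 1 - h^2.  For a loss direction
# rtil = dL/dP, with a = J rtil:
#   gW1 += q a^T + m D^T,  gb1 += m,  gW2 += c6 ((W1 a) * s')^T,
# where m = (W1 a) * (W2^T c6) * (-2 h) * s'.
.dense_vector_terms <- function(p, fr, eg, hvec, D, w, grad) {
  J <- fr$J
  sp_ <- 1 - hvec^2
  out <- list(loss_force = 0, loss_nacv = 0)
  if (grad) {
    out$gW1 <- matrix(0, nrow(p$W1), ncol(p$W1))
    out$gb1 <- numeric(length(p$b1))
    out$gW2 <- matrix(0, 6, ncol(p$W2))
    out$gW3 <- matrix(0, 6, ncol(p$W3))
  }
  add_term <- function(c6, rtil) {
    a <- as.vector(J %*% rtil)
    Wa <- as.vector(p$W1 %*% a)
    pvec <- as.vector(crossprod(p$W2, c6))
    q <- pvec * sp_
    m <- Wa * pvec * (-2 * hvec) * sp_
    out$gW1 <<- out$gW1 + outer(q, a) + outer(m, D)
    out$gb1 <<- out$gb1 + m
    out$gW2 <<- out$gW2 + outer(c6, Wa * sp_)
    out$gW3 <<- out$gW3 + outer(c6, a)
  }
  pred_P <- function(c6) {
    q <- as.vector(crossprod(p$W2, c6)) * sp_
    gd <- as.vector(crossprod(p$W1, q)) + as.vector(crossprod(p$W3, c6))
    as.vector(crossprod(J, gd))
  }
  if (w$w_force > 0) {
    dof <- length(fr$f0)
    for (n in 0:1) {
      c6 <- if (n == 0) eg$a0 else eg$a1
      flab <- if (n == 0) fr$f0 else fr$f1
      P <- pred_P(c6)
      r <- (-P) - flab
      out$loss_force <- out$loss_force + w$w_force * sum(r^2) / dof
      if (grad) add_term(c6, -(2 * w$w_force / dof) * r)
    }
  }
  if (w$w_nacv > 0 && !is.null(fr$h01)) {
    u <- eg$u
    c6 <- c(u[1, 1] * u[1, 2], u[2, 1] * u[2, 2], u[3, 1] * u[3, 2],
            u[1, 1] * u[2, 2] + u[2, 1] * u[1, 2],
            u[1, 1] * u[3, 2] + u[3, 1] * u[1, 2],
            u[2, 1] * u[3, 2] + u[3, 1] * u[2, 2])
    P <- pred_P(c6)
    sgn <- if (sum((P - fr$h01)^2) <= sum((P + fr$h01)^2)) 1 else -1
    r <- P - sgn * fr$h01
    out$loss_nacv <- out$loss_nacv + w$w_nacv * sum(r^2) / fr$natom
    if (grad) add_term(c6, (2 * w$w_nacv / fr$natom) * r)
  }
  out
}

#' @export
train_model.dann_mpnn <- function(frames, model, w = loss_weights(),
                                  cfg = train_config(), val_frames = NULL) {
  if (w$w_force > 0 || w$w_nacv > 0)
    warning("force/NACV loss terms are not differentiable for the ",
            "message-passing backbone; training on energy terms only")
  set.seed(cfg$seed)
  if (!is.null(val_frames)) {
    n_tr <- length(frames)
    frames <- c(frames, val_frames)
    sp <- list(train = seq_len(n_tr), val = n_tr + seq_along(val_frames))
  } else {
    sp <- .train_split(length(frames), cfg)
  }
  nf <- length(frames)
  theta <- unlist(model$params)
  skel <- model$params
  opt <- adam_new(length(theta))
  best <- list(val = Inf, theta = theta)
  hist <- list()
  n_bad <- 0
  frame_loss <- function(fr, want_grad) {
    fw <- mpnn_forward(model, fr$geometry$z, fr$geometry$pos)
    eg <- .eig6(fw$y)
    r0 <- eg$E[1] - fr$e0; r1 <- eg$E[2] - fr$e1
    rg <- (eg$E[2] - eg$E[1]) - (fr$e1 - fr$e0)
    dLdY <- 2 * w$w_energy * (r0 * eg$a0 + r1 * eg$a1) +
      2 * w$w_gap * rg * (eg$a1 - eg$a0)
    lr_ <- 0
    iso <- fr$geometry$isomer
    if (iso == "trans") {
      rr0 <- fr$e0 - fw$y[1]; rr1 <- fr$e1 - fw$y[2]
      lr_ <- w$w_ref * (rr0^2 + rr1^2)
      dLdY[1] <- dLdY[1] - 2 * w$w_ref * rr0
      dLdY[2] <- dLdY[2] - 2 * w$w_ref * rr1
    } else if (iso == "cis") {
      rr0 <- fr$e0 - fw$y[3]; rr1 <- fr$e1 - fw$y[1]
      lr_ <- w$w_ref * (rr0^2 + rr1^2)
      dLdY[3] <- dLdY[3] - 2 * w$w_ref * rr0
      dLdY[1] <- dLdY[1] - 2 * w$w_ref * rr1
    }
    core <- w$w_energy * (r0^2 + r1^2) + w$w_gap * rg^2
    g <- if (want_grad) unlist(mpnn_backward(model, fw, dLdY,
                                             want_params = TRUE)$gparams)
    list(core = core, ref = lr_, gap_err = abs(rg), grad = g)
  }
  for (ep in seq_len(cfg$epochs)) {
    lr_now <- cfg$lr * (cfg$lr_final / cfg$lr)^((ep - 1) / max(cfg$epochs - 1, 1))
    model$params <- utils::relist(theta, skel)
    idx <- if (cfg$batch_size > 0)
      sample(sp$train, min(cfg$batch_size, length(sp$train))) else sp$train
    g <- numeric(length(theta)); lc <- 0; lrf <- 0
    for (i in idx) {
      fl <- frame_loss(frames[[i]], TRUE)
      g <- g + fl$grad; lc <- lc + fl$core; lrf <- lrf + fl$ref
    }
    nb <- length(idx)
    total <- (lc + lrf) / nb
    if (!is.finite(total)) stop("divergent loss at epoch ", ep)
    st <- adam_step(opt, theta, g / nb, lr_now)
    theta <- st$theta; opt <- st$state
    model$params <- utils::relist(theta, skel)
    vals <- lapply(sp$val, function(i) frame_loss(frames[[i]], FALSE))
    vtot <- mean(vapply(vals, function(x) x$core + x$ref, 0))
    hist[[ep]] <- data.frame(epoch = ep, loss_core = lc / nb, loss_ref = lrf / nb,
                             loss_nacv = 0, loss_total = total, val_total = vtot,
                             val_gap_mae = mean(vapply(vals, `[[`, 0, "gap_err")))
    if (vtot < best$val - 1e-12) {
      best <- list(val = vtot, theta = theta); n_bad <- 0
    } else {
      n_bad <- n_bad + 1
      if (n_bad >= cfg$patience) break
    }
  }
  model$params <- utils::relist(best$theta, skel)
  model$initialized <- TRUE
  list(model = model, history = do.call(rbind, hist))
}

#' Train a committee of models
#'
#' Trains `n` models on identical data with distinct seeds (different
#' initializations and batch orders), the query-by-committee setup used
#' for active learning.
#'
#' @param frames list of [labeled_frame()]s
#' @param n committee size (>= 2)
#' @param cfg a [train_config()]; member i uses `cfg$seed + i - 1`
#' @param model_factory function(seed) returning an untrained model;
#'   defaults to a descriptor model built from the first frame
#' @param w a [loss_weights()]
#' @param seeds optional explicit per-member seeds
#' @return list of trained models
#' @export
train_committee <- function(frames, n = 2, cfg = train_config(),
                            model_factory = NULL, w = loss_weights(),
                            seeds = NULL) {
  if (n < 2) stop("committee size must be >= 2")
  if (is.null(model_factory))
    model_factory <- function(seed) dense_model(frames[[1]]$geometry, seed = seed)
  if (is.null(seeds)) seeds <- cfg$seed + seq_len(n) - 1
  lapply(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    train_model(frames, model_factory(seeds[i]), w = w, cfg = cfg_i)$model
  })
}
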