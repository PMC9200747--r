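# Equivariant message-passing backbone (PaiNN-style).  Each atom carries
# scalar features s_i (rotation-invariant) and vector features v_i
# (rotation-equivariant).  Messages gather neighbor information within a
# cutoff through radial-basis filters on the interatomic distance and the
# unit displacement; updates mix scalar and vector channels per atom.
# Scalar features are read out into per-atom energies and summed, one head
# per independent diabatic element (off-diagonal heads share no weights
# with diagonal ones and carry no positivity constraint, since couplings
# must pass through zero).  Forward, position-gradient and
# parameter-gradient passes are all written out explicitly; the gradient
# of any scalar combination of the six outputs costs a single backward
# pass.

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }

#' Equivariant message-passing model
#'
#' @param n_feats feature width F
#' @param n_interactions message/update rounds
#' @param cutoff neighbor cutoff (Angstrom)
#' @param n_rbf radial basis size
#' @param n_readout readout hidden width
#' @param seed RNG seed for initialization
#' @param core optional CNNC core indices
#' @return a `dann_mpnn` potential model
#' @export
mpnn_model <- function(n_feats = 64L, n_interactions = 3L, cutoff = 5,
                       n_rbf = 16L, n_readout = 32L, seed = 1, core = NULL) {
  set.seed(seed)
  F <- n_feats; B <- n_rbf; Fr <- n_readout
  rmat <- function(a, b, sd = 1 / sqrt(b)) matrix(rnorm(a * b, sd = sd), a, b)
  inter <- lapply(seq_len(n_interactions), function(t) list(
    W_in = rmat(F, F), b_in = rep(0, F),
    W_phi = rmat(3 * F, F), b_phi = rep(0, 3 * F),
    W_rbf = rmat(3 * F, B), b_rbf = rep(0, 3 * F),
    W_U = rmat(F, F), W_V = rmat(F, F),
    W_u1 = rmat(F, 2 * F), b_u1 = rep(0, F),
    W_u2 = rmat(3 * F, F), b_u2 = rep(0, 3 * F)))
  heads <- lapply(1:6, function(k) list(
    W_r1 = rmat(Fr, F), b_r1 = rep(0, Fr),
    w_r2 = rnorm(Fr, sd = 0.05 / sqrt(Fr)), b_r2 = 0))
  params <- list(emb = rmat(18, F, sd = 1), elem_ref = matrix(0, 18, 6),
                 inter = inter, heads = heads)
  structure(list(params = params, n_feats = F, n_interactions = n_interactions,
                 cutoff = cutoff, n_rbf = B, n_readout = Fr, seed = seed,
                 core = core, counter = new_model_counter()),
            class = c("dann_mpnn", "dann_model"))
}

# edge list within the cutoff (both directions), with distances, unit
# vectors, radial basis values and cutoff envelope
.mpnn_edges <- function(model, pos) {
  n <- nrow(pos)
  rc <- model$cutoff
  B <- model$n_rbf
  src <- integer(0); dst <- integer(0)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    if (sum((pos[i, ] - pos[j, ])^2) < rc^2) { dst <- c(dst, i); src <- c(src, j) }
  }
  E <- length(src)
  if (E == 0)
    return(list(E = 0L, src = src, dst = dst))
  rvec <- pos[src, , drop = FALSE] - pos[dst, , drop = FALSE]  # j - i
  r <- sqrt(rowSums(rvec^2))
  rhat <- rvec / r
  ns <- seq_len(B)
  arg <- outer(r, ns * pi / rc)
  rbf <- sin(arg) / r
  drbf <- (outer(1 / r, ns * pi / rc) * cos(arg) - rbf / r)  # d rbf / d r
  fc <- 0.5 * (1 + cos(pi * r / rc))
  dfc <- -0.5 * pi / rc * sin(pi * r / rc)
  list(E = E, src = src, dst = dst, rvec = rvec, r = r, rhat = rhat,
       rbf = rbf, drbf = drbf, fc = fc, dfc = dfc)
}

.rowsum_to <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# forward pass with full cache for the backward pass
mpnn_forward <- function(model, z, pos) {
  p <- model$params
  F <- model$n_feats
  n <- length(z)
  ed <- .mpnn_edges(model, pos)
  s <- p$emb[z, , drop = FALSE]
  v <- list(matrix(0, n, F), matrix(0, n, F), matrix(0, n, F))
  cache <- list(edges = ed, z = z, layers = vector("list", model$n_interactions))
  for (t in seq_len(model$n_interactions)) {
    ip <- p$inter[[t]]
    lc <- list(s_in = s, v_in = v)
    # message
    z_in <- sweep(s %*% t(ip$W_in), 2, ip$b_in, "+")
    h_in <- silu(z_in)
    z_phi <- sweep(h_in %*% t(ip$W_phi), 2, ip$b_phi, "+")
    lc$z_in <- z_in; lc$h_in <- h_in; lc$z_phi <- z_phi
    if (ed$E > 0) {
      Wlin <- sweep(ed$rbf %*% t(ip$W_rbf), 2, ip$b_rbf, "+")
      We <- Wlin * ed$fc
      phi_j <- z_phi[ed$src, , drop = FALSE]
      prod_e <- phi_j * We
      a1 <- prod_e[, 1:F, drop = FALSE]
      a2 <- prod_e[, F + 1:F, drop = FALSE]
      a3 <- prod_e[, 2 * F + 1:F, drop = FALSE]
      lc$Wlin <- Wlin; lc$We <- We; lc$prod_e <- prod_e
      s <- s + .rowsum_to(a1, ed$dst, n)
      for (cmp in 1:3) {
        dv <- v[[cmp]][ed$src, , drop = FALSE] * a2 + ed$rhat[, cmp] * a3
        v[[cmp]] <- v[[cmp]] + .rowsum_to(dv, ed$dst, n)
      }
    }
    lc$s_mid <- s; lc$v_mid <- v
    # update
    Uv <- lapply(v, function(m) m %*% t(ip$W_U))
    Vv <- lapply(v, function(m) m %*% t(ip$W_V))
    vn <- sqrt(Vv[[1]]^2 + Vv[[2]]^2 + Vv[[3]]^2 + 1e-8)
    m_in <- cbind(s, vn)
    z_u1 <- sweep(m_in %*% t(ip$W_u1), 2, ip$b_u1, "+")
    h_u1 <- silu(z_u1)
    z_u2 <- sweep(h_u1 %*% t(ip$W_u2), 2, ip$b_u2, "+")
    bb1 <- z_u2[, 1:F, drop = FALSE]
    bb2 <- z_u2[, F + 1:F, drop = FALSE]
    bb3 <- z_u2[, 2 * F + 1:F, drop = FALSE]
    dotUV <- Uv[[1]] * Vv[[1]] + Uv[[2]] * Vv[[2]] + Uv[[3]] * Vv[[3]]
    lc$Uv <- Uv; lc$Vv <- Vv; lc$vn <- vn; lc$m_in <- m_in
    lc$z_u1 <- z_u1; lc$h_u1 <- h_u1; lc$z_u2 <- z_u2; lc$dotUV <- dotUV
    s <- s + bb2 + bb3 * dotUV
    for (cmp in 1:3) v[[cmp]] <- v[[cmp]] + bb1 * Uv[[cmp]]
    cache$layers[[t]] <- lc
  }
  # readout
  y <- numeric(6)
  ro <- vector("list", 6)
  for (k in 1:6) {
    hp <- model$params$heads[[k]]
    z_r1 <- sweep(s %*% t(hp$W_r1), 2, hp$b_r1, "+")
    h_r1 <- silu(z_r1)
    e_atom <- as.vector(h_r1 %*% hp$w_r2) + hp$b_r2 + p$elem_ref[cbind(z, k)]
    y[k] <- sum(e_atom)
    ro[[k]] <- list(z_r1 = z_r1, h_r1 = h_r1)
  }
  cache$s_out <- s; cache$v_out <- v; cache$readout <- ro
  list(y = y, s = s, v = v, cache = cache)
}

# backward pass for scalar sum(c6 * y): returns gradient w.r.t. positions
# and (optionally) the parameter gradients in the same structure as params
mpnn_backward <- function(model, fw, c6, want_params = FALSE) {
  p <- model$params
  F <- model$n_feats
  cache <- fw$cache
  ed <- cache$edges
  z <- cache$z
  n <- length(z)
  gpos <- matrix(0, n, 3)
  gp <- NULL
  if (want_params) {
    zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
      numeric(length(x))
    gp <- rapply(p, zero_like, how = "replace")
  }
  ds <- matrix(0, n, F)
  dv <- list(matrix(0, n, F), matrix(0, n, F), matrix(0, n, F))
  # readout
  for (k in 1:6) {
    if (c6[k] == 0) next
    hp <- p$heads[[k]]
    ro <- cache$readout[[k]]
    dh_r1 <- c6[k] * matrix(hp$w_r2, n, length(hp$w_r2), byrow = TRUE)
    dz_r1 <- dh_r1 * silu_grad(ro$z_r1)
    ds <- ds + dz_r1 %*% hp$W_r1
    if (want_params) {
      gp$heads[[k]]$W_r1 <- gp$heads[[k]]$W_r1 + crossprod(dz_r1, cache$s_out)
      gp$heads[[k]]$b_r1 <- gp$heads[[k]]$b_r1 + colSums(dz_r1)
      gp$heads[[k]]$w_r2 <- gp$heads[[k]]$w_r2 + c6[k] * colSums(ro$h_r1)
      gp$heads[[k]]$b_r2 <- gp$heads[[k]]$b_r2 + c6[k] * n
      for (i in seq_len(n))
        gp$elem_ref[z[i], k] <- gp$elem_ref[z[i], k] + c6[k]
    }
  }
  for (t in rev(seq_len(model$n_interactions))) {
    ip <- p$inter[[t]]
    lc <- cache$layers[[t]]
    # ---- update block (reverse) ----
    dUv <- list(matrix(0, n, F), matrix(0, n, F), matrix(0, n, F))
    dVv <- list(matrix(0, n, F), matrix(0, n, F), matrix(0, n, F))
    db1 <- matrix(0, n, F)
    for (cmp in 1:3) {
      db1 <- db1 + dv[[cmp]] * lc$Uv[[cmp]]
      dUv[[cmp]] <- dUv[[cmp]] + dv[[cmp]] *
        lc$z_u2[, 1:F, drop = FALSE]          # bb1
    }
    db2 <- ds
    db3 <- ds * lc$dotUV
    ddot <- ds * lc$z_u2[, 2 * F + 1:F, drop = FALSE]  # bb3
    for (cmp in 1:3) {
      dUv[[cmp]] <- dUv[[cmp]] + ddot * lc$Vv[[cmp]]
      dVv[[cmp]] <- dVv[[cmp]] + ddot * lc$Uv[[cmp]]
    }
    dz_u2 <- cbind(db1, db2, db3)
    dh_u1 <- dz_u2 %*% ip$W_u2
    dz_u1 <- dh_u1 * silu_grad(lc$z_u1)
    dm <- dz_u1 %*% ip$W_u1
    if (want_params) {
      gp$inter[[t]]$W_u2 <- gp$inter[[t]]$W_u2 + crossprod(dz_u2, lc$h_u1)
      gp$inter[[t]]$b_u2 <- gp$inter[[t]]$b_u2 + colSums(dz_u2)
      gp$inter[[t]]$W_u1 <- gp$inter[[t]]$W_u1 + crossprod(dz_u1, lc$m_in)
      gp$inter[[t]]$b_u1 <- gp$inter[[t]]$b_u1 + colSums(dz_u1)
    }
    ds_mid <- ds + dm[, 1:F, drop = FALSE]
    dvn <- dm[, F + 1:F, drop = FALSE]
    for (cmp in 1:3)
      dVv[[cmp]] <- dVv[[cmp]] + dvn * lc$Vv[[cmp]] / lc$vn
    dv_mid <- dv
    for (cmp in 1:3) {
      dv_mid[[cmp]] <- dv_mid[[cmp]] + dUv[[cmp]] %*% ip$W_U + dVv[[cmp]] %*% ip$W_V
      if (want_params) {
        gp$inter[[t]]$W_U <- gp$inter[[t]]$W_U + crossprod(dUv[[cmp]], lc$v_mid[[cmp]])
        gp$inter[[t]]$W_V <- gp$inter[[t]]$W_V + crossprod(dVv[[cmp]], lc$v_mid[[cmp]])
      }
    }
    # ---- message block (reverse) ----
    ds_pre <- ds_mid
    dv_pre <- dv_mid
    dz_phi <- matrix(0, n, 3 * F)
    if (ed$E > 0) {
      da1 <- ds_mid[ed$dst, , drop = FALSE]
      da2 <- matrix(0, ed$E, F)
      da3 <- matrix(0, ed$E, F)
      drhat <- matrix(0, ed$E, 3)
      for (cmp in 1:3) {
        dv_i <- dv_mid[[cmp]][ed$dst, , drop = FALSE]
        a2 <- lc$prod_e[, F + 1:F, drop = FALSE]
        a3 <- lc$prod_e[, 2 * F + 1:F, drop = FALSE]
        da2 <- da2 + dv_i * lc$v_in[[cmp]][ed$src, , drop = FALSE]
        da3 <- da3 + dv_i * ed$rhat[, cmp]
        drhat[, cmp] <- rowSums(dv_i * a3)
        dv_pre[[cmp]] <- dv_pre[[cmp]] + .rowsum_to(dv_i * a2, ed$src, n)
      }
      dprod <- cbind(da1, da2, da3)
      phi_j <- lc$z_phi[ed$src, , drop = FALSE]
      dphi_e <- dprod * lc$We
      dWe <- dprod * phi_j
      dz_phi <- .rowsum_to(dphi_e, ed$src, n)
      dWlin <- dWe * ed$fc
      dfc_e <- rowSums(dWe * lc$Wlin)
      drbf <- dWlin %*% ip$W_rbf
      if (want_params) {
        gp$inter[[t]]$W_rbf <- gp$inter[[t]]$W_rbf + crossprod(dWlin, ed$rbf)
        gp$inter[[t]]$b_rbf <- gp$inter[[t]]$b_rbf + colSums(dWlin)
      }
      dr_e <- dfc_e * ed$dfc + rowSums(drbf * ed$drbf)
      # rhat = rvec / r
      dot_dr <- rowSums(drhat * ed$rhat)
      dvec <- dr_e * ed$rhat + (drhat - dot_dr * ed$rhat) / ed$r
      for (cmp in 1:3) {
        agg_s <- rowsum(dvec[, cmp], ed$src)
        gpos[as.integer(rownames(agg_s)), cmp] <-
          gpos[as.integer(rownames(agg_s)), cmp] + agg_s
        agg_d <- rowsum(dvec[, cmp], ed$dst)
        gpos[as.integer(rownames(agg_d)), cmp] <-
          gpos[as.integer(rownames(agg_d)), cmp] - agg_d
      }
    }
    dh_in <- dz_phi %*% ip$W_phi
    dz_in <- dh_in * silu_grad(lc$z_in)
    ds_pre <- ds_pre + dz_in %*% ip$W_in
    if (want_params) {
      gp$inter[[t]]$W_phi <- gp$inter[[t]]$W_phi + crossprod(dz_phi, lc$h_in)
      gp$inter[[t]]$b_phi <- gp$inter[[t]]$b_phi + colSums(dz_phi)
      gp$inter[[t]]$W_in <- gp$inter[[t]]$W_in + crossprod(dz_in, lc$s_in)
      gp$inter[[t]]$b_in <- gp$inter[[t]]$b_in + colSums(dz_in)
    }
    ds <- ds_pre
    dv <- dv_pre
  }
  if (want_params) {
    for (i in seq_len(n))
      gp$emb[z[i], ] <- gp$emb[z[i], ] + ds[i, ]
  }
  list(gpos = gpos, gparams = gp)
}

#' Encode a geometry into atomic features
#'
#' Runs the message/update rounds and returns rotation-invariant scalar
#' features and rotation-equivariant vector features per atom.
#'
#' @param geom a [geometry()]
#' @param model a `dann_mpnn` model
#' @return list with `s` (N x F) and `v` (N x F x 3 array)
#' @export
encode <- function(geom, model) {
  if (!inherits(model, "dann_mpnn")) stop("encode expects an mpnn model")
  if (n_atoms(geom) < 2) stop("fewer than 2 atoms")
  if (!all(is.finite(geom$pos))) stop("non-finite positions")
  fw <- mpnn_forward(model, geom$z, geom$pos)
  varr <- array(0, c(nrow(fw$s), ncol(fw$s), 3))
  for (cmp in 1:3) varr[, , cmp] <- fw$v[[cmp]]
  list(s = fw$s, v = varr)
}

#' Read out the diabatic Hamiltonian from atomic features
#'
#' Maps the scalar features of each atom through six independent heads to
#' per-atom energies and sums them into the six independent elements of
#' the symmetric diabatic matrix (size-extensive by construction).
#'
#' @param geom the [geometry()] the features came from
#' @param model a `dann_mpnn` model
#' @return list with `d` (3x3 symmetric matrix)
#' @export
readout_diabatic <- function(geom, model) {
  fw <- mpnn_forward(model, geom$z, geom$pos)
  list(d = .y_to_d(fw$y))
}

#' @export
model_diabatic_impl.dann_mpnn <- function(model, geom, gradient) {
  if (n_atoms(geom) < 2) stop("fewer than 2 atoms")
  fw <- mpnn_forward(model, geom$z, geom$pos)
  d <- .y_to_d(fw$y)
  if (!gradient) return(list(d = d, grad = NULL))
  n <- n_atoms(geom)
  grad <- array(0, c(3, 3, n, 3))
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:6) {
    c6 <- numeric(6); c6[k] <- 1
    g <- mpnn_backward(model, fw, c6)$gpos
    grad[idx[k, 1], idx[k, 2], , ] <- g
    grad[idx[k, 2], idx[k, 1], , ] <- g
  }
  list(d = d, grad = grad)
}

#' @export
model_grad_combo_impl.dann_mpnn <- function(model, geom, w) {
  fw <- mpnn_forward(model, geom$z, geom$pos)
  mpnn_backward(model, fw, .w_to_c6(w))$gpos
}
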