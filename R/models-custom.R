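#' Wrap an arbitrary analytic diabatic surface as a potential model
#'
#' `fn(pos)` must return a list with `d` (symmetric 3x3, kcal/mol) and
#' `grad` (3 x 3 x N x 3 array of element gradients, kcal/mol/A).  Useful
#' for validating the dynamics stack against closed-form surfaces.
#'
#' @param fn evaluation function of the positions matrix
#' @param core optional CNNC core indices for isomer classification
#' @return a `dann_model`
#' @export
custom_model <- function(fn, core = NULL) {
  structure(list(fn = fn, core = core, counter = new_model_counter()),
            class = c("dann_custom", "dann_model"))
}

#' @export
model_diabatic_impl.dann_custom <- function(model, geom, gradient) {
  res <- model$fn(geom$pos)
  if (!gradient) res$grad <- NULL
  res
}

#' @export
model_grad_combo_impl.dann_custom <- function(model, geom, w) {
  res <- model$fn(geom$pos)
  n <- nrow(geom$pos)
  matrix(as.vector(w) %*% matrix(res$grad, nrow = 9), n, 3)
}

#' One-dimensional linear avoided-crossing model
#'
#' A two-atom system whose reactive coordinate is the x position of atom 1:
#' diabats `d00 = -slope * x`, `d11 = +slope * x`, constant coupling `d01`,
#' and a far-detached third state.  This is the textbook Landau-Zener
#' geometry: a single passage at speed v transfers between diabats with
#' probability `exp(-2 pi Gamma)`, `Gamma = d01^2 / (hbar v |slope diff|)`.
#'
#' @param slope diabatic slope (kcal/mol/A)
#' @param coupling constant diabatic coupling (kcal/mol)
#' @return a `dann_model` over a 2-atom geometry
#' @export
linear_crossing_model <- function(slope, coupling) {
  fn <- function(pos) {
    n <- nrow(pos)
    x <- pos[1, 1]
    d <- matrix(0, 3, 3)
    d[1, 1] <- -slope * x
    d[2, 2] <- slope * x
    d[3, 3] <- 1e4
    d[1, 2] <- d[2, 1] <- coupling
    grad <- array(0, c(3, 3, n, 3))
    grad[1, 1, 1, 1] <- -slope
    grad[2, 2, 1, 1] <- slope
    list(d = d, grad = grad)
  }
  custom_model(fn)
}

#' Saturating avoided-crossing model (Tully-style)
#'
#' One-dimensional scattering benchmark: diabats `-A tanh(x/w)` and
#' `+A tanh(x/w)` with constant coupling `b` (linear near the crossing,
#' flat asymptotically, so both adiabatic channels are open).  A single
#' passage at crossing speed v follows Landau-Zener statistics with
#' `Gamma = b^2 / (hbar v (2A/w))`.
#'
#' @param A asymptotic diabat level (kcal/mol)
#' @param w crossing width (A)
#' @param b constant diabatic coupling (kcal/mol)
#' @return a `dann_model` over a 2-atom geometry
#' @export
tanh_crossing_model <- function(A = 2, w = 0.6, b = 0.9) {
  fn <- function(pos) {
    n <- nrow(pos)
    x <- pos[1, 1]
    th <- tanh(x / w)
    d <- matrix(0, 3, 3)
    d[1, 1] <- -A * th
    d[2, 2] <- A * th
    d[3, 3] <- 1e4
    d[1, 2] <- d[2, 1] <- b
    grad <- array(0, c(3, 3, n, 3))
    sech2 <- (1 - th^2) / w
    grad[1, 1, 1, 1] <- -A * sech2
    grad[2, 2, 1, 1] <- A * sech2
    list(d = d, grad = grad)
  }
  custom_model(fn)
}
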