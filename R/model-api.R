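# PotentialModel surface.  A model maps a geometry to a symmetric 3x3
# diabatic Hamiltonian (kcal/mol) and, on request, to the Cartesian
# gradients of its six independent elements.  Three implementations ship
# with the package: the equivariant message-passing backbone
# ([mpnn_model()]), the internal-coordinate descriptor backbone
# ([dense_model()]) and the analytic oracle ([oracle_model()]).
#
# Gradient accounting: each backward pass for one scalar function of the
# positions counts as one gradient evaluation.  The rotated-gradient route
# differentiates every independent diabatic element (6 for three states);
# the direct adiabatic route differentiates one eigenvalue per requested
# state (2 for S0/S1).  The counter makes that cost difference observable.

#' Evaluate a model's diabatic Hamiltonian
#'
#' @param model a potential model (`dann_model`)
#' @param geom a [geometry()]
#' @param gradient if `TRUE`, also return the gradients of the six
#'   independent elements as a `3 x 3 x N x 3` array (symmetric in the first
#'   two indices); counts 6 gradient evaluations
#' @return list with `d` (3x3 symmetric matrix, kcal/mol) and `grad`
#'   (array or `NULL`)
#' @export
model_diabatic <- function(model, geom, gradient = TRUE) {
  res <- model_diabatic_impl(model, geom, gradient)
  if (gradient) bump_grad_counter(model, 6L)
  res
}

model_diabatic_impl <- function(model, geom, gradient) UseMethod("model_diabatic_impl")

#' Gradient of a weighted combination of diabatic elements
#'
#' Computes the Cartesian gradient of `sum_nm w_nm d_nm` in a single
#' backward pass; this is the primitive behind [direct_forces()] and counts
#' one gradient evaluation.
#'
#' @param model a potential model
#' @param geom a [geometry()]
#' @param w symmetric 3x3 weight matrix
#' @return N x 3 gradient matrix (kcal/mol/A)
#' @export
model_grad_combo <- function(model, geom, w) {
  res <- model_grad_combo_impl(model, geom, w)
  bump_grad_counter(model, 1L)
  res
}

model_grad_combo_impl <- function(model, geom, w) UseMethod("model_grad_combo_impl")

#' @export
print.dann_model <- function(x, ...) {
  cat(sprintf("<dann potential model: %s>\n", class(x)[1]))
  invisible(x)
}

new_model_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n_grad <- 0L
  e
}

bump_grad_counter <- function(model, k) {
  model$counter$n_grad <- model$counter$n_grad + as.integer(k)
  invisible(NULL)
}

#' Read or reset a model's gradient-evaluation counter
#'
#' @param model a potential model
#' @return the number of gradient evaluations since the last reset
#' @export
grad_counter <- function(model) model$counter$n_grad

#' @rdname grad_counter
#' @export
reset_grad_counter <- function(model) {
  model$counter$n_grad <- 0L
  invisible(model)
}

#' Full adiabatic evaluation of a model at a geometry
#'
#' One-stop evaluation used by the dynamics engine: diabatic matrix,
#' adiabatic energies and diagonalizer (with optional sign continuity
#' against a previous step), per-state forces, the S0/S1 force NACV and
#' derivative coupling, and the gap.
#'
#' @param model a potential model
#' @param geom a [geometry()]
#' @param prev_u optional previous diagonalizer for sign continuity
#' @param deg_tol degeneracy tolerance for the coupling division (kcal/mol)
#' @return list with `d`, `energies`, `u`, `forces`, `h01`, `k01`,
#'   `k01_defined`, `gap`
#' @export
adiabatic_eval <- function(model, geom, prev_u = NULL, deg_tol = 1e-6) {
  hd <- model_diabatic(model, geom, gradient = TRUE)
  sol <- adiabatize(hd$d, prev_u = prev_u)
  der <- rotated_gradient(list(d = hd$d, grad = hd$grad), sol, deg_tol = deg_tol)
  list(d = hd$d, energies = sol$energies, u = sol$u,
       forces = der$forces, h01 = der$h[["01"]], k01 = der$k[["01"]],
       k01_defined = der$k_defined[["01"]],
       gap = sol$energies[2] - sol$energies[1])
}
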