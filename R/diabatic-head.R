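# Adiabatization of the diabatic matrix and the rotated-gradient identity.
#
# The model predicts a smooth symmetric 3x3 diabatic Hamiltonian H_d(R).
# Diagonalizing it, (U^T H_d U)_nm = E_n delta_nm, gives the adiabatic
# energies; rotating the element-wise Cartesian gradient into the same
# basis gives, in one stroke, the adiabatic forces (diagonal, with a minus
# sign) and the force non-adiabatic coupling vectors h_nm (off-diagonal).
# The derivative coupling follows as k_nm = h_nm / (E_m - E_n) and diverges
# at conical intersections, where it is flagged undefined rather than
# clamped.

state_pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))  # 1-based index pairs (01,02,12)
pair_names <- c("01", "02", "12")

#' Diagonalize a diabatic Hamiltonian
#'
#' Returns the ascending adiabatic energies and the orthogonal diagonalizer
#' with a fixed per-column sign convention (largest-magnitude entry
#' positive), or sign continuity against a previous diagonalizer when
#' `prev_u` is supplied (used along trajectories to prevent spurious NACV
#' sign flips between steps).
#'
#' @param d symmetric 3x3 matrix (kcal/mol), or a list with element `d`
#' @param prev_u optional previous 3x3 diagonalizer for sign continuity
#' @param tol symmetry tolerance (relative)
#' @return list with `energies` (ascending, length 3) and `u` (3x3)
#' @export
adiabatize <- function(d, prev_u = NULL, tol = 1e-8) {
  if (is.list(d)) d <- d$d
  if (!is.matrix(d) || !all(dim(d) == c(3, 3)) || !all(is.finite(d)))
    stop("d must be a finite 3x3 matrix")
  scale <- max(abs(d), 1)
  if (max(abs(d - t(d))) > tol * scale)
    stop("diabatic Hamiltonian is not symmetric")
  es <- eigen((d + t(d)) / 2, symmetric = TRUE)
  ord <- order(es$values)            # base eigen() returns descending
  energies <- es$values[ord]
  u <- es$vectors[, ord, drop = FALSE]
  for (c in 1:3) {
    s <- if (!is.null(prev_u)) {
      if (sum(prev_u[, c] * u[, c]) >= 0) 1 else -1
    } else {
      if (u[which.max(abs(u[, c])), c] >= 0) 1 else -1
    }
    u[, c] <- s * u[, c]
  }
  structure(list(energies = energies, u = u), class = "dann_adiabatic")
}

#' Forces and couplings from the rotated-gradient identity
#'
#' Rotates the element-wise gradient of the diabatic matrix into the
#' adiabatic basis: the diagonal gives minus the adiabatic forces, the
#' off-diagonal gives the force NACVs h_nm; the derivative couplings are
#' k_nm = h_nm / (E_m - E_n) where the gap exceeds `deg_tol`, and are
#' flagged undefined below it (the divergence at a conical intersection is
#' physical, and silently clamping it would corrupt hopping dynamics).
#'
#' @param hd list with `d` (3x3) and `grad` (3 x 3 x N x 3 array) as
#'   returned by [model_diabatic()]
#' @param sol adiabatic solution from [adiabatize()]
#' @param deg_tol degeneracy tolerance for the k division, kcal/mol
#' @return list with `forces` (list of three N x 3 matrices), `h` and `k`
#'   (named lists over state pairs "01", "02", "12") and `k_defined` flags
#' @export
rotated_gradient <- function(hd, sol, deg_tol = 1e-6) {
  grad <- hd$grad
  if (is.null(grad)) stop("hd carries no element gradients")
  dims <- dim(grad)
  n <- dims[3]
  G <- matrix(grad, nrow = 9)          # 9 x 3N, element index fastest
  u <- sol$u
  rot <- function(a, b) {              # (U^T grad U)_ab as N x 3
    w <- as.vector(outer(u[, a], u[, b]))
    matrix(w %*% G, n, 3)
  }
  forces <- lapply(1:3, function(s) -rot(s, s))
  h <- list(); k <- list(); k_defined <- list()
  for (p in 1:3) {
    a <- state_pairs[p, 1]; b <- state_pairs[p, 2]
    hp <- rot(a, b)
    dE <- sol$energies[b] - sol$energies[a]
    h[[pair_names[p]]] <- hp
    if (abs(dE) > deg_tol) {
      k[[pair_names[p]]] <- hp / dE
      k_defined[[pair_names[p]]] <- TRUE
    } else {
      k[[pair_names[p]]] <- NULL
      k_defined[[pair_names[p]]] <- FALSE
    }
  }
  list(forces = forces, h = h, k = k, k_defined = k_defined)
}

#' Adiabatic forces by direct differentiation of the eigenvalues
#'
#' Differentiates E_n directly through the eigendecomposition
#' (dE_n = (U^T dH_d U)_nn, one backward pass per requested state), which
#' for two states costs 2 gradient evaluations instead of the 6 needed to
#' differentiate every independent diabatic element.  Near an exact
#' degeneracy (gap below `10 * deg_tol`) the eigen-derivative is
#' ill-conditioned and the rotated-gradient route is used instead.
#'
#' @param model a potential model
#' @param geom a [geometry()]
#' @param states integer vector of adiabatic state indices (0-based, < 3)
#' @param deg_tol degeneracy tolerance, kcal/mol
#' @return named list of N x 3 force matrices, names `"0"`, `"1"`, ...
#' @export
direct_forces <- function(model, geom, states = c(0L, 1L), deg_tol = 1e-6) {
  if (any(states >= 3L | states < 0L)) stop("requested state must be in 0..2")
  hd0 <- model_diabatic(model, geom, gradient = FALSE)
  sol <- adiabatize(hd0$d)
  gaps <- abs(diff(sol$energies))
  if (min(gaps) < 10 * deg_tol) {
    hd <- model_diabatic(model, geom, gradient = TRUE)
    der <- rotated_gradient(hd, sol, deg_tol = deg_tol)
    out <- lapply(states, function(s) der$forces[[s + 1L]])
  } else {
    out <- lapply(states, function(s) {
      w <- outer(sol$u[, s + 1L], sol$u[, s + 1L])
      -model_grad_combo(model, geom, w)
    })
  }
  stats::setNames(out, as.character(states))
}

#' Branching-plane directions at a near-degenerate geometry
#'
#' Computes the unit gap-gradient direction g (proportional to
#' grad(E1 - E0)) and the unit force-NACV direction h at a geometry whose
#' S0/S1 gap lies below the conical-intersection window.  Far from the
#' seam the two vectors lose their meaning, so the function refuses to
#' evaluate there.
#'
#' @param model a potential model
#' @param geom a [geometry()]
#' @param ci_window gap window in eV (default 0.2 eV)
#' @return list with unit `g` and `h_dir` (N x 3) and the `origin` geometry
#' @export
branching_plane <- function(model, geom, ci_window = 0.2) {
  ev <- adiabatic_eval(model, geom)
  window_kcal <- ci_window * dann_constants$ev_to_kcal
  if (ev$gap > window_kcal)
    stop(sprintf("gap %.3f kcal/mol above the CI window (%.3f kcal/mol)",
                 ev$gap, window_kcal))
  g <- -(ev$forces[[2]] - ev$forces[[1]])   # grad(E1 - E0)
  h <- ev$h01
  normalize <- function(v) v / sqrt(sum(v^2))
  structure(list(g = normalize(g), h_dir = normalize(h), origin = geom,
                 gap = ev$gap), class = "dann_branching_plane")
}

#' Scan the potential over the branching plane
#'
#' Evaluates diabatic elements, adiabatic energies and the gap on an
#' n x n grid of displacements x*g + y*h around the branching-plane
#' origin, the standard way of exhibiting the conical topography of an
#' intersection.
#'
#' @param model a potential model
#' @param bp a branching plane from [branching_plane()]
#' @param extent half-width of the scan in Angstrom (> 0)
#' @param n grid points per axis
#' @return data.frame with columns x, y, d00, d11, d22, d01, e0, e1, gap
#' @export
scan_branching_plane <- function(model, bp, extent, n = 11L) {
  if (extent <= 0) stop("extent must be positive")
  xs <- if (n == 1L) 0 else seq(-extent, extent, length.out = n)
  grid <- expand.grid(x = xs, y = xs)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- bp$origin
    g$pos <- g$pos + grid$x[i] * bp$g + grid$y[i] * bp$h_dir
    hd <- model_diabatic(model, g, gradient = FALSE)
    sol <- adiabatize(hd$d)
    c(d00 = hd$d[1, 1], d11 = hd$d[2, 2], d22 = hd$d[3, 3], d01 = hd$d[1, 2],
      e0 = sol$energies[1], e1 = sol$energies[2],
      gap = sol$energies[2] - sol$energies[1])
  })
  cbind(grid, as.data.frame(do.call(rbind, res)))
}

#' Write a branching-plane scan as tabular text
#'
#' @param scan data.frame from [scan_branching_plane()]
#' @param path output path (tab-separated)
#' @return `path`, invisibly
#' @export
write_branching_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
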