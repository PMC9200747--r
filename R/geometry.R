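#' Molecular geometry
#'
#' A validated container for one molecular configuration: atomic numbers,
#' Cartesian positions in Angstrom, optional velocities in Angstrom/fs,
#' per-atom masses in amu (derived from the atomic numbers) and an isomer
#' label used by the reference-geometry loss and by yield analysis.
#'
#' @param z integer vector of atomic numbers (length N >= 2)
#' @param pos N x 3 numeric matrix of positions (Angstrom)
#' @param vel optional N x 3 numeric matrix of velocities (Angstrom/fs)
#' @param isomer one of "cis", "trans", "unknown"
#' @return an object of class `dann_geometry`
#' @export
geometry <- function(z, pos, vel = NULL, isomer = "unknown") {
  z <- as.integer(z)
  pos <- as.matrix(pos)
  if (length(z) < 2) stop("a geometry needs at least 2 atoms")
  if (!is.numeric(pos) || ncol(pos) != 3 || nrow(pos) != length(z))
    stop("pos must be an N x 3 numeric matrix matching length(z)")
  if (!all(is.finite(pos))) stop("non-finite coordinates")
  if (!is.null(vel)) {
    vel <- as.matrix(vel)
    if (!all(dim(vel) == dim(pos))) stop("velocity shape must match positions")
    if (!all(is.finite(vel))) stop("non-finite velocities")
  }
  if (!isomer %in% c("cis", "trans", "unknown"))
    stop("isomer must be cis, trans or unknown")
  m <- atomic_masses(z)
  if (any(m <= 0)) stop("masses must be strictly positive")
  structure(list(z = z, pos = unname(pos), vel = if (is.null(vel)) NULL else unname(vel),
                 masses = m, isomer = isomer),
            class = "dann_geometry")
}

#' @export
print.dann_geometry <- function(x, ...) {
  cat(sprintf("<dann_geometry: %d atoms (%s), isomer=%s, velocities=%s>\n",
              length(x$z), paste(unique(element_symbol(x$z)), collapse = ","),
              x$isomer, if (is.null(x$vel)) "no" else "yes"))
  invisible(x)
}

n_atoms <- function(g) length(g$z)

#' Labeled training frame
#'
#' A geometry together with quantum-chemistry-style labels: ground and
#' excited adiabatic energies (kcal/mol), per-state forces (kcal/mol/A) and
#' optionally the force non-adiabatic coupling vector h01 (kcal/mol/A, sign
#' arbitrary).  `provenance` records how the frame was generated.
#'
#' @param geometry a [geometry()] object
#' @param e0,e1 adiabatic energies, kcal/mol, with `e1 >= e0`
#' @param f0,f1 N x 3 force matrices, kcal/mol/A
#' @param h01 optional N x 3 force-NACV matrix (absent in ZN-only datasets)
#' @param provenance one of "namd", "normal_mode", "rot_inv", "active_learning"
#' @return an object of class `dann_frame`
#' @export
labeled_frame <- function(geometry, e0, e1, f0, f1, h01 = NULL,
                          provenance = "normal_mode") {
  if (!inherits(geometry, "dann_geometry")) stop("geometry must be a dann_geometry")
  n <- n_atoms(geometry)
  chk <- function(m, nm) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(n, 3))) stop(nm, " must be N x 3")
    if (!all(is.finite(m))) stop("non-finite values in ", nm)
    unname(m)
  }
  if (!is.finite(e0) || !is.finite(e1)) stop("non-finite energies")
  if (e1 < e0) stop("label invariant violated: e1 < e0")
  if (!provenance %in% c("namd", "normal_mode", "rot_inv", "active_learning"))
    stop("unknown provenance: ", provenance)
  structure(list(geometry = geometry, e0 = e0, e1 = e1,
                 f0 = chk(f0, "f0"), f1 = chk(f1, "f1"),
                 h01 = if (is.null(h01)) NULL else chk(h01, "h01"),
                 provenance = provenance),
            class = "dann_frame")
}

#' @export
print.dann_frame <- function(x, ...) {
  cat(sprintf("<dann_frame: %d atoms, e0=%.3f e1=%.3f kcal/mol, gap=%.3f, h01=%s, %s>\n",
              n_atoms(x$geometry), x$e0, x$e1, x$e1 - x$e0,
              if (is.null(x$h01)) "absent" else "present", x$provenance))
  invisible(x)
}

# rigid-body helpers used across tests and sampling
rotate_geometry <- function(g, R) {
  g$pos <- g$pos %*% t(R)
  if (!is.null(g$vel)) g$vel <- g$vel %*% t(R)
  g
}

random_rotation <- function() {
  # QR of a Gaussian matrix, determinant fixed to +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
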