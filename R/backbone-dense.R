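# Internal-coordinate descriptor backbone: fixed symmetry-adapted
# descriptors (bond stretches, bends, torsion cosines relative to a
# molecular template) feeding a small one-hidden-layer dense network with
# six output heads, one per independent diabatic element.  Everything is
# analytic: descriptor Jacobians come from the compiled internal-coordinate
# kernels, so element gradients, the single-backward-pass combo gradient
# and the mixed parameter/position second derivatives needed to train on
# forces and NACVs are all closed-form.  The descriptors are invariant
# under rotation, translation and reflection, which matches the symmetries
# of a real molecular Hamiltonian.

.covalent_radii <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
                     1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06)

# connectivity and internal-coordinate lists from a template geometry
.molecular_graph <- function(z, pos) {
  n <- length(z)
  rc <- .covalent_radii[z]
  bonds <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (r < 1.3 * (rc[i] + rc[j])) bonds <- rbind(bonds, c(i, j))
  }
  adj <- lapply(1:n, function(i)
    sort(unique(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))))
  angles <- NULL
  for (j in 1:n) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      angles <- rbind(angles, t(rbind(cmb[1, ], j, cmb[2, ])))
    }
  }
  torsions <- NULL
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      if (i != l) torsions <- rbind(torsions, c(i, j, k, l))
  }
  list(bonds = bonds, angles = angles,
       torsions = if (is.null(torsions)) matrix(0L, 0, 4) else torsions)
}

#' Internal-coordinate descriptor model
#'
#' Builds the descriptor set from a template geometry (bond stretches and
#' bends, linear and squared, plus torsion-cosine features `cos(k phi)`
#' for k = 1..torsion_order, all relative to the template values) and
#' initializes a one-hidden-layer tanh network with a linear skip
#' connection and six diabatic-element heads.
#'
#' @param template a [geometry()] defining the connectivity
#' @param hidden hidden width
#' @param seed RNG seed for the parameter initialization
#' @param core optional CNNC core indices (carried for classification)
#' @param torsion_order highest torsion harmonic in the descriptor set
#' @return a `dann_dense` potential model
#' @export
dense_model <- function(template, hidden = 32L, seed = 1, core = NULL,
                        torsion_order = 6L) {
  graph <- .molecular_graph(template$z, template$pos)
  ref <- internal_coords_cpp(template$pos, graph$bonds, graph$angles,
                             graph$torsions, jacobian = FALSE)
  n_tor <- nrow(graph$torsions)
  torsion_order <- as.integer(torsion_order)
  dim_d <- 2L * nrow(graph$bonds) + 2L * nrow(graph$angles) +
    torsion_order * n_tor
  set.seed(seed)
  params <- list(
    W1 = matrix(rnorm(hidden * dim_d, sd = 1 / sqrt(dim_d)), hidden, dim_d),
    b1 = rnorm(hidden, sd = 0.1),
    W2 = matrix(rnorm(6 * hidden, sd = 0.1 / sqrt(hidden)), 6, hidden),
    W3 = matrix(0, 6, dim_d),           # linear skip connection
    b2 = rep(0, 6))
  structure(list(z = template$z, graph = graph, ref = ref, hidden = hidden,
                 dim_d = dim_d, params = params, seed = seed, core = core,
                 torsion_order = torsion_order,
                 fingerprint = NA_character_,
                 counter = new_model_counter()),
            class = c("dann_dense", "dann_model"))
}

# descriptors + Jacobian (D, and J as dim_d x 3N, atom-major columns)
dense_descriptors <- function(model, geom, jacobian = TRUE) {
  ic <- internal_coords_cpp(geom$pos, model$graph$bonds, model$graph$angles,
                            model$graph$torsions, jacobian = jacobian)
  tor <- as.vector(ic$torsions)
  tor_ref <- as.vector(model$ref$torsions)
  db <- as.vector(ic$bonds) - as.vector(model$ref$bonds)
  da <- as.vector(ic$angles) - as.vector(model$ref$angles)
  ks <- seq_len(model$torsion_order %||% 3L)
  feat_t <- as.vector(vapply(ks, function(k) cos(k * tor) - cos(k * tor_ref),
                             numeric(length(tor))))
  # stretches and bends enter both linearly and squared, so harmonic terms
  # are linear in the basis; torsions enter as low-order cosines
  D <- c(db, db^2, da, da^2, feat_t)
  if (!jacobian) return(list(D = D))
  Jt <- do.call(rbind, lapply(ks, function(k)
    (-k * sin(k * tor)) * ic$J_torsions))
  J <- rbind(ic$J_bonds, 2 * db * ic$J_bonds, ic$J_angles, 2 * da * ic$J_angles,
             Jt)
  list(D = D, J = J)
}

dense_forward <- function(model, D) {
  p <- model$params
  z1 <- as.vector(p$W1 %*% D + p$b1)
  h <- tanh(z1)
  y <- as.vector(p$W2 %*% h + p$W3 %*% D + p$b2)
  list(y = y, h = h, sp = 1 - h^2)
}

.y_to_d <- function(y) {
  d <- matrix(0, 3, 3)
  d[1, 1] <- y[1]; d[2, 2] <- y[2]; d[3, 3] <- y[3]
  d[1, 2] <- d[2, 1] <- y[4]
  d[1, 3] <- d[3, 1] <- y[5]
  d[2, 3] <- d[3, 2] <- y[6]
  d
}

#' @export
model_diabatic_impl.dann_dense <- function(model, geom, gradient) {
  dd <- dense_descriptors(model, geom, jacobian = gradient)
  fw <- dense_forward(model, dd$D)
  d <- .y_to_d(fw$y)
  if (!gradient) return(list(d = d, grad = NULL))
  p <- model$params
  n <- nrow(geom$pos)
  grad <- array(0, c(3, 3, n, 3))
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:6) {
    gd <- as.vector(crossprod(p$W1, p$W2[k, ] * fw$sp)) + p$W3[k, ]
    gpos <- matrix(as.vector(gd %*% dd$J), n, 3, byrow = TRUE)
    a <- idx[k, 1]; b <- idx[k, 2]
    grad[a, b, , ] <- gpos
    grad[b, a, , ] <- gpos
  }
  list(d = d, grad = grad)
}

#' @export
model_grad_combo_impl.dann_dense <- function(model, geom, w) {
  dd <- dense_descriptors(model, geom, jacobian = TRUE)
  fw <- dense_forward(model, dd$D)
  p <- model$params
  c6 <- .w_to_c6(w)
  q <- as.vector(crossprod(p$W2, c6)) * fw$sp
  gd <- as.vector(crossprod(p$W1, q)) + as.vector(crossprod(p$W3, c6))
  matrix(as.vector(gd %*% dd$J), nrow(geom$pos), 3, byrow = TRUE)
}

# symmetric 3x3 weight matrix -> coefficients of the 6 independent elements
.w_to_c6 <- function(w) {
  c(w[1, 1], w[2, 2], w[3, 3], w[1, 2] + w[2, 1], w[1, 3] + w[3, 1],
    w[2, 3] + w[3, 2])
}

# parameter vector <-> list
dense_flatten <- function(p) c(as.vector(p$W1), p$b1, as.vector(p$W2),
                               as.vector(p$W3), p$b2)

dense_unflatten <- function(model, theta) {
  H <- model$hidden; D <- model$dim_d
  i <- 0
  W1 <- matrix(theta[i + seq_len(H * D)], H, D); i <- i + H * D
  b1 <- theta[i + seq_len(H)]; i <- i + H
  W2 <- matrix(theta[i + seq_len(6 * H)], 6, H); i <- i + 6 * H
  W3 <- matrix(theta[i + seq_len(6 * D)], 6, D); i <- i + 6 * D
  b2 <- theta[i + seq_len(6)]
  list(W1 = W1, b1 = b1, W2 = W2, W3 = W3, b2 = b2)
}

#' Save a model checkpoint
#'
#' Self-describing JSON container with the architecture, parameters,
#' template information, dataset fingerprint and seed.
#'
#' @param model a `dann_dense` model
#' @param path output path
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "dann_dense")) stop("checkpoints support dense models")
  obj <- list(type = "dense", z = model$z, hidden = model$hidden,
              dim_d = model$dim_d, seed = model$seed,
              torsion_order = model$torsion_order,
              fingerprint = model$fingerprint,
              core = model$core,
              graph = lapply(model$graph, function(m) as.vector(t(m))),
              graph_dims = lapply(model$graph, dim),
              ref = model$ref[c("bonds", "angles", "torsions")],
              params = lapply(model$params, function(x)
                if (is.matrix(x)) list(dim = dim(x), v = as.vector(x))
                else list(dim = NULL, v = as.vector(x))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint path
#' @return a `dann_dense` model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "dense")) stop("unknown checkpoint type")
  graph <- list()
  for (nm in names(obj$graph)) {
    dm <- unlist(obj$graph_dims[[nm]])
    graph[[nm]] <- matrix(as.integer(unlist(obj$graph[[nm]])), nrow = dm[1],
                          ncol = dm[2], byrow = TRUE)
  }
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(unlist(p$v), p$dim[[1]], p$dim[[2]])
    else unlist(p$v)
  })
  structure(list(z = as.integer(obj$z), graph = graph,
                 ref = lapply(obj$ref, unlist), hidden = as.integer(obj$hidden),
                 dim_d = as.integer(obj$dim_d), params = params,
                 seed = obj$seed, core = if (is.null(obj$core)) NULL
                                         else as.integer(unlist(obj$core)),
                 torsion_order = as.integer(obj$torsion_order %||% 3L),
                 fingerprint = obj$fingerprint,
                 counter = new_model_counter()),
            class = c("dann_dense", "dann_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
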