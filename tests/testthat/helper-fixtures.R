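# Shared fixtures, all generated in code.  The cache lives for the duration
# of one test file.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_spec <- function() fixture("spec", oracle_spec())

fx_oracle_model <- function() fixture("om", oracle_model(fx_spec()))

fx_cis_min <- function() fixture("cis_min",
                                 oracle_min_geometry(fx_spec(), "cis"))

fx_trans_min <- function() fixture("trans_min",
                                   oracle_min_geometry(fx_spec(), "trans"))

# a mildly distorted geometry away from any degeneracy
fx_geom <- function(seed = 1, sd = 0.04) {
  spec <- fx_spec()
  set.seed(seed)
  geometry(spec$z, spec$pos_trans + matrix(rnorm(30, sd = sd), 10, 3))
}

fx_frames <- function(n_nm = 40, n_rot = 30, seed = 101) {
  key <- sprintf("frames_%d_%d_%d", n_nm, n_rot, seed)
  fixture(key, {
    spec <- fx_spec()
    gs <- c(generate_geometries(spec, "normal_mode", n = n_nm, T = 300,
                                seed = seed, isomer = "cis"),
            generate_geometries(spec, "normal_mode", n = n_nm, T = 300,
                                seed = seed + 1, isomer = "trans"),
            generate_geometries(spec, "rot_inv", n = n_rot, seed = seed + 2))
    lapply(gs, function(g) oracle_labels(spec, g))
  })
}

# two constant-predictor models whose E1 differs by `delta` (via d11),
# everything else identical; used for committee-variance arithmetic
fx_constant_pair <- function(delta = 2) {
  mk <- function(shift) {
    custom_model(function(pos) {
      n <- nrow(pos)
      d <- diag(c(0, 10 + shift, 1e4))
      list(d = d, grad = array(0, c(3, 3, n, 3)))
    })
  }
  list(mk(-delta / 2), mk(delta / 2))
}

rand_sym3 <- function() {
  m <- matrix(rnorm(9, sd = 10), 3)
  (m + t(m)) / 2
}
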