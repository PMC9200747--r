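# Committee-based active learning: run surface hopping with the current
# model, score the visited geometries by committee disagreement and by
# proximity to the intersection seam, acquire reference labels for the
# top-scoring ones, retrain, repeat.

#' Committee variance at a geometry
#'
#' Across-model population variance of the predicted energies and forces,
#' combined with equal weight: the energy part averages the variances of
#' E0 and E1 ((kcal/mol)^2), the force part averages the per-component
#' variances ((kcal/mol/A)^2).
#'
#' @param models list of >= 2 potential models
#' @param geom a [geometry()]
#' @return list with `total`, `var_e0`, `var_e1`, `var_force`
#' @export
committee_variance <- function(models, geom) {
  if (length(models) < 2) stop("need at least 2 committee members")
  evs <- lapply(models, function(m) adiabatic_eval(m, geom))
  popvar <- function(x) mean((x - mean(x))^2)
  e0 <- vapply(evs, function(e) e$energies[1], 0)
  e1 <- vapply(evs, function(e) e$energies[2], 0)
  fstack <- lapply(evs, function(e) cbind(as.vector(e$forces[[1]]),
                                          as.vector(e$forces[[2]])))
  fmat <- do.call(rbind, lapply(fstack, as.vector))   # models x (2*3N)
  var_f <- mean(apply(fmat, 2, popvar))
  out <- list(var_e0 = popvar(e0), var_e1 = popvar(e1), var_force = var_f)
  out$total <- mean(c(out$var_e0, out$var_e1, out$var_force))
  out
}

#' Conical-intersection proximity score
#'
#' A monotone-decreasing function of the predicted S0/S1 gap: by default
#' the gap itself (selected ascending); alternatively an exponential
#' weight `exp(-gap/tau)` (selected descending).  Gaps below 4.6 kcal/mol
#' (0.2 eV) count as "small" by the usual convention.
#'
#' @param model a potential model
#' @param geom a [geometry()]
#' @param mode "gap" or "exp"
#' @param tau decay constant for the exponential mode (kcal/mol)
#' @return list with `gap` (kcal/mol), `score`, `small_gap` flag
#' @export
ci_proximity_score <- function(model, geom, mode = c("gap", "exp"), tau = 4.6) {
  mode <- match.arg(mode)
  sol <- adiabatize(model_diabatic(model, geom, gradient = FALSE)$d)
  gap <- sol$energies[2] - sol$energies[1]
  score <- if (mode == "gap") gap else exp(-gap / tau)
  list(gap = gap, score = score, small_gap = gap < 4.6)
}

#' Select an acquisition batch
#'
#' `variance` mode takes the top-k geometries by committee variance;
#' `mixed` mode takes ceiling(k/2) by variance and then floor(k/2) by
#' smallest predicted gap from the remainder.  Ties break
#' deterministically by candidate index.
#'
#' @param candidates list of [geometry()] candidates
#' @param models committee of potential models
#' @param k batch size (<= number of candidates)
#' @param mode "variance" or "mixed"
#' @return integer indices of the selected candidates
#' @export
select_batch <- function(candidates, models, k, mode = c("variance", "mixed")) {
  mode <- match.arg(mode)
  nc <- length(candidates)
  if (nc == 0) stop("empty candidate set")
  if (k > nc) stop("k exceeds the number of candidates")
  vars <- vapply(candidates, function(g) committee_variance(models, g)$total, 0)
  ord_var <- order(-vars, seq_len(nc))
  if (mode == "variance") return(ord_var[seq_len(k)])
  k_var <- ceiling(k / 2)
  sel <- ord_var[seq_len(k_var)]
  rest <- setdiff(seq_len(nc), sel)
  gaps <- vapply(candidates[rest], function(g)
    ci_proximity_score(models[[1]], g)$gap, 0)
  sel_gap <- rest[order(gaps, rest)][seq_len(k - k_var)]
  c(sel, sel_gap)
}

#' One active-learning cycle
#'
#' Runs surface-hopping trajectories with the first committee member from
#' thermal initial conditions, pools the visited geometries, selects an
#' acquisition batch, labels it with the oracle, retrains both members on
#' the enlarged dataset (warm start), and reports held-out gap MAE before
#' and after plus the trajectory-abort fraction.
#'
#' @param models committee (list of trained models)
#' @param oracle_spec_ the [oracle_spec()] providing reference labels
#' @param frames current training frames
#' @param holdout held-out frames for the gap-MAE metric
#' @param start_geometry basin geometry (or list of geometries, cycled
#'   over trajectories) for trajectory initial conditions
#' @param n_acquire number of frames to acquire (0 = identity cycle)
#' @param n_traj surface-hopping trajectories per cycle
#' @param horizon trajectory horizon (fs)
#' @param T temperature (K)
#' @param seed RNG seed
#' @param cfg retraining [train_config()]
#' @param w [loss_weights()] for retraining
#' @param select_mode acquisition mode, see [select_batch()]
#' @param e_window acquisition energy window (kcal/mol): labeled frames
#'   whose ground-state energy exceeds the lowest training energy by more
#'   than this are discarded, the usual guard against the unphysical
#'   structures early-cycle models drive trajectories into
#' @param val_frames optional fixed validation frames for the retrains (a
#'   stable model-selection criterion across cycles)
#' @param model_factory optional function(seed) returning a fresh untrained
#'   model; when given, retrains are cold starts from a fixed
#'   initialization per member, so the only thing that changes across
#'   cycles is the training data (the most reproducible protocol)
#' @return list with `models`, `frames`, `acquired`, `metrics`
#' @export
al_cycle <- function(models, oracle_spec_, frames, holdout, start_geometry,
                     n_acquire = 200, n_traj = 10, horizon = 400, T = 300,
                     seed = 1, cfg = train_config(), w = loss_weights(),
                     select_mode = "mixed", e_window = 300,
                     val_frames = NULL, model_factory = NULL) {
  mae_before <- holdout_gap_mae(models, holdout)
  if (n_acquire == 0)
    return(list(models = models, frames = frames, acquired = list(),
                metrics = data.frame(mae_before = mae_before,
                                     mae_after = mae_before, abort_frac = 0)))
  starts <- if (inherits(start_geometry, "dann_geometry")) list(start_geometry)
            else start_geometry
  # initial conditions from ground-state reference MD (cheap classical-MD
  # step); the excited-state dynamics themselves run on the learned model
  ref_model <- oracle_model(oracle_spec_)
  snaps <- unlist(lapply(seq_along(starts), function(i)
    sample_initial_conditions(ref_model, starts[[i]], T = T,
                              n = ceiling(n_traj / length(starts)),
                              seed = seed + i)), recursive = FALSE)
  cands <- list()
  n_abort <- 0
  for (k in seq_len(min(n_traj, length(snaps)))) {
    tr <- run_trajectory(snaps[[k]], models[[1]], scheme = "fs",
                         horizon = horizon, seed = seed + k, stride = 4L,
                         core = models[[1]]$core)
    if (tr$aborted) n_abort <- n_abort + 1
    cands <- c(cands, lapply(tr$frames[-1], function(f)
      geometry(f$z, f$pos)))
  }
  if (length(cands) == 0) stop("NAMD produced no candidate geometries")
  # walk the acquisition ranking, labeling until the in-window budget is
  # filled: high-variance/low-gap structures that turn out unphysical when
  # labeled are discarded and the next candidates take their place
  e_floor <- min(vapply(frames, `[[`, 0, "e0"))
  vars <- vapply(cands, function(g) committee_variance(models, g)$total, 0)
  ord_var <- order(-vars, seq_along(cands))
  ord_gap <- if (select_mode == "mixed") {
    gaps <- vapply(cands, function(g)
      ci_proximity_score(models[[1]], g)$gap, 0)
    order(gaps, seq_along(cands))
  } else integer(0)
  n_var <- if (select_mode == "mixed") ceiling(n_acquire / 2) else n_acquire
  acquired <- list()
  taken <- rep(FALSE, length(cands))
  fill_from <- function(ord, budget) {
    for (i in ord) {
      if (budget == 0) break
      if (taken[i]) next
      fr <- oracle_labels(oracle_spec_, cands[[i]], provenance = "active_learning")
      taken[i] <<- TRUE
      if (fr$e0 <= e_floor + e_window) {
        acquired[[length(acquired) + 1L]] <<- fr
        budget <- budget - 1
      }
    }
  }
  fill_from(ord_var, n_var)
  if (select_mode == "mixed")
    fill_from(ord_gap, n_acquire - min(n_var, length(acquired)))
  if (length(acquired) == 0)
    return(list(models = models, frames = frames, acquired = list(),
                metrics = data.frame(mae_before = mae_before,
                                     mae_after = mae_before,
                                     abort_frac = n_abort / n_traj,
                                     n_acquired = 0L)))
  frames2 <- c(frames, acquired)
  # fixed per-member retrain seeds: across cycles the only thing that
  # changes is the data, so the held-out metric tracks the acquisitions
  models2 <- lapply(seq_along(models), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1
    start <- if (is.null(model_factory)) models[[i]]
             else model_factory(cfg$seed + i - 1)
    train_model(frames2, start, w = w, cfg = cfg_i,
                val_frames = val_frames)$model
  })
  metrics <- data.frame(mae_before = mae_before,
                        mae_after = holdout_gap_mae(models2, holdout),
                        abort_frac = n_abort / n_traj,
                        n_acquired = length(acquired))
  list(models = models2, frames = frames2, acquired = acquired,
       metrics = metrics)
}

#' Held-out gap mean absolute error
#'
#' @param model a potential model
#' @param frames labeled frames
#' @return MAE of the predicted S0/S1 gap, kcal/mol
#' @export
holdout_gap_mae <- function(model, frames) {
  models <- if (inherits(model, "dann_model")) list(model) else model
  errs <- vapply(frames, function(fr) {
    gaps <- vapply(models, function(m) {
      sol <- adiabatize(model_diabatic(m, fr$geometry, gradient = FALSE)$d)
      sol$energies[2] - sol$energies[1]
    }, 0)
    abs(mean(gaps) - (fr$e1 - fr$e0))
  }, 0)
  mean(errs)
}

#' Run several active-learning cycles
#'
#' Repeats [al_cycle()] (default five cycles) and collects the per-cycle
#' metrics.
#'
#' @inheritParams al_cycle
#' @param cycles number of cycles
#' @return list with final `models`, `frames` and a `metrics` data.frame
#' @export
run_active_learning <- function(models, oracle_spec_, frames, holdout,
                                start_geometry, cycles = 5, n_acquire = 200,
                                n_traj = 10, horizon = 400, T = 300, seed = 1,
                                cfg = train_config(), w = loss_weights(),
                                e_window = 300, val_frames = NULL,
                                model_factory = NULL) {
  metrics <- list()
  for (cy in seq_len(cycles)) {
    res <- al_cycle(models, oracle_spec_, frames, holdout, start_geometry,
                    n_acquire = n_acquire, n_traj = n_traj, horizon = horizon,
                    T = T, seed = seed + 1000 * cy, cfg = cfg, w = w,
                    e_window = e_window, val_frames = val_frames,
                    model_factory = model_factory)
    models <- res$models
    frames <- res$frames
    metrics[[cy]] <- cbind(cycle = cy, res$metrics)
  }
  list(models = models, frames = frames, metrics = do.call(rbind, metrics))
}
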