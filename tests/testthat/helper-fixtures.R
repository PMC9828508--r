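# Shared desk-scale water fixture: a labelled synthetic trajectory plus
# memoised active-learning runs, reused by the evaluation and end-to-end
# tests so the expensive loops execute once per session.

.fixture_env <- new.env(parent = emptyenv())

water_trajectory <- function(n_frames = 1000L, temperature = 300) {
  key <- sprintf("traj_%d_%g", n_frames, temperature)
  if (is.null(.fixture_env[[key]])) {
    sys <- default_systems("water")
    traj <- suppressWarnings(
      sample_configurations(sys$geometry, temperature, n_frames, seed = 20260101L))
    .fixture_env[[key]] <- label_energies(traj, sys$pes)
  }
  .fixture_env[[key]]
}

# PSO settings for the learning loops: swarm parameters as in pso_control()
# defaults, with a desk-scale swarm and iteration cap.
al_pso <- function(seed = 1L) pso_control(n_particles = 12L, max_iter = 40L,
                                          seed = seed)

water_al_run <- function(seed, batch_size = 1L, acquisition = "mepe",
                         mode = "per_atom", max_train = 59L, atoms = NULL) {
  key <- sprintf("run_%d_%d_%s_%s_%d_%s", seed, batch_size, acquisition, mode,
                 max_train, paste(atoms, collapse = "-"))
  if (is.null(.fixture_env[[key]])) {
    traj <- water_trajectory()
    pes <- default_systems("water")$pes
    ctrl <- al_control(mode = mode, batch_size = batch_size,
                       max_train = max_train, seed = seed,
                       acquisition = acquisition, pso = al_pso())
    .fixture_env[[key]] <- suppressWarnings(
      active_learn(traj, pes, ctrl, atoms = atoms))
  }
  .fixture_env[[key]]
}

final_rmse <- function(run) {
  h <- run$history
  mean(vapply(split(h, h$atom), function(s) s$val_rmse[nrow(s)], numeric(1L)))
}

first_rmse <- function(run) {
  h <- run$history
  mean(vapply(split(h, h$atom), function(s) s$val_rmse[1L], numeric(1L)))
}
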