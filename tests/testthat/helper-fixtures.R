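# Small shared fixtures. Heavy objects are built lazily and cached so several
# test files can reuse them without re-simulating.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

tiny_call <- function(taper = 0.1)
  make_call(100e3, 40e3, 1e-3, sample_rate = 400e3, taper = taper)

tiny_ertf <- function() ertf_model()

one_sphere_scene <- function(n = 48)
  scene(sononerf:::sphere_surface_points(c(0, 0, 0), 0.03, n, seed = 2),
        name = "one-sphere")

# reduced observation settings used by the toy training runs
toy_obs <- function() obs_config(overlap = 0.75)
toy_sim <- function() sim_config(max_range = 0.45)

toy_ensemble <- function() fx("toy_ensemble", function() {
  poses <- pose_sphere(6, 0.3, seed = 31)
  simulate_ensemble(one_sphere_scene(32), poses, tiny_call(), tiny_ertf(),
                    sim_config(max_range = 0.35), obs_config(overlap = 0.5))
})
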