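# Shared fixtures, computed once per test run. The study run is the
# package's reference synthetic condition (200 x 60 px, 10 sections,
# 50-node tree, seed 1); the small run trades size for speed where the
# full condition is not needed.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

study_run <- function() {
  fixture("study", run_pipeline(synthetic_study_config(seed = 1)))
}

small_config <- function(seed = 1, ...) {
  pipeline_config(seed = seed,
                  phantom = list(height = 40, width = 120, S = 10),
                  k = 50, ...)
}

small_run <- function() {
  fixture("small", run_pipeline(small_config()))
}

# Build a retrieved-flavor cube from a pixels-in-rows matrix (column-major
# pixel order), for toy assignment/section tests.
toy_cube <- function(pixmat, H, W, flavor = "retrieved", mask = NULL) {
  C <- ncol(pixmat)
  hyper_cube(array(as.vector(pixmat), c(H, W, C)),
             wavenumber_axis(500, 2, C), flavor, mask = mask)
}

# Noise-free default phantom and its rendered cube (shared by synth /
# retrieve ground-truth checks).
noisefree_phantom <- function() {
  fixture("nf_phantom", make_phantom(height = 40, width = 120, S = 10,
                                     jitter_sd = 0, seed = 7))
}

noisefree_render <- function() {
  fixture("nf_render", {
    ph <- noisefree_phantom()
    render_cars_cube(ph, default_component_library(),
                     noise = noise_model(0), seed = 7)
  })
}
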