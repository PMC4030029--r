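# Shared phantom fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# few-band spec keeps geometry-only tests fast
small_spec <- function(rotation_deg = 40, rows = 176L, cols = 176L,
                       wl_stop = 420, ...) {
  phantom_spec(rows = rows, cols = cols, wl_stop = wl_stop,
               rotation_deg = rotation_deg, noise_sd = 0,
               impulse_fraction = 0, illum_gradient = 0, ...)
}

clean_phantom <- function() {
  cached("clean_phantom", generate_phantom_cube(small_spec()))
}

# default study-conditions phantom (noise, illumination, impulses on)
default_phantom <- function() {
  cached("default_phantom", generate_phantom_cube(phantom_spec()))
}

default_pipeline_config <- function(spec = phantom_spec(), ...) {
  pipeline_config(phantom = spec, downscale_factor = 0.5,
                  se_size_fullres = 31, ...)
}

default_pipeline_run <- function() {
  cached("default_pipeline_run", run_pipeline(default_pipeline_config()))
}

# map full-resolution coordinates into the working (downscaled) frame
to_working <- function(v, n_full, n_work) (v - 0.5) * n_work / n_full + 0.5
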