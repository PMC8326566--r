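# Shared fixtures. Small grids (32^3 template at 4 mm) keep unit tests fast;
# acceptance tests use the full default phantom resolution.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 32), template_voxel_mm = 4, ...)
}

# memoized templates (deterministic, so safe to share across tests)
.fixture_env <- new.env()

small_template <- function() {
  if (is.null(.fixture_env$small_tpl))
    .fixture_env$small_tpl <- make_template(small_spec())
  .fixture_env$small_tpl
}

default_template <- function() {
  if (is.null(.fixture_env$default_tpl))
    .fixture_env$default_tpl <- make_template(phantom_spec())
  .fixture_env$default_tpl
}

# tiny axis-aligned image for I/O and interpolation tests
tiny_image <- function(shape = c(10, 10, 10), voxel = 2, values = NULL,
                       kind = "arbitrary") {
  g <- centered_geometry(shape, voxel)
  if (is.null(values)) {
    set.seed(99)
    values <- array(stats::runif(prod(shape)), shape)
  }
  volumetric_image(values, g, kind)
}

full_mask <- function(geometry) {
  volumetric_image(array(1, geometry$shape), geometry, "mask")
}
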