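# Shared fixtures and small numeric helpers for the test suite.
# Everything is generated in code; no stored data.

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

# Default 2D acquisition used throughout the tests.
test_params <- function(shape = c(64L, 64L), ...) {
  acq_params(shape, ...)
}

# One phantom + smooth-field study on a 64x64 grid.
test_study <- function(seed = 1L, amplitude_hz = 90, smoothness = 16,
                       shape = c(64L, 64L), ...) {
  params <- acq_params(shape, ...)
  img <- make_phantom(shape, seed = seed)
  field <- make_field_map(shape, amplitude_hz, smoothness, seed = seed + 100L)
  list(params = params, img = img, field = field,
       mask = otsu_mask(Mod(img)))
}

zero_field <- function(shape) field_map(array(0, shape))
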