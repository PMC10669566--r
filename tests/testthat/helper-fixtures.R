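# shared fixtures: small phantoms and stacks built in code

# phantom spec that fits a 32-cube with the required shell margins;
# used wherever a realistically structured head is needed at small scale
small_phantom_spec <- function(seed = 1L, noise_sigma = 2, shape = c(32, 32, 32)) {
  phantom_spec(shape = shape, brain_axes = c(8.5, 7.75, 8),
               center_offset = c(0.25, 0.25, -0.25),
               noise_sigma = noise_sigma, seed = seed)
}

# even smaller head for fast training tests
tiny_phantom_spec <- function(seed = 1L, noise_sigma = 2) {
  phantom_spec(shape = c(24, 24, 24), brain_axes = c(4.75, 4.4, 4.6),
               center_offset = c(0.25, 0.25, -0.25),
               noise_sigma = noise_sigma, seed = seed)
}

# cohort of tiny phantoms whose jitter keeps the shells feasible in 24^3
tiny_cohort <- function(n, seed) {
  generate_cohort(n, tiny_phantom_spec(),
                  jitter = list(axes = 0.04, means = 2, sigma = 0.2,
                                offset = 0.25),
                  seed = seed)
}

# a slice stack from a plain list of matrices
stack_of <- function(slices, plane, source_shape) {
  structure(list(slices = slices, plane = plane, source_shape = source_shape),
            class = "bx_slice_stack")
}

# min-max scale a volume's data to [0, 1]
unit_scale <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

# training inputs for one phantom and plane: intensity (+ gradient) stacks
phantom_stacks <- function(ph, plane, hybrid = FALSE, stride = 1L) {
  v <- unit_scale(ph$volume$data)
  st1 <- extract_slices(v, plane)
  sty <- extract_slices(ph$brain_mask, plane)
  keep <- seq(1, length(st1$slices), by = stride)
  out <- list(x1 = st1$slices[keep], y = sty$slices[keep],
              shape = dim(ph$brain_mask$data))
  if (hybrid) {
    g <- gradient_map(bx_volume(v), plane)
    out$x2 <- extract_slices(g$data, plane)$slices[keep]
  }
  out
}
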