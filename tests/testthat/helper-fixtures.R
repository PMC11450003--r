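# shared in-code fixtures; coarse grids keep the wave tests fast while the
# acceptance suite runs at production resolution

coarse_medium <- function(phantom = NULL, dx = 50e-6, width = 8e-3,
                          thickness = 8e-3, ...) {
  build_medium(phantom, dx = dx, width = width, thickness = thickness,
               f_max = 2e6, sponge_cells = 30L, ...)
}

disc_p0 <- function(medium, depth, offset = 0, radius = 0.3e-3, amp = 1) {
  p0 <- matrix(0, medium$nz, medium$nx)
  p0[outer((medium$z - depth)^2, (medium$x - offset)^2, `+`) <= radius^2] <- amp
  p0
}

ellipse_points <- function(cx, cy, a, b, phi, n = 400, noise = 0) {
  th <- seq(0, 2 * pi, length.out = n)
  list(x = cx + a * cos(th) * cos(phi) - b * sin(th) * sin(phi) +
         rnorm(n, sd = noise),
       y = cy + a * cos(th) * sin(phi) + b * sin(th) * cos(phi) +
         rnorm(n, sd = noise))
}

# calibration ellipse for a model, fitted from a clean reference vibration
reference_ellipse <- function(model, fs = 65e6) {
  clean <- model
  clean$sigma <- 0
  ref <- make_reference_vibration(clean, fs = fs)
  fit_ellipse(as.vector(ref$i), as.vector(ref$q))
}

gauss_burst <- function(t, t0, width, freq, amp = 1) {
  amp * exp(-((t - t0) / width)^2) * sin(2 * pi * freq * (t - t0))
}
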