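#' Describe an ink-channel silicone phantom
#'
#' Specifies a PDMS slab with cylindrical ink-filled channels, the sample
#' geometry used throughout the package: a 10--13 mm thick slab with 2 mm
#' diameter channels whose water--ink filling absorbs the excitation light
#' and launches the photoacoustic wave.
#'
#' @param thickness Slab thickness in m (detection surface at z = 0,
#'   backside at z = thickness). Default 12 mm.
#' @param channels List of channels, each a list with elements `depth`
#'   (centre depth below the detection surface, m), `offset` (lateral offset
#'   from the slab midline, m) and `diameter` (m, default 2 mm).
#' @param concentration Ink concentration in percent v/v. The absorption
#'   coefficient scales linearly: a 0.1 % solution has `extinction_ref`.
#' @param extinction_ref Extinction coefficient of the 0.1 % reference
#'   solution, in cm^-1. Default 12.5.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' ph <- phantom_spec(channels = list(list(depth = 7e-3, offset = 0)))
#' absorption_coefficient(ph)  # 125 cm^-1 at the default 1 % concentration
#' @export
phantom_spec <- function(thickness = 12e-3,
                         channels = list(list(depth = 7e-3, offset = 0,
                                              diameter = 2e-3)),
                         concentration = 1,
                         extinction_ref = 12.5) {
  stopifnot(is.numeric(thickness), thickness > 0)
  if (concentration < 0)
    stop("ink concentration must be >= 0")
  channels <- lapply(channels, function(ch) {
    ch <- modifyList(list(diameter = 2e-3), ch)
    if (is.null(ch$depth) || is.null(ch$offset))
      stop("each channel needs `depth` and `offset`")
    if (ch$diameter <= 0) stop("channel diameter must be > 0")
    r <- ch$diameter / 2
    if (ch$depth - r <= 0 || ch$depth + r >= thickness)
      stop(sprintf(
        "channel at depth %.3g m with diameter %.3g m does not fit inside the %.3g m slab",
        ch$depth, ch$diameter, thickness))
    ch
  })
  structure(list(thickness = thickness, channels = channels,
                 concentration = concentration,
                 extinction_ref = extinction_ref),
            class = "phantom_spec")
}

#' Optical absorption coefficient of the channel filling
#'
#' Linear (Beer--Lambert) scaling of the reference extinction with ink
#' concentration: `extinction_ref * concentration / 0.1`.
#'
#' @param phantom A [phantom_spec()].
#' @return Absorption coefficient in cm^-1.
#' @export
absorption_coefficient <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  phantom$extinction_ref * phantom$concentration / 0.1
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("PDMS phantom: %.1f mm slab, %d channel(s), %.3g %% ink (mu_a = %.3g cm^-1)\n",
              1e3 * x$thickness, length(x$channels), x$concentration,
              absorption_coefficient(x)))
  for (ch in x$channels)
    cat(sprintf("  channel: depth %.2f mm, offset %+0.2f mm, diameter %.2f mm\n",
                1e3 * ch$depth, 1e3 * ch$offset, 1e3 * ch$diameter))
  invisible(x)
}

#' Build a discretized acoustic medium from a phantom
#'
#' Rasterizes a [phantom_spec()] onto a regular grid: PDMS background with
#' sound speed 1020 m/s and channel discs with water-like 1500 m/s; density
#' is 1000 kg/m^3 everywhere so that the sound speed alone sets the acoustic
#' impedance (1.02 MRayl for PDMS, 1.5 MRayl for the channels). The
#' detection surface (z = 0) and the backside (z = thickness) are soft
#' (pressure-release) boundaries; the lateral edges carry an absorbing
#' sponge emulating an unbounded slab.
#'
#' @param phantom A [phantom_spec()], or `NULL` for a homogeneous PDMS slab.
#' @param dx Grid spacing in m. Must resolve the shortest acoustic
#'   wavelength with at least 10 cells (see `f_max`).
#' @param width Lateral physical extent in m (before sponge margins).
#' @param depth Depth extent in m; defaults to the phantom thickness. A
#'   larger value (with `soft_bottom = FALSE`) gives the extended domain
#'   used for time-reversal reconstruction.
#' @param thickness Slab thickness in m when `phantom` is `NULL`.
#' @param sponge_cells Width of each lateral absorbing margin in cells.
#' @param f_max Highest acoustic frequency (Hz) the grid must support;
#'   `dx > c_min / (10 * f_max)` is an error.
#' @param soft_top,soft_bottom Mark the corresponding surface as
#'   pressure-release. An unmarked bottom is absorbing (sponge-free
#'   Dirichlet-less edge used for reconstruction media).
#' @param homogeneous If `TRUE`, ignore channel heterogeneity (uniform PDMS
#'   speed), as used for reconstruction.
#'
#' @return An object of class `pa_medium` with fields `nx`, `nz`, `dx`,
#'   `c_map`, `rho_map` (nz x nx, z down rows), cell-centre coordinates `x`
#'   (lateral, centred on the slab midline) and `z` (depth), the boundary
#'   specification and the sponge width.
#' @examples
#' m <- build_medium(phantom_spec(), dx = 50e-6, f_max = 2e6)
#' range(m$c_map)                       # 1020 and 1500 m/s
#' max(m$c_map * m$rho_map) / 1e6       # 1.5 MRayl in the channel
#' @export
build_medium <- function(phantom = NULL, dx = 20e-6, width = 14e-3,
                         depth = NULL, thickness = 12e-3,
                         sponge_cells = 40L, f_max = 5e6,
                         soft_top = TRUE, soft_bottom = TRUE,
                         homogeneous = FALSE) {
  stopifnot(dx > 0, width > 0)
  def <- .pa_defaults
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "phantom_spec"))
    thickness <- phantom$thickness
  }
  if (is.null(depth)) depth <- thickness
  c_min <- def$c_pdms
  if (dx > c_min / (10 * f_max))
    stop(sprintf(
      "dx = %.3g m too coarse: need <= %.3g m for 10 cells per wavelength at %.3g MHz",
      dx, c_min / (10 * f_max), f_max / 1e6))

  nz <- as.integer(round(depth / dx)) + 1L
  nx_core <- as.integer(round(width / dx)) + 1L
  nx <- nx_core + 2L * sponge_cells
  x <- (seq_len(nx) - 1L) * dx
  x <- x - x[sponge_cells + 1L] - width / 2   # midline at x = 0
  z <- (seq_len(nz) - 1L) * dx

  c_map <- matrix(def$c_pdms, nz, nx)
  rho_map <- matrix(def$rho, nz, nx)
  if (!is.null(phantom) && !homogeneous) {
    for (ch in phantom$channels) {
      r <- ch$diameter / 2
      dz2 <- (z - ch$depth)^2
      dx2 <- (x - ch$offset)^2
      mask <- outer(dz2, dx2, `+`) <= r^2
      c_map[mask] <- def$c_channel
    }
  }
  structure(list(nx = nx, nz = nz, dx = dx, c_map = c_map, rho_map = rho_map,
                 x = x, z = z, sponge_cells = as.integer(sponge_cells),
                 boundary = list(
                   top = if (soft_top) "soft" else "absorbing",
                   bottom = if (soft_bottom) "soft" else "absorbing",
                   left = "absorbing", right = "absorbing"),
                 phantom = phantom, thickness = thickness),
            class = "pa_medium")
}

#' @export
print.pa_medium <- function(x, ...) {
  cat(sprintf("acoustic medium: %d x %d cells, dx = %.3g um\n",
              x$nz, x$nx, 1e6 * x$dx))
  cat(sprintf("  c in [%g, %g] m/s, Z in [%.3g, %.3g] MRayl\n",
              min(x$c_map), max(x$c_map),
              min(x$c_map * x$rho_map) / 1e6, max(x$c_map * x$rho_map) / 1e6))
  cat(sprintf("  boundaries: top %s, bottom %s, lateral sponge %d cells\n",
              x$boundary$top, x$boundary$bottom, x$sponge_cells))
  invisible(x)
}

#' Initial photoacoustic pressure map from optical absorption
#'
#' Places a uniform initial pressure inside each channel disc, with
#' amplitude proportional to the optical absorption coefficient of the ink
#' filling (thermoelastic generation under stress confinement), and zero
#' elsewhere.
#'
#' @param phantom A [phantom_spec()].
#' @param medium A [build_medium()] grid congruent with the phantom.
#' @param fluence_scale Pressure per unit absorption coefficient, Pa cm
#'   (the product of the Grueneisen parameter and local fluence). A 0.1 %
#'   ink channel (12.5 cm^-1) with the default 1000 Pa cm yields 12.5 kPa.
#'
#' @return An nz x nx pressure matrix (Pa).
#' @export
initial_pressure_from_absorption <- function(phantom, medium,
                                             fluence_scale = 1e3) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(medium, "pa_medium"))
  if (phantom$concentration < 0) stop("ink concentration must be >= 0")
  p0 <- matrix(0, medium$nz, medium$nx)
  amp <- absorption_coefficient(phantom) * fluence_scale
  for (ch in phantom$channels) {
    r <- ch$diameter / 2
    mask <- outer((medium$z - ch$depth)^2, (medium$x - ch$offset)^2, `+`) <= r^2
    p0[mask] <- amp
  }
  p0
}
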