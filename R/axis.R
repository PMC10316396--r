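#' Uniform wavenumber axis
#'
#' The spectral axis of a hyperspectral cube: `n_channels` values starting at
#' `start` with spacing `step` (cm^-1). The default covers the fingerprint
#' region, 500 to 1800 cm^-1 sampled every 2 cm^-1, i.e. 651 channels.
#'
#' @param start first wavenumber (cm^-1)
#' @param step channel spacing (cm^-1), must be positive
#' @param n_channels number of channels (>= 2)
#' @return an object of class `wavenumber_axis` with fields `start`, `step`,
#'   `n_channels` and the precomputed `values`
#' @export
#' @examples
#' ax <- wavenumber_axis()
#' ax$n_channels  # 651
wavenumber_axis <- function(start = 500, step = 2, n_channels = 651) {
  stopifnot(step > 0, n_channels >= 2)
  structure(
    list(start = start, step = step, n_channels = as.integer(n_channels),
         values = start + step * (seq_len(n_channels) - 1)),
    class = "wavenumber_axis")
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("<wavenumber_axis> %g..%g cm^-1, step %g, %d channels\n",
              x$values[1], x$values[x$n_channels], x$step, x$n_channels))
  invisible(x)
}

#' Nearest channel index for a wavenumber
#' @param axis a [wavenumber_axis()]
#' @param wavenumber target position (cm^-1); must lie within the axis
#' @return integer channel index
#' @export
axis_channel <- function(axis, wavenumber) {
  v <- axis$values
  if (wavenumber < v[1] - axis$step / 2 ||
      wavenumber > v[length(v)] + axis$step / 2)
    stop("wavenumber ", wavenumber, " cm^-1 outside axis range")
  which.min(abs(v - wavenumber))
}

#' A single Lorentzian Raman resonance
#'
#' @param omega peak centre (cm^-1)
#' @param amplitude resonance amplitude (> 0, arbitrary susceptibility units)
#' @param gamma half-width (cm^-1, > 0)
#' @export
lorentzian <- function(omega, amplitude, gamma) {
  stopifnot(amplitude > 0, gamma > 0)
  structure(list(omega = omega, amplitude = amplitude, gamma = gamma),
            class = "lorentzian")
}

#' A named spectral component: resonances plus a nonresonant amplitude
#'
#' @param name component label
#' @param resonances list of [lorentzian()] resonances (may be empty)
#' @param chi_nr nonresonant susceptibility amplitude (> 0; the nonresonant
#'   background is always present in CARS)
#' @export
spectral_component <- function(name, resonances = list(), chi_nr = 1) {
  stopifnot(is.character(name), length(name) == 1, chi_nr > 0)
  if (length(resonances) &&
      !all(vapply(resonances, inherits, TRUE, "lorentzian")))
    stop("resonances must be lorentzian objects")
  structure(list(name = name, resonances = resonances, chi_nr = chi_nr),
            class = "spectral_component")
}

#' Library of spectral components
#'
#' @param components list of [spectral_component()]s with unique names
#' @param background_chi_nr nonresonant amplitude of bare background pixels
#'   (medium with no tissue component)
#' @export
component_library <- function(components, background_chi_nr = 1) {
  stopifnot(length(components) >= 1, background_chi_nr > 0)
  nms <- vapply(components, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("component names must be unique")
  structure(list(components = components, names = nms,
                 background_chi_nr = background_chi_nr),
            class = "component_library")
}

#' Default five-component tissue library
#'
#' Peak positions follow common fingerprint-band assignments for nucleic
#' acids (785, 811, 1340 cm^-1), proteins (936, 1004, 1230, 1655 cm^-1) and
#' lipids (877, 1300, 1450, 1740 cm^-1), distributed over components named
#' nucleus, cytoplasm, yolk, ecm and fluid. Amplitudes are free parameters of
#' the generator (weak relative to the nonresonant background so retrieval
#' operates in its near-linear regime); they are not calibrated to any real
#' tissue.
#'
#' @return a [component_library()] with components
#'   `nucleus`, `cytoplasm`, `yolk`, `ecm`, `fluid`
#' @export
default_component_library <- function() {
  lz <- function(o, a, g) lorentzian(o, a, g)
  component_library(list(
    spectral_component("nucleus", list(
      lz(785, 1.00, 8), lz(811, 0.80, 7), lz(1004, 0.25, 5),
      lz(1340, 0.70, 10), lz(1655, 0.45, 12)), chi_nr = 1.05),
    spectral_component("cytoplasm", list(
      lz(1004, 1.00, 5), lz(1230, 0.55, 12), lz(1450, 0.70, 10),
      lz(1655, 0.90, 12)), chi_nr = 1.00),
    spectral_component("yolk", list(
      lz(877, 0.50, 9), lz(1300, 0.90, 9), lz(1450, 1.00, 10),
      lz(1740, 0.60, 10)), chi_nr = 0.95),
    spectral_component("ecm", list(
      lz(877, 0.55, 9), lz(936, 0.90, 9), lz(1230, 0.70, 12),
      lz(1655, 0.80, 12)), chi_nr = 1.00),
    spectral_component("fluid", list(
      lz(1655, 0.35, 40)), chi_nr = 0.90)),
    background_chi_nr = 1.0)
}

#' Complex resonant susceptibility of a component on an axis
#'
#' Evaluates chi_R(omega) = sum_j A_j / (Omega_j - omega - i Gamma_j) on the
#' axis. The imaginary part is the Raman-like (spontaneous-Raman-equivalent)
#' spectrum of the component.
#'
#' @param component a [spectral_component()] (or list of [lorentzian()]s)
#' @param axis a [wavenumber_axis()]
#' @return complex vector of length `axis$n_channels`
#' @export
resonant_chi <- function(component, axis) {
  res <- if (inherits(component, "spectral_component"))
    component$resonances else component
  chi <- complex(real = numeric(axis$n_channels),
                 imaginary = numeric(axis$n_channels))
  for (r in res)
    chi <- chi + r$amplitude / complex(real = r$omega - axis$values,
                                       imaginary = -r$gamma)
  chi
}
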