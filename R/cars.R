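#' Noise model for the CARS forward simulation
#'
#' Additive Gaussian noise with standard deviation proportional to the
#' square root of the intensity (shot-noise-like), the photon-counting
#' character of a spectrograph without a full detector model.
#'
#' @param sd_scale noise s.d. at unit intensity; 0 disables noise
#' @export
noise_model <- function(sd_scale = 0.01) {
  stopifnot(sd_scale >= 0)
  structure(list(type = "shot", sd_scale = sd_scale), class = "noise_model")
}

#' Render the raw CARS cube of a phantom
#'
#' Per-pixel coherent forward model
#' `I(omega) = |chi_NR + sum_p a_p chi_R,p(omega)|^2`, where the pixel's
#' nonresonant amplitude is the abundance-weighted mix of the component
#' nonresonant amplitudes plus the bare background for the unfilled
#' fraction, and `chi_R,p` is the component's Lorentzian-sum resonant
#' susceptibility. Background pixels (all abundances zero) carry the pure
#' nonresonant background, whose noise-free intensity spectrum is returned
#' as the NRB reference.
#'
#' @param phantom a [make_phantom()] result
#' @param library a [component_library()]; component order must match the
#'   phantom's `component_names`
#' @param axis a [wavenumber_axis()]
#' @param noise a [noise_model()]
#' @param seed RNG seed for the noise draw
#' @return list with `cube` (raw-flavor [hyper_cube()], mask = tissue
#'   pixels) and `nrb` (length-C noise-free NRB reference spectrum)
#' @export
render_cars_cube <- function(phantom, library, axis = wavenumber_axis(),
                             noise = noise_model(), seed = 1) {
  P <- length(phantom$component_names)
  if (length(library$components) != P ||
      !identical(library$names, phantom$component_names))
    stop("library components do not match phantom components")
  d <- dim(phantom$abundances)
  H <- d[1]; W <- d[2]; C <- axis$n_channels
  A <- matrix(phantom$abundances, H * W, P)

  # per-component complex resonant spectra, P x C
  Rre <- matrix(0, P, C); Rim <- matrix(0, P, C)
  chi_nr <- numeric(P)
  for (p in seq_len(P)) {
    chi <- resonant_chi(library$components[[p]], axis)
    Rre[p, ] <- Re(chi); Rim[p, ] <- Im(chi)
    chi_nr[p] <- library$components[[p]]$chi_nr
  }
  chi0 <- library$background_chi_nr

  nr_pix <- chi0 * (1 - rowSums(A)) + drop(A %*% chi_nr)  # N-vector
  re <- A %*% Rre + nr_pix      # N x C, recycled by column
  im <- A %*% Rim
  I <- re * re + im * im
  if (min(I) < 0) stop("negative pre-noise intensity")  # cannot happen

  if (noise$sd_scale > 0) {
    set.seed(stage_seed(seed, "cars"))
    I <- I + noise$sd_scale * sqrt(I) * matrix(rnorm(length(I)), nrow(I))
  }
  cube <- hyper_cube(array(I, c(H, W, C)), axis, "raw",
                     mask = phantom$labels > 0)
  list(cube = cube, nrb = rep(chi0^2, C))
}
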