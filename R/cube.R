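#' Hyperspectral image cube
#'
#' An H x W x C array of intensities with a uniform wavenumber axis. Flavor
#' `raw` holds CARS intensities (|chi|^2 plus noise), flavor `retrieved`
#' holds Kramers-Kronig-retrieved Raman-like spectra (which may contain
#' small negatives from baseline correction). An optional logical mask marks
#' analyzable pixels.
#'
#' @param data numeric H x W x C array
#' @param axis a [wavenumber_axis()]; `C` must equal `axis$n_channels`
#' @param flavor `"raw"` or `"retrieved"`
#' @param mask optional H x W logical matrix of valid pixels
#' @export
hyper_cube <- function(data, axis, flavor = c("raw", "retrieved"),
                       mask = NULL) {
  flavor <- match.arg(flavor)
  d <- dim(data)
  if (length(d) != 3) stop("cube data must be a 3-d array")
  if (d[3] != axis$n_channels)
    stop("cube has ", d[3], " channels but axis has ", axis$n_channels)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
      stop("mask must be a logical H x W matrix matching the cube")
  }
  structure(list(data = data, axis = axis, flavor = flavor, mask = mask),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube %s> %d x %d pixels, %d channels (%g..%g cm^-1)\n",
              x$flavor, d[1], d[2], d[3], x$axis$values[1],
              x$axis$values[d[3]]))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d / %d pixels valid\n", sum(x$mask), d[1] * d[2]))
  invisible(x)
}

cube_dim <- function(cube) dim(cube$data)[1:2]

# Pixels-in-rows matrix of the masked pixels, plus their (row, col) indices.
# Used by every stage that treats pixels as points in spectral space.
cube_pixel_matrix <- function(cube, mask = NULL) {
  d <- dim(cube$data)
  mask <- mask %||% cube$mask %||% matrix(TRUE, d[1], d[2])
  idx <- which(mask)
  mat <- matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  list(spectra = mat, idx = idx, dim = d[1:2])
}

#' Mean spectrum over masked pixels
#' @param cube a [hyper_cube()]
#' @param mask optional H x W logical overriding the cube mask
#' @return numeric vector of length C
#' @export
cube_mean_spectrum <- function(cube, mask = NULL) {
  pm <- cube_pixel_matrix(cube, mask)
  colMeans(pm$spectra)
}
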