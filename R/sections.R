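#' Per-section node frequencies
#'
#' Counts, for every tree node, the pixels assigned to it inside each
#' section of the label raster, and the corresponding fractions of each
#' section's pixels. Empty sections (no assigned pixels) are flagged and
#' their fraction columns left `NA`, to be dropped from downstream
#' correlation analyses.
#'
#' @param assignment a [assign_pixels()] result
#' @param section_mask H x W integer raster, 0 = background, 1..S sections
#' @param S section count (defaults to the raster maximum)
#' @return a `node_frequency_table`: `counts` (k x S integer), `fractions`
#'   (k x S, columns sum to 1 where defined), `section_sizes`,
#'   `dropped_sections`
#' @export
section_node_frequency <- function(assignment, section_mask,
                                   S = max(section_mask)) {
  if (!identical(dim(section_mask), dim(assignment$node_id)))
    stop("section mask not aligned with assignment")
  k <- assignment$k
  sel <- !is.na(assignment$node_id) & section_mask > 0
  if (!any(sel)) stop("no assigned pixels inside any section")
  counts <- matrix(0L, k, S)
  tab <- table(factor(assignment$node_id[sel], levels = seq_len(k)),
               factor(section_mask[sel], levels = seq_len(S)))
  counts[] <- as.integer(tab)
  sizes <- colSums(counts)
  fractions <- sweep(counts, 2, pmax(sizes, 1), "/")
  dropped <- which(sizes == 0)
  if (length(dropped)) fractions[, dropped] <- NA_real_
  structure(list(counts = counts, fractions = fractions,
                 section_sizes = as.integer(sizes),
                 dropped_sections = dropped, k = k, S = as.integer(S)),
            class = "node_frequency_table")
}

#' @export
print.node_frequency_table <- function(x, ...) {
  cat(sprintf("<node_frequency_table> %d nodes x %d sections (%d dropped)\n",
              x$k, x$S, length(x$dropped_sections)))
  invisible(x)
}

#' Per-section difference spectra
#'
#' Row s is the mean spectrum of section s minus the mean spectrum over all
#' section pixels (the whole-tissue reference). Empty sections give `NA`
#' rows.
#'
#' @param cube retrieved-flavor [hyper_cube()]
#' @param section_mask H x W integer raster, 0 = background
#' @return S x C matrix with attribute `reference_mean` (the grand mean)
#' @export
section_difference_spectra <- function(cube, section_mask) {
  d <- dim(cube$data)
  if (!identical(dim(section_mask), d[1:2]))
    stop("section mask not aligned with cube")
  S <- max(section_mask)
  idx <- which(section_mask > 0)
  if (!length(idx)) stop("no section pixels")
  mat <- matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  grand <- colMeans(mat)
  out <- matrix(NA_real_, S, d[3])
  sec <- section_mask[idx]
  sums <- rowsum(mat, sec)
  n <- tabulate(sec, S)
  present <- as.integer(rownames(sums))
  out[present, ] <- sums / n[present] - rep(grand, each = length(present))
  attr(out, "reference_mean") <- grand
  attr(out, "section_sizes") <- n
  out
}

#' Node difference spectra against a reference mean
#'
#' @param node_spectra k x C matrix (e.g. from [node_mean_spectra()])
#' @param reference_mean length-C reference spectrum (e.g. the whole-image
#'   in-mask mean)
#' @return k x C matrix of `node - reference` rows
#' @export
node_difference_spectra <- function(node_spectra, reference_mean) {
  node_spectra <- as.matrix(node_spectra)
  if (length(reference_mean) != ncol(node_spectra))
    stop("reference length does not match spectra")
  sweep(node_spectra, 2, reference_mean)
}

#' Band intensity ratio
#'
#' Ratio of the spectrum maxima within `window`-wide intervals centred on
#' two bands; the default 811/785 cm^-1 pair indexes RNA abundance relative
#' to total nucleic-acid backbone signal.
#'
#' @param spectrum length-C vector
#' @param axis a [wavenumber_axis()]
#' @param num_band,den_band band centres (cm^-1)
#' @param window full window width (cm^-1), at least one channel step
#' @param eps denominator floor
#' @return the ratio, with attribute `bands = c(num_band, den_band)`
#' @export
band_ratio <- function(spectrum, axis, num_band = 811, den_band = 785,
                       window = 20, eps = 1e-12) {
  if (window < axis$step) stop("window narrower than the channel step")
  pick <- function(b) {
    lo <- b - window / 2; hi <- b + window / 2
    sel <- which(axis$values >= lo & axis$values <= hi)
    if (!length(sel)) stop("band ", b, " cm^-1 outside axis")
    max(spectrum[sel])
  }
  r <- pick(num_band) / max(pick(den_band), eps)
  attr(r, "bands") <- c(num_band, den_band)
  r
}
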