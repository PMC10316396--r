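#' Retrieval parameters
#'
#' @param pad_factor mirror padding, in multiples of the axis length, added
#'   at each edge before the Hilbert transform (suppresses wraparound)
#' @param baseline `"asls"` (iterative asymmetric penalized smoothing) or
#'   `"off"`
#' @param lambda smoothness of the baseline fit (channel units)
#' @param p asymmetry of the baseline fit (0 < p < 0.5)
#' @param baseline_iter reweighting iterations
#' @param clip_negative clip retrieved values at 0 (off by default; small
#'   negatives are tolerated downstream and clipping distorts difference
#'   spectra)
#' @param floor_frac positivity floor, as a fraction of the NRB maximum,
#'   applied to raw and reference intensities before taking logs
#' @export
retrieval_params <- function(pad_factor = 2, baseline = c("asls", "off"),
                             lambda = 1e5, p = 0.01, baseline_iter = 10,
                             clip_negative = FALSE, floor_frac = 1e-12) {
  baseline <- match.arg(baseline)
  stopifnot(pad_factor >= 1, lambda > 0, p > 0, p < 0.5, baseline_iter >= 1,
            floor_frac > 0)
  structure(list(pad_factor = pad_factor, baseline = baseline,
                 lambda = lambda, p = p, baseline_iter = baseline_iter,
                 clip_negative = clip_negative, floor_frac = floor_frac),
            class = "retrieval_params")
}

# Discrete Hilbert transform of each column (via the analytic signal).
# For x = cos, returns sin.
hilbert_mat <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  a <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  Im(a)
}

# Kramers-Kronig phase retrieval, spectra in columns (C x N).
# ratio = raw/nrb = |1 + chi_R/chi_NR|^2 for a minimum-phase response, so
# the phase is the Hilbert transform of log(ratio)/2 and
# sqrt(ratio) * sin(phase) ~ Im(chi_R)/chi_NR.
kk_retrieve_mat <- function(raw, nrb_ref, params) {
  C <- nrow(raw)
  if (length(nrb_ref) != C) stop("raw and NRB reference lengths differ")
  fl <- params$floor_frac * max(nrb_ref)
  if (!is.finite(fl) || fl <= 0) {
    bad <- which(nrb_ref <= 0)[1]
    stop("retrieval error: NRB reference nonpositive at channel ", bad)
  }
  ratio <- pmax(raw, fl) / pmax(nrb_ref, fl)
  u <- 0.5 * log(ratio)
  # periodic-mirror padding: [u, rev, u, rev, u, ...] keeps the extension
  # continuous at every joint; the analyzed copy sits pad_factor*C deep
  pf <- as.integer(ceiling(params$pad_factor))
  blocks <- vector("list", 2 * pf + 1)
  for (b in seq_along(blocks))
    blocks[[b]] <- if (b %% 2 == 1) u else u[C:1, , drop = FALSE]
  ext <- do.call(rbind, blocks)
  ph <- hilbert_mat(ext)[(pf * C + 1):((pf + 1) * C), , drop = FALSE]
  sqrt(ratio) * sin(ph)
}

#' Kramers-Kronig retrieval of one spectrum
#'
#' Extracts the Raman-resonance phase of a raw CARS spectrum against a
#' nonresonant-background (NRB) reference and returns the phase-derived
#' Raman-like spectrum, normalized by the NRB (so amplitudes are
#' reference-standardized), followed by residual baseline correction per
#' `params`.
#'
#' @param raw raw CARS intensity spectrum (length C)
#' @param nrb_ref NRB reference intensity spectrum (length C)
#' @param params a [retrieval_params()]
#' @return retrieved spectrum (length C)
#' @export
kk_retrieve_spectrum <- function(raw, nrb_ref, params = retrieval_params()) {
  ret <- kk_retrieve_mat(matrix(raw, ncol = 1), nrb_ref, params)[, 1]
  ret <- remove_baseline(ret, params)
  if (params$clip_negative) ret <- pmax(ret, 0)
  ret
}

#' Remove a smooth baseline from a spectrum
#'
#' Iterative asymmetric penalized smoothing: a Whittaker smoother with a
#' second-difference penalty whose weights are asymmetric (small above the
#' fit, near 1 below), so the fit hugs the lower envelope and suppresses
#' slowly varying trends while leaving sharp peaks intact.
#'
#' @param spectrum numeric vector (finite)
#' @param params a [retrieval_params()]; `baseline = "off"` returns the
#'   input unchanged
#' @return baseline-corrected spectrum
#' @export
remove_baseline <- function(spectrum, params = retrieval_params()) {
  if (!all(is.finite(spectrum))) stop("non-finite input spectrum")
  if (params$baseline == "off") return(spectrum)
  b <- .asls_baseline_mat(matrix(spectrum, ncol = 1), params$lambda,
                          params$p, params$baseline_iter)[, 1]
  spectrum - b
}

#' Retrieve a whole cube
#'
#' Applies [kk_retrieve_spectrum()] (vectorized over pixels, in blocks) and
#' baseline correction to every pixel of a raw cube. Pixels whose retrieval
#' produces non-finite values are masked out and counted, not fatal.
#'
#' @param raw_cube raw-flavor [hyper_cube()]
#' @param nrb_ref NRB reference spectrum (length C)
#' @param params a [retrieval_params()]
#' @param block_pixels pixels retrieved per block (memory/progress granularity)
#' @param verbose log one line per block
#' @return retrieved-flavor [hyper_cube()] with the propagated mask
#' @export
retrieve_cube <- function(raw_cube, nrb_ref, params = retrieval_params(),
                          block_pixels = 4000, verbose = FALSE) {
  if (raw_cube$flavor != "raw") stop("expected a raw-flavor cube")
  d <- dim(raw_cube$data)
  N <- d[1] * d[2]; C <- d[3]
  mask <- raw_cube$mask %||% matrix(TRUE, d[1], d[2])
  idx <- which(mask)
  out <- array(0, d)
  outm <- matrix(out, N, C)
  rawm <- matrix(raw_cube$data, N, C)
  dropped <- 0L
  blocks <- split(idx, ceiling(seq_along(idx) / block_pixels))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    ret <- kk_retrieve_mat(t(rawm[b, , drop = FALSE]), nrb_ref, params)
    if (params$baseline == "asls")
      ret <- ret - .asls_baseline_mat(ret, params$lambda, params$p,
                                      params$baseline_iter)
    if (params$clip_negative) ret[ret < 0] <- 0
    bad <- !apply(is.finite(ret), 2, all)
    if (any(bad)) {
      dropped <- dropped + sum(bad)
      mask[b[bad]] <- FALSE
      ret[, bad] <- 0
    }
    outm[b, ] <- t(ret)
    if (verbose)
      message("retrieve: block ", bi, "/", length(blocks), " (",
              length(b), " pixels)")
  }
  if (dropped > 0)
    message("retrieve: masked out ", dropped, " pixels with failed retrieval")
  hyper_cube(array(outm, d), raw_cube$axis, "retrieved", mask = mask)
}
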