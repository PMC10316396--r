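#' Downsampling parameters
#'
#' Density-dependent downsampling: points below the `outlier_percentile` of
#' the local-density distribution are removed as outliers; points between
#' the outlier and `target_percentile` are kept; denser points are kept with
#' probability target-density / density, flattening the point density in
#' spectral space. An absolute cap `max_kept` thins uniformly if exceeded.
#'
#' @param outlier_percentile outlier threshold (percentile of densities)
#' @param target_percentile target density (percentile of densities)
#' @param max_kept maximum number of kept points
#' @param metric `"L1"` or `"L2"`
#' @param radius_alpha density radius = `radius_alpha` x median
#'   nearest-neighbour distance of a random subsample
#' @param density_subsample subsample size for the radius estimate
#' @export
downsample_params <- function(outlier_percentile = 1, target_percentile = 3,
                              max_kept = 2e5, metric = c("L1", "L2"),
                              radius_alpha = 5, density_subsample = 2000) {
  metric <- match.arg(metric)
  stopifnot(outlier_percentile >= 0,
            outlier_percentile <= target_percentile,
            target_percentile <= 100, max_kept >= 1, radius_alpha > 0,
            density_subsample >= 2)
  structure(list(outlier_percentile = outlier_percentile,
                 target_percentile = target_percentile,
                 max_kept = max_kept, metric = metric,
                 radius_alpha = radius_alpha,
                 density_subsample = density_subsample),
            class = "downsample_params")
}

metric_code <- function(metric) if (metric == "L2") 2L else 1L
dist_method <- function(metric) if (metric == "L2") "euclidean" else "manhattan"

#' Local spectral density
#'
#' Exact count of points (including the point itself) within `radius` of
#' each point under the chosen metric.
#'
#' @param spectra N x C matrix (pixels in rows)
#' @param radius neighbourhood radius (> 0)
#' @param metric `"L1"` or `"L2"`
#' @return integer vector of N densities
#' @export
estimate_density <- function(spectra, radius, metric = c("L1", "L2")) {
  metric <- match.arg(metric)
  if (radius <= 0) stop("radius must be > 0")
  spectra <- as.matrix(spectra)
  .count_within_radius(t(spectra), radius, metric_code(metric))
}

#' Choose the density neighbourhood radius
#'
#' `radius_alpha` times the median, over a seeded random subsample, of each
#' sampled point's nearest-neighbour distance within the subsample. Falls
#' back to the smallest nonzero pairwise distance in the full data when the
#' subsample is all-coincident.
#'
#' @param spectra N x C matrix
#' @param radius_alpha multiplier
#' @param density_subsample subsample size
#' @param metric `"L1"` or `"L2"`
#' @param seed RNG seed for the subsample
#' @return radius (> 0)
#' @export
choose_radius <- function(spectra, radius_alpha = 5,
                          density_subsample = 2000,
                          metric = c("L1", "L2"), seed = 1) {
  metric <- match.arg(metric)
  spectra <- as.matrix(spectra)
  N <- nrow(spectra)
  if (N < 2) stop("need at least 2 points")
  set.seed(stage_seed(seed, "radius"))
  sub <- if (N > density_subsample)
    spectra[sort(sample.int(N, density_subsample)), , drop = FALSE]
  else spectra
  dm <- as.matrix(dist(sub, method = dist_method(metric)))
  diag(dm) <- Inf
  med <- median(apply(dm, 1, min))
  if (med == 0) {
    du <- dist(unique(spectra), method = dist_method(metric))
    pos <- du[du > 0]
    if (!length(pos)) stop("all points coincide; no usable radius")
    med <- min(pos)
  }
  radius_alpha * med
}

#' Density-dependent downsampling with outlier removal
#'
#' @param spectra N x C matrix (used only for dimension checks)
#' @param densities integer densities aligned with `spectra` rows
#' @param params a [downsample_params()]
#' @param seed RNG seed for the stochastic keep decisions
#' @return sorted integer vector of kept row indices
#' @export
density_downsample <- function(spectra, densities,
                               params = downsample_params(), seed = 1) {
  N <- length(densities)
  if (nrow(spectra) != N) stop("densities not aligned with spectra")
  od <- quantile(densities, params$outlier_percentile / 100, names = FALSE)
  td <- quantile(densities, params$target_percentile / 100, names = FALSE)
  set.seed(stage_seed(seed, "downsample"))
  u <- runif(N)  # one draw per point, so the rule replays deterministically
  keep <- densities >= od & (densities <= td | u <= td / densities)
  kept <- which(keep)
  if (!length(kept))
    stop("downsampling removed every point; increase the radius or lower ",
         "the percentiles")
  if (length(kept) > params$max_kept)
    kept <- sort(sample(kept, params$max_kept))
  sort(kept)
}
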