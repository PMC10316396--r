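#' Section-wise component class probabilities
#'
#' The phantom emulates the ordered maturation of the gonad: each of the S
#' sections has a mixture of tissue classes whose proportions follow
#' logistic transitions along the section axis, with one sharp changeover
#' (the distal-to-proximal switch at the gonad loop) so that two blocks of
#' mutually similar sections arise. Each component uses a distinct logistic
#' centre and width so no two profiles are affinely related, which keeps
#' gene-to-component attribution identifiable.
#'
#' @param S number of sections
#' @param P number of components
#' @param changeover section coordinate of the sharp transition; default
#'   `0.65 * S` (between sections 6 and 7 for S = 10)
#' @param sharpness logistic width (sections) of the main transition
#' @return an S x P matrix of class probabilities (rows sum to 1) with
#'   attribute `post_component`, the index of the component whose abundance
#'   rises sharply after the changeover
#' @export
class_profiles <- function(S, P = 5, changeover = 0.65 * S,
                           sharpness = 0.4) {
  stopifnot(S >= 2, P >= 3)
  s <- seq_len(S)
  L <- function(c0, tau) 1 / (1 + exp(-(s - c0) / tau))
  if (P == 5) {
    base <- cbind(
      nucleus   = 0.32 * (1 - L(changeover, sharpness)) + 0.05,
      cytoplasm = 0.26 * (1 - L(changeover - 1.5, sharpness * 3.5)) + 0.07,
      yolk      = 0.30 * L(changeover, sharpness) + 0.03,
      ecm       = 0.22 * L(changeover + 1.0, sharpness * 1.75) + 0.04)
    post <- 3L
  } else {
    # generic fallback: first half falling, second half rising, staggered
    # centres/widths; last rising component is the sharp post one
    n_fall <- floor((P - 1) / 2)
    n_rise <- P - 1 - n_fall
    cols <- list()
    for (i in seq_len(n_fall))
      cols[[i]] <- (0.55 / n_fall) *
        (1 - L(changeover - (i - 1) * 0.8, sharpness * (1 + 0.8 * (i - 1)))) +
        0.03
    for (i in seq_len(n_rise))
      cols[[n_fall + i]] <- (0.55 / n_rise) *
        L(changeover + (i - 1) * 0.8, sharpness * (1 + 0.8 * (i - 1))) + 0.03
    base <- do.call(cbind, cols)
    post <- n_fall + 1L
  }
  filler <- 1 - rowSums(base)
  if (any(filler <= 0)) stop("class profile weights exceed 1")
  prof <- cbind(base, filler)
  attr(prof, "post_component") <- post
  prof
}

#' Generate a tissue phantom
#'
#' Builds an H x W label raster of S contiguous, equal-width section bands
#' (1..S left to right) framed by background rows (label 0), and per-pixel
#' component abundances. Each tissue pixel is assigned one dominant tissue
#' class, drawn per section according to [class_profiles()]; the dominant
#' component gets abundance ~0.65 and every component additionally
#' contributes a minor abundance 0.25 * profile, so per-pixel abundances sum
#' to < 1. Class counts per section are deterministic quotas (the sharp
#' "post-loop" component by monotone rounding, the rest by largest
#' remainder), so section-mean abundances follow the planted profiles
#' exactly; only pixel placement and the optional abundance jitter are
#' random.
#'
#' @param height,width raster size in pixels; `height * width >= 100 * S`
#' @param S number of sections (>= 2)
#' @param component_names character vector of component names (P >= 3)
#' @param changeover,sharpness passed to [class_profiles()]
#' @param jitter_sd relative s.d. of the multiplicative abundance jitter;
#'   0 disables it (noise off)
#' @param margin background rows added at the top and bottom
#' @param seed RNG seed (pixel placement and jitter)
#' @return an object of class `phantom`: `labels` (H x W integer),
#'   `abundances` (H x W x P), `truth` (H x W dominant component index, 0 on
#'   background), `S`, `component_names`, `profiles`, `pre_sections`,
#'   `post_sections`, `section_sizes`, `seed`
#' @export
make_phantom <- function(height = 60, width = 200, S = 10,
                         component_names = c("nucleus", "cytoplasm", "yolk",
                                             "ecm", "fluid"),
                         changeover = 0.65 * S, sharpness = 0.4,
                         jitter_sd = 0.05, margin = 4, seed = 1) {
  if (S < 2) stop("S must be >= 2")
  P <- length(component_names)
  if (P < 3) stop("need at least 3 components")
  if (height * width < 100 * S) stop("raster too small: need >= 100 pixels per section")
  if (2 * margin >= height) stop("margin leaves no tissue rows")

  prof <- class_profiles(S, P, changeover, sharpness)
  post <- attr(prof, "post_component")

  labels <- matrix(0L, height, width)
  band <- rep(seq_len(S), times = diff(round(seq(0, width, length.out = S + 1))))
  rows <- (margin + 1):(height - margin)
  labels[rows, ] <- matrix(band, length(rows), width, byrow = TRUE)

  set.seed(stage_seed(seed, "phantom"))
  truth <- matrix(0L, height, width)
  abundances <- array(0, c(height, width, P))
  for (s in seq_len(S)) {
    pix <- which(labels == s)
    n <- length(pix)
    # deterministic quotas: monotone rounding for the sharp post component,
    # largest remainder for the rest
    counts <- integer(P)
    counts[post] <- round(n * prof[s, post])
    rest <- setdiff(seq_len(P), post)
    tgt <- prof[s, rest] / sum(prof[s, rest]) * (n - counts[post])
    fl <- floor(tgt)
    rem <- (n - counts[post]) - sum(fl)
    extra <- order(tgt - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
    counts[rest] <- fl
    cls <- sample(rep.int(seq_len(P), counts))
    truth[pix] <- cls
    # abundances: dominant 0.65, minors 0.25 * profile
    ab <- matrix(rep(0.25 * prof[s, ], each = n), n, P)
    ab[cbind(seq_len(n), cls)] <- 0.65
    if (jitter_sd > 0) {
      ab <- ab * matrix(pmax(1 + rnorm(n * P, 0, jitter_sd), 0), n, P)
      over <- rowSums(ab) > 1
      if (any(over)) ab[over, ] <- ab[over, , drop = FALSE] / rowSums(ab[over, , drop = FALSE])
    }
    for (p in seq_len(P)) abundances[, , p][pix] <- ab[, p]
  }

  structure(list(
    labels = labels, abundances = abundances, truth = truth,
    S = as.integer(S), component_names = component_names,
    profiles = prof, post_component = post,
    changeover = changeover, sharpness = sharpness,
    pre_sections = seq_len(floor(changeover)),
    post_sections = (floor(changeover) + 1):S,
    section_sizes = as.integer(tabulate(labels[labels > 0], S)),
    jitter_sd = jitter_sd, seed = seed), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, %d sections, components: %s\n",
              nrow(x$labels), ncol(x$labels), x$S,
              paste(x$component_names, collapse = ", ")))
  invisible(x)
}

#' Per-section mean component abundances of a phantom
#' @param phantom a [make_phantom()] result
#' @return P x S matrix (components x sections)
#' @export
section_mean_abundance <- function(phantom) {
  P <- length(phantom$component_names)
  out <- matrix(NA_real_, P, phantom$S,
                dimnames = list(phantom$component_names, NULL))
  for (s in seq_len(phantom$S)) {
    pix <- which(phantom$labels == s)
    for (p in seq_len(P)) out[p, s] <- mean(phantom$abundances[, , p][pix])
  }
  out
}
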