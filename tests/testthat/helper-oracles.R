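# Independent oracles used across the suite. Each one re-derives the
# quantity from its definition, by a route different from the package code.

# Closed-form complex CARS susceptibility of a list of (omega, A, gamma)
# resonances, evaluated directly from the Lorentzian sum.
oracle_chi <- function(peaks, wavenumbers) {
  chi <- rep(0 + 0i, length(wavenumbers))
  for (p in peaks)
    chi <- chi + p[2] * (complex(real = p[1] - wavenumbers,
                                 imaginary = rep(-p[3],
                                                 length(wavenumbers))))^-1
  chi
}

# O(N^2) local-density count straight from the definition, via stats::dist.
oracle_density <- function(spectra, radius, metric = "L1") {
  method <- if (metric == "L2") "euclidean" else "manhattan"
  dm <- as.matrix(dist(spectra, method = method))
  as.integer(rowSums(dm <= radius))  # diagonal zero counts self
}

# Exhaustive minimum spanning-tree weight by Prufer enumeration of all
# k^(k-2) labeled trees.
oracle_mst_weight <- function(D) {
  k <- nrow(D)
  decode <- function(code) {
    degree <- rep(1L, k)
    for (v in code) degree[v] <- degree[v] + 1L
    w <- 0
    deg <- degree
    for (v in code) {
      leaf <- which(deg == 1L)[1]
      w <- w + D[leaf, v]
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    last <- which(deg == 1L)
    w + D[last[1], last[2]]
  }
  codes <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  min(apply(codes, 1, decode))
}

# Naive average-linkage agglomeration on a distance matrix: returns merge
# heights (ascending) and the member set created by each merge.
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d <- D
  heights <- numeric(0)
  merges <- list()
  while (sum(active) > 1) {
    idx <- which(active)
    bd <- Inf; ba <- NA; bb <- NA
    for (a in idx) for (b in idx) if (a < b && d[a, b] < bd) {
      bd <- d[a, b]; ba <- a; bb <- b
    }
    heights <- c(heights, bd)
    merges[[length(merges) + 1]] <- sort(c(members[[ba]], members[[bb]]))
    for (cc in idx) if (cc != ba && cc != bb) {
      v <- (sizes[ba] * d[ba, cc] + sizes[bb] * d[bb, cc]) /
        (sizes[ba] + sizes[bb])
      d[ba, cc] <- v; d[cc, ba] <- v
    }
    members[[ba]] <- c(members[[ba]], members[[bb]])
    sizes[ba] <- sizes[ba] + sizes[bb]
    active[bb] <- FALSE
  }
  list(heights = heights, merges = merges)
}

# Pearson correlation from its definition.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
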