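#' Cluster downsampled spectra into tree nodes
#'
#' K-means uses seeded plus-plus initialization with `n_restarts` restarts
#' (keeping the lowest within-cluster sum of squares) and Lloyd iterations;
#' empty clusters are repaired by reseeding at the point farthest from its
#' centroid. Agglomerative clustering uses Ward linkage with cluster means
#' as centroids.
#'
#' @param x M x C matrix of downsampled spectra
#' @param k number of clusters (nodes); `M >= k`
#' @param method `"kmeans"` or `"agglomerative"`
#' @param seed RNG seed
#' @param n_restarts k-means restarts
#' @param iter_max Lloyd iteration cap per restart
#' @return list with `centroids` (k x C), `labels` (length M, in 1..k) and
#'   `wss` (total within-cluster sum of squares)
#' @export
cluster_nodes <- function(x, k, method = c("kmeans", "agglomerative"),
                          seed = 1, n_restarts = 10, iter_max = 50) {
  method <- match.arg(method)
  x <- as.matrix(x)
  M <- nrow(x)
  if (k < 1) stop("k must be >= 1")
  if (M < k) stop("fewer points (", M, ") than clusters (", k, ")")
  if (method == "agglomerative") {
    hc <- hclust(dist(x), method = "ward.D2")
    labels <- cutree(hc, k)
    cen <- rowsum(x, labels) / as.vector(table(labels))
    wss <- sum((x - cen[labels, , drop = FALSE])^2)
    return(list(centroids = unname(cen), labels = unname(labels), wss = wss))
  }
  set.seed(stage_seed(seed, "cluster"))
  xs <- rowSums(x^2)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cen <- x[kmeanspp_init(x, xs, k), , drop = FALSE]
    labels <- integer(M)
    for (it in seq_len(iter_max)) {
      d2 <- sq_dist(x, xs, cen)
      new_labels <- max.col(-d2, ties.method = "first")
      # empty-cluster repair: reseed at the point farthest from its centroid
      empty <- setdiff(seq_len(k), unique(new_labels))
      if (length(empty)) {
        resid <- d2[cbind(seq_len(M), new_labels)]
        for (e in empty) {
          far <- which.max(resid)
          cen[e, ] <- x[far, ]
          resid[far] <- -Inf
          new_labels[far] <- e
        }
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      cen <- rowsum(x, labels) / as.vector(tabulate(labels, k))
    }
    wss <- sum((x - cen[labels, , drop = FALSE])^2)
    if (is.null(best) || wss < best$wss)
      best <- list(centroids = unname(cen), labels = labels, wss = wss)
  }
  best
}

# squared Euclidean distances points x centroids via the BLAS identity
sq_dist <- function(x, xs, cen) {
  d2 <- xs - 2 * x %*% t(cen)
  d2 <- sweep(d2, 2, rowSums(cen^2), "+")
  pmax(d2, 0)
}

kmeanspp_init <- function(x, xs, k) {
  M <- nrow(x)
  ids <- integer(k)
  ids[1] <- sample.int(M, 1)
  if (k == 1) return(ids)
  d2 <- sq_dist(x, xs, x[ids[1], , drop = FALSE])[, 1]
  for (j in 2:k) {
    tot <- sum(d2)
    ids[j] <- if (tot <= 0) sample.int(M, 1)
      else sample.int(M, 1, prob = d2 / tot)
    d2 <- pmin(d2, sq_dist(x, xs, x[ids[j], , drop = FALSE])[, 1])
  }
  ids
}

#' Minimum spanning tree over node centroids
#'
#' Prim's algorithm on the pairwise centroid distances with deterministic
#' lexicographic tie-breaking: equal-weight candidate edges are resolved in
#' favour of the earliest-added tree vertex, then the lowest node id.
#'
#' @param centroids k x C matrix
#' @param metric `"L1"` or `"L2"`
#' @return data.frame with columns `from`, `to` (1-based node ids,
#'   `from < to`) and `weight`; `k - 1` rows (zero rows for k = 1)
#' @export
build_mst <- function(centroids, metric = c("L1", "L2")) {
  metric <- match.arg(metric)
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k == 0) stop("no centroids")
  if (k == 1) return(data.frame(from = integer(), to = integer(),
                                weight = numeric()))
  D <- as.matrix(dist(centroids, method = dist_method(metric)))
  intree <- c(TRUE, rep(FALSE, k - 1))
  key <- D[1, ]; key[1] <- Inf
  parent <- rep(1L, k)
  edges <- matrix(0, k - 1, 3)
  for (e in seq_len(k - 1)) {
    cand <- which(!intree)
    v <- cand[which.min(key[cand])]   # first index wins ties -> lowest id
    intree[v] <- TRUE
    i <- min(parent[v], v); j <- max(parent[v], v)
    edges[e, ] <- c(i, j, key[v])
    key[v] <- Inf
    upd <- !intree & D[v, ] < key     # strict improvement keeps first parent
    parent[upd] <- v
    key[upd] <- D[v, upd]
  }
  out <- data.frame(from = as.integer(edges[, 1]),
                    to = as.integer(edges[, 2]), weight = edges[, 3])
  out[order(out$from, out$to), , drop = FALSE]
}

#' Force-directed layout of a spanning tree
#'
#' Fruchterman-Reingold spring-electrical layout with a seeded random
#' initial placement and a fixed iteration count; coordinates are
#' deterministic given the seed and carry no meaning beyond connectivity.
#'
#' @param edges data.frame from [build_mst()]
#' @param k node count
#' @param seed RNG seed
#' @param iterations iteration count
#' @return k x 2 matrix of coordinates
#' @export
layout_tree <- function(edges, k, seed = 1, iterations = 500) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to),
    directed = FALSE, vertices = data.frame(name = seq_len(k)))
  if (nrow(edges) != k - 1 || !igraph::is_connected(g))
    stop("edges do not form a spanning tree")
  set.seed(stage_seed(seed, "layout"))
  init <- matrix(runif(2 * k, -1, 1), k, 2)
  xy <- igraph::layout_with_fr(g, coords = init, niter = iterations,
                               weights = rep(1, nrow(edges)))
  # guarantee distinct coordinates (degenerate overlaps get a tiny
  # deterministic displacement)
  dup <- duplicated(round(xy, 9))
  if (any(dup)) xy[dup, ] <- xy[dup, ] + 1e-6 * seq_len(sum(dup))
  xy
}

#' Spectral spanning tree
#'
#' Bundles node centroids, MST edges, layout, the training image's in-mask
#' mean spectrum (for centered cross-image projection) and the parameters
#' and seed that produced them.
#'
#' @param centroids k x C matrix
#' @param edges data.frame from [build_mst()]
#' @param layout k x 2 matrix
#' @param axis the training cube's [wavenumber_axis()]
#' @param train_mean training in-mask mean spectrum (length C)
#' @param params parameter echo (list)
#' @param seed seed echo
#' @export
spectral_tree <- function(centroids, edges, layout, axis, train_mean,
                          params = list(), seed = NA_integer_) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (!all(is.finite(centroids))) stop("non-finite centroid rows")
  if (nrow(edges) != max(k - 1, 0)) stop("edges must number k - 1")
  structure(list(centroids = centroids, edges = edges, layout = layout,
                 k = k, axis = axis, train_mean = train_mean,
                 params = params, seed = seed),
            class = "spectral_tree")
}

#' @export
print.spectral_tree <- function(x, ...) {
  cat(sprintf("<spectral_tree> %d nodes, %d edges, %d channels\n",
              x$k, nrow(x$edges), ncol(x$centroids)))
  invisible(x)
}

#' Assign every masked pixel to its nearest node
#'
#' All in-mask pixels (including density outliers removed before
#' clustering) are assigned to the nearest centroid under the metric; ties
#' break to the lowest node id.
#'
#' @param cube retrieved-flavor [hyper_cube()]
#' @param mask H x W logical (defaults to the cube mask)
#' @param centroids k x C matrix
#' @param metric `"L1"` or `"L2"`
#' @return a `pixel_assignment`: `node_id` (H x W integer, `NA` outside the
#'   mask), `counts` (per-node pixel counts), `k`
#' @export
assign_pixels <- function(cube, mask = NULL, centroids,
                          metric = c("L1", "L2")) {
  metric <- match.arg(metric)
  pm <- cube_pixel_matrix(cube, mask)
  if (!length(pm$idx)) stop("empty mask")
  centroids <- as.matrix(centroids)
  ids <- .nearest_centroid_idx(t(pm$spectra), t(centroids),
                               metric_code(metric))
  node_id <- matrix(NA_integer_, pm$dim[1], pm$dim[2])
  node_id[pm$idx] <- ids
  structure(list(node_id = node_id, counts = tabulate(ids, nrow(centroids)),
                 k = nrow(centroids)), class = "pixel_assignment")
}

#' Mean spectrum of each node
#'
#' Row n is the arithmetic mean of the spectra of pixels assigned to node
#' n. Empty nodes are flagged (attribute `empty_nodes`) and filled with the
#' supplied centroid when available.
#'
#' @param cube retrieved-flavor [hyper_cube()]
#' @param assignment a [assign_pixels()] result
#' @param centroids optional k x C fallback for empty nodes
#' @return k x C matrix
#' @export
node_mean_spectra <- function(cube, assignment, centroids = NULL) {
  d <- dim(cube$data)
  ids <- assignment$node_id
  idx <- which(!is.na(ids))
  mat <- matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  k <- assignment$k
  sums <- rowsum(mat, ids[idx])
  out <- matrix(NA_real_, k, d[3])
  present <- as.integer(rownames(sums))
  out[present, ] <- sums / assignment$counts[present]
  empty <- which(assignment$counts == 0)
  if (length(empty) && !is.null(centroids))
    out[empty, ] <- as.matrix(centroids)[empty, , drop = FALSE]
  attr(out, "empty_nodes") <- empty
  out
}

#' Project a new cube onto an existing tree
#'
#' With `center = TRUE`, the new image's in-mask mean spectrum is
#' subtracted from each pixel and the training image's in-mask mean from
#' each centroid before nearest-centroid assignment, which cancels
#' image-to-image offset spectra (difference-spectrum correction); with
#' `center = FALSE` assignment runs on the retrieved spectra as is.
#'
#' @param new_cube retrieved-flavor [hyper_cube()] sharing the tree's axis
#' @param mask H x W logical (defaults to the cube mask)
#' @param tree a [spectral_tree()]
#' @param center subtract the respective mean spectra first?
#' @param metric `"L1"` or `"L2"`
#' @return a `pixel_assignment`
#' @export
project_to_tree <- function(new_cube, mask = NULL, tree, center = FALSE,
                            metric = c("L1", "L2")) {
  metric <- match.arg(metric)
  if (!isTRUE(all.equal(new_cube$axis$values, tree$axis$values)))
    stop("wavenumber axis mismatch between cube and tree")
  if (!center)
    return(assign_pixels(new_cube, mask, tree$centroids, metric))
  pm <- cube_pixel_matrix(new_cube, mask)
  if (!length(pm$idx)) stop("empty mask")
  sp <- sweep(pm$spectra, 2, colMeans(pm$spectra))
  cen <- sweep(as.matrix(tree$centroids), 2, tree$train_mean)
  ids <- .nearest_centroid_idx(t(sp), t(cen), metric_code(metric))
  node_id <- matrix(NA_integer_, pm$dim[1], pm$dim[2])
  node_id[pm$idx] <- ids
  structure(list(node_id = node_id, counts = tabulate(ids, tree$k),
                 k = tree$k), class = "pixel_assignment")
}

#' Grow a spectral tree from a retrieved cube
#'
#' The full SPADE-style sequence: radius selection, exact local densities,
#' density-dependent downsampling with outlier removal, clustering into `k`
#' nodes, MST over the centroids, force-directed layout, and assignment of
#' every in-mask pixel to its nearest node.
#'
#' @param cube retrieved-flavor [hyper_cube()]
#' @param mask H x W logical (defaults to the cube mask)
#' @param k node count (the reference configuration uses 300)
#' @param downsample a [downsample_params()]
#' @param cluster_method `"kmeans"` or `"agglomerative"`
#' @param layout_iterations force-directed iterations
#' @param seed RNG seed governing every stochastic step
#' @return list with `tree` ([spectral_tree()]), `assignment`
#'   ([assign_pixels()] result), `node_spectra`, `kept` (downsampled row
#'   indices into the in-mask pixel list), `densities`, `radius`
#' @export
grow_spectral_tree <- function(cube, mask = NULL, k = 300,
                               downsample = downsample_params(),
                               cluster_method = "kmeans",
                               layout_iterations = 500, seed = 1) {
  if (cube$flavor != "retrieved")
    stop("grow_spectral_tree expects a retrieved cube")
  pm <- cube_pixel_matrix(cube, mask)
  radius <- choose_radius(pm$spectra, downsample$radius_alpha,
                          downsample$density_subsample, downsample$metric,
                          seed = seed)
  dens <- estimate_density(pm$spectra, radius, downsample$metric)
  kept <- density_downsample(pm$spectra, dens, downsample, seed = seed)
  cl <- cluster_nodes(pm$spectra[kept, , drop = FALSE], k,
                      method = cluster_method, seed = seed)
  edges <- build_mst(cl$centroids, downsample$metric)
  layout <- layout_tree(edges, k, seed = seed,
                        iterations = layout_iterations)
  tree <- spectral_tree(cl$centroids, edges, layout, cube$axis,
                        train_mean = colMeans(pm$spectra),
                        params = list(k = k, downsample = downsample,
                                      cluster_method = cluster_method,
                                      layout_iterations = layout_iterations),
                        seed = seed)
  assignment <- assign_pixels(cube, mask, cl$centroids, downsample$metric)
  list(tree = tree, assignment = assignment,
       node_spectra = node_mean_spectra(cube, assignment, cl$centroids),
       kept = kept, densities = dens, radius = radius)
}
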