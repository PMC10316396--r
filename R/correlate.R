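#' Section-by-section profile correlation
#'
#' Pearson correlation between every pair of section columns across the
#' table rows — identical machinery for node-frequency tables (rows =
#' nodes) and gene-expression tables (rows = genes). Constant columns give
#' undefined (`NA`) entries, never silent zeros.
#'
#' @param table rows x S numeric matrix, or a `node_frequency_table`
#'   (fractions used) or `gene_expression_table`
#' @param use_sections optional subset of section indices (dropped sections
#'   are excluded automatically for frequency tables)
#' @return S x S correlation matrix of class `correlation_matrix` (entries
#'   `NA` where undefined; diagonal 1 where defined), with attribute
#'   `method = "pearson"`
#' @export
section_profile_correlation <- function(table, use_sections = NULL) {
  m <- profile_matrix(table)
  if (is.null(use_sections) && inherits(table, "node_frequency_table"))
    use_sections <- setdiff(seq_len(ncol(m)), table$dropped_sections)
  S <- ncol(m)
  sel <- use_sections %||% seq_len(S)
  if (nrow(m) < 2 || length(sel) < 2) stop("need >= 2 rows and >= 2 sections")
  cm <- matrix(NA_real_, S, S)
  cm[sel, sel] <- suppressWarnings(cor(m[, sel, drop = FALSE]))
  ok <- intersect(sel, which(apply(m, 2, sd) > 0))
  undef <- setdiff(sel, ok)
  cm[undef, ] <- NA_real_
  cm[, undef] <- NA_real_
  dg <- diag(cm); dg[ok] <- 1; diag(cm) <- dg
  structure(cm, method = "pearson", class = c("correlation_matrix",
                                              "matrix", "array"))
}

profile_matrix <- function(table) {
  if (inherits(table, "node_frequency_table")) return(table$fractions)
  if (inherits(table, "gene_expression_table")) return(gene_values(table))
  as.matrix(table)
}

#' Filter for dynamic genes
#'
#' Keeps genes whose expression changes by at least `fold` across sections:
#' `max / max(min, eps) >= fold` with pseudocount
#' `eps = 1e-6 * max(table)`; the threshold is inclusive.
#'
#' @param table a `gene_expression_table` (or G x S matrix)
#' @param fold fold-change threshold (>= 1), default 2
#' @return the filtered table (same class), possibly with zero rows
#' @export
dynamic_gene_filter <- function(table, fold = 2) {
  stopifnot(fold >= 1)
  m <- profile_matrix(table)
  eps <- 1e-6 * max(m)
  keep <- apply(m, 1, max) / pmax(apply(m, 1, min), eps) >= fold
  if (!any(keep)) message("dynamic_gene_filter: no gene passes ", fold,
                          "-fold")
  if (is.data.frame(table)) table[keep, , drop = FALSE]
  else m[keep, , drop = FALSE]
}

#' Node-node correlation clustermap
#'
#' Pearson correlation between every pair of node fraction profiles across
#' sections (a k x k matrix), hierarchically clustered (average linkage on
#' Euclidean distances between correlation-matrix rows) to give a leaf
#' ordering, plus per-node standardized fractions in that ordering.
#' Zero-variance nodes get undefined (`NA`) rows and sink to the end of the
#' ordering.
#'
#' @param freq_table a `node_frequency_table`
#' @param zscore_divisor `"sd"` (standard; unit-variance rows) or `"var"`
#' @return list with `corr` (k x k), `order` (leaf ordering, undefined
#'   nodes last), `zscores` (k x S, rows in that ordering, rownames = node
#'   ids), `linkage = "average"`, `dist_metric = "euclidean"`
#' @export
node_clustermap <- function(freq_table, zscore_divisor = c("sd", "var")) {
  zscore_divisor <- match.arg(zscore_divisor)
  sel <- setdiff(seq_len(freq_table$S), freq_table$dropped_sections)
  if (length(sel) < 3) stop("need at least 3 non-empty sections")
  f <- freq_table$fractions[, sel, drop = FALSE]
  k <- nrow(f)
  sds <- apply(f, 1, sd)
  defined <- which(sds > 0)
  corr <- matrix(NA_real_, k, k)
  corr[defined, defined] <- suppressWarnings(cor(t(f[defined, , drop = FALSE])))
  ord <- if (length(defined) > 2) {
    hc <- hclust(dist(corr[defined, defined, drop = FALSE]),
                 method = "average")
    defined[hc$order]
  } else defined
  ord <- c(ord, setdiff(seq_len(k), defined))
  mu <- rowMeans(f)
  div <- if (zscore_divisor == "sd") sds else sds^2
  z <- (f - mu) / div
  z[sds == 0, ] <- NA_real_
  z <- z[ord, , drop = FALSE]
  rownames(z) <- ord
  list(corr = corr, order = ord, zscores = z, linkage = "average",
       dist_metric = "euclidean", zscore_divisor = zscore_divisor,
       sections_used = sel)
}

#' Correlate one gene profile with every node's fraction profile
#'
#' @param gene_profile length-S expression profile (full section set;
#'   dropped sections are excluded together with the table's)
#' @param freq_table a `node_frequency_table`
#' @return length-k vector of Pearson r values (`NA` where undefined, e.g.
#'   constant gene or constant node profile)
#' @export
gene_node_correlation <- function(gene_profile, freq_table) {
  sel <- setdiff(seq_len(freq_table$S), freq_table$dropped_sections)
  if (length(gene_profile) != freq_table$S)
    stop("gene profile length does not match section count")
  if (length(sel) < 3) stop("fewer than 3 shared sections")
  g <- gene_profile[sel]
  suppressWarnings(
    as.vector(cor(g, t(freq_table$fractions[, sel, drop = FALSE]))))
}

#' Top gene-correlated nodes
#'
#' Defined r values sorted descending, ties broken by ascending node id;
#' undefined values never enter the selection.
#'
#' @param r_values length-k vector from [gene_node_correlation()]
#' @param top_k how many nodes (default 10)
#' @return integer vector of node ids (possibly shorter than `top_k`;
#'   empty, with a warning, when no r is defined)
#' @export
top_gene_nodes <- function(r_values, top_k = 10) {
  stopifnot(top_k >= 1)
  defined <- which(!is.na(r_values))
  if (!length(defined)) {
    warning("no defined correlations; returning no nodes")
    return(integer())
  }
  ord <- defined[order(-r_values[defined], defined)]
  head(ord, top_k)
}

#' Highlight the pixels of selected nodes
#'
#' @param node_ids integer node ids (1-based)
#' @param assignment a [assign_pixels()] result
#' @return H x W logical mask, `TRUE` exactly where the pixel's node is in
#'   `node_ids`
#' @export
highlight_gene_pixels <- function(node_ids, assignment) {
  if (length(node_ids) &&
      (any(node_ids < 1) || any(node_ids > assignment$k)))
    stop("unknown node id")
  m <- matrix(FALSE, nrow(assignment$node_id), ncol(assignment$node_id))
  if (length(node_ids))
    m[] <- assignment$node_id %in% node_ids
  m
}

#' Histogram of gene-node correlations
#'
#' @param r_values vector of r values (`NA` allowed)
#' @param bins number of equal-width bins on `[-1, 1]`
#' @return list with `counts`, `edges` (length `bins + 1`) and
#'   `undefined` (count of `NA` values)
#' @export
correlation_histogram <- function(r_values, bins = 20) {
  stopifnot(bins >= 1)
  edges <- seq(-1, 1, length.out = bins + 1)
  def <- r_values[!is.na(r_values)]
  bin <- pmin(pmax(findInterval(def, edges, rightmost.closed = TRUE), 1),
              bins)
  list(counts = tabulate(bin, bins), edges = edges,
       undefined = sum(is.na(r_values)))
}

#' Full per-gene node report
#'
#' @param gene_profile length-S expression profile
#' @param freq_table a `node_frequency_table`
#' @param assignment a [assign_pixels()] result
#' @param top_k top-node count
#' @param bins histogram bins
#' @return list: `r_values`, `top_nodes`, `highlight` mask, `histogram`
#' @export
gene_node_report <- function(gene_profile, freq_table, assignment,
                             top_k = 10, bins = 20) {
  r <- gene_node_correlation(gene_profile, freq_table)
  top <- if (all(is.na(r))) integer() else top_gene_nodes(r, top_k)
  list(r_values = r, top_nodes = top,
       highlight = highlight_gene_pixels(top, assignment),
       histogram = correlation_histogram(r, bins))
}
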