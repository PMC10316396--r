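#' Write a cube bundle
#'
#' Self-describing on-disk layout for a hyperspectral cube and its phantom
#' companions: `meta.json` (axis, dimensions, flavor, config echo) next to
#' flat little-endian float32 binaries (`cube.f32`, optional
#' `abundances.f32`), 16-bit integer TIFF rasters (`labels.tif`,
#' `truth.tif`, `mask.tif`) and a CSV NRB reference. Values round-trip at
#' float32 precision.
#'
#' @param dir directory to create/overwrite
#' @param cube a [hyper_cube()]
#' @param nrb optional NRB reference spectrum
#' @param phantom optional [make_phantom()] result (labels, abundances,
#'   truth are stored)
#' @param config optional list echoed into the metadata
#' @export
write_cube_bundle <- function(dir, cube, nrb = NULL, phantom = NULL,
                              config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cube$data)
  meta <- list(format = "spectree-bundle-1",
               dim = d, order = "H,W,C column-major", dtype = "float32le",
               axis = list(start = cube$axis$start, step = cube$axis$step,
                           n_channels = cube$axis$n_channels),
               flavor = cube$flavor,
               has_nrb = !is.null(nrb), has_phantom = !is.null(phantom),
               config = config)
  if (!is.null(phantom)) {
    meta$components <- phantom$component_names
    meta$S <- phantom$S
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  write_f32(file.path(dir, "cube.f32"), as.vector(cube$data))
  if (!is.null(cube$mask)) write_label_tiff(cube$mask * 1L,
                                            file.path(dir, "mask.tif"))
  if (!is.null(nrb))
    write.csv(data.frame(wavenumber = cube$axis$values, nrb = nrb),
              file.path(dir, "nrb.csv"), row.names = FALSE)
  if (!is.null(phantom)) {
    write_label_tiff(phantom$labels, file.path(dir, "labels.tif"))
    write_label_tiff(phantom$truth, file.path(dir, "truth.tif"))
    write_f32(file.path(dir, "abundances.f32"),
              as.vector(phantom$abundances))
  }
  invisible(dir)
}

#' Read a cube bundle
#' @param dir directory written by [write_cube_bundle()]
#' @return list with `cube`, and `nrb`, `labels`, `truth`, `abundances`,
#'   `meta` when present
#' @export
read_cube_bundle <- function(dir) {
  mp <- file.path(dir, "meta.json")
  if (!file.exists(mp)) stop("format error: missing dataset meta.json")
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(meta$format, "spectree-bundle-1"))
    stop("format error: unrecognized bundle format")
  d <- as.integer(meta$dim)
  cf <- file.path(dir, "cube.f32")
  if (!file.exists(cf)) stop("format error: missing dataset cube.f32")
  vals <- read_f32(cf, prod(d))
  axis <- wavenumber_axis(meta$axis$start, meta$axis$step,
                          meta$axis$n_channels)
  mask <- if (file.exists(file.path(dir, "mask.tif")))
    read_label_tiff(file.path(dir, "mask.tif")) > 0 else NULL
  out <- list(cube = hyper_cube(array(vals, d), axis, meta$flavor,
                                mask = mask),
              meta = meta)
  if (file.exists(file.path(dir, "nrb.csv")))
    out$nrb <- read.csv(file.path(dir, "nrb.csv"))$nrb
  if (file.exists(file.path(dir, "labels.tif")))
    out$labels <- read_label_tiff(file.path(dir, "labels.tif"))
  if (file.exists(file.path(dir, "truth.tif")))
    out$truth <- read_label_tiff(file.path(dir, "truth.tif"))
  af <- file.path(dir, "abundances.f32")
  if (file.exists(af)) {
    P <- length(meta$components)
    out$abundances <- array(read_f32(af, d[1] * d[2] * P),
                            c(d[1], d[2], P))
  }
  out
}

write_f32 <- function(path, values) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 4, endian = "little")
}

read_f32 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(out) != n) stop("format error: ", basename(path),
                             " truncated (", length(out), " of ", n, ")")
  out
}

#' Write / read an integer label raster as 16-bit TIFF
#'
#' @param labels H x W integer matrix with values in 0..65535
#' @param path file path
#' @export
write_label_tiff <- function(labels, path) {
  if (any(labels < 0) || any(labels > 65535))
    stop("labels out of 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read a gene-expression table as CSV
#'
#' First column `gene`, then `section_1..section_S`.
#'
#' @param table a `gene_expression_table`
#' @param path file path
#' @export
write_gene_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @param S expected section count (checked when given)
#' @export
read_gene_table <- function(path, S = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("format error: missing column gene")
  sec <- grep("^section_", names(df), value = TRUE)
  want <- paste0("section_", seq_len(S %||% length(sec)))
  missing <- setdiff(want, sec)
  if (length(missing))
    stop("format error: missing column ", missing[1])
  if (!all(vapply(df[sec], is.numeric, TRUE)))
    stop("format error: non-numeric section column")
  structure(df[c("gene", want)], class = c("gene_expression_table",
                                           "data.frame"))
}

#' Write / read a spectral tree as JSON
#'
#' Centroids, edges, layout, axis, training mean, params and seed; edges
#' round-trip exactly (integer ids), numeric payloads at full printed
#' precision.
#'
#' @param tree a [spectral_tree()]
#' @param path file path
#' @export
write_tree <- function(tree, path) {
  obj <- list(format = "spectree-tree-1", k = tree$k,
              axis = list(start = tree$axis$start, step = tree$axis$step,
                          n_channels = tree$axis$n_channels),
              centroids = tree$centroids,
              edges = list(from = tree$edges$from, to = tree$edges$to,
                           weight = tree$edges$weight),
              layout = tree$layout, train_mean = tree$train_mean,
              params = tree$params, seed = tree$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "spectree-tree-1"))
    stop("format error: not a spectree tree file")
  axis <- wavenumber_axis(obj$axis$start, obj$axis$step,
                          obj$axis$n_channels)
  edges <- data.frame(from = as.integer(obj$edges$from),
                      to = as.integer(obj$edges$to),
                      weight = as.numeric(obj$edges$weight))
  spectral_tree(obj$centroids, edges, obj$layout, axis, obj$train_mean,
                params = obj$params, seed = obj$seed)
}

#' Write a node-frequency table (fractions + counts) as CSV
#'
#' @param freq a `node_frequency_table`
#' @param path fractions CSV path; counts go to `*_counts.csv`
#' @export
write_frequency_table <- function(freq, path) {
  secs <- paste0("section_", seq_len(freq$S))
  fr <- data.frame(node = seq_len(freq$k), freq$fractions)
  names(fr) <- c("node", secs)
  write.csv(fr, path, row.names = FALSE)
  ct <- data.frame(node = seq_len(freq$k), freq$counts)
  names(ct) <- c("node", secs)
  write.csv(ct, sub("\\.csv$", "_counts.csv", path), row.names = FALSE)
  invisible(path)
}

#' Write the assignment raster as 16-bit TIFF
#'
#' Node ids are stored 1-based; 0 marks pixels outside the mask.
#'
#' @param assignment a [assign_pixels()] result
#' @param path file path
#' @export
write_assignment_tiff <- function(assignment, path) {
  m <- assignment$node_id
  m[is.na(m)] <- 0L
  write_label_tiff(m, path)
}

#' @rdname write_assignment_tiff
#' @export
read_assignment_tiff <- function(path) {
  m <- read_label_tiff(path)
  ids <- m
  ids[ids == 0] <- NA_integer_
  structure(list(node_id = ids, counts = tabulate(ids[!is.na(ids)],
                                                  max(m)),
                 k = max(m)), class = "pixel_assignment")
}
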