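#' Pipeline configuration
#'
#' One structured configuration object from which every stage reads its
#' parameters; all randomness flows from the single root `seed` through
#' named per-stage substreams.
#'
#' @param seed root RNG seed
#' @param axis a [wavenumber_axis()]
#' @param phantom list of [make_phantom()] arguments (ignored when
#'   `input_dir` points at an existing bundle)
#' @param library a [component_library()]
#' @param gene_specs list of [gene_spec()]s
#' @param noise a [noise_model()]
#' @param retrieve a [retrieval_params()]; set `retrieve_enabled = FALSE`
#'   to feed an already retrieved cube through unchanged
#' @param retrieve_enabled run retrieval? (a retrieved-flavor input skips
#'   it regardless)
#' @param downsample a [downsample_params()]
#' @param k node count
#' @param cluster_method `"kmeans"` or `"agglomerative"`
#' @param layout_iterations force-directed iterations
#' @param top_k top gene-correlated nodes per gene
#' @param fold dynamic-gene fold threshold
#' @param zscore_divisor `"sd"` or `"var"`
#' @param input_dir optional bundle directory to load instead of simulating
#' @param out_dir optional output directory for all artifacts
#' @export
pipeline_config <- function(seed = 1, axis = wavenumber_axis(),
                            phantom = list(height = 60, width = 200, S = 10),
                            library = default_component_library(),
                            gene_specs = default_gene_specs(),
                            noise = noise_model(),
                            retrieve = retrieval_params(),
                            retrieve_enabled = TRUE,
                            downsample = downsample_params(),
                            k = 300, cluster_method = "kmeans",
                            layout_iterations = 500, top_k = 10, fold = 2,
                            zscore_divisor = "sd", input_dir = NULL,
                            out_dir = NULL) {
  structure(list(seed = seed, axis = axis, phantom = phantom,
                 library = library, gene_specs = gene_specs, noise = noise,
                 retrieve = retrieve, retrieve_enabled = retrieve_enabled,
                 downsample = downsample, k = k,
                 cluster_method = cluster_method,
                 layout_iterations = layout_iterations, top_k = top_k,
                 fold = fold, zscore_divisor = zscore_divisor,
                 input_dir = input_dir, out_dir = out_dir),
            class = "pipeline_config")
}

#' Reference synthetic study configuration
#'
#' The fixed conditions used throughout the package's validation: a
#' 200 x 60 px phantom with 10 sections and the default five-component
#' library and gene panel, and a 50-node tree.
#'
#' @param seed root RNG seed
#' @param ... overrides passed to [pipeline_config()]
#' @export
synthetic_study_config <- function(seed = 1, ...) {
  pipeline_config(seed = seed, k = 50, ...)
}

#' Run the full pipeline
#'
#' simulate (or load) -> retrieve -> tree -> sections -> correlate. Writes
#' all artifacts when `config$out_dir` is set and returns the report
#' bundle.
#'
#' @param config a [pipeline_config()]
#' @param verbose log stage progress
#' @return a list report: `phantom`, `cube` (retrieved), `nrb`, `tree`,
#'   `assignment`, `node_spectra`, `freq`, `section_corr`, `clustermap`,
#'   `section_diff`, `gene_table`, `dynamic_genes`, `gene_section_corr`,
#'   `gene_reports`, `dropped_sections`, `timings`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
    if (verbose) message(sprintf("stage %-10s %.1fs", stage,
                                 timings[[stage]]))
  }

  # --- simulate / load -------------------------------------------------
  phantom <- NULL; gene_table <- NULL
  if (!is.null(config$input_dir)) {
    b <- read_cube_bundle(config$input_dir)
    cube <- b$cube; nrb <- b$nrb
    labels <- b$labels %||% stop("input bundle lacks a section raster")
    gt <- file.path(config$input_dir, "genes.csv")
    if (file.exists(gt)) gene_table <- read_gene_table(gt)
  } else {
    phantom <- do.call(make_phantom, c(config$phantom,
                                       list(seed = config$seed)))
    r <- render_cars_cube(phantom, config$library, config$axis,
                          config$noise, seed = config$seed)
    cube <- r$cube; nrb <- r$nrb; labels <- phantom$labels
    gene_table <- make_expression_table(phantom, config$gene_specs,
                                        seed = config$seed)
  }
  tick("simulate")

  # --- retrieve --------------------------------------------------------
  if (cube$flavor == "raw") {
    if (!config$retrieve_enabled)
      stop("raw-flavor input but retrieval is disabled")
    cube <- retrieve_cube(cube, nrb, config$retrieve, verbose = verbose)
  }
  tick("retrieve")

  # --- tree ------------------------------------------------------------
  tr <- grow_spectral_tree(cube, mask = NULL, k = config$k,
                           downsample = config$downsample,
                           cluster_method = config$cluster_method,
                           layout_iterations = config$layout_iterations,
                           seed = config$seed)
  tick("tree")

  # --- sections --------------------------------------------------------
  freq <- section_node_frequency(tr$assignment, labels)
  section_diff <- section_difference_spectra(cube, labels)
  tick("sections")

  # --- correlate -------------------------------------------------------
  section_corr <- section_profile_correlation(freq)
  cm <- node_clustermap(freq, config$zscore_divisor)
  dynamic <- gene_section_corr <- gene_reports <- NULL
  if (!is.null(gene_table)) {
    dynamic <- dynamic_gene_filter(gene_table, config$fold)
    if (nrow(dynamic) >= 2)
      gene_section_corr <- section_profile_correlation(
        gene_values(dynamic)[, setdiff(seq_len(freq$S),
                                       freq$dropped_sections),
                             drop = FALSE])
    gv <- gene_values(gene_table)
    gene_reports <- lapply(seq_len(nrow(gv)), function(i)
      gene_node_report(gv[i, ], freq, tr$assignment,
                       top_k = config$top_k))
    names(gene_reports) <- rownames(gv)
  }
  tick("correlate")

  report <- list(phantom = phantom, cube = cube, nrb = nrb,
                 labels = labels, tree = tr$tree,
                 assignment = tr$assignment,
                 node_spectra = tr$node_spectra, radius = tr$radius,
                 freq = freq, section_corr = section_corr,
                 clustermap = cm, section_diff = section_diff,
                 gene_table = gene_table, dynamic_genes = dynamic,
                 gene_section_corr = gene_section_corr,
                 gene_reports = gene_reports,
                 dropped_sections = freq$dropped_sections,
                 timings = timings, config = config)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the report bundle to disk
#'
#' CSV matrices and tables, JSON tree and summary, TIFF rasters.
#'
#' @param report a [run_pipeline()] result
#' @param out_dir output directory
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_frequency_table(report$freq, fp("node_frequencies.csv"))
  write_matrix_csv(report$section_corr, fp("section_correlation.csv"),
                   "section")
  write_matrix_csv(report$clustermap$corr, fp("node_correlation.csv"),
                   "node")
  write_matrix_csv(report$clustermap$zscores, fp("node_zscores.csv"),
                   "node", rownames(report$clustermap$zscores))
  write_matrix_csv(report$section_diff, fp("section_difference_spectra.csv"),
                   "section")
  write_tree(report$tree, fp("tree.json"))
  write_assignment_tiff(report$assignment, fp("assignment.tif"))
  write_label_tiff(report$labels, fp("sections.tif"))
  if (!is.null(report$gene_table))
    write_gene_table(report$gene_table, fp("genes.csv"))
  if (!is.null(report$gene_section_corr))
    write_matrix_csv(report$gene_section_corr,
                     fp("gene_section_correlation.csv"), "section")
  summary <- list(
    dropped_sections = report$dropped_sections,
    node_order = report$clustermap$order,
    radius = report$radius,
    top_nodes = lapply(report$gene_reports, function(g)
      list(top_nodes = g$top_nodes,
           undefined = g$histogram$undefined)),
    timings = as.list(report$timings),
    config_hash = config_hash(report$config))
  jsonlite::write_json(summary, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

write_matrix_csv <- function(m, path, prefix, rnames = NULL) {
  m <- as.matrix(m)
  df <- data.frame(id = rnames %||% seq_len(nrow(m)), m)
  names(df) <- c(prefix, paste0(prefix, "_", seq_len(ncol(m))))
  write.csv(df, path, row.names = FALSE)
}

# stable short hash of the serialized config (djb2 over the deparsed text;
# enough to detect config drift between outputs)
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
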