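#' Specification of one synthetic gene
#'
#' Three kinds: `anchor` genes track the per-section mean abundance of a
#' linked component (`expr(s) = a + b * mean_abundance(s) + noise`), `flat`
#' genes are constant negative controls (gain 0), and `random` genes have
#' i.i.d. lognormal section values unrelated to the phantom.
#'
#' @param name gene label
#' @param kind `"anchor"`, `"flat"` or `"random"`
#' @param component linked component name (anchor genes only)
#' @param a baseline expression offset (>= 0)
#' @param b coupling slope (anchor genes; forced 0 for flat genes)
#' @param noise_sd Gaussian noise s.d. on the expression scale
#' @export
gene_spec <- function(name, kind = c("anchor", "flat", "random"),
                      component = NA_character_, a = 0, b = 0,
                      noise_sd = 0) {
  kind <- match.arg(kind)
  stopifnot(a >= 0, noise_sd >= 0)
  if (kind == "anchor" && is.na(component))
    stop("anchor gene ", name, " must name a component")
  if (kind == "flat") b <- 0
  structure(list(name = name, kind = kind, component = component,
                 a = a, b = b, noise_sd = noise_sd), class = "gene_spec")
}

#' Default synthetic gene panel
#'
#' One anchor gene per component (baseline 2, gain 40, noise s.d. 0.5 on the
#' expression scale), one exactly flat control at roughly three times the
#' anchors' typical level, and five random genes.
#'
#' @param component_names components to anchor
#' @export
default_gene_specs <- function(component_names = c("nucleus", "cytoplasm",
                                                   "yolk", "ecm", "fluid")) {
  specs <- lapply(component_names, function(nm)
    gene_spec(paste0("anchor_", nm), "anchor", component = nm,
              a = 2, b = 40, noise_sd = 0.5))
  specs <- c(specs, list(gene_spec("flat_ctrl", "flat", a = 30,
                                   noise_sd = 0)))
  c(specs, lapply(seq_len(5), function(i)
    gene_spec(paste0("random_", i), "random", a = 10, noise_sd = 0)))
}

#' Synthetic gene-expression table coupled to a phantom
#'
#' @param phantom a [make_phantom()] result
#' @param gene_specs list of [gene_spec()]s; must contain at least one
#'   anchor and one flat gene
#' @param seed RNG seed
#' @return a `gene_expression_table`: data.frame with column `gene` followed
#'   by `section_1..section_S`; gene kinds echoed in attribute `specs`
#' @export
make_expression_table <- function(phantom,
                                  gene_specs = default_gene_specs(phantom$component_names),
                                  seed = 1) {
  kinds <- vapply(gene_specs, `[[`, "", "kind")
  if (!any(kinds == "anchor") || !any(kinds == "flat"))
    stop("need at least one anchor and one flat gene")
  msec <- section_mean_abundance(phantom)  # P x S
  S <- phantom$S
  set.seed(stage_seed(seed, "genes"))
  rows <- lapply(gene_specs, function(g) {
    v <- switch(g$kind,
      anchor = {
        p <- match(g$component, phantom$component_names)
        if (is.na(p)) stop("anchor gene ", g$name,
                           " names unknown component ", g$component)
        g$a + g$b * msec[p, ]
      },
      flat = rep(g$a, S),
      random = rlnorm(S, meanlog = log(pmax(g$a, 1e-6)), sdlog = 0.5))
    if (g$noise_sd > 0) v <- v + rnorm(S, 0, g$noise_sd)
    pmax(v, 0)
  })
  values <- do.call(rbind, rows)
  colnames(values) <- paste0("section_", seq_len(S))
  tab <- data.frame(gene = vapply(gene_specs, `[[`, "", "name"),
                    values, check.names = FALSE)
  structure(tab, specs = gene_specs, class = c("gene_expression_table",
                                               "data.frame"))
}

# G x S numeric matrix of a gene table, with gene names as rownames
gene_values <- function(table) {
  m <- as.matrix(table[, grep("^section_", names(table)), drop = FALSE])
  rownames(m) <- table$gene
  storage.mode(m) <- "double"
  m
}
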