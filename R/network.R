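#' Load a compartmentalized metabolic factor graph from module and gene tables
#'
#' Builds the directed bipartite factor graph used throughout the package:
#' reaction modules are factor nodes, metabolites are variable nodes, and
#' edges run metabolite -> module (consumption) and module -> metabolite
#' (production). Each intermediate metabolite carries a flux-balance
#' constraint; end metabolites are network boundaries (pure sources or
#' sinks) and are exempt.
#'
#' @param modules Path to a tab-separated module table, or a data frame.
#'   Required columns: `module_id`, `substrates`, `products` (semicolon
#'   separated metabolite ids). Optional: `name`, `compartment`
#'   (`cytosol`, `mitochondrion` or `extracellular`), `pathway_group`.
#' @param genes Path to a long-format gene table (`module_id`, `gene`), or a
#'   data frame. Every module must have at least one gene. Alternatively a
#'   `genes` column (semicolon separated) may be supplied in `modules` and
#'   `genes` left `NULL`.
#' @param metabolites Optional metabolite table (`id`, plus any of `name`,
#'   `compartment`, `kind`). When absent, compartment is inferred from the
#'   id suffix (`_c`, `_m`, `_e`) and kind is inferred: a metabolite is an
#'   intermediate iff it has at least one producing and one consuming
#'   module. An explicit `kind` column overrides the inference.
#' @return A `metab_graph` object: list with tibbles `modules` (one row per
#'   module, list-columns `substrates`, `products`, `genes`) and
#'   `metabolites` (`id`, `name`, `compartment`, `kind`, `n_producers`,
#'   `n_consumers`).
#' @examples
#' g <- fluxcyte_example_network()
#' glance(g)
#' @export
read_network <- function(modules, genes = NULL, metabolites = NULL) {
  mtab <- read_table_arg_(modules, "module table")
  if (nrow(mtab) == 0) abort("no modules: the module table is empty")
  need <- setdiff(c("module_id", "substrates", "products"), names(mtab))
  if (length(need) > 0)
    abort(paste0("module table lacks column(s): ", paste(need, collapse = ", ")))

  ids <- as.character(mtab$module_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    abort(paste0("duplicate module id(s): ", paste(dup, collapse = ", ")))

  split_semi <- function(x) {
    out <- strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE)
    lapply(out, function(v) unique(trimws(v[nzchar(trimws(v))])))
  }
  subs <- split_semi(mtab$substrates)
  prods <- split_semi(mtab$products)

  both <- purrr::map2_lgl(subs, prods, ~ length(intersect(.x, .y)) > 0)
  if (any(both))
    abort(paste0("metabolite appears as both substrate and product of module(s): ",
                 paste(ids[both], collapse = ", ")))
  empty <- purrr::map2_lgl(subs, prods, ~ length(.x) + length(.y) == 0)
  if (any(empty))
    abort(paste0("module(s) with no substrates or products: ",
                 paste(ids[empty], collapse = ", ")))

  # gene membership: long table, or a semicolon genes column in the module table
  if (is.null(genes)) {
    if (!"genes" %in% names(mtab))
      abort("no gene table given and module table has no `genes` column")
    gl <- split_semi(mtab$genes)
    gtab <- tibble::tibble(module_id = rep(ids, lengths(gl)), gene = unlist(gl))
  } else {
    gtab <- read_table_arg_(genes, "gene table")
    need <- setdiff(c("module_id", "gene"), names(gtab))
    if (length(need) > 0)
      abort(paste0("gene table lacks column(s): ", paste(need, collapse = ", ")))
  }
  gtab$module_id <- as.character(gtab$module_id)
  gtab$gene <- trimws(as.character(gtab$gene))
  bad <- setdiff(unique(gtab$module_id), ids)
  if (length(bad) > 0)
    abort(paste0("gene table references unknown module id(s): ",
                 paste(bad, collapse = ", ")))

  gene_lists <- lapply(ids, function(id) {
    gs <- gtab$gene[gtab$module_id == id]
    keep <- !duplicated(toupper(gs))
    if (any(!keep))
      warn(paste0("module ", id, ": dropped duplicate gene(s) ",
                  paste(unique(gs[!keep]), collapse = ", ")))
    gs[keep]
  })
  nogene <- lengths(gene_lists) == 0
  if (any(nogene))
    abort(paste0("module(s) with zero genes: ", paste(ids[nogene], collapse = ", ")))

  met_ids <- sort(unique(c(unlist(subs), unlist(prods))))
  n_prod <- vapply(met_ids, function(m) sum(purrr::map_lgl(prods, ~ m %in% .x)), integer(1))
  n_cons <- vapply(met_ids, function(m) sum(purrr::map_lgl(subs, ~ m %in% .x)), integer(1))
  kind <- ifelse(n_prod >= 1L & n_cons >= 1L, "intermediate", "end")
  comp <- infer_compartment_(met_ids)
  met_name <- met_ids

  if (!is.null(metabolites)) {
    xtab <- read_table_arg_(metabolites, "metabolite table")
    if (!"id" %in% names(xtab)) abort("metabolite table lacks an `id` column")
    xtab$id <- as.character(xtab$id)
    dangling <- setdiff(met_ids, xtab$id)
    if (length(dangling) > 0)
      abort(paste0("dangling metabolite reference(s) not in metabolite table: ",
                   paste(dangling, collapse = ", ")))
    i <- match(met_ids, xtab$id)
    if ("kind" %in% names(xtab)) {
      explicit <- as.character(xtab$kind[i])
      ok <- explicit %in% c("intermediate", "end")
      kind[ok] <- explicit[ok]
      bad_int <- kind == "intermediate" & (n_prod == 0L | n_cons == 0L)
      if (any(bad_int))
        abort(paste0("metabolite(s) declared intermediate but lacking a producer ",
                     "or consumer: ", paste(met_ids[bad_int], collapse = ", ")))
    }
    if ("compartment" %in% names(xtab)) {
      cc <- as.character(xtab$compartment[i])
      comp[!is.na(cc)] <- cc[!is.na(cc)]
    }
    if ("name" %in% names(xtab)) {
      nn <- as.character(xtab$name[i])
      met_name[!is.na(nn)] <- nn[!is.na(nn)]
    }
  }

  graph <- structure(list(
    modules = tibble::tibble(
      module_id = ids,
      name = if ("name" %in% names(mtab)) as.character(mtab$name) else ids,
      compartment = if ("compartment" %in% names(mtab))
        as.character(mtab$compartment) else "cytosol",
      pathway_group = if ("pathway_group" %in% names(mtab))
        as.character(mtab$pathway_group) else NA_character_,
      substrates = subs, products = prods, genes = gene_lists),
    metabolites = tibble::tibble(
      id = met_ids, name = unname(met_name), compartment = comp,
      kind = unname(kind), n_producers = unname(n_prod),
      n_consumers = unname(n_cons))
  ), class = "metab_graph")
  validate_network(graph)
  graph
}

read_table_arg_ <- function(x, what) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0(what, " file not found: ", x))
    return(readr::read_tsv(x, show_col_types = FALSE, progress = FALSE,
                           comment = "#"))
  }
  abort(paste0(what, " must be a path or a data frame"))
}

infer_compartment_ <- function(ids) {
  suffix <- sub(".*_([cme])$", "\\1", ids)
  out <- c(c = "cytosol", m = "mitochondrion", e = "extracellular")[suffix]
  out[is.na(out)] <- "cytosol"
  unname(out)
}

#' Validate factor-graph invariants
#'
#' Checks bipartite structure, metabolite bookkeeping, and that every
#' intermediate metabolite has at least one producing and one consuming
#' module (otherwise its balance constraint would be unsatisfiable by any
#' positive flux).
#'
#' @param graph A `metab_graph`.
#' @return `graph`, invisibly; errors describe the first violation found.
#' @export
validate_network <- function(graph) {
  stopifnot(inherits(graph, "metab_graph"))
  met <- graph$metabolites
  refd <- unique(c(unlist(graph$modules$substrates), unlist(graph$modules$products)))
  missing <- setdiff(refd, met$id)
  if (length(missing) > 0)
    abort(paste0("metabolite(s) referenced but not recorded: ",
                 paste(missing, collapse = ", ")))
  bad <- met$kind == "intermediate" & (met$n_producers < 1 | met$n_consumers < 1)
  if (any(bad))
    abort(paste0("intermediate metabolite(s) without both a producer and a ",
                 "consumer: ", paste(met$id[bad], collapse = ", ")))
  invisible(graph)
}

#' Producing and consuming module sets for an intermediate metabolite
#'
#' For metabolite \eqn{C_k}, `f_in` is the set of modules producing it and
#' `f_out` the set consuming it; the flux-balance constraint requires the
#' in-flux and out-flux sums to agree per sample. Balance is not defined
#' for end metabolites.
#'
#' @param graph A `metab_graph`.
#' @param metabolite_id Metabolite id (must be an intermediate).
#' @return List with character vectors `f_in` (producers) and `f_out`
#'   (consumers).
#' @export
balance_sets <- function(graph, metabolite_id) {
  stopifnot(inherits(graph, "metab_graph"))
  met <- graph$metabolites
  i <- match(metabolite_id, met$id)
  if (is.na(i)) abort(paste0("unknown metabolite: ", metabolite_id))
  if (met$kind[i] != "intermediate")
    abort(paste0("balance is not defined for end metabolite: ", metabolite_id))
  list(
    f_in = graph$modules$module_id[
      purrr::map_lgl(graph$modules$products, ~ metabolite_id %in% .x)],
    f_out = graph$modules$module_id[
      purrr::map_lgl(graph$modules$substrates, ~ metabolite_id %in% .x)]
  )
}

#' Slice an expression matrix down to one module's genes
#'
#' Gene symbols are matched case-insensitively after trimming; row order
#' follows the module's gene-table order. Genes absent from the matrix are
#' reported in the `missing_genes` attribute (and a message).
#'
#' @param graph A `metab_graph`.
#' @param module_id Module id.
#' @param expr Expression input accepted by [as_expression_matrix()].
#' @return Numeric sub-matrix (module genes x samples) with attribute
#'   `missing_genes`; zero overlapping genes yields a 0-row matrix.
#' @export
module_gene_slice <- function(graph, module_id, expr) {
  stopifnot(inherits(graph, "metab_graph"))
  j <- match(module_id, graph$modules$module_id)
  if (is.na(j)) abort(paste0("unknown module: ", module_id))
  expr <- as_expression_matrix(expr)
  mg <- graph$modules$genes[[j]]
  hit <- match(toupper(mg), toupper(trimws(rownames(expr))))
  missing <- mg[is.na(hit)]
  if (length(missing) > 0)
    inform(paste0("module ", module_id, ": ", length(missing),
                  " gene(s) not measured: ", paste(missing, collapse = ", ")))
  out <- expr[hit[!is.na(hit)], , drop = FALSE]
  rownames(out) <- mg[!is.na(hit)]
  attr(out, "missing_genes") <- missing
  out
}

#' All distinct gene symbols in a network
#' @param graph A `metab_graph`.
#' @return Character vector of distinct gene symbols (module-table order).
#' @export
network_genes <- function(graph) {
  stopifnot(inherits(graph, "metab_graph"))
  gs <- unlist(graph$modules$genes, use.names = FALSE)
  gs[!duplicated(toupper(gs))]
}

#' Write a network back to canonical module/gene tables
#'
#' Canonical form: one module per row, semicolon-separated metabolite lists,
#' tab separation; the long gene table preserves module order. Loading the
#' written tables reproduces the graph, and re-writing a loaded graph is
#' byte-stable.
#'
#' @param graph A `metab_graph`.
#' @param modules_path,genes_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(graph, modules_path, genes_path) {
  stopifnot(inherits(graph, "metab_graph"))
  m <- graph$modules
  mt <- tibble::tibble(
    module_id = m$module_id, name = m$name, compartment = m$compartment,
    pathway_group = m$pathway_group,
    substrates = purrr::map_chr(m$substrates, paste, collapse = ";"),
    products = purrr::map_chr(m$products, paste, collapse = ";"))
  gt <- tibble::tibble(module_id = rep(m$module_id, lengths(m$genes)),
                       gene = unlist(m$genes))
  readr::write_tsv(mt, modules_path, progress = FALSE)
  readr::write_tsv(gt, genes_path, progress = FALSE)
  invisible(c(modules_path, genes_path))
}

#' Export the factor graph as a plain edge list
#'
#' @param graph A `metab_graph`.
#' @return Tibble with columns `source`, `target`, `edge_type`
#'   (`"consumption"` for metabolite -> module, `"production"` for
#'   module -> metabolite). Suitable for graph-viz tools.
#' @export
network_edges <- function(graph) {
  stopifnot(inherits(graph, "metab_graph"))
  m <- graph$modules
  dplyr::bind_rows(
    tibble::tibble(source = unlist(m$substrates),
                   target = rep(m$module_id, lengths(m$substrates)),
                   edge_type = "consumption"),
    tibble::tibble(source = rep(m$module_id, lengths(m$products)),
                   target = unlist(m$products),
                   edge_type = "production"))
}

#' Bundled curated central-metabolism network (synthetic stand-in)
#'
#' A curated-style network covering glycolysis, upper and lower TCA cycle,
#' glutaminolysis, glutamine/glutamate metabolism and glutathione
#' metabolism, plus three minor branches (G3P to nucleotide synthesis, 3PG
#' to serine synthesis, and the aspartate-malate shuttle), with species
#' duplicated per compartment (cytosol, mitochondrion, extracellular). It
#' has 31 reaction modules, 16 intermediate and 15 end metabolites, and 253
#' distinct genes; glutamate-to-glutathione is module `M27` (GCLC/GCLM/GSS)
#' and glutamate-to-2-oxoglutarate is `M28` (GLUD1/GLUD2). The gene
#' memberships are a plausible synthetic reconstruction, not a published
#' table.
#'
#' @return A `metab_graph`.
#' @export
fluxcyte_example_network <- function() {
  read_network(
    system.file("extdata", "synthetic_central_network_modules.tsv",
                package = "fluxcyte", mustWork = TRUE),
    system.file("extdata", "synthetic_central_network_genes.tsv",
                package = "fluxcyte", mustWork = TRUE))
}

#' @export
print.metab_graph <- function(x, ...) {
  g <- glance(x)
  cat("<metab_graph> ", g$n_modules, " modules, ", g$n_genes,
      " distinct genes, ", g$n_intermediates, " intermediate + ", g$n_ends,
      " end metabolites\n", sep = "")
  invisible(x)
}

#' @describeIn read_network one-row structural summary (module, gene and
#'   metabolite counts) of a `metab_graph`.
#' @param x A `metab_graph`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.metab_graph <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$modules),
    n_genes = length(network_genes(x)),
    n_metabolites = nrow(x$metabolites),
    n_intermediates = sum(x$metabolites$kind == "intermediate"),
    n_ends = sum(x$metabolites$kind == "end"))
}

#' @describeIn read_network edge-list view of a `metab_graph` (same as
#'   [network_edges()]).
#' @exportS3Method generics::tidy
tidy.metab_graph <- function(x, ...) network_edges(x)
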