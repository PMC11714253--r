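#' Marker gene sets for CD8+ T-cell abundance and cytotoxicity
#'
#' `marker_set()` builds a named marker list; `tcell_markers()` and
#' `cytotoxicity_markers()` return the default sets used throughout:
#' T-cell abundance — CD3E, CD2, CD3G, CD3D, SIRPG, CD6, TIGIT;
#' cytotoxicity — CD8A, SLA2, NKG7, PRF1, GZMA, GZMH.
#'
#' @param name Set name (used in messages and errors).
#' @param genes Non-empty character vector of gene symbols.
#' @return A `marker_set` object.
#' @export
marker_set <- function(name, genes) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) abort(paste0("marker set '", name, "' is empty"))
  structure(list(name = as.character(name), genes = unique(genes)),
            class = "marker_set")
}

#' @rdname marker_set
#' @export
tcell_markers <- function() {
  marker_set("tcell", c("CD3E", "CD2", "CD3G", "CD3D", "SIRPG", "CD6", "TIGIT"))
}

#' @rdname marker_set
#' @export
cytotoxicity_markers <- function() {
  marker_set("cytotoxicity", c("CD8A", "SLA2", "NKG7", "PRF1", "GZMA", "GZMH"))
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", x$name, ": ", paste(x$genes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read marker sets from YAML or a two-column TSV
#'
#' YAML: a mapping of set name to a list of gene symbols. TSV: columns
#' `set_name` and `gene`, one gene per row.
#'
#' @param path File path (`.yml`/`.yaml` or `.tsv`).
#' @return Named list of `marker_set` objects.
#' @export
read_marker_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("marker file not found: ", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    sets <- yaml::read_yaml(path)
    if (!is.list(sets) || is.null(names(sets)))
      abort("marker YAML must map set names to gene lists")
    return(purrr::imap(sets, ~ marker_set(.y, unlist(.x))))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  need <- setdiff(c("set_name", "gene"), names(tab))
  if (length(need) > 0)
    abort(paste0("marker TSV lacks column(s): ", paste(need, collapse = ", ")))
  split(tab$gene, tab$set_name) |> purrr::imap(~ marker_set(.y, .x))
}

#' Score a marker signature per sample
#'
#' Score = mean of log1p-transformed expression over the markers present in
#' the matrix. This is a declared stand-in for the full reference
#' deconvolution the statistic originates from: it is simple, monotone and
#' rank-stable, and the downstream analyses (grouping, correlation
#' ranking) depend only on sample ranks. Marker matching is
#' case-insensitive; missing markers are reported.
#'
#' @param expr Expression input accepted by [as_expression_matrix()].
#' @param markers A `marker_set`.
#' @return Named non-negative numeric vector (one score per sample).
#' @export
signature_score <- function(expr, markers) {
  stopifnot(inherits(markers, "marker_set"))
  expr <- as_expression_matrix(expr)
  hit <- match(toupper(markers$genes), toupper(trimws(rownames(expr))))
  missing <- markers$genes[is.na(hit)]
  if (length(missing) == length(markers$genes))
    abort(paste0("no marker of set '", markers$name,
                 "' is present in the expression matrix"))
  if (length(missing) > 0)
    inform(paste0("marker set '", markers$name, "': ", length(missing),
                  " marker(s) not measured: ", paste(missing, collapse = ", ")))
  colMeans(log1p(expr[hit[!is.na(hit)], , drop = FALSE]))
}

#' Per-sample CD8+ T-cell cytotoxicity profile
#'
#' Computes the CD8+ T-cell abundance score, the cytotoxic-level score, and
#' the relative-cytotoxicity statistic: total cytotoxic level divided by
#' total CD8+ T-cell abundance. Samples whose abundance falls below
#' `floor` get an undefined (NA) ratio rather than a blown-up division;
#' downstream correlation steps drop those samples pairwise.
#'
#' @param expr Expression input accepted by [as_expression_matrix()].
#' @param tcell,cyto `marker_set`s for abundance and cytotoxicity; defaults
#'   are [tcell_markers()] and [cytotoxicity_markers()].
#' @param floor Small positive abundance below which the ratio is NA.
#' @return A `cytotox_profile` tibble: `sample`, `cd8_abundance`,
#'   `cytotoxic_level`, `relative_cytotoxicity`.
#' @examples
#' sim <- simulate_cohorts(simulation_spec(n_samples = 40, seed = 1), n_cohorts = 1)
#' cytotoxicity_profile(sim$cohorts[[1]]$expr)
#' @export
cytotoxicity_profile <- function(expr, tcell = tcell_markers(),
                                 cyto = cytotoxicity_markers(), floor = 1e-8) {
  stopifnot(floor > 0)
  expr <- as_expression_matrix(expr)
  ab <- signature_score(expr, tcell)
  ct <- signature_score(expr, cyto)
  out <- tibble::tibble(
    sample = colnames(expr),
    cd8_abundance = unname(ab),
    cytotoxic_level = unname(ct),
    relative_cytotoxicity = unname(ifelse(ab < floor, NA_real_,
                                           ct / pmax(ab, floor))))
  if (anyNA(out$relative_cytotoxicity))
    inform(paste0(sum(is.na(out$relative_cytotoxicity)),
                  " sample(s) below the abundance floor; ratio set to NA"))
  class(out) <- c("cytotox_profile", class(out))
  out
}

#' Split samples into high/low groups by one gene's expression
#'
#' Samples are ranked by the gene's expression; the top and bottom
#' fractions (default 40%/40%, sizes `floor(n * frac)`) are returned. Ties
#' are broken by stable sample order.
#'
#' @param expr Expression input accepted by [as_expression_matrix()].
#' @param gene Gene symbol (case-insensitive).
#' @param top_frac,bottom_frac Fractions in (0, 1] with sum at most 1.
#' @return List with character vectors `high` and `low` of sample ids.
#' @export
group_by_expression <- function(expr, gene, top_frac = 0.4, bottom_frac = 0.4) {
  stopifnot(top_frac > 0, bottom_frac > 0, top_frac + bottom_frac <= 1)
  expr <- as_expression_matrix(expr)
  i <- match(toupper(trimws(gene)), toupper(trimws(rownames(expr))))
  if (is.na(i)) abort(paste0("gene not present in expression matrix: ", gene))
  x <- expr[i, ]
  n <- length(x)
  ord <- order(x, decreasing = TRUE) # stable: ties keep sample order
  list(high = colnames(expr)[ord[seq_len(floor(n * top_frac))]],
       low = colnames(expr)[rev(ord)[seq_len(floor(n * bottom_frac))]])
}

#' @rdname cytotoxicity_profile
#' @param object A `cytotox_profile`.
#' @param ... Unused.
#' @return `autoplot()`: a ggplot of cytotoxic level against abundance,
#'   colored by the relative-cytotoxicity ratio.
#' @exportS3Method ggplot2::autoplot
autoplot.cytotox_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cd8_abundance,
                                       .data$cytotoxic_level,
                                       colour = .data$relative_cytotoxicity)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "CD8+ T-cell abundance score",
                  y = "cytotoxic level score",
                  colour = "relative\ncytotoxicity") +
    ggplot2::theme_minimal()
}
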