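#' Pearson correlation with the package's missing-data contract
#'
#' Pairwise-complete product-moment correlation. Degenerate inputs (fewer
#' than 3 complete pairs, or a constant vector) yield `NA` with a message
#' instead of an error, so cohort-level gaps propagate as missing values
#' through the ranking rather than aborting it.
#'
#' @param x,y Equal-length numeric vectors.
#' @param quiet Suppress the degenerate-input message.
#' @return A correlation in \eqn{[-1, 1]}, or `NA`.
#' @export
pearson_cc <- function(x, y, quiet = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    if (!quiet) inform("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    if (!quiet) inform("constant vector; correlation undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok])
}

#' Assemble cohorts for cross-cohort ranking
#'
#' Each cohort couples an expression matrix with its cytotoxicity profile
#' (and optionally a sample-by-module flux matrix). Sample ids must be
#' consistent within a cohort across the three objects.
#'
#' @param ... Named cohort entries, each a list with elements `expr`,
#'   `profile` (a [cytotoxicity_profile()] tibble) and optionally `flux`.
#' @param .list Alternatively, a named list of such entries.
#' @return A `cohort_collection`.
#' @export
cohort_collection <- function(..., .list = NULL) {
  cohorts <- .list %||% list(...)
  if (length(cohorts) == 0) abort("no cohorts given")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    abort("cohorts must be named")
  cohorts <- purrr::imap(cohorts, function(co, nm) {
    co$expr <- as_expression_matrix(co$expr)
    if (is.null(co$profile))
      abort(paste0("cohort '", nm, "' lacks a cytotoxicity profile"))
    if (!setequal(co$profile$sample, colnames(co$expr)))
      abort(paste0("cohort '", nm,
                   "': profile samples do not match expression samples"))
    if (!is.null(co$flux)) {
      if (inherits(co$flux, "flux_fit")) co$flux <- co$flux$flux
      if (!setequal(rownames(co$flux), colnames(co$expr)))
        abort(paste0("cohort '", nm,
                     "': flux samples do not match expression samples"))
    }
    co
  })
  structure(cohorts, class = "cohort_collection")
}

#' Rank features by average correlation with relative cytotoxicity
#'
#' For every feature (gene, or module flux with `features = "modules"`),
#' computes the per-cohort Pearson correlation against the
#' relative-cytotoxicity statistic, averages the defined coefficients with
#' an unweighted mean across cohorts, and ranks in increasing order — the
#' most negatively correlated feature gets rank 1. Ties are broken
#' lexicographically by feature id; features with no defined correlation
#' keep `NA` rank.
#'
#' @param cohorts A [cohort_collection()].
#' @param features Character vector of gene symbols, or `"modules"` to
#'   rank module fluxes (requires a `flux` entry in every cohort).
#' @return A `corr_table` tibble: `feature`, one correlation column per
#'   cohort, `avg_pcc`, `rank`.
#' @examples
#' sim <- simulate_cohorts(simulation_spec(n_samples = 60, seed = 2), n_cohorts = 3)
#' cc <- as_cohort_collection(sim)
#' rank_features(cc, c("GLS", rownames(sim$cohorts[[1]]$expr)[1:5])) |> head()
#' @export
rank_features <- function(cohorts, features) {
  stopifnot(inherits(cohorts, "cohort_collection"))
  by_module <- identical(features, "modules")
  if (by_module) {
    fl <- purrr::map(cohorts, "flux")
    if (any(purrr::map_lgl(fl, is.null)))
      abort("features = \"modules\" requires a flux matrix in every cohort")
    features <- sort(unique(unlist(purrr::map(fl, colnames))))
  }
  features <- unique(as.character(features))

  per_cohort <- purrr::imap(cohorts, function(co, nm) {
    v <- co$profile$relative_cytotoxicity[
      match(colnames(co$expr), co$profile$sample)]
    vapply(features, function(f) {
      y <- if (by_module) {
        if (f %in% colnames(co$flux))
          co$flux[match(colnames(co$expr), rownames(co$flux)), f] else NULL
      } else {
        i <- match(toupper(f), toupper(trimws(rownames(co$expr))))
        if (!is.na(i)) co$expr[i, ] else NULL
      }
      if (is.null(y)) NA_real_ else pearson_cc(as.numeric(y), v, quiet = TRUE)
    }, numeric(1), USE.NAMES = FALSE)
  })

  tab <- tibble::tibble(feature = features, !!!per_cohort)
  pcc <- as.matrix(tab[, names(cohorts), drop = FALSE])
  tab$avg_pcc <- rowMeans(pcc, na.rm = TRUE)
  tab$avg_pcc[rowSums(is.finite(pcc)) == 0] <- NA_real_
  ord <- order(tab$avg_pcc, tab$feature, na.last = TRUE)
  rk <- rep(NA_integer_, nrow(tab))
  rk[ord[seq_len(sum(is.finite(tab$avg_pcc)))]] <-
    seq_len(sum(is.finite(tab$avg_pcc)))
  tab$rank <- rk
  tab <- dplyr::arrange(tab, dplyr::desc(is.finite(.data$avg_pcc)), .data$rank)
  class(tab) <- c("corr_table", class(tab))
  tab
}

#' Correlate module fluxes with effector-gene expression
#'
#' The branch-discrimination readout: Pearson correlation of every module's
#' predicted flux against the expression of each CD8+ T-cell effector
#' marker gene, over the samples shared by the two matrices. Default
#' effector genes: GZMA, TNF, IFNG, PRF1.
#'
#' @param flux Samples x modules matrix (or a `flux_fit`).
#' @param expr Expression input accepted by [as_expression_matrix()].
#' @param effector_genes Character vector of effector gene symbols.
#' @return A `corr_table` tibble, one row per module and one correlation
#'   column per effector gene; genes absent from the matrix give an NA
#'   column (with a message).
#' @export
flux_effector_correlation <- function(flux, expr,
                                      effector_genes = c("GZMA", "TNF",
                                                         "IFNG", "PRF1")) {
  if (inherits(flux, "flux_fit")) flux <- flux$flux
  expr <- as_expression_matrix(expr)
  shared <- intersect(rownames(flux), colnames(expr))
  if (length(shared) == 0) abort("flux and expression share no samples")
  flux <- flux[shared, , drop = FALSE]
  up <- toupper(trimws(rownames(expr)))
  cols <- purrr::map(setNames(effector_genes, effector_genes), function(g) {
    i <- match(toupper(g), up)
    if (is.na(i)) {
      inform(paste0("effector gene not measured: ", g))
      return(rep(NA_real_, ncol(flux)))
    }
    y <- expr[i, shared]
    vapply(colnames(flux), function(m) pearson_cc(flux[, m], y, quiet = TRUE),
           numeric(1), USE.NAMES = FALSE)
  })
  tab <- tibble::tibble(module = colnames(flux), !!!cols)
  class(tab) <- c("corr_table", class(tab))
  tab
}

#' @export
print.corr_table <- function(x, ...) {
  cat("<corr_table> ", nrow(x), " feature(s)\n", sep = "")
  NextMethod()
}

#' Plot a correlation table
#'
#' For ranked gene tables: a bar chart of the average correlation of the
#' `n_top` most negative features. For module x effector tables: a tile
#' heatmap of all pairs.
#'
#' @param object A `corr_table`.
#' @param n_top Number of top-ranked features to show (ranked tables only).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.corr_table <- function(object, n_top = 15, ...) {
  if ("avg_pcc" %in% names(object)) {
    df <- head(dplyr::arrange(object, .data$rank), n_top)
    return(
      ggplot2::ggplot(df, ggplot2::aes(
        stats::reorder(.data$feature, -.data$rank), .data$avg_pcc)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = "average PCC vs relative cytotoxicity") +
        ggplot2::theme_minimal())
  }
  key <- names(object)[1]
  df <- tidyr::pivot_longer(object, -1, names_to = "effector",
                            values_to = "pcc")
  ggplot2::ggplot(df, ggplot2::aes(.data$effector, .data[[key]],
                                   fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal()
}
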