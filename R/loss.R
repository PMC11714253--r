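#' Total metabolic activity per sample
#'
#' \eqn{TA_j} is the surrogate for the total metabolic activity of sample
#' \eqn{j}: the sum of raw expression over the network's gene universe.
#' It anchors the absolute scale of the predicted fluxes; genes outside
#' the network are ignored.
#'
#' @param expr Expression input accepted by [as_expression_matrix()].
#' @param graph A `metab_graph`.
#' @return Named non-negative numeric vector, one entry per sample.
#' @export
total_activity <- function(expr, graph) {
  expr <- as_expression_matrix(expr)
  keep <- toupper(trimws(rownames(expr))) %in% toupper(network_genes(graph))
  if (!any(keep))
    abort("no network gene is present in the expression matrix")
  colSums(expr[keep, , drop = FALSE])
}

# internal: signed stoichiometry over intermediate metabolites
# (modules x intermediates; +1 produce, -1 consume)
balance_matrix_ <- function(graph) {
  inter <- graph$metabolites$id[graph$metabolites$kind == "intermediate"]
  m <- graph$modules
  S <- matrix(0, nrow = nrow(m), ncol = length(inter),
              dimnames = list(m$module_id, inter))
  for (k in seq_along(inter)) {
    S[purrr::map_lgl(m$products, ~ inter[k] %in% .x), k] <- 1
    S[purrr::map_lgl(m$substrates, ~ inter[k] %in% .x), k] <- -1
  }
  S
}

# internal: check a sample x module flux matrix against the graph
check_flux_ <- function(flux, graph) {
  if (inherits(flux, "flux_fit")) flux <- flux$flux
  if (!is.matrix(flux) || !is.numeric(flux))
    abort("flux must be a numeric sample-by-module matrix")
  ids <- graph$modules$module_id
  if (is.null(colnames(flux)) || !identical(sort(colnames(flux)), sort(ids)))
    abort("flux columns do not match the graph's module ids")
  flux[, ids, drop = FALSE]
}

#' Flux-balance loss terms
#'
#' The training loss is
#' \deqn{L = \sum_j \sum_k \Big(\sum_{m \in F_{in}(C_k)} Flux_{m,j} -
#'   \sum_{m' \in F_{out}(C_k)} Flux_{m',j}\Big)^2
#'   + \alpha \sum_{j,m} \big(|Flux_{m,j}| - Flux_{m,j}\big)
#'   + \beta \sum_j \Big(\sum_m Flux_{m,j} - TA_j\Big)^2}
#' summed over intermediate metabolites \eqn{C_k} only: a squared in/out
#' imbalance per metabolite and sample, a non-negativity penalty equal to
#' twice the total negative part, and a squared deviation of each sample's
#' total flux from its total metabolic activity \eqn{TA_j}.
#'
#' @param flux Numeric sample-by-module matrix (or a `flux_fit`).
#' @param graph A `metab_graph`; flux columns must match its module ids.
#' @return `imbalance_loss()`, `nonneg_penalty()`, `scale_penalty()`: a
#'   single non-negative number.
#' @export
imbalance_loss <- function(flux, graph) {
  flux <- check_flux_(flux, graph)
  sum((flux %*% balance_matrix_(graph))^2)
}

#' @rdname imbalance_loss
#' @export
nonneg_penalty <- function(flux) {
  if (inherits(flux, "flux_fit")) flux <- flux$flux
  sum(abs(flux) - flux)
}

#' @rdname imbalance_loss
#' @param ta Named per-sample total activity, as from [total_activity()];
#'   names must match the flux rownames.
#' @export
scale_penalty <- function(flux, ta) {
  if (inherits(flux, "flux_fit")) flux <- flux$flux
  if (!is.null(rownames(flux)) && !is.null(names(ta))) {
    if (!identical(sort(rownames(flux)), sort(names(ta))))
      abort("flux rows and total-activity samples do not match")
    ta <- ta[rownames(flux)]
  } else if (nrow(flux) != length(ta)) {
    abort("flux rows and total-activity samples do not match")
  }
  sum((rowSums(flux) - ta)^2)
}

#' @rdname imbalance_loss
#' @param config A [flux_config()]; supplies the weights `alpha` and `beta`.
#' @return `total_loss()`: list with `total` and the `imbalance`, `nonneg`
#'   and `scale` terms (the weighted sum uses
#'   `imbalance + alpha * nonneg + beta * scale`).
#' @export
total_loss <- function(flux, graph, ta, config = flux_config()) {
  imb <- imbalance_loss(flux, graph)
  nn <- nonneg_penalty(flux)
  sc <- scale_penalty(flux, ta)
  list(total = imb + config$alpha * nn + config$beta * sc,
       imbalance = imb, nonneg = nn, scale = sc)
}
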