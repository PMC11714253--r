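#' Specification for a synthetic multi-cohort simulation
#'
#' Describes the stated world the generator emulates: cohorts of
#' non-negative bulk expression with planted cell-type signature
#' structure, a planted metabolic gene anti-correlated with latent
#' cytotoxicity, and module fluxes that balance exactly on their factor
#' graph, with expression generated from flux through a monotone
#' gene-specific response plus multiplicative log-normal noise.
#'
#' @param graph_spec Toy graph name (see [make_toy_graph()]) or a
#'   `metab_graph`.
#' @param n_samples Samples per cohort.
#' @param noise_sd Log-scale SD of the multiplicative expression noise.
#' @param effect_size Exponent tying the planted metabolic gene to latent
#'   cytotoxic activity (expression proportional to
#'   `activity^effect_size`, times noise): negative = anti-correlated,
#'   -1 = anti-proportional, 0 = null gene.
#' @param cyto_fold Fold-change of latent cytotoxic activity between the
#'   planted high and low groups.
#' @param flux_coupling Slope tying the M27-analog flux to standardized
#'   latent cytotoxicity (negative = the flux is high where effector
#'   expression is low); the M28-analog stays uncoupled.
#' @param n_background Number of non-network background genes per cohort.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(graph_spec = "glnlike6", n_samples = 100L,
                            noise_sd = 0.2, effect_size = -1.5,
                            cyto_fold = 4, flux_coupling = -0.8,
                            n_background = 200L, seed = 1L) {
  stopifnot(n_samples >= 2, noise_sd >= 0, cyto_fold > 0, n_background >= 0)
  structure(list(graph_spec = graph_spec, n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, effect_size = effect_size,
                 cyto_fold = cyto_fold, flux_coupling = flux_coupling,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Built-in toy factor graphs
#'
#' * `chain3` — linear chain A -> M1 -> B -> M2 -> C -> M3 -> D
#'   (2 intermediates, 2 ends).
#' * `branch5` — a chain that forks at B into two branches of two modules
#'   each (3 intermediates).
#' * `glnlike6` — a 6-module glutaminolysis-like topology: uptake and
#'   conversion feed a branch-point glutamate analog consumed by both a
#'   glutathione-synthesis analog (`M27`) and a 2-oxoglutarate analog
#'   (`M28`), each draining to an end metabolite.
#'
#' Every toy graph is acyclic, passes [validate_network()], and carries
#' three synthetic genes per module.
#'
#' @param name One of `"chain3"`, `"branch5"`, `"glnlike6"`.
#' @return A `metab_graph`.
#' @export
make_toy_graph <- function(name = c("chain3", "branch5", "glnlike6")) {
  name <- match.arg(name)
  tab <- switch(name,
    chain3 = tibble::tibble(
      module_id = c("M1", "M2", "M3"),
      substrates = c("A", "B", "C"),
      products = c("B", "C", "D")),
    branch5 = tibble::tibble(
      module_id = paste0("M", 1:5),
      substrates = c("A", "B", "B", "C", "D"),
      products = c("B", "C", "D", "E", "F")),
    glnlike6 = tibble::tibble(
      module_id = c("M1", "M2", "M27", "M28", "M5", "M6"),
      name = c("gln uptake analog", "glutaminase analog",
               "glu-to-GSH analog", "glu-to-2-OG analog",
               "GSH drain analog", "2-OG drain analog"),
      compartment = c("extracellular", "mitochondrion", "cytosol",
                      "mitochondrion", "cytosol", "mitochondrion"),
      substrates = c("GLN_e", "GLN_c", "GLU_m", "GLU_m", "GSH_c", "AKG_m"),
      products = c("GLN_c", "GLU_m", "GSH_c", "AKG_m", "GSX_e", "MAL_e")))
  genes <- tibble::tibble(
    module_id = rep(tab$module_id, each = 3),
    gene = paste0(rep(tab$module_id, each = 3), "_g", 1:3))
  read_network(tab, genes)
}

#' Simulate exactly balanced ground-truth fluxes
#'
#' Source modules (those consuming no intermediate metabolite) draw
#' positive log-normal fluxes; interior fluxes are propagated so that
#' every intermediate metabolite balances exactly, with branch points
#' split by Dirichlet-drawn per-sample proportions. The result zeroes the
#' imbalance term by construction. Requires an acyclic graph in which
#' each module consumes at most one intermediate metabolite (all toy
#' graphs qualify).
#'
#' @param graph A `metab_graph`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the source fluxes.
#' @param dirichlet_alpha Concentration of the branch-split proportions.
#' @return Samples x modules flux matrix with `imbalance_loss()` equal to
#'   0 up to float tolerance.
#' @export
simulate_balanced_flux <- function(graph, n_samples, seed = 1L,
                                   meanlog = 1, sdlog = 0.4,
                                   dirichlet_alpha = 2) {
  stopifnot(inherits(graph, "metab_graph"), n_samples >= 1)
  m <- graph$modules
  inter <- graph$metabolites$id[graph$metabolites$kind == "intermediate"]
  in_subs <- purrr::map(m$substrates, intersect, inter)
  if (any(lengths(in_subs) > 1))
    abort(paste0("module(s) consuming more than one intermediate metabolite",
                 " are not supported by the balanced-flux generator: ",
                 paste(m$module_id[lengths(in_subs) > 1], collapse = ", ")))

  flux <- matrix(NA_real_, n_samples, nrow(m),
                 dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                 m$module_id))
  with_seed_(sub_seed_(seed, "flux"), {
    src <- lengths(in_subs) == 0
    for (id in m$module_id[src])
      flux[, id] <- rlnorm(n_samples, meanlog, sdlog)
    done_met <- character(0)
    repeat {
      todo <- setdiff(inter, done_met)
      if (length(todo) == 0) break
      progressed <- FALSE
      for (k in todo) {
        bs <- balance_sets(graph, k)
        if (anyNA(flux[, bs$f_in, drop = FALSE])) next
        inflow <- rowSums(flux[, bs$f_in, drop = FALSE])
        nc <- length(bs$f_out)
        prop <- matrix(rgamma(n_samples * nc, shape = dirichlet_alpha),
                       n_samples, nc)
        prop <- prop / rowSums(prop)
        flux[, bs$f_out] <- inflow * prop
        done_met <- c(done_met, k)
        progressed <- TRUE
      }
      if (!progressed)
        abort("graph has a cycle through intermediate metabolites; cannot propagate balanced fluxes")
    }
  })
  if (anyNA(flux))
    abort("internal error: some module fluxes were never assigned")
  flux
}

#' Generate expression from known fluxes through a monotone gene response
#'
#' Inverts the flux model's central assumption with a known monotone map:
#' each module gene \eqn{g} gets expression
#' \eqn{w_g \cdot Flux_m^{e_g} \cdot \exp(N(0, \sigma^2))} with a
#' gene-specific weight \eqn{w_g} (log-normal) and exponent
#' \eqn{e_g \in [0.5, 1.5]} (uniform), so the gene-to-flux dependency is
#' satisfiable by the neural model without sharing its functional form.
#' Non-network background genes (log-normal, flux-independent) are
#' appended so gene matching and the TA restriction are exercised.
#'
#' @param true_flux Samples x modules matrix aligned to `graph`.
#' @param graph A `metab_graph`.
#' @param noise_sd Log-scale SD of the multiplicative noise.
#' @param seed Integer seed.
#' @param n_background Number of background genes.
#' @return Genes x samples expression matrix (module genes first, then
#'   `BG...` background genes).
#' @export
simulate_expression <- function(true_flux, graph, noise_sd = 0.2, seed = 1L,
                                n_background = 200L) {
  true_flux <- check_flux_(true_flux, graph)
  stopifnot(noise_sd >= 0)
  m <- graph$modules
  gene2mod <- tibble::tibble(
    gene = unlist(m$genes),
    module = rep(m$module_id, lengths(m$genes)))
  gene2mod <- gene2mod[!duplicated(toupper(gene2mod$gene)), ]
  G <- nrow(gene2mod)
  n <- nrow(true_flux)

  resp <- with_seed_(sub_seed_(seed, "weights"), list(
    w = rlnorm(G, meanlog = 1, sdlog = 0.3),
    e = runif(G, 0.5, 1.5)))
  base <- resp$w * t(true_flux[, gene2mod$module, drop = FALSE])^resp$e
  noise <- with_seed_(sub_seed_(seed, "noise"),
                      matrix(exp(rnorm(G * n, 0, noise_sd)), G, n))
  expr <- base * noise
  dimnames(expr) <- list(gene2mod$gene, rownames(true_flux))

  if (n_background > 0) {
    bg <- with_seed_(sub_seed_(seed, "background"),
                     matrix(rlnorm(n_background * n, meanlog = 2, sdlog = 1),
                            n_background, n))
    rownames(bg) <- sprintf("BG%04d", seq_len(n_background))
    colnames(bg) <- rownames(true_flux)
    expr <- rbind(expr, bg)
  }
  expr
}

#' Simulate a multi-cohort collection with planted immune structure
#'
#' Each cohort gets: two equal-sized sample groups whose latent cytotoxic
#' activity differs by `cyto_fold`; T-cell marker genes expressed
#' proportional to a latent CD8 abundance; cytotoxicity and effector
#' marker genes (including TNF and IFNG) proportional to abundance times
#' activity; one planted metabolic gene (`"GLS"`) coupled to
#' standardized log activity with slope `effect_size`; and exactly
#' balanced module fluxes in which — for the `glnlike6` graph — the
#' `M27` flux is tied to activity with slope `flux_coupling` while `M28`
#' stays independent. Expression is then generated from the fluxes with
#' [simulate_expression()]. Sample ids are disjoint across cohorts.
#'
#' @param spec A [simulation_spec()].
#' @param n_cohorts Number of cohorts (the emulated multi-dataset design
#'   uses nine).
#' @return List with `cohorts` (named list; each has `expr`, `true_flux`,
#'   `group`, `latent`), `graph`, `spec`, and `truth` (planted feature
#'   ids and module analogs).
#' @export
simulate_cohorts <- function(spec = simulation_spec(), n_cohorts = 9L) {
  stopifnot(inherits(spec, "simulation_spec"), n_cohorts >= 1)
  graph <- if (inherits(spec$graph_spec, "metab_graph")) spec$graph_spec
           else make_toy_graph(spec$graph_spec)
  glnlike <- all(c("M27", "M28") %in% graph$modules$module_id)
  n <- spec$n_samples

  cohorts <- purrr::map(seq_len(n_cohorts), function(i) {
    cseed <- (sub_seed_(spec$seed, "cohort") + 331L * i) %% 2147483647L
    ids <- sprintf("c%02d_s%03d", i, seq_len(n))
    group <- rep(c("high", "low"), length.out = n)

    lat <- with_seed_(sub_seed_(cseed, "immune"), {
      la <- log(spec$cyto_fold) * (group == "high") + rnorm(n, 0, 0.3)
      list(activity = exp(la), abundance = rlnorm(n, 1, 0.4),
           marker_noise = matrix(exp(rnorm(16 * n, 0, 0.25)), 16, n),
           marker_w = rlnorm(16, 2, 0.2),
           planted_noise = rnorm(n, 0, max(spec$noise_sd, 0.05)))
    })
    zs <- log(lat$activity)
    zs <- if (sd(zs) > 0) (zs - mean(zs)) / sd(zs) else rep(0, n)

    tg <- tcell_markers()$genes
    cg <- cytotoxicity_markers()$genes
    eff_extra <- c("TNF", "IFNG")
    mk <- c(tg, cg, eff_extra)
    latent_level <- rbind(
      matrix(lat$abundance, length(tg), n, byrow = TRUE),
      matrix(lat$abundance * lat$activity, length(cg) + 2, n, byrow = TRUE))
    marker_expr <- lat$marker_w[seq_along(mk)] * latent_level *
      lat$marker_noise[seq_along(mk), , drop = FALSE]
    rownames(marker_expr) <- mk

    # planted metabolic gene: expression proportional to activity^effect_size
    # with the generator's shared multiplicative noise, so effect_size = -1
    # means exactly anti-proportional to latent cytotoxicity
    planted <- matrix(exp(2 + spec$effect_size * log(lat$activity) +
                            lat$planted_noise),
                      1, n, dimnames = list("GLS", NULL))

    true_flux <- if (glnlike) {
      with_seed_(sub_seed_(cseed, "flux"), {
        m27 <- exp(1 + spec$flux_coupling * zs + rnorm(n, 0, 0.3))
        m28 <- rlnorm(n, 1, 0.3)
        fl <- cbind(M1 = m27 + m28, M2 = m27 + m28, M27 = m27, M28 = m28,
                    M5 = m27, M6 = m28)
        fl[, graph$modules$module_id, drop = FALSE]
      })
    } else {
      simulate_balanced_flux(graph, n, seed = cseed)
    }
    rownames(true_flux) <- ids

    expr <- simulate_expression(true_flux, graph, noise_sd = spec$noise_sd,
                                seed = cseed, n_background = spec$n_background)
    expr <- rbind(expr, marker_expr, planted)
    colnames(expr) <- ids

    list(expr = expr, true_flux = true_flux, group = setNames(group, ids),
         latent = tibble::tibble(sample = ids, abundance = lat$abundance,
                                 activity = lat$activity))
  })
  names(cohorts) <- sprintf("cohort_%02d", seq_len(n_cohorts))

  list(cohorts = cohorts, graph = graph, spec = spec,
       truth = list(planted_features = "GLS",
                    m27_analog = if (glnlike) "M27" else NULL,
                    m28_analog = if (glnlike) "M28" else NULL))
}

#' Turn a simulation into a scored cohort collection
#'
#' Computes the cytotoxicity profile of every simulated cohort and bundles
#' expression, profile and (by default) the ground-truth flux into a
#' [cohort_collection()] ready for [rank_features()].
#'
#' @param sim Output of [simulate_cohorts()].
#' @param with_flux Attach the ground-truth flux matrices?
#' @param floor Abundance floor passed to [cytotoxicity_profile()].
#' @return A `cohort_collection`.
#' @export
as_cohort_collection <- function(sim, with_flux = TRUE, floor = 1e-8) {
  cohorts <- purrr::map(sim$cohorts, function(co) {
    list(expr = co$expr,
         profile = cytotoxicity_profile(co$expr, floor = floor),
         flux = if (with_flux) co$true_flux else NULL)
  })
  cohort_collection(.list = cohorts)
}
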