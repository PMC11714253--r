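# Fixture builders and independent brute-force oracles shared by the suite.
# Oracles are deliberately written as naive loops / direct formulas so they
# share no code path with the package implementations they check.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# -- tiny toy tables ---------------------------------------------------------

chain3_tables <- function() {
  list(
    modules = data.frame(module_id = c("M1", "M2", "M3"),
                         substrates = c("A", "B", "C"),
                         products = c("B", "C", "D")),
    genes = data.frame(module_id = c("M1", "M2", "M3"),
                       gene = c("g1", "g2", "g3")))
}

branch_tables <- function() {
  list(
    modules = data.frame(module_id = c("M1", "M2", "M3"),
                         substrates = c("A", "B", "B"),
                         products = c("B", "C", "D")),
    genes = data.frame(module_id = c("M1", "M2", "M3"),
                       gene = c("g1", "g2", "g3")))
}

# random acyclic factor graph: each module consumes either a fresh source or
# a previously produced metabolite, and produces one fresh metabolite
random_graph <- function(n_modules, seed) {
  set.seed(seed)
  subs <- character(n_modules)
  prods <- character(n_modules)
  open <- character(0) # produced metabolites available for consumption
  met <- 0
  for (m in seq_len(n_modules)) {
    if (length(open) > 0 && runif(1) < 0.7) {
      subs[m] <- sample(open, 1)
    } else {
      met <- met + 1
      subs[m] <- paste0("X", met)
    }
    met <- met + 1
    prods[m] <- paste0("X", met)
    open <- c(open, prods[m])
  }
  ids <- paste0("M", seq_len(n_modules))
  read_network(
    data.frame(module_id = ids, substrates = subs, products = prods),
    data.frame(module_id = ids, gene = paste0("g", seq_len(n_modules))))
}

random_flux <- function(graph, n_samples, seed) {
  set.seed(seed)
  ids <- graph$modules$module_id
  matrix(rnorm(n_samples * length(ids), mean = 2, sd = 2),
         n_samples, length(ids),
         dimnames = list(paste0("s", seq_len(n_samples)), ids))
}

# -- brute-force loss oracles ------------------------------------------------

imbalance_oracle <- function(flux, graph) {
  inter <- graph$metabolites$id[graph$metabolites$kind == "intermediate"]
  total <- 0
  for (j in seq_len(nrow(flux))) {
    for (k in inter) {
      bs <- balance_sets(graph, k)
      d <- 0
      for (m in bs$f_in) d <- d + flux[j, m]
      for (m in bs$f_out) d <- d - flux[j, m]
      total <- total + d^2
    }
  }
  total
}

nonneg_oracle <- function(flux) 2 * sum(pmax(-flux, 0))

scale_oracle <- function(flux, ta) {
  total <- 0
  for (j in seq_len(nrow(flux)))
    total <- total + (sum(flux[j, ]) - unname(ta[j]))^2
  total
}

# textbook product-moment formula via explicit sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sqrt((sum(x^2) - n * mean(x)^2) / (n - 1))
  sy <- sqrt((sum(y^2) - n * mean(y)^2) / (n - 1))
  (sum(x * y) - n * mean(x) * mean(y)) / ((n - 1) * sx * sy)
}

# -- expression fixtures -----------------------------------------------------

random_expr <- function(genes, n_samples, seed, max_val = 50) {
  set.seed(seed)
  matrix(runif(length(genes) * n_samples, 0, max_val), length(genes),
         n_samples,
         dimnames = list(genes, paste0("s", seq_len(n_samples))))
}
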