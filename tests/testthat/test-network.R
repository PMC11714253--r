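test_that("a 3-module chain loads with the hand-counted structure", {
  t3 <- chain3_tables()
  g <- read_network(t3$modules, t3$genes)
  expect_s3_class(g, "metab_graph")
  gl <- glance(g)
  expect_equal(gl$n_modules, 3)
  expect_equal(gl$n_genes, 3)
  expect_equal(gl$n_intermediates, 2) # B and C, counted by hand
  expect_equal(gl$n_ends, 2)          # A and D
  expect_setequal(g$metabolites$id[g$metabolites$kind == "intermediate"],
                  c("B", "C"))
})

test_that("malformed tables are rejected with informative errors", {
  t3 <- chain3_tables()
  expect_error(read_network(t3$modules[0, ], t3$genes), "no modules")
  dup <- rbind(t3$modules, t3$modules[1, ])
  expect_error(read_network(dup, t3$genes), "M1")
  expect_error(read_network(t3$modules, t3$genes[1:2, ]), "zero genes")
  badg <- rbind(t3$genes, data.frame(module_id = "M9", gene = "gX"))
  expect_error(read_network(t3$modules, badg), "M9")
  both <- t3$modules
  both$products[1] <- "A"
  expect_error(read_network(both, t3$genes), "both substrate and product")
  met <- data.frame(id = c("A", "B", "C")) # D referenced but not listed
  expect_error(read_network(t3$modules, t3$genes, metabolites = met),
               "dangling")
})

test_that("explicit metabolite kind overrides the inference", {
  t3 <- chain3_tables()
  met <- data.frame(id = LETTERS[1:4],
                    kind = c("end", "end", "intermediate", "end"))
  g <- read_network(t3$modules, t3$genes, metabolites = met)
  expect_equal(g$metabolites$kind[g$metabolites$id == "B"], "end")
  expect_error(balance_sets(g, "B"), "end metabolite")
  bad <- data.frame(id = LETTERS[1:4],
                    kind = c("intermediate", "intermediate",
                             "intermediate", "end"))
  expect_error(read_network(t3$modules, t3$genes, metabolites = bad),
               "lacking a producer")
})

test_that("duplicate genes within a module are de-duplicated with a warning", {
  t3 <- chain3_tables()
  gt <- rbind(t3$genes, data.frame(module_id = "M1", gene = " G1 "))
  expect_warning(g <- read_network(t3$modules, gt), "duplicate gene")
  expect_equal(g$modules$genes[[1]], "g1")
})

test_that("balance sets read off producers and consumers", {
  t3 <- chain3_tables()
  g <- read_network(t3$modules, t3$genes)
  expect_equal(balance_sets(g, "B"), list(f_in = "M1", f_out = "M2"))
  expect_error(balance_sets(g, "A"), "end metabolite")
  expect_error(balance_sets(g, "ZZ"), "unknown")

  bt <- branch_tables()
  gb <- read_network(bt$modules, bt$genes)
  bs <- balance_sets(gb, "B")
  expect_equal(bs$f_in, "M1")
  expect_setequal(bs$f_out, c("M2", "M3"))
  expect_length(intersect(bs$f_in, bs$f_out), 0)
})

test_that("module gene slices follow module order and report missing genes", {
  mods <- data.frame(module_id = "M1", substrates = "A", products = "B")
  genes <- data.frame(module_id = c("M1", "M1"), gene = c("g1", "g2"))
  g <- read_network(mods, genes)
  expr <- random_expr(c("g2", "g3", "g1"), 4, seed = 1)
  sl <- module_gene_slice(g, "M1", expr)
  expect_equal(rownames(sl), c("g1", "g2")) # module-table order
  expect_equal(unname(sl["g1", ]), unname(expr["g1", ]))
  expect_length(attr(sl, "missing_genes"), 0)

  expr2 <- random_expr(c("G1", "g3"), 4, seed = 2) # case-insensitive match
  expect_message(sl2 <- module_gene_slice(g, "M1", expr2), "g2")
  expect_equal(nrow(sl2), 1)
  expect_equal(attr(sl2, "missing_genes"), "g2")
  expect_error(module_gene_slice(g, "M9", expr), "unknown module")
})

test_that("the bundled network slices M27 to its full gene-table membership", {
  g <- fluxcyte_example_network()
  expr <- random_expr(network_genes(g), 3, seed = 3)
  j <- match("M27", g$modules$module_id)
  sl <- module_gene_slice(g, "M27", expr)
  expect_equal(nrow(sl), length(g$modules$genes[[j]]))
  expect_true(all(c("GCLC", "GCLM", "GSS") %in% rownames(sl)))
})

test_that("writing and reloading a network is canonical and byte-stable", {
  g <- fluxcyte_example_network()
  d <- withr::local_tempdir()
  p1 <- file.path(d, c("m1.tsv", "g1.tsv"))
  write_network(g, p1[1], p1[2])
  g2 <- read_network(p1[1], p1[2])
  p2 <- file.path(d, c("m2.tsv", "g2.tsv"))
  write_network(g2, p2[1], p2[2])
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))
  expect_equal(glance(g2), glance(g))
})

test_that("the factor graph is bipartite with non-empty disjoint balance sets", {
  graphs <- c(lapply(c("chain3", "branch5", "glnlike6"), make_toy_graph),
              list(fluxcyte_example_network()))
  for (g in graphs) {
    ed <- network_edges(g)
    mods <- g$modules$module_id
    mets <- g$metabolites$id
    cons <- ed[ed$edge_type == "consumption", ]
    prod <- ed[ed$edge_type == "production", ]
    expect_true(all(cons$source %in% mets) && all(cons$target %in% mods))
    expect_true(all(prod$source %in% mods) && all(prod$target %in% mets))
    for (k in mets[g$metabolites$kind == "intermediate"]) {
      bs <- balance_sets(g, k)
      expect_gt(length(bs$f_in), 0)
      expect_gt(length(bs$f_out), 0)
      expect_length(intersect(bs$f_in, bs$f_out), 0)
    }
  }
})
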