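test_that("total activity sums network-gene expression per sample", {
  t3 <- chain3_tables()
  g <- read_network(t3$modules, t3$genes)
  expr <- matrix(c(2, 3, 7, 0, 1, 5), 3, 2,
                 dimnames = list(c("g1", "g2", "other"), c("s1", "s2")))
  expect_equal(total_activity(expr, g), c(s1 = 5, s2 = 1)) # 'other' ignored
  expect_equal(unname(total_activity(expr * 0, g)), c(0, 0))
  expr20 <- random_expr(c(paste0("g", 1:3), paste0("bg", 1:17)), 5, seed = 4)
  expect_equal(total_activity(expr20, g),
               colSums(expr20[1:3, ])) # independent column-sum oracle
  nohit <- random_expr(c("x1", "x2"), 2, seed = 5)
  expect_error(total_activity(nohit, g), "no network gene")
})

test_that("loss terms reproduce small hand-computed cases", {
  t3 <- chain3_tables()
  g <- read_network(t3$modules, t3$genes)
  bal <- matrix(4, 3, 3, dimnames = list(paste0("s", 1:3), c("M1", "M2", "M3")))
  expect_equal(imbalance_loss(bal, g), 0)
  one <- matrix(c(2, 1, 1), 1, 3,
                dimnames = list("s1", c("M1", "M2", "M3")))
  expect_equal(imbalance_loss(one, g), 1) # (2-1)^2 at B, balanced at C
  expect_equal(nonneg_penalty(bal), 0)
  expect_equal(nonneg_penalty(matrix(-1)), 2) # |-1| - (-1)
  expect_equal(scale_penalty(matrix(c(1, 1, 1), 1), ta = 1), 4) # (3-1)^2
  expect_equal(scale_penalty(bal, setNames(rep(12, 3), paste0("s", 1:3))), 0)
  expect_error(imbalance_loss(bal[, 1:2], g), "module ids")
  expect_error(scale_penalty(bal, setNames(1:3, c("a", "b", "c"))),
               "do not match")
})

test_that("loss terms match brute-force oracles on random graphs and fluxes", {
  for (i in 1:25) {
    g <- random_graph(n_modules = sample(3:8, 1), seed = 100 + i)
    fl <- random_flux(g, n_samples = sample(2:5, 1), seed = 200 + i)
    set.seed(300 + i)
    ta <- runif(nrow(fl), 0, 20)
    names(ta) <- rownames(fl)
    expect_equal(imbalance_loss(fl, g), imbalance_oracle(fl, g),
                 tolerance = 1e-12)
    expect_equal(nonneg_penalty(fl), nonneg_oracle(fl), tolerance = 1e-12)
    expect_equal(scale_penalty(fl, ta), scale_oracle(fl, ta),
                 tolerance = 1e-12)
    cfg <- flux_config(alpha = runif(1, 0, 2), beta = runif(1, 0, 1))
    tl <- total_loss(fl, g, ta, cfg)
    expect_equal(tl$total,
                 imbalance_oracle(fl, g) + cfg$alpha * nonneg_oracle(fl) +
                   cfg$beta * scale_oracle(fl, ta),
                 tolerance = 1e-12)
    cfg0 <- flux_config(alpha = 0, beta = 0)
    expect_equal(total_loss(fl, g, ta, cfg0)$total, imbalance_loss(fl, g))
  }
})

test_that("flux functions are built per module with seeded determinism", {
  g31 <- fluxcyte_example_network()
  fns <- build_flux_functions(g31, flux_config(seed = 1))
  expect_length(fns, 31)
  expect_true(all(purrr::map_chr(fns, "type") == "nn"))
  gg <- make_toy_graph("chain3")
  f1 <- build_flux_functions(gg, flux_config(seed = 9))
  f2 <- build_flux_functions(gg, flux_config(seed = 9))
  expect_identical(f1, f2)
  # distinct modules get distinct initializations
  expect_false(identical(f1$M1$W1, f1$M2$W1))
  f3 <- build_flux_functions(gg, flux_config(seed = 10))
  expect_false(identical(f1$M1$W1, f3$M1$W1))
  # unmeasured modules degrade to free per-sample parameters
  fns_part <- build_flux_functions(gg, flux_config(), genes = c("M1_g1"))
  expect_equal(fns_part$M2$type, "free")
  expect_equal(fns_part$M1$genes, "M1_g1")
})

test_that("fitting is deterministic, loss-decreasing, and handles epochs = 0", {
  gg <- make_toy_graph("chain3")
  tf <- simulate_balanced_flux(gg, 25, seed = 2)
  expr <- simulate_expression(tf, gg, noise_sd = 0.1, seed = 2,
                              n_background = 10)
  f0 <- fit_flux(expr, gg, flux_config(epochs = 0, seed = 1))
  expect_equal(nrow(f0$loss_history), 1)
  expect_equal(f0$loss_history$epoch, 0)

  for (sd in 1:3) {
    ft <- fit_flux(expr, gg, flux_config(epochs = 150, seed = sd))
    h <- ft$loss_history
    expect_lte(min(h$total), h$total[h$epoch == 0]) # monotone vs start
    expect_true(all(is.finite(ft$flux)))
  }
  fa <- fit_flux(expr, gg, flux_config(epochs = 150, seed = 5))
  fb <- fit_flux(expr, gg, flux_config(epochs = 150, seed = 5))
  expect_identical(fa$flux, fb$flux) # bit-reproducible
})

test_that("training restores balance and TA anchoring on noise-free data", {
  gg <- make_toy_graph("glnlike6")
  tf <- simulate_balanced_flux(gg, 60, seed = 3)
  expr <- simulate_expression(tf, gg, noise_sd = 0, seed = 3)
  ft <- fit_flux(expr, gg, flux_config(epochs = 6000, seed = 3)) # to convergence
  h <- ft$loss_history
  # residual per-(sample, metabolite) imbalance is small against the flux scale
  n_int <- sum(gg$metabolites$kind == "intermediate")
  rms_imb <- sqrt(h$imbalance[ft$best_epoch + 1] / (nrow(ft$flux) * n_int))
  expect_lt(rms_imb, 0.05 * mean(ft$flux))
  rel_dev <- function(P) median(abs(rowSums(P) - ft$ta) / ft$ta)
  f0 <- fit_flux(expr, gg, flux_config(epochs = 0, seed = 3))
  expect_lt(rel_dev(ft$flux), rel_dev(f0$flux))
})

test_that("identical expression columns give identical flux rows", {
  gg <- make_toy_graph("chain3")
  tf <- simulate_balanced_flux(gg, 10, seed = 4)
  expr <- simulate_expression(tf, gg, noise_sd = 0.2, seed = 4,
                              n_background = 5)
  const <- expr[, rep(1, 8)]
  colnames(const) <- paste0("c", 1:8)
  ft <- fit_flux(const, gg, flux_config(epochs = 100, seed = 1))
  for (j in 2:8)
    expect_equal(unname(ft$flux[j, ]), unname(ft$flux[1, ]), tolerance = 1e-10)
})

test_that("prediction reproduces training output and scores new samples", {
  gg <- make_toy_graph("glnlike6")
  tf <- simulate_balanced_flux(gg, 30, seed = 6)
  expr <- simulate_expression(tf, gg, noise_sd = 0.2, seed = 6)
  ft <- fit_flux(expr, gg, flux_config(epochs = 200, seed = 6))
  expect_equal(predict_flux(ft, expr), ft$flux)
  one <- expr[, 1, drop = FALSE]
  p1 <- predict_flux(ft, one)
  expect_equal(dim(p1), c(1L, 6L))
  expect_equal(unname(p1[1, ]), unname(ft$flux[1, ]))
  dupd <- expr[, c(1, 1)]
  colnames(dupd) <- c("a", "b")
  pd <- predict_flux(ft, dupd)
  expect_equal(unname(pd[1, ]), unname(pd[2, ]))
  expect_error(predict_flux(ft, expr[-1, ]), rownames(expr)[1])
})

test_that("non-finite training aborts with an epoch/term diagnostic", {
  gg <- make_toy_graph("chain3")
  tf <- simulate_balanced_flux(gg, 10, seed = 8)
  expr <- simulate_expression(tf, gg, noise_sd = 0.1, seed = 8,
                              n_background = 0)
  expr["M1_g1", 1] <- 1e300 # TA overflows the squared scale term
  expect_error(fit_flux(expr, gg, flux_config(epochs = 5)),
               "non-finite loss at epoch")
})
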