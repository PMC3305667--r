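make_nbhd <- function(selected, nodes = names(selected), freq = NULL) {
  bgmlasso:::new_neighborhoods(nodes, selected,
                               setNames(rep(NA_real_, length(nodes)), nodes),
                               method = "test", params = list(),
                               frequencies = freq)
}

test_that("AND and OR rules combine neighborhoods as defined", {
  sym <- make_nbhd(list(a = "b", b = "a", c = character(0)),
                   nodes = c("a", "b", "c"))
  expect_equal(combine_edges(sym, "AND")$edges, combine_edges(sym, "OR")$edges)

  asym <- make_nbhd(list(a = character(0), b = "a", c = character(0)),
                    nodes = c("a", "b", "c"))
  g_or <- combine_edges(asym, "OR")
  g_and <- combine_edges(asym, "AND")
  expect_equal(g_or$edges, cbind("a", "b"), ignore_attr = TRUE)
  expect_equal(nrow(g_and$edges), 0)
})

test_that("the AND edge set is contained in the OR edge set", {
  nodes <- paste0("V", 1:6)
  for (r in 1:50) {
    set.seed(r)
    sel <- lapply(seq_along(nodes), function(a) {
      sample(nodes[-a], rbinom(1, 5, 0.4))
    })
    names(sel) <- nodes
    nb <- make_nbhd(sel, nodes)
    and_keys <- bgmlasso:::graph_keys(combine_edges(nb, "AND"))
    or_keys <- bgmlasso:::graph_keys(combine_edges(nb, "OR"))
    expect_true(all(and_keys %in% or_keys))
  }
})

test_that("bolasso edge sets shrink as the threshold rises", {
  d <- m6_data(300, seed = 55)
  nb <- bolasso_neighborhoods(d, B = 20, penalty = "size", l = 2,
                              pi_cut = 0.9, seed = 9)
  expect_true(all(nb$frequencies >= 0 & nb$frequencies <= 1))
  expect_true(all(diag(nb$frequencies) == 0))
  keys <- lapply(c(0.90, 0.95, 0.99, 1.00), function(pc) {
    bgmlasso:::graph_keys(combine_edges(apply_cut(nb, pc), "OR"))
  })
  for (k in 2:4) expect_true(all(keys[[k]] %in% keys[[k - 1]]))
})

test_that("a single bootstrap with pi_cut 1 reproduces that fit's active set", {
  d <- m6_data(300, seed = 55)
  n <- nrow(d)
  seed <- 21
  # reconstruct the resample the bolasso draws for b = 1
  idx <- bgmlasso:::with_seed(seed + 1, sample.int(n, n, replace = TRUE))
  boot <- unclass(d)[idx, ]

  # retuned size rule: the size-l fit on the resample itself
  nb <- bolasso_neighborhoods(d, B = 1, penalty = "size", l = 2,
                              pi_cut = 1.0, seed = seed)
  for (a in c(1, 4)) {
    y <- boot[, a]
    Xs <- standardize_predictors(boot[, -a])$x
    lam <- penalty_for_size(y, Xs, lambda_grid(y, Xs), 2)
    fit <- fit_l1_logistic(y, Xs, lam)
    expect_setequal(nb$selected[[colnames(d)[a]]], fit$active_set)
  }

  # fixed-penalty protocol: the original-data penalty applied to the resample
  nbf <- bolasso_neighborhoods(d, B = 1, penalty = "size", l = 2,
                               pi_cut = 1.0, seed = seed, retune = FALSE)
  for (a in c(2, 5)) {
    y <- boot[, a]
    Xs <- standardize_predictors(boot[, -a])$x
    fit <- fit_l1_logistic(y, Xs, nbf$lambda[[a]])
    expect_setequal(nbf$selected[[colnames(d)[a]]], fit$active_set)
  }
})

test_that("bolasso frequencies are exact multiples of 1/B", {
  d <- m6_data(300, seed = 55)
  nb <- bolasso_neighborhoods(d, B = 7, penalty = "size", l = 1,
                              pi_cut = 0.9, seed = 3)
  expect_true(all(abs(nb$frequencies * 7 - round(nb$frequencies * 7)) < 1e-12))
})

test_that("estimation is deterministic given data, params and seed", {
  d <- m6_data(300, seed = 55)
  g1 <- estimate_graph(d, "bolasso", rule = "OR", B = 10, pi_cut = 0.9,
                       l = 2, seed = 5)
  g2 <- estimate_graph(d, "bolasso", rule = "OR", B = 10, pi_cut = 0.9,
                       l = 2, seed = 5)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$frequencies, g2$frequencies)
  c1 <- estimate_graph(d, "lasso-cv", rule = "AND", seed = 8)
  c2 <- estimate_graph(d, "lasso-cv", rule = "AND", seed = 8)
  expect_identical(c1$edges, c2$edges)
})

test_that("single-LASSO graphs are invariant to row order", {
  d <- m6_data(300, seed = 55)
  g1 <- estimate_graph(d, "lasso-bic", rule = "OR")
  set.seed(1)
  perm <- sample(nrow(d))
  g2 <- estimate_graph(unclass(d)[perm, ], "lasso-bic", rule = "OR")
  expect_identical(g1$edges, g2$edges)
})

test_that("independence data yields empty BIC neighborhoods", {
  ones <- interaction_matrix(matrix(1, 6, 6))
  empty <- 0
  for (r in 1:20) {
    d <- gibbs_sample(ones, 1000, burn_in = 200, spacing = 1, seed = 900 + r)
    nb <- lasso_neighborhoods(d, "bic")
    if (sum(lengths(nb$selected)) == 0) empty <- empty + 1
  }
  expect_gte(empty / 20, 0.8)
})

test_that("BIC neighborhoods recover the m6 edges under the AND rule", {
  tg <- true_graph(preset_structure("m6"))
  tkeys <- bgmlasso:::graph_keys(tg)
  hits <- 0
  for (r in 1:20) {
    d <- gibbs_sample(preset_structure("m6"), 1000, burn_in = 1000,
                      spacing = 5, seed = 3000 + r)
    nb <- lasso_neighborhoods(d, "bic")
    keys <- bgmlasso:::graph_keys(combine_edges(nb, "AND"))
    if (all(tkeys %in% keys)) hits <- hits + 1
  }
  expect_gt(hits / 20, 0.5)
})

test_that("size-rule neighborhoods reach the target size before combination", {
  d <- m6_data(300, seed = 55)
  nb <- lasso_neighborhoods(d, "size", l = 2)
  expect_true(all(lengths(nb$selected) >= 2))
  for (a in names(nb$selected)) {
    expect_false(a %in% nb$selected[[a]])
  }
})

test_that("estimate_graph validates method parameters and composition", {
  d <- m6_data(300, seed = 55)
  expect_error(estimate_graph(d, "bolasso", B = 5, pi_cut = 0.9), "`l`")
  expect_error(estimate_graph(d, "bolasso", B = 5, l = 2), "`pi_cut`")
  expect_error(estimate_graph(d, "bolasso-cv", pi_cut = 0.9), "`B`")
  g <- estimate_graph(d, "lasso-bic", rule = "AND")
  ref <- combine_edges(lasso_neighborhoods(d, "bic"), "AND")
  expect_identical(g$edges, ref$edges)
})

test_that("constant columns are dropped with a warning, tiny p rejected", {
  d <- cbind(unclass(m6_data(300, seed = 55)), Z = 0L)
  expect_warning(nb <- lasso_neighborhoods(d, "bic"), "constant.*Z")
  expect_false("Z" %in% nb$nodes)
  expect_error(
    suppressWarnings(lasso_neighborhoods(cbind(a = rep(0:1, 10),
                                               b = rep(c(0L, 1L), each = 10)))),
    "at least 3"
  )
})
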