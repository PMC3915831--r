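test_that("a single forced cascade is a path with the expected edges", {
  truth <- generate_regulatory_network(
    n_tfs = 4L, n_targets = 1L, chain_length_range = c(5L, 5L),
    branching = 1L, decoy_frac = 0, seed = 2
  )
  expect_equal(nrow(truth$edges), 4L)
  expect_equal(nrow(truth$chains), 1L)
  # in-degree 1 everywhere except the root: a simple path of 5 nodes
  expect_equal(anyDuplicated(truth$edges$target), 0L)
  expect_length(
    setdiff(truth$edges$regulator, truth$edges$target), 1L
  )
})

test_that("network generation is deterministic and validates arguments", {
  a <- generate_regulatory_network(seed = 9)
  b <- generate_regulatory_network(seed = 9)
  expect_identical(a$edges, b$edges)
  expect_identical(a$nodes, b$nodes)
  expect_false(identical(
    a$edges, generate_regulatory_network(seed = 10)$edges
  ))

  expect_error(
    generate_regulatory_network(n_tfs = 3L, chain_length_range = c(5L, 6L)),
    "n_tfs"
  )
  expect_error(
    generate_regulatory_network(chain_length_range = c(2L, 5L)), "within"
  )
  expect_error(generate_regulatory_network(decoy_frac = 1), "decoy_frac")
})

test_that("edge counts follow the documented generative rule", {
  for (seed in 1:30) {
    truth <- generate_regulatory_network(
      n_tfs = 12L, n_targets = 40L, branching = 2L, seed = seed
    )
    n_decoy <- sum(truth$nodes$role == "decoy")
    expect_equal(n_decoy, round(0.2 * 40))
    chain_edges <- sum(truth$chains$n_tfs - 1L) + sum(truth$chains$has_leaf)
    n_free <- sum(truth$nodes$role == "free_leaf")
    expect_equal(nrow(truth$edges), chain_edges + 2L * n_free)
    # acyclic by construction: a topological order exists
    expect_silent(haracne:::topological_order(truth$nodes$id, truth$edges))
    # every regulator is a TF; non-decoy targets have a regulator
    expect_true(all(
      truth$edges$regulator %in% truth$nodes$id[truth$nodes$is_tf]
    ))
    regulated <- unique(truth$edges$target)
    leaves <- truth$nodes$id[truth$nodes$role %in% c("chain_leaf", "free_leaf")]
    expect_true(all(leaves %in% regulated))
  }
})

test_that("simulated expression has the right shape and is seeded", {
  truth <- generate_regulatory_network(seed = 4)
  expr <- simulate_expression(truth, n_samples = 60, seed = 8)
  expect_equal(dim(expr), c(nrow(truth$nodes), 60L))
  expect_identical(rownames(expr), truth$nodes$id)
  expr2 <- simulate_expression(truth, n_samples = 60, seed = 8)
  expect_identical(unclass(expr), unclass(expr2))
  expect_error(simulate_expression(truth, n_samples = 10), "at least 50")
  expect_error(simulate_expression(truth, noise_sd = -1), "non-negative")

  cyclic <- truth
  cyclic$edges <- tibble::tibble(
    regulator = c("TF01", "TF02"), target = c("TF02", "TF01"),
    chain_id = 1L
  )
  expect_error(simulate_expression(cyclic, n_samples = 60), "cycle")
})

test_that("noiseless chains are deterministic copies; noise restores the DPI gap", {
  truth <- generate_regulatory_network(
    n_tfs = 2L, n_targets = 1L, chain_length_range = c(3L, 3L),
    decoy_frac = 0, seed = 1
  )
  e0 <- simulate_expression(truth, n_samples = 200, noise_sd = 0, seed = 5)
  topo <- haracne:::topological_order(truth$nodes$id, truth$edges)
  # monotone transfer without noise preserves ranks exactly, so the MI of
  # (root, child) and (root, grandchild) coincide at estimator resolution
  i12 <- mutual_information(e0[topo[1L], ], e0[topo[2L], ])$value
  i13 <- mutual_information(e0[topo[1L], ], e0[topo[3L], ])$value
  expect_equal(i12, i13)

  gap <- vapply(1:10, function(s) {
    e <- simulate_expression(truth, n_samples = 400, noise_sd = 0.5, seed = s)
    i12 <- mutual_information(e[topo[1L], ], e[topo[2L], ])$value
    i23 <- mutual_information(e[topo[2L], ], e[topo[3L], ])$value
    i13 <- mutual_information(e[topo[1L], ], e[topo[3L], ])$value
    i13 < min(i12, i23)
  }, logical(1))
  expect_gte(sum(gap), 9L)
})

test_that("the Markov property holds: no partial association at one remove", {
  truth <- generate_regulatory_network(
    n_tfs = 3L, n_targets = 1L, chain_length_range = c(4L, 4L),
    decoy_frac = 0, seed = 3
  )
  topo <- haracne:::topological_order(truth$nodes$id, truth$edges)
  pcors <- vapply(1:5, function(s) {
    e <- simulate_expression(truth, n_samples = 2000, seed = s)
    g <- e[topo[1L], ]
    p <- e[topo[2L], ]
    c_ <- e[topo[3L], ]
    # subtracting the child's true conditional mean given the parent
    # leaves pure innovation noise, independent of the grandparent
    rc <- c_ - tanh(3 * p)
    cor(g, rc)
  }, numeric(1))
  # sampling noise alone bounds the association at one remove
  expect_true(all(abs(pcors) < 3.3 / sqrt(2000)))
})

test_that("recovery scoring is exact undirected set arithmetic", {
  truth <- generate_regulatory_network(
    n_tfs = 6L, n_targets = 10L, decoy_frac = 0.2, seed = 12
  )
  perfect <- as_mi_network(
    tibble::tibble(
      u = truth$edges$regulator, v = truth$edges$target, mi = 1
    ),
    tfs = truth$nodes$id[truth$nodes$is_tf], nodes = truth$nodes$id
  )
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$f1, 1)

  empty <- as_mi_network(
    tibble::tibble(u = character(), v = character(), mi = numeric()),
    tfs = truth$nodes$id[truth$nodes$is_tf], nodes = truth$nodes$id
  )
  sc0 <- score_recovery(empty, truth)
  expect_equal(sc0$recall, 0)
  expect_true(is.na(sc0$precision))
  expect_false(sc0$precision_defined)

  for (seed in 1:10) {
    some <- withr::with_seed(seed, {
      keep <- sample(c(TRUE, FALSE), nrow(truth$edges), replace = TRUE)
      fake <- tibble::tibble(
        u = "TF01", v = c("TG901", "TG902"), mi = 0.5
      )
      as_mi_network(
        dplyr::bind_rows(
          tibble::tibble(
            u = truth$edges$regulator[keep],
            v = truth$edges$target[keep], mi = 1
          ),
          fake
        ) |> dplyr::distinct(u, v, .keep_all = TRUE),
        tfs = truth$nodes$id[truth$nodes$is_tf],
        nodes = c(truth$nodes$id, "TG901", "TG902")
      )
    })
    sc <- score_recovery(some, truth)
    true_keys <- paste(
      pmin(truth$edges$regulator, truth$edges$target),
      pmax(truth$edges$regulator, truth$edges$target),
      sep = "~"
    )
    expect_equal(sc$tp, sum(edge_keys(some) %in% true_keys))
    expect_equal(sc$fp, nrow(some) - sc$tp)
    expect_equal(sc$fn, length(unique(true_keys)) - sc$tp)
  }
})

test_that("the saturation experiment returns a coherent per-stage table", {
  sat <- saturation_experiment(
    n_seeds = 10, seed = 5,
    config = list(
      n_tfs = 8L, n_targets = 20L, n_samples = 150L,
      n_perm = 2000L, max_order = 3L
    )
  )
  expect_s3_class(sat, "saturation_experiment")
  expect_equal(nrow(sat), 10L * 4L)  # orders 0..3 per seed
  expect_true(all(sat$order %in% 0:3))
  expect_true(all(sat$tie_rate >= 0 & sat$tie_rate <= 1))
  by_seed <- split(sat, sat$seed)
  for (s in by_seed) {
    s <- s[order(s$order), ]
    expect_equal(s$edges[-1L], s$edges[-nrow(s)] - s$removed[-1L])
    expect_true(all(diff(s$recall) <= 1e-12))
  }
  expect_error(saturation_experiment(n_seeds = 2), "at least 10")
  expect_error(
    saturation_experiment(n_seeds = 10, config = list(bogus = 1)), "unknown"
  )
})
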