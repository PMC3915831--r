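tf_triangle <- function(iab, ibc, iac) {
  as_mi_network(
    data.frame(
      u = c("A", "B", "A"), v = c("B", "C", "C"),
      mi = c(iab, ibc, iac)
    ),
    tfs = c("A", "B", "C")
  )
}

# chain A-B-C-D plus the long-range shortcut A-D
chain_fixture <- function(iad = 0.3) {
  as_mi_network(
    data.frame(
      u = c("A", "B", "C", "A"), v = c("B", "C", "D", "D"),
      mi = c(0.9, 0.8, 0.7, iad)
    ),
    tfs = c("A", "B", "C", "D")
  )
}

test_that("first-order DPI removes the weakest edge of a triangle", {
  res <- dpi1_prune(tf_triangle(0.5, 0.4, 0.2))
  expect_setequal(edge_keys(res$network), c("A~B", "B~C"))
  rec <- res$ledger$records
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$witness_path, "A|B|C")
  expect_equal(rec$margin, 0.4 - 0.2)

  # exact ties survive: the inequality is strict
  tie <- dpi1_prune(tf_triangle(0.3, 0.3, 0.3))
  expect_equal(nrow(tie$ledger$records), 0L)

  expect_error(dpi1_prune(tf_triangle(0.5, 0.4, 0.2), tolerance = 1), "0, 1")
  expect_error(dpi1_prune(tf_triangle(0.5, 0.4, 0.2), tolerance = -0.1), "0, 1")
})

test_that("tolerance relaxes the comparison multiplicatively", {
  # mi(A,C) = 0.36 vs min = 0.4: removed at eps = 0, kept at eps = 0.15
  net <- tf_triangle(0.5, 0.4, 0.36)
  expect_equal(nrow(dpi1_prune(net, tolerance = 0)$network), 2L)
  expect_equal(nrow(dpi1_prune(net, tolerance = 0.15)$network), 3L)
})

test_that("second-order DPI removes a quadruplet shortcut via the chain", {
  net <- chain_fixture(0.3)
  first <- dpi1_prune(net)
  expect_equal(nrow(first$ledger$records), 0L)  # no triangle exists

  second <- dpik_prune(first$network, k = 2)
  expect_setequal(edge_keys(second$network), c("A~B", "B~C", "C~D"))
  rec <- second$ledger$records
  expect_identical(rec$witness_path, "A|B|C|D")
  expect_equal(rec$order_removed, 2L)
  expect_equal(rec$margin, 0.7 - 0.3)

  # a direct edge stronger than every chain edge survives all orders (the
  # weakest chain edge may itself fall via a path through the strong edge)
  strong <- haracne_prune(chain_fixture(0.95), max_order = 4)
  for (k in 1:4) {
    expect_true("A~D" %in% edge_keys(strong$stages[[as.character(k)]]))
  }

  expect_error(dpik_prune(net, k = 1), ">= 2")
})

test_that("the sequential schedule reduces to its parts and logs per order", {
  net <- chain_fixture(0.3)
  k1 <- haracne_prune(net, max_order = 1)
  d1 <- dpi1_prune(net)
  expect_identical(edge_keys(k1$network), edge_keys(d1$network))
  expect_equal(per_order_summary(k1)$removed, 0L)

  k4 <- haracne_prune(net, max_order = 4)
  po <- per_order_summary(k4)
  expect_equal(po$order, 1:4)
  expect_equal(po$removed, c(0L, 1L, 0L, 0L))
  expect_equal(po$entering, c(4L, 4L, 3L, 3L))
  expect_equal(po$leaving, po$entering - po$removed)
})

test_that("non-TF nodes cannot serve as path intermediaries by default", {
  # two TFs bridged by a shared non-TF target
  net <- as_mi_network(
    data.frame(
      u = c("TFA", "TFB", "TFA"), v = c("tgt", "tgt", "TFB"),
      mi = c(0.9, 0.8, 0.2)
    ),
    tfs = c("TFA", "TFB")
  )
  strict <- dpi1_prune(net)
  expect_equal(nrow(strict$network), 3L)
  permissive <- dpi1_prune(net, allow_nontf_bridge = TRUE)
  expect_setequal(edge_keys(permissive$network), c("TFA~tgt", "TFB~tgt"))
})

test_that("each pass matches the exhaustive tuple-enumeration oracle", {
  for (seed in 1:40) {
    net <- random_test_network(seed,
      n_nodes = 8L + seed %% 3L, n_tfs = 4L + seed %% 3L
    )
    for (eps in c(0, 0.1)) {
      current <- net
      for (k in 1:4) {
        pass <- if (k == 1L) dpi1_prune(current, eps) else {
          dpik_prune(current, k, eps)
        }
        oracle <- oracle_dpi_flags(current, k, eps)
        expect_identical(
          sort(edge_keys(pass$ledger$records)),
          sort(edge_keys(current)[oracle]),
          label = sprintf("seed %d k %d eps %g", seed, k, eps)
        )
        current <- pass$network
      }
    }
  }
})

test_that("witness paths are valid certificates of each removal", {
  for (seed in c(3, 17, 29)) {
    net <- random_test_network(seed, n_nodes = 10L, n_tfs = 6L, density = 0.6)
    fit <- haracne_prune(net, max_order = 4)
    stages <- c(list(net), unname(fit$stages))
    rec <- fit$ledger$records
    for (i in seq_len(nrow(rec))) {
      entering <- stages[[rec$order_removed[i]]]
      keys <- edge_keys(entering)
      path <- strsplit(rec$witness_path[i], "|", fixed = TRUE)[[1L]]
      expect_length(path, rec$order_removed[i] + 2L)
      expect_false(anyDuplicated(path) > 0)
      # interior nodes are TFs and every step is a surviving edge
      interior <- path[-c(1L, length(path))]
      expect_true(all(interior %in% network_tfs(net)))
      step_keys <- paste(
        pmin(path[-length(path)], path[-1L]),
        pmax(path[-length(path)], path[-1L]),
        sep = "~"
      )
      expect_true(all(step_keys %in% keys))
      step_mi <- entering$mi[match(step_keys, keys)]
      expect_equal(min(step_mi) - rec$mi[i], rec$margin[i])
      expect_gt(rec$margin[i], 0)
    }
  }
})

test_that("within a pass the removed set is invariant to scan order", {
  for (seed in c(2, 9, 25)) {
    net <- random_test_network(seed, n_nodes = 10L, n_tfs = 5L, density = 0.6)
    ref <- haracne_prune(net, max_order = 3)
    perm <- withr::with_seed(seed, sample(nrow(net)))
    shuffled <- as_mi_network(tibble::as_tibble(net)[perm, ],
      tfs = network_tfs(net), nodes = network_nodes(net)
    )
    alt <- haracne_prune(shuffled, max_order = 3)
    expect_setequal(edge_keys(ref$network), edge_keys(alt$network))
    expect_equal(
      per_order_summary(ref)$removed, per_order_summary(alt)$removed
    )
  }
})

test_that("surviving edge sets are nested and tolerance is conservative", {
  for (seed in 1:15) {
    net <- random_test_network(seed + 300, n_nodes = 11L, n_tfs = 6L)
    fit <- haracne_prune(net, max_order = 4)
    prev <- edge_keys(net)
    for (k in 1:4) {
      cur <- edge_keys(fit$stages[[as.character(k)]])
      expect_true(all(cur %in% prev))
      prev <- cur
    }
    # larger tolerance removes (weakly) fewer edges at every order
    loose <- haracne_prune(net, max_order = 4, tolerance = 0.1)
    expect_true(
      all(edge_keys(fit$network) %in% edge_keys(loose$network)) ||
        nrow(loose$network) >= nrow(fit$network)
    )
    removed_strict <- edge_keys(fit$ledger$records)
    removed_loose <- edge_keys(loose$ledger$records)
    expect_true(all(removed_loose %in% removed_strict))
  }
})

test_that("ledger arithmetic chains across orders and matches set differences", {
  for (seed in 1:10) {
    net <- random_test_network(seed + 600, n_nodes = 10L, n_tfs = 5L)
    fit <- haracne_prune(net, max_order = 4)
    po <- per_order_summary(fit)
    expect_equal(po$leaving, po$entering - po$removed)
    expect_equal(po$entering[-1L], po$leaving[-nrow(po)])
    expect_equal(sum(po$removed), nrow(fit$ledger$records))
    # per-order removal counts agree with stage-to-stage set differences
    stages <- c(list(net), unname(fit$stages))
    for (k in 1:4) {
      expect_equal(
        nrow(network_difference(stages[[k]], stages[[k + 1L]])),
        po$removed[k]
      )
    }
  }
})
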