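test_that("link enumeration is a bijection with trophic links", {
  lk <- enumerate_links(chain_web(3))
  expect_identical(lk$nodes, c("1-2", "2-3"))
  lk_ac <- enumerate_links(ac_triad_web())
  expect_identical(lk_ac$nodes, c("1-3", "2-3"))
  set.seed(51)
  web <- niche_web(15)
  mutual <- sum(web$adjacency & t(web$adjacency)) / 2
  expect_identical(nrow(enumerate_links(web)), as.integer(n_links(web) - mutual))
})

test_that("triads are classified by their induced link sets", {
  expect_identical(enumerate_triads(ac_triad_web())$motif_class, "AC")

  ec <- web_topology(3, c(0.1, 0.5, 0.9), {
    a <- matrix(FALSE, 3, 3); a[1, 2] <- a[1, 3] <- TRUE; a
  })
  expect_identical(enumerate_triads(ec)$motif_class, "EC")

  ttc <- chain_web(3)
  expect_identical(enumerate_triads(ttc)$motif_class, "TTC")

  omni <- web_topology(3, c(0.1, 0.5, 0.9), {
    a <- matrix(FALSE, 3, 3); a[1, 2] <- a[2, 3] <- a[1, 3] <- TRUE; a
  })
  expect_identical(enumerate_triads(omni)$motif_class, "OTHER3")
})

test_that("triad enumeration keeps exactly the weakly connected 3-subsets", {
  set.seed(52)
  for (q in 1:10) {
    web <- niche_web(10)
    tri <- enumerate_triads(web)
    U <- web$adjacency | t(web$adjacency)
    all3 <- combn(10, 3)
    connected <- apply(all3, 2, function(nd) {
      g <- igraph::graph_from_adjacency_matrix(U[nd, nd], mode = "undirected")
      igraph::components(g)$no == 1L
    })
    expect_identical(nrow(tri), as.integer(sum(connected)))
    expect_identical(
      tri$nodes,
      apply(all3[, connected, drop = FALSE], 2, paste, collapse = "-")
    )
  }
})

test_that("scan fractions never exceed one and the full set attains it", {
  set.seed(53)
  rea <- sample_stable_reactive(n = 10)
  sc <- scan_motifs(rea$J, rea$web)
  expect_true(all(sc$fraction <= 1 + 1e-10))
  expect_equal(
    submatrix_reactivity(rea$J, 1:10) / attr(sc, "system_r"), 1
  )
})

test_that("scan winners match brute-force enumeration on small webs", {
  set.seed(54)
  for (q in 1:8) {
    rea <- sample_stable_reactive(n = 8, max_tries = 1e4)
    sc <- scan_motifs(rea$J, rea$web)

    lk <- enumerate_links(rea$web)
    link_sets <- Map(c, lk$n1, lk$n2)
    bf_link <- brute_force_best(rea$J, link_sets)
    best_link <- most_reactive_instance(rea$J, sc, motif_class = "PP")
    expect_identical(best_link$nodes, paste(bf_link$nodes, collapse = "-"))
    expect_lt(abs(best_link$reactivity - bf_link$r), 1e-10)

    tri <- enumerate_triads(rea$web)
    tri_sets <- Map(c, tri$n1, tri$n2, tri$n3)
    bf_tri <- brute_force_best(rea$J, tri_sets)
    best_tri <- most_reactive_instance(
      rea$J, sc, motif_class = c("AC", "EC", "TTC", "OTHER3")
    )
    expect_identical(best_tri$nodes, paste(bf_tri$nodes, collapse = "-"))
    expect_lt(abs(best_tri$reactivity - bf_tri$r), 1e-10)
  }
})

test_that("a block-diagonal maximum pins the winning pair at fraction one", {
  S <- diag(-1, 6)
  S[1, 2] <- S[2, 1] <- 3 # leading pair: eigenvalue 2
  sc <- scan_motifs(S) # no topology: exhaustive subsets
  top <- most_reactive_instance(S, sc, motif_class = "PAIR")
  expect_identical(top$nodes, "1-2")
  expect_equal(top$fraction, 1)
})

test_that("most_reactive_instance validates reactivity and empty filters", {
  expect_error(
    most_reactive_instance(diag(c(-1, -2)), tibble::tibble()),
    "not positive"
  )
  set.seed(55)
  rea <- sample_stable_reactive(n = 8)
  sc <- scan_motifs(rea$J, rea$web)
  expect_identical(nrow(most_reactive_instance(rea$J, sc, "NOPE")), 0L)
})

test_that("node participation recovers known winner frequencies", {
  rec <- tibble::tibble(
    topology_hash = "x",
    n_species = 6L,
    best_nodes_AC = c("1-2-3", "1-2-3", "4-5-6", "1-2-3")
  )
  np <- node_participation(rec)
  expect_equal(np$participation, c(0.75, 0.75, 0.75, 0.25, 0.25, 0.25))

  rec2 <- tibble::tibble(
    topology_hash = "x", n_species = 6L,
    best_nodes_AC = c("1-2-3", "4-5-6")
  )
  expect_equal(node_participation(rec2)$participation, rep(0.5, 6))

  rec3 <- tibble::tibble(topology_hash = c("x", "y"), n_species = 6L,
                         best_nodes_AC = "1-2-3")
  expect_error(node_participation(rec3), "single fixed topology")
})

test_that("generic subgraph enumeration finds connected k-sets", {
  web <- chain_web(4)
  sub3 <- enumerate_subgraphs(web, 3)
  expect_identical(
    purrr::map_chr(sub3$nodes, paste, collapse = "-"),
    c("1-2-3", "2-3-4")
  )
  sub4 <- enumerate_subgraphs(web, 4)
  expect_identical(nrow(sub4), 1L)
})
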