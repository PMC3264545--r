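test_that("degree matches direct neighbor counts", {
  g <- fig1_network()
  d <- degree_centrality(g)
  expect_equal(d[["b"]], 3)
  expect_equal(d[["g2"]], 4)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_true(all(degree_centrality(k4) == 3))
})

test_that("the toy tree reproduces all printed centrality values jointly", {
  g <- fig1_network()
  d <- degree_centrality(g)
  ec <- eigenvector_centrality(g)
  ti1 <- topological_importance(g, 1)
  b <- betweenness_centrality(g)
  cl <- closeness_centrality(g)

  expect_equal(d[["b"]], 3)
  expect_equal(round(ec[["b"]], 3), 0.925)
  expect_equal(round(ec[["g3"]], 3), 0.676)
  expect_equal(max(ec), 1.0)          # the three-leaf branch node tops EC
  expect_equal(ti1[["b"]], 1 + 1/4 + 1/3, tolerance = 1e-12)
  expect_equal(ti1[["b"]], 1.58, tolerance = 0.01)
  expect_equal(b[["b"]], 19)
  expect_equal(cl[["b"]], 8 / 13, tolerance = 1e-12)
  expect_equal(round(cl[["b"]], 3), 0.615)
})

test_that("eigenvector centrality satisfies the eigen-relation and demands connectivity", {
  g <- fig1_network()
  ec <- eigenvector_centrality(g, tol = 1e-9)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[names(ec), names(ec)]
  av <- as.numeric(A %*% ec)
  lambda <- sum(av * ec) / sum(ec^2)
  expect_lt(max(abs(av - lambda * ec)), 1e-9)
  expect_equal(max(ec), 1.0)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(unname(eigenvector_centrality(k5)), rep(1, 5))

  expect_error(eigenvector_centrality(named_graph("A", "B", "C", "D")),
               "giant component")
})

test_that("eigenvector output is invariant to vertex order", {
  g <- fig1_network()
  perm <- igraph::permute(g, c(5, 3, 9, 1, 2, 8, 4, 6, 7))
  expect_equal(eigenvector_centrality(g), eigenvector_centrality(perm),
               tolerance = 1e-9)
})

test_that("closeness equals (n-1) over total distance", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", sprintf("l%d", 1:5))
  expect_equal(closeness_centrality(star)[["hub"]], 1.0)
  p3 <- path3()
  expect_equal(closeness_centrality(p3)[["b"]], 1.0)
  expect_error(closeness_centrality(named_graph("A", "B", "C", "D")),
               "giant component")
})

test_that("betweenness splits pair counts across multiple geodesics", {
  c4 <- igraph::make_ring(4)
  igraph::V(c4)$name <- letters[1:4]
  expect_equal(unname(betweenness_centrality(c4)), rep(0.5, 4))
  g <- fig1_network()
  b <- betweenness_centrality(g)
  expect_true(all(b[c("g1", "w1", "w2", "w3", "w4", "w5")] == 0))
})

test_that("effect matrix is row-stochastic with zero diagonal", {
  g <- fig1_network()
  E <- effect_matrix(g)
  expect_equal(unname(Matrix::rowSums(E)), rep(1, 9))
  expect_equal(max(abs(Matrix::diag(E))), 0)
  expect_equal(E["b", "g1"], 1/3)

  e1 <- named_graph("A", "B")
  expect_equal(as.numeric(effect_matrix(e1)["A", "B"]), 1)
  expect_equal(as.numeric(effect_matrix(path3())["b", "a"]), 0.5)

  iso <- igraph::add_vertices(named_graph("A", "B"), 1, name = "Z")
  expect_error(effect_matrix(iso), "Z")
})

test_that("topological importance matches hand-computed powers and validates m", {
  ti2 <- topological_importance(path3(), 2)
  expect_equal(ti2, c(a = 0.5, b = 1.0, c = 0.5), tolerance = 1e-12)
  expect_error(topological_importance(path3(), 0), "m must be")
  expect_error(topological_importance(path3(), 2.5), "m must be")
})

test_that("TI conservation: one-step effects sum to n, q-step to n minus the trace", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    g <- igraph::sample_gnm(n, sample(n:(2 * n), 1))
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    if (igraph::vcount(g) < 2) next
    nn <- igraph::vcount(g)
    expect_equal(sum(topological_importance(g, 1)), nn, tolerance = 1e-9)
    E <- effect_matrix(g)
    for (q in 2:3) {
      Pq <- E
      for (i in seq_len(q - 1)) Pq <- Pq %*% E
      phi_q <- Matrix::colSums(Pq) - Matrix::diag(Pq)
      expect_equal(sum(phi_q), nn - sum(Matrix::diag(Pq)), tolerance = 1e-9)
    }
  }
})

test_that("centrality table has all indices, normalized columns peaking at 1", {
  g <- fig1_network()
  tab <- centrality_table(g)
  expect_equal(nrow(tab), 9)
  expect_setequal(setdiff(names(tab), "protein_id"),
                  c(multicent:::INDEX_LABELS, paste0(multicent:::INDEX_LABELS, "_norm")))
  for (lab in multicent:::INDEX_LABELS) {
    expect_equal(max(tab[[paste0(lab, "_norm")]]), 1.0)
  }
  # the barycentric hub tops the global indices; the three-leaf branch
  # node tops the local ones (it is the degree-4, EC = 1 vertex)
  brow <- tab[tab$protein_id == "b", ]
  grow <- tab[tab$protein_id == "g2", ]
  expect_equal(brow$B, max(tab$B))
  expect_equal(brow$C, max(tab$C))
  expect_equal(grow$D, max(tab$D))
  expect_equal(grow$EC, 1.0)

  e1 <- named_graph("A", "B")
  # a single edge has zero betweenness everywhere, which normalization warns about
  expect_warning(t1 <- centrality_table(e1), "column B")
  expect_equal(unlist(t1[1, -1]), unlist(t1[2, -1]), ignore_attr = TRUE)
})

test_that("normalize_max1 rescales, is idempotent, and warns on all-zero columns", {
  tab <- data.frame(protein_id = c("x", "y"), D = c(2, 4), EC = c(1, 1),
                    TI1 = c(0.2, 0.1), TI4 = c(0.3, 0.3), B = c(0, 0), C = c(0.5, 1))
  expect_warning(out <- normalize_max1(tab), "column B")
  expect_equal(out$D_norm, c(0.5, 1.0))
  expect_equal(out$B_norm, c(0, 0))
  out2 <- suppressWarnings(normalize_max1(out))
  expect_equal(out2, out)
  expect_error(normalize_max1(tab[0, ]), "empty")
})

test_that("centrality table round-trips through TSV", {
  tab <- centrality_table(fig1_network())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_centrality_table(tab, path)
  back <- read_centrality_table(path)
  expect_equal(back$protein_id, tab$protein_id)
  expect_equal(back$TI4, tab$TI4, tolerance = 1e-12)
})

test_that("betweenness, closeness and TI agree with brute-force oracles on every small connected graph", {
  graphs <- atlas_connected()
  expect_gt(length(graphs), 900)
  for (g in graphs) {
    b <- betweenness_centrality(g)
    cl <- closeness_centrality(g)
    ob <- oracle_betweenness(g)
    oc <- oracle_closeness(g)
    expect_equal(b, ob[names(b)], tolerance = 1e-9)
    expect_equal(cl, oc[names(cl)], tolerance = 1e-9)
  }
  # TI oracle is exponential in m; check m = 1..3 on a subsample
  set.seed(3)
  for (g in sample(graphs, 60)) {
    for (m in 1:3) {
      ti <- topological_importance(g, m)
      ot <- oracle_ti(g, m)
      expect_equal(ti, ot[names(ti)], tolerance = 1e-9)
    }
  }
})
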