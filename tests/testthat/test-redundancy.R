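test_that("gamma matches pair-enumeration values and the identity/reversal poles", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(gk_gamma(x, x), 1.0)
  expect_equal(gk_gamma(x, -x), -1.0)
  expect_equal(gk_gamma(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6)
})

test_that("gamma excludes tied pairs and flags the all-tied case", {
  # ties in y: pairs (1,2) and (3,4) are tied in y and must be excluded
  expect_equal(gk_gamma(c(1, 2, 3, 4), c(1, 1, 2, 2)), 1.0)
  expect_warning(g <- gk_gamma(c(1, 2, 3), c(5, 5, 5)), "undefined")
  expect_true(is.na(g))
})

test_that("gamma is invariant under strictly monotone transforms and aligns by name", {
  set.seed(21)
  x <- rnorm(40)
  y <- rnorm(40)
  g0 <- gk_gamma(x, y)
  expect_equal(gk_gamma(exp(x), y), g0)
  expect_equal(gk_gamma(x, rank(y)), g0)
  expect_equal(gk_gamma(-x, y), -g0)

  names(x) <- names(y) <- sprintf("p%02d", 1:40)
  expect_equal(gk_gamma(x, y[sample(names(y))]), g0)
  expect_error(gk_gamma(x, y[-1]), "different protein sets")
})

test_that("association matrix is symmetric with unit diagonal and permutation invariant", {
  tab <- centrality_table(fig1_network())
  m <- association_matrix(tab)
  expect_equal(unname(diag(m)), rep(1, 6))
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(m >= -1 & m <= 1))

  m2 <- association_matrix(tab[sample(nrow(tab)), ])
  expect_equal(unclass(m), unclass(m2))

  # identical columns give all-ones; a reversed column gives -1
  tab2 <- tab
  for (lab in c("EC", "TI1", "TI4", "B", "C")) tab2[[lab]] <- tab2$D
  expect_true(all(association_matrix(tab2) == 1))
  tab3 <- tab
  tab3$B <- -tab3$D
  expect_equal(association_matrix(tab3)["D", "B"], -1)
})

test_that("index dendrogram groups perfectly associated blocks first", {
  labs <- c("D", "EC", "TI1", "TI4", "B", "C")
  ones <- structure(matrix(1, 6, 6, dimnames = list(labs, labs)),
                    class = c("rank_association", "matrix"))
  d_all <- index_dendrogram(ones)
  expect_equal(max(d_all$height), 0)

  # two perfect blocks {D,B} and {EC,C}; TI1/TI4 unrelated to everything
  m <- diag(1, 6)
  dimnames(m) <- list(labs, labs)
  m["D", "B"] <- m["B", "D"] <- 0.95
  m["EC", "C"] <- m["C", "EC"] <- 0.95
  m["D", "EC"] <- m["EC", "D"] <- 0.2
  m["D", "C"] <- m["C", "D"] <- 0.2
  m["B", "EC"] <- m["EC", "B"] <- 0.2
  m["B", "C"] <- m["C", "B"] <- 0.2
  dend <- index_dendrogram(structure(m, class = c("rank_association", "matrix")))
  first_two <- list(sort(dend$labels[-dend$merge[1, ]]),
                    sort(dend$labels[-dend$merge[2, ]]))
  expect_true(any(vapply(first_two, identical, logical(1), y = c("B", "D"))))
  expect_true(any(vapply(first_two, identical, logical(1), y = c("C", "EC"))))

  expect_error(index_dendrogram(ones, linkage = "mystery"))
})

test_that("dendrogram structure ignores index label order and exports Newick heights", {
  tab <- centrality_table(fig1_network())
  m <- association_matrix(tab)
  perm <- c("C", "B", "TI4", "TI1", "EC", "D")
  m_perm <- structure(unclass(m)[perm, perm], class = class(m))
  d1 <- index_dendrogram(m)
  d2 <- index_dendrogram(m_perm)
  merges <- function(d) {
    cl <- stats::cutree(d, k = 3)
    unname(split(names(cl), cl)[order(vapply(split(names(cl), cl), min, ""))])
  }
  expect_setequal(lapply(merges(d1), sort), lapply(merges(d2), sort))

  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(d1, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(m))
  expect_true(all(is.finite(tree$edge.length)))
})

test_that("merge heights are non-decreasing", {
  tab <- centrality_table(fig1_network())
  d <- index_dendrogram(association_matrix(tab))
  expect_equal(length(d$height), 5)
  expect_true(all(diff(d$height) >= -1e-12))
})

test_that("subset evaluation on the full index set is self-consistent", {
  tab <- toy_table(n = 120, n_hi = 10)
  cfg <- hub_config(k_max = 6, seed = 5)
  hr <- detect_hubs(tab, config = cfg)
  ev <- evaluate_subset(tab, c("D", "EC", "TI1", "TI4", "B", "C"),
                        reference_hubs = hr$hubs, config = cfg)
  expect_equal(ev$overlap_1cluster[["recovered"]], length(hr$hubs))
  expect_gte(ev$overlap_2clusters[["recovered"]], ev$overlap_1cluster[["recovered"]])
  expect_gte(ev$overlap_2clusters[["size"]], ev$overlap_1cluster[["size"]])
  expect_lte(ev$overlap_1cluster[["recovered"]], ev$reference_size)
  expect_error(evaluate_subset(tab, c("D", "XX", "B", "C"), hr$hubs, cfg),
               "unknown index")
})

test_that("four-index subsets still recover planted hubs in the top two clusters", {
  spec <- synthetic_spec(seed = 4)
  gen <- generate_network(spec)
  tab <- centrality_table(gen$network)
  cfg <- hub_config(k_max = 9, seed = 4)
  for (sub in list(c("TI1", "TI4", "B", "C"), c("D", "EC", "TI1", "TI4"))) {
    ev <- suppressWarnings(
      evaluate_subset(tab, sub, reference_hubs = gen$truth$hub_ids, config = cfg)
    )
    expect_gte(ev$overlap_2clusters[["recovered"]] / length(gen$truth$hub_ids), 0.8)
  }
})
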