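test_that("BIC selects the generative component count on well-separated data", {
  set.seed(1)
  blob <- function(center, n) {
    matrix(stats::rnorm(n * 6, mean = center, sd = 1), n, 6)
  }
  x <- rbind(blob(0, 200), blob(10, 200))
  rownames(x) <- sprintf("p%03d", seq_len(nrow(x)))
  fit <- fit_mixture_bic(x, k_range = 1:6, seed = 1)
  expect_equal(fit$K, 2)
  expect_true(is.finite(fit$bic))
  expect_equal(length(fit$assignments), 400)
  # the two components split exactly along the blobs
  expect_equal(length(unique(fit$assignments[1:200])), 1)
  expect_equal(length(unique(fit$assignments[201:400])), 1)

  x1 <- blob(0, 300)
  rownames(x1) <- sprintf("q%03d", seq_len(300))
  fit1 <- fit_mixture_bic(x1, k_range = 1:5, seed = 1)
  expect_equal(fit1$K, 1)
})

test_that("degenerate identical rows fall back to a regularized single component", {
  x <- matrix(0.5, nrow = 3, ncol = 6,
              dimnames = list(c("a", "b", "c"), NULL))
  fit <- suppressWarnings(fit_mixture_bic(x, k_range = 1, seed = 1))
  expect_equal(fit$K, 1)
  expect_equal(length(unique(fit$assignments)), 1)
})

test_that("mixture fitting is deterministic and row-permutation invariant", {
  tab <- toy_table()
  f1 <- fit_mixture_bic(tab, k_range = 1:5, seed = 3)
  f2 <- fit_mixture_bic(tab, k_range = 1:5, seed = 3)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$bic, f2$bic)

  shuffled <- tab[sample(nrow(tab)), ]
  f3 <- fit_mixture_bic(shuffled, k_range = 1:5, seed = 3)
  expect_identical(f1$assignments, f3$assignments)
  expect_equal(f1$family, f3$family)
})

test_that("central cluster selection follows mean-of-means dominance", {
  fit <- structure(list(
    K = 2,
    component_means = rbind(`1` = rep(0.9, 6), `2` = rep(0.1, 6)),
    component_sizes = c(5L, 10L),
    assignments = stats::setNames(c(1, 1, 1, 1, 1, rep(2, 10)),
                                  sprintf("p%02d", 1:15))
  ), class = "mixture_fit")
  colnames(fit$component_means) <- c("D", "EC", "TI1", "TI4", "B", "C")
  expect_setequal(select_central_cluster(fit), sprintf("p%02d", 1:5))

  # K = 1: everything is the central cluster
  fit1 <- structure(list(
    K = 1, component_means = matrix(rep(0.5, 6), 1,
                                    dimnames = list("1", colnames(fit$component_means))),
    component_sizes = 15L,
    assignments = stats::setNames(rep(1, 15), sprintf("p%02d", 1:15))
  ), class = "mixture_fit")
  expect_equal(length(select_central_cluster(fit1)), 15)

  expect_error(select_central_cluster(fit, data.frame(protein_id = "zz")),
               "different protein sets")
})

test_that("two-round detection isolates the high-centrality block of a structured table", {
  tab <- toy_table(n = 120, n_hi = 10)
  hr <- detect_hubs(tab, config = hub_config(k_max = 6, seed = 5))
  expect_true(all(hr$hubs %in% tab$protein_id))
  expect_true(length(hr$hubs) >= 1)
  expect_true(all(sprintf("p%03d", 1:10) %in% hr$round1_central_cluster) ||
                all(sprintf("p%03d", 1:10) %in% hr$hubs))
  # hub rows dominate the complement on every index mean
  x <- multicent:::norm_matrix(tab)
  in_hub <- rownames(x) %in% hr$round1_central_cluster
  expect_true(all(colMeans(x[in_hub, , drop = FALSE]) >
                    colMeans(x[!in_hub, , drop = FALSE])))
})

test_that("a homogeneous table triggers the small-central-cluster warning path", {
  set.seed(9)
  n <- 80
  tab <- data.frame(protein_id = sprintf("p%03d", 1:n),
                    D = runif(n), EC = runif(n), TI1 = runif(n),
                    TI4 = runif(n), B = runif(n), C = runif(n))
  tab <- normalize_max1(tab)
  # a minimum above n guarantees the degenerate-input contract fires
  expect_warning(
    hr <- detect_hubs(tab, config = hub_config(k_max = 6, seed = 2,
                                               min_central_cluster = n + 1)),
    "round 2 skipped")
  expect_identical(hr$hubs, hr$round1_central_cluster)
  expect_null(hr$round2)
})

test_that("hub detection recovers planted hubs across generator seeds", {
  pr <- recovery_run(seeds = 1:3)
  expect_gte(stats::median(pr[, "recall"]), 0.9)
  expect_gte(stats::median(pr[, "precision"]), 0.8)
})

test_that("hub results serialize to JSON with per-round audit", {
  tab <- toy_table(n = 120, n_hi = 10)
  hr <- detect_hubs(tab, config = hub_config(k_max = 6, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_hub_result(hr, path)
  parsed <- jsonlite::read_json(path)
  expect_setequal(unlist(parsed$hubs), sort(hr$hubs))
  expect_equal(parsed$round1$K, hr$round1$K)
  expect_true(!is.null(parsed$round1$component_means))
})
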