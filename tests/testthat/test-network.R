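test_that("APMI detects perfect dependence and vanishes under independence", {
  set.seed(1)
  x <- rnorm(100)
  expect_gt(apmi(x, x), log(2))
  mi0 <- replicate(50, apmi(rnorm(1000), rnorm(1000)))
  expect_lt(mean(mi0), 0.02)
  expect_true(all(mi0 >= 0))
  expect_warning(z <- apmi(rep(1, 50), rnorm(50)), "constant")
  expect_equal(z, 0)
  expect_error(apmi(1:5, 1:5), "at least 8")
  expect_error(apmi(1:10, 1:9), "equal length")
})

test_that("MI null model has a calibrated, continuous, monotone p-value", {
  nm <- fit_mi_null(100, n_pairs = 1e4, seed = 3)
  # the junction sits at the nominal 5% up to ties among discrete MI values
  expect_lt(abs(p_mi(nm, nm$q95) - 0.05), 0.015)
  grid <- seq(0, 2, 0.002)
  pg <- p_mi(nm, grid)
  expect_true(all(diff(pg) <= 1e-12))
  expect_true(all(pg > 0 & pg <= 1))
  # fresh null draws hit the nominal rate
  set.seed(5)
  fresh <- narnea:::apmi_null_cpp(100L, 10000L, qchisq(0.95, 3), 8L)
  expect_lt(abs(mean(p_mi(nm, fresh) < 0.05) - 0.05), 0.012)
  # shuffled data behave like the null body (two-sample KS)
  set.seed(6)
  x <- rexp(100)
  shuf <- replicate(500, apmi(x, sample(x)))
  ks <- suppressWarnings(stats::ks.test(shuf, nm$body))
  expect_gt(ks$p.value, 0.001)
  expect_error(fit_mi_null(100, n_pairs = 500), "tail")
})

test_that("subnetwork inference recovers strong targets at controlled FDR", {
  tr <- ground_truth_network(1, 5, 95, strength_range = c(0.8, 1), seed = 11)
  ex <- synth_expression(tr, 200, noise = 0.3, seed = 12)
  nm <- fit_mi_null(round(200 * (1 - exp(-1))), n_pairs = 1e4, seed = 13)
  edges <- infer_subnetwork(ex, "R01", nm, fdr = 0.05, seed = 14)
  true_targets <- tr$target
  expect_true(all(true_targets %in% edges$target))
  decoy_rate <- mean(setdiff(rownames(ex), c("R01", true_targets)) %in% edges$target)
  expect_lte(decoy_rate, 2 * 0.05)
})

test_that("subsampling uses the 63.21% bootstrap-coverage fraction", {
  expect_equal(round(100 * (1 - exp(-1))), 63)
  tr <- ground_truth_network(1, 2, 10, seed = 21)
  ex <- synth_expression(tr, 100, seed = 22)
  nm <- fit_mi_null(63, n_pairs = 2e3, seed = 23)
  # a null model fitted at 63 samples matches the subsample: no warning
  expect_no_warning(infer_subnetwork(ex, "R01", nm, seed = 24))
  nm50 <- fit_mi_null(50, n_pairs = 2e3, seed = 25)
  expect_warning(infer_subnetwork(ex, "R01", nm50, seed = 26), "n = 63")
})

test_that("DPI removes the weakest edge of each clique and nothing else", {
  tri <- tibble::tibble(regulator = c("A", "B", "A"),
                        target = c("B", "C", "C"),
                        mi = c(3, 2, 1))
  out <- dpi_prune(tri)
  expect_identical(nrow(out), 2L)
  expect_false(any(out$regulator == "A" & out$target == "C"))

  chain <- tibble::tibble(regulator = c("A", "B"), target = c("B", "C"),
                          mi = c(3, 2))
  expect_identical(dpi_prune(chain), chain)

  # never adds edges; idempotent
  set.seed(31)
  rnd <- tibble::tibble(
    regulator = sample(LETTERS[1:8], 20, replace = TRUE),
    target = sample(letters[1:8], 20, replace = TRUE),
    mi = runif(20)
  )
  rnd <- rnd[!duplicated(rnd[1:2]), ]
  once <- dpi_prune(rnd)
  expect_lte(nrow(once), nrow(rnd))
  expect_identical(dpi_prune(once), once)

  # tied minima are all removed
  tie <- tibble::tibble(regulator = c("A", "B", "A"),
                        target = c("B", "C", "C"),
                        mi = c(3, 1, 1))
  expect_identical(nrow(dpi_prune(tie)), 1L)
})

test_that("DPI prunes the indirect edge of a simulated Markov chain", {
  ok <- vapply(1:40, function(s) {
    set.seed(s)
    x <- rnorm(200)
    y <- x + 0.5 * rnorm(200)
    z <- y + 0.5 * rnorm(200)
    e <- tibble::tibble(regulator = c("X", "Y", "X"),
                        target = c("Y", "Z", "Z"),
                        mi = c(apmi(x, y), apmi(y, z), apmi(x, z)))
    pruned <- dpi_prune(e)
    !any(pruned$regulator == "X" & pruned$target == "Z")
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("consensus integrates subnetworks with occurrence counts", {
  tr <- ground_truth_network(3, 4, 30, seed = 41)
  ex <- synth_expression(tr, 150, seed = 42)
  net <- suppressWarnings(
    consensus_network(ex, unique(tr$regulator), max_nets = 2,
                      min_targets = 1000, seed = 43, n_null = 2e3,
                      keep_all = TRUE)
  )
  expect_identical(attr(net, "n_subnetworks"), 2L)
  expect_true(all(net$count %in% 1:2))
  expect_true(all(net$mi >= 0))
  expect_true(all(abs(net$spearman) <= 1))
  expect_false(anyDuplicated(net[c("regulator", "target")]) > 0)
})

test_that("true edges dominate decoys in counts and match programmed direction", {
  tr <- ground_truth_network(5, 5, 60, seed = 51)
  ex <- synth_expression(tr, 200, seed = 52)
  net <- suppressWarnings(
    consensus_network(ex, unique(tr$regulator), max_nets = 7,
                      min_targets = 1000, seed = 53, n_null = 5e3,
                      keep_all = TRUE)
  )
  truth_key <- paste(tr$regulator, tr$target)
  is_true <- paste(net$regulator, net$target) %in% truth_key
  expect_gt(mean(net$count[is_true]), mean(net$count[!is_true]))
  joined <- dplyr::inner_join(net, tr, by = c("regulator", "target"))
  expect_gte(mean(sign(joined$spearman) == joined$direction), 0.95)
})

test_that("consensus networks convert to copula-weighted regulons", {
  net <- tibble::tibble(
    regulator = "R", target = c("a", "b", "c"),
    count = c(7L, 7L, 3L), mi = c(2, 1, 3), spearman = c(0.9, -0.5, 0.2)
  )
  regs <- network_to_regulons(net)
  expect_equal(regs$aw[match(c("a", "b", "c"), regs$target)], c(0.75, 0.5, 0.25))
  expect_equal(regs$am[match(c("a", "b", "c"), regs$target)], c(0.9, -0.5, 0.2))

  single <- tibble::tibble(regulator = "R", target = "a", count = 2L,
                           mi = 1, spearman = 0.4)
  expect_equal(network_to_regulons(single)$aw, 0.5)
})
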