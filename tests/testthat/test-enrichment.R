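rss5 <- rank_sign_transform(sig5())

test_that("worked micro-example reproduces through the whole pipeline", {
  raw <- raw_scores(rss5, reg5())
  expect_equal(raw$des, 4.5)
  expect_equal(raw$ues, 4.5)

  ns <- normalize_scores(rss5, reg5(), raw$des, raw$ues)
  expect_equal(ns$ndes, 3.1 / sqrt(4.52), tolerance = 1e-12)
  expect_equal(ns$nues, 1.5, tolerance = 1e-12)
  expect_equal(ns$phi, 1.4 / sqrt(4.52), tolerance = 1e-12)
  expect_identical(ns$degenerate, "none")

  cs <- combine_scores(ns$ndes, ns$nues, ns$phi)
  expect_equal(cs$nes_pos, 1.6242, tolerance = 1e-4)
  expect_equal(cs$nes_neg, -0.0507, tolerance = 1e-3)

  sig <- enrichment_significance(cs$nes_pos, cs$nes_neg, ns$ndes)
  expect_equal(sig$p_pos, 0.0522, tolerance = 1e-3)
  expect_equal(sig$p_neg, 0.4798, tolerance = 1e-3)
  expect_equal(sig$p, 0.1016, tolerance = 1e-3)
  expect_equal(sig$nes, 1.637, tolerance = 1e-3)

  # the observed targets occupy the two best positions -> maximal effect
  expect_equal(proportional_enrichment(rss5, reg5()), 1)
})

test_that("analytical null moments equal exhaustive enumeration to 1e-12", {
  set.seed(21)
  for (rep in 1:6) {
    G <- sample(4:6, 1)
    N <- sample(2:3, 1)
    sig <- synth_signature(G)
    rss <- rank_sign_transform(sig)
    aw <- runif(N, 0.2, 1)
    am <- runif(N, -1, 1)
    oracle <- enum_null_moments(rss$r, rss$s, aw, am)
    np <- narnea:::null_params(rss$moments, aw, am)
    expect_equal(np$e_des, oracle$e_des, tolerance = 1e-12)
    expect_equal(np$v_des, oracle$v_des, tolerance = 1e-12)
    expect_equal(np$e_ues, oracle$e_ues, tolerance = 1e-12)
    expect_equal(np$v_ues, oracle$v_ues, tolerance = 1e-12)
    expect_equal(np$cov, oracle$cov, tolerance = 1e-12)
  }
})

test_that("fully directed or fully undirected regulons fall back cleanly", {
  # all |am| = 1: undirected branch carries no information
  reg_dir <- tibble::tibble(regulator = "d", target = c("g1", "g5"),
                            aw = 1, am = c(1, -1))
  raw <- raw_scores(rss5, reg_dir)
  expect_equal(raw$ues, 0)
  ns <- normalize_scores(rss5, reg_dir)
  expect_identical(ns$degenerate, "undirected")
  sc <- narnea:::score_from_raw(raw$des, raw$ues,
                                narnea:::null_params(rss5$moments, reg_dir$aw, reg_dir$am))
  expect_equal(sc$nes, ns$ndes)

  # all am = 0: directed branch carries no information
  reg_und <- tibble::tibble(regulator = "u", target = c("g1", "g5"),
                            aw = 1, am = 0)
  raw <- raw_scores(rss5, reg_und)
  expect_equal(raw$des, 0)
  ns <- normalize_scores(rss5, reg_und)
  expect_identical(ns$degenerate, "directed")
  sc <- narnea:::score_from_raw(raw$des, raw$ues,
                                narnea:::null_params(rss5$moments, reg_und$aw, reg_und$am))
  expect_equal(sc$nes, ns$nues)
})

test_that("combine/significance handle boundary inputs", {
  expect_equal(combine_scores(0, 0, 0.3), list(nes_pos = 0, nes_neg = 0))
  expect_error(combine_scores(1, 1, 1), "phi")
  z <- enrichment_significance(0, 0)
  expect_equal(z$p_pos, 0.5)
  expect_equal(z$p_neg, 0.5)
  expect_equal(z$p, 0.75)
  # extreme scores stay representable in log space
  ext <- enrichment_significance(40, -2)
  expect_gt(ext$p, 0)
  expect_true(is.finite(ext$nes))
  expect_gt(ext$nes, 30)
})

test_that("null correlation phi stays inside (-1, 1) for mixed modes", {
  set.seed(8)
  rss <- rank_sign_transform(synth_signature(300))
  for (i in 1:20) {
    reg <- tibble::tibble(regulator = "x",
                          target = sample(rss$gene, 40),
                          aw = copula_weights(runif(40) + 0.1),
                          am = runif(40, -1, 1))
    ns <- normalize_scores(rss, reg)
    expect_lt(abs(ns$phi), 1)
  }
})

test_that("standardized scores are calibrated under Monte-Carlo null placements", {
  rss <- rank_sign_transform(synth_signature(500, seed = 13))
  set.seed(14)
  aw <- copula_weights(runif(50) + 0.01)
  am <- runif(50, -1, 1)
  mc <- mc_null_scores(rss, aw, am, n_draws = 20000, seed = 15)
  n <- nrow(mc)
  se_mean <- 1 / sqrt(n)
  se_var <- sqrt(2 / n)
  expect_lt(abs(mean(mc$ndes)), 3 * se_mean)
  expect_lt(abs(sd(mc$ndes) - 1), 3 * se_var)
  expect_lt(abs(mean(mc$nues)), 3 * se_mean)
  expect_lt(abs(sd(mc$nues) - 1), 3 * se_var)
  # combined scores: unit variance, uncorrelated, independent tails
  expect_lt(abs(stats::var(mc$nes_pos) - 1), 3 * se_var)
  expect_lt(abs(stats::var(mc$nes_neg) - 1), 3 * se_var)
  expect_lt(abs(cor(mc$nes_pos, mc$nes_neg)), 3 * se_mean)
  expect_lt(abs(cor(mc$p_pos, mc$p_neg)), 3 * se_mean)
})

test_that("effect size is bounded and centered under random placements", {
  rss <- rank_sign_transform(synth_signature(200, seed = 23))
  groups <- narnea:::rss_groups(rss)
  set.seed(24)
  aw <- copula_weights(runif(25) + 0.01)
  am <- runif(25, -1, 1)
  np <- narnea:::null_params(rss$moments, aw, am)
  pes <- vapply(1:1000, function(i) {
    idx <- sample.int(rss$G, 25)
    r <- rss$r[idx]
    s <- rss$s[idx]
    sc <- narnea:::score_from_raw(sum(aw * am * r * s),
                                  sum(aw * (1 - abs(am)) * r), np)
    narnea:::pes_value(rss, groups, aw, am, np, sc$nes)
  }, numeric(1))
  expect_true(all(pes >= -1 & pes <= 1))
  expect_lt(abs(mean(pes)), 0.1)
})

test_that("negating the signature negates NES and PES", {
  set.seed(31)
  sig <- synth_signature(400)
  reg <- tibble::tibble(regulator = "r", target = sample(sig$gene, 40),
                        aw = copula_weights(runif(40) + 0.1),
                        am = runif(40, -1, 1))
  res_pos <- suppressWarnings(narnea(sig, reg))
  res_neg <- suppressWarnings(narnea(dplyr::mutate(sig, z = -z), reg))
  expect_equal(res_neg$nes, -res_pos$nes, tolerance = 1e-8)
  expect_equal(res_neg$pes, -res_pos$pes, tolerance = 1e-8)
})

test_that("median NES rises monotonically with injected effect", {
  set.seed(41)
  base <- synth_signature(2000)
  regs <- random_regulons(15, c(50, 50), base$gene)
  med <- vapply(c(0, 0.5, 1, 2), function(eff) {
    median(suppressWarnings(narnea(active_signature(base, regs, eff), regs))$nes)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  # negative effect flips the enrichment direction
  neg <- median(suppressWarnings(narnea(active_signature(base, regs, -2), regs))$nes)
  expect_lt(neg, 0)
})

test_that("leading edge reproduces the worked example and its bounds", {
  le <- leading_edge(rss5, reg5(), nes = 1.637)
  expect_equal(le$les[le$target == "g5"], 5)
  expect_equal(le$p[le$target == "g5"], 1 / 5)
  expect_equal(le$les[le$target == "g1"], 4)
  expect_true(all(le$p >= 1 / rss5$G))
  expect_error(leading_edge(rss5, reg5(), nes = 0), "undefined")

  # am = 0 reduces to the plain rank tail
  reg0 <- tibble::tibble(regulator = "u", target = c("g2", "g5"), aw = 1, am = 0)
  le0 <- leading_edge(rss5, reg0, nes = 1)
  expect_equal(le0$les, c(5, 3)[order(c(5, 3), decreasing = TRUE)])
  expect_equal(le0$p[le0$target == "g2"], mean(rss5$r >= 3))
  expect_equal(le0$p[le0$target == "g5"], mean(rss5$r >= 5))
})

test_that("leading-edge p-values fall with distance into the signature tail", {
  set.seed(51)
  rss <- rank_sign_transform(synth_signature(500))
  reg <- tibble::tibble(regulator = "r", target = sample(rss$gene, 60),
                        aw = 1, am = 0.5)
  le <- leading_edge(rss, reg, nes = 2)
  expect_true(all(diff(le$p) >= 0)) # ordered by decreasing les
})

test_that("PES bootstrap interval behaves sensibly", {
  set.seed(61)
  sig <- synth_signature(300)
  reg <- tibble::tibble(regulator = "r", target = sample(sig$gene, 40),
                        aw = copula_weights(runif(40) + 0.1),
                        am = runif(40, -1, 1))
  rss <- rank_sign_transform(sig)
  ci <- pes_confidence_interval(rss, reg, n_boot = 100, seed = 5)
  expect_true(ci$lower <= ci$pes && ci$pes <= ci$upper)
  ci2 <- pes_confidence_interval(rss, reg, n_boot = 100, seed = 5)
  expect_equal(ci, ci2)

  # interval narrows with gene set size at fixed effect
  sizes <- c(30, 100, 300)
  sig_big <- synth_signature(5000, seed = 62)
  widths <- vapply(sizes, function(n) {
    set.seed(63)
    regn <- tibble::tibble(regulator = "r",
                           target = sample(sig_big$gene, n),
                           aw = copula_weights(runif(n) + 0.1),
                           am = runif(n, 0.2, 1))
    shifted <- active_signature(sig_big, regn, effect = 1.5)
    rssn <- rank_sign_transform(shifted)
    ci <- pes_confidence_interval(rssn, regn, n_boot = 80, seed = 64)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(widths[3] < widths[1])
})

test_that("degenerate bootstrap collapses to a point with a warning", {
  # two targets tied in |z| with identical parameters: every resample
  # produces the same effect size
  sig <- tibble::tibble(gene = paste0("g", 1:5), z = c(2, 2, -1, 0.5, 3))
  rss <- rank_sign_transform(sig)
  reg <- tibble::tibble(regulator = "r", target = c("g1", "g2"), aw = 1, am = 0.5)
  expect_warning(ci <- pes_confidence_interval(rss, reg, n_boot = 50, seed = 1),
                 "zero-width")
  expect_equal(ci$lower, ci$upper, tolerance = 1e-9)
})

test_that("Lindeberg share identifies dominated regulons", {
  rss <- rank_sign_transform(synth_signature(200, seed = 71))
  even <- tibble::tibble(regulator = "e", target = rss$gene[1:20],
                         aw = 0.5, am = c(rep(0.8, 10), rep(-0.8, 10)))
  expect_equal(lindeberg_diagnostic(rss, even)$share, 1 / 20)

  dom <- even
  dom$aw[1] <- 50
  expect_gt(lindeberg_diagnostic(rss, dom)$share, 0.9)

  cop <- tibble::tibble(regulator = "c", target = rss$gene[1:50],
                        aw = copula_weights(1:50), am = 0.5)
  expect_lt(lindeberg_diagnostic(rss, cop)$share, 0.1)
})

test_that("narnea orchestration returns a stable, complete result table", {
  set.seed(81)
  sig <- synth_signature(1000)
  regs <- random_regulons(8, c(40, 80), sig$gene)
  res <- suppressWarnings(narnea(sig, regs))
  expect_s3_class(res, "narnea_result")
  expect_named(res, c("regulator", "size", "des", "ues", "ndes", "nues",
                      "phi", "nes", "pes", "p", "p_bh", "p_bonf"))
  expect_identical(nrow(res), 8L)
  expect_type(res$size, "integer")
  expect_true(all(res$p > 0 & res$p < 1))
  expect_true(all(abs(res$pes) <= 1))
  expect_true(all(res$p_bh >= res$p - 1e-15))
  expect_true(all(res$p_bonf >= res$p_bh - 1e-15))
  # sign of nes agrees with the winning tail through pes
  expect_true(all(sign(res$nes) == sign(res$pes) | res$pes == 0))
  # deterministic re-run
  res2 <- suppressWarnings(narnea(sig, regs))
  expect_equal(tibble::as_tibble(res), tibble::as_tibble(res2))

  expect_error(narnea(sig, regs[0, ]), "empty")
  expect_message(suppressWarnings(narnea(sig, regs, min_size = 60)), "skipped")
})

test_that("leading-edge attachment covers every scored regulon", {
  set.seed(91)
  sig <- synth_signature(500)
  regs <- random_regulons(3, c(30, 40), sig$gene)
  res <- suppressWarnings(narnea(sig, regs, leading_edge = TRUE))
  le <- attr(res, "leading_edge")
  expect_identical(sort(names(le)), sort(res$regulator))
  expect_true(all(vapply(le, nrow, integer(1)) >= 30))
})
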