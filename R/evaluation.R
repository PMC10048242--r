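#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up control of the FDR or Bonferroni control of
#' the FWER (thin wrapper over [stats::p.adjust()] with this package's
#' method names).
#'
#' @param p Numeric vector of p-values.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values, monotone and bounded by 1.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Clopper-Pearson binomial confidence interval
#'
#' Exact central interval for a binomial proportion, computed from beta
#' quantiles.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `estimate`, `lower`, `upper` (proportions).
#' @export
binomial_ci <- function(k, n, conf = 0.95) {
  stopifnot(k >= 0, n >= 1, k <= n)
  a <- (1 - conf) / 2
  tibble::tibble(
    estimate = k / n,
    lower = if (k == 0) 0 else qbeta(a, k, n - k + 1),
    upper = if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  )
}

#' Classify results into ordered UP / NS / DOWN calls
#'
#' A result is UP if its adjusted p-value is below `threshold` and its
#' effect is positive, DOWN if below threshold with negative effect, and NS
#' otherwise (boundary values are NS: the inequality is strict).
#'
#' @param results A data frame of test results (e.g. a [narnea()] result).
#' @param p_col Column holding unadjusted p-values.
#' @param effect_col Column holding the signed effect size.
#' @param threshold Significance threshold on the adjusted p-value.
#' @param method Adjustment method passed to [adjust_pvalues()].
#' @return `results` with an added ordered factor column `call`
#'   (DOWN < NS < UP).
#' @export
classify_calls <- function(results, p_col = "p", effect_col = "pes",
                           threshold = 0.05, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  p_adj <- adjust_pvalues(results[[p_col]], method)
  eff <- results[[effect_col]]
  call <- dplyr::case_when(
    p_adj < threshold & eff > 0 ~ "UP",
    p_adj < threshold & eff < 0 ~ "DOWN",
    .default = "NS"
  )
  results$call <- factor(call, levels = c("DOWN", "NS", "UP"), ordered = TRUE)
  results
}

#' Agreement analysis of a 3x3 table of ordered calls
#'
#' Tests the association between two sets of three-level ordered calls
#' (DOWN < NS < UP on both axes, e.g. differential activity vs differential
#' abundance calls for the same proteins). Reports expected counts under
#' independence (`row_total * col_total / N`), adjusted standardized
#' residuals `(O - E) / sqrt(E (1 - row/N) (1 - col/N))` with
#' Bonferroni-corrected two-sided cell significance, the chi-squared test
#' (4 df), and Kendall's tau-b with tie-corrected denominator and a
#' normal-approximation confidence interval.
#'
#' @param observed 3x3 matrix of non-negative integer counts with rows and
#'   columns ordered DOWN, NS, UP (row/column names are kept if present).
#' @param conf Confidence level for the tau-b interval.
#' @return An object of class `narnea_contingency`.
#' @examples
#' tab <- matrix(c(30, 10, 5, 10, 40, 10, 5, 10, 30), 3, byrow = TRUE)
#' contingency_analysis(tab)
#' @export
contingency_analysis <- function(observed, conf = 0.95) {
  observed <- as.matrix(observed)
  stopifnot(nrow(observed) == 3, ncol(observed) == 3,
            all(observed >= 0), all(observed == round(observed)))
  n <- sum(observed)
  rs <- rowSums(observed)
  cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin", call. = FALSE)
  expected <- outer(rs, cs) / n
  z <- (observed - expected) /
    sqrt(expected * outer(1 - rs / n, 1 - cs / n))
  cell_p <- pmin(1, 9 * 2 * pnorm(-abs(z)))
  chisq <- sum((observed - expected)^2 / expected)
  tau <- tau_b_table(observed, conf = conf)
  structure(
    list(
      observed = observed, expected = expected, z = z, cell_fwer = cell_p,
      chisq = chisq, dof = 4L, p = pchisq(chisq, 4, lower.tail = FALSE),
      tau_b = tau$tau_b, tau_ci = c(tau$lower, tau$upper), n = n
    ),
    class = "narnea_contingency"
  )
}

# Kendall's tau-b from an r x c contingency table with ordered categories,
# with the Kendall-Stuart asymptotic standard error for the CI
tau_b_table <- function(tab, conf = 0.95) {
  n <- sum(tab)
  r <- nrow(tab)
  cc <- ncol(tab)
  # concordance/discordance counts per cell
  A <- D <- matrix(0, r, cc)
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      A[i, j] <- sum(tab[seq_len(r) < i, seq_len(cc) < j]) +
        sum(tab[seq_len(r) > i, seq_len(cc) > j])
      D[i, j] <- sum(tab[seq_len(r) < i, seq_len(cc) > j]) +
        sum(tab[seq_len(r) > i, seq_len(cc) < j])
    }
  }
  P <- sum(tab * A) # 2 * concordant pairs
  Q <- sum(tab * D) # 2 * discordant pairs
  wr <- n^2 - sum(rowSums(tab)^2)
  wc <- n^2 - sum(colSums(tab)^2)
  w <- sqrt(wr * wc)
  tau <- (P - Q) / w
  d <- A - D
  v <- outer(rowSums(tab), rep(1, cc)) * wc + outer(rep(1, r), colSums(tab)) * wr
  var_tau <- (sum(tab * (2 * w * d + tau * v)^2) - n^3 * tau^2 * (wr + wc)^2) / w^4
  se <- sqrt(max(var_tau, 0))
  zc <- qnorm(1 - (1 - conf) / 2)
  list(tau_b = tau, se = se, lower = tau - zc * se, upper = tau + zc * se)
}

#' @export
print.narnea_contingency <- function(x, ...) {
  cat("<3x3 agreement analysis> N =", x$n, "\n")
  cat(sprintf("  Kendall's tau-b = %.4f [%.4f, %.4f]\n",
              x$tau_b, x$tau_ci[1], x$tau_ci[2]))
  cat(sprintf("  chi-squared = %.4g, df = %d, p = %.4g\n", x$chisq, x$dof, x$p))
  print(x$observed)
  invisible(x)
}

#' @export
tidy.narnea_contingency <- function(x, ...) {
  dn <- dimnames(x$observed)
  rn <- dn[[1]] %||% paste0("row", 1:3)
  cn <- dn[[2]] %||% paste0("col", 1:3)
  tidyr::expand_grid(row = rn, col = cn) |>
    dplyr::mutate(
      observed = as.vector(t(x$observed)),
      expected = as.vector(t(x$expected)),
      z = as.vector(t(x$z)),
      fwer = as.vector(t(x$cell_fwer))
    )
}

#' @export
glance.narnea_contingency <- function(x, ...) {
  tibble::tibble(
    n = x$n, tau_b = x$tau_b,
    tau_lower = x$tau_ci[1], tau_upper = x$tau_ci[2],
    chisq = x$chisq, dof = x$dof, p = x$p
  )
}

#' Type-I-error calibration of the analytical null model
#'
#' Generates an i.i.d. null signature, draws random regulons, runs the
#' enrichment pipeline and summarizes how the analytical null behaves:
#' raw false-positive rate at 0.05, counts significant after BH and
#' Bonferroni adjustment, one-sample Kolmogorov-Smirnov statistics of the
#' NES against the standard normal and of the p-values against the uniform,
#' and (optionally, with `effect > 0`) power against shifted signatures.
#'
#' @param G Signature length.
#' @param n_sets Number of random regulons.
#' @param size_range Regulon size range.
#' @param seed Optional integer seed.
#' @param effect If non-zero, targets are shifted via [active_signature()]
#'   before scoring (power rather than calibration).
#' @return A list with `summary` (one-row tibble: `fpr_raw`, `pct_raw`,
#'   `n_sig_bh`, `n_sig_bonf`, `ks_stat_nes`, `ks_p_nes`, `ks_stat_p`) and
#'   `results` (the full [narnea()] table).
#' @export
calibration_suite <- function(G, n_sets, size_range = c(50, 300), seed = NULL,
                              effect = 0) {
  if (!is.null(seed)) set.seed(seed)
  sig <- synth_signature(G)
  regs <- random_regulons(n_sets, size_range, sig$gene)
  if (effect != 0) sig <- active_signature(sig, regs, effect)
  res <- narnea(sig, regs, min_size = min(30, size_range[1]))
  ks_nes <- suppressWarnings(ks.test(res$nes, "pnorm"))
  ks_p <- suppressWarnings(ks.test(res$p, "punif"))
  list(
    summary = tibble::tibble(
      n_sets = nrow(res),
      fpr_raw = mean(res$p < 0.05),
      pct_raw = 100 * mean(res$p < 0.05),
      n_sig_bh = sum(res$p_bh < 0.05),
      n_sig_bonf = sum(res$p_bonf < 0.05),
      ks_stat_nes = unname(ks_nes$statistic),
      ks_p_nes = ks_nes$p.value,
      ks_stat_p = unname(ks_p$statistic)
    ),
    results = res
  )
}

#' Diagnostics for phenotype-shuffled null signatures
#'
#' For each null signature from [shuffled_null_signatures()], computes the
#' Spearman correlation with the original signature (with two-sided p-value
#' and Bonferroni significance flag across permutations) and tests the
#' association between that correlation and the net imbalance of the null
#' groups. A positive association reproduces the systematic bias that makes
#' phenotype-permutation null models conservative: imbalanced relabelings
#' leak the true signature into the null.
#'
#' @param null_sigs Output of [shuffled_null_signatures()].
#' @param original_sig The original signature tibble.
#' @return A list with `table` (per-permutation `rho`, `p`, `significant`)
#'   and `association` (Spearman rho and p of `rho` vs `net_imbalance`).
#' @export
shuffled_null_diagnostics <- function(null_sigs, original_sig) {
  original_sig <- as_signature(original_sig)
  per <- purrr::map_dfr(seq_len(nrow(null_sigs)), function(i) {
    s <- null_sigs$signature[[i]]
    stopifnot(identical(s$gene, original_sig$gene))
    ct <- suppressWarnings(
      cor.test(s$z, original_sig$z, method = "spearman")
    )
    tibble::tibble(perm = null_sigs$perm[i],
                   rho = unname(ct$estimate), p = ct$p.value)
  })
  per$significant <- adjust_pvalues(per$p, "bonferroni") < 0.05
  per$net_imbalance <- null_sigs$net_imbalance
  assoc <- if (nrow(per) >= 3 && sd(per$net_imbalance) > 0) {
    ct <- suppressWarnings(
      cor.test(per$rho, per$net_imbalance, method = "spearman")
    )
    list(rho = unname(ct$estimate), p = ct$p.value)
  } else {
    list(rho = NA_real_, p = NA_real_)
  }
  list(table = per, association = assoc)
}

#' Cross-cohort agreement tables for differential activity vs abundance
#'
#' The published 3x3 call tables comparing transcriptional-regulator
#' differential activity inferred from TCGA expression cohorts (rows:
#' UP / NS / DOWN) against differential protein abundance inferred from the
#' phenotype-matched CPTAC proteomic cohorts (columns: DOWN / NS / UP) for
#' lung adenocarcinoma (LUAD), colon adenocarcinoma (COAD) and head and
#' neck squamous cell carcinoma (HNSC). Used as worked inputs for
#' [contingency_analysis()].
#'
#' @return Named list of three 3x3 integer matrices with informative
#'   dimnames; rows and columns are ordered UP, NS, DOWN and DOWN, NS, UP
#'   respectively, as published.
#' @export
cptac_agreement_tables <- function() {
  dn <- list(activity = c("UP", "NS", "DOWN"),
             abundance = c("DOWN", "NS", "UP"))
  list(
    luad = matrix(c(77, 91, 279, 142, 131, 190, 204, 71, 40),
                  3, byrow = TRUE, dimnames = dn),
    coad = matrix(c(104, 45, 167, 153, 66, 101, 111, 25, 18),
                  3, byrow = TRUE, dimnames = dn),
    hnsc = matrix(c(43, 97, 270, 95, 168, 187, 117, 71, 50),
                  3, byrow = TRUE, dimnames = dn)
  )
}
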