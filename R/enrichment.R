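#' Raw directed and undirected enrichment scores
#'
#' The Directed Enrichment Score (DES) is the AW*AM-weighted sum of the
#' signed rank values `r*s` of a regulon's targets; the Undirected
#' Enrichment Score (UES) is the `AW*(1-|AM|)`-weighted sum of the unsigned
#' ranks `r`. Monotonically regulated targets (|AM| near 1) drive the DES,
#' non-monotonically regulated targets (AM near 0) drive the UES.
#'
#' @param rss A rank/sign signature ([rank_sign_transform()]).
#' @param regulon A data frame with columns `target`, `aw`, `am` (one
#'   regulator's rows of a regulon set).
#' @return A list with elements `des` and `ues`.
#' @export
raw_scores <- function(rss, regulon) {
  idx <- match(regulon$target, rss$gene)
  if (anyNA(idx)) {
    stop("target(s) missing from the signature: ",
         paste(head(regulon$target[is.na(idx)], 3), collapse = ", "), call. = FALSE)
  }
  r <- rss$r[idx]
  s <- rss$s[idx]
  list(
    des = sum(regulon$aw * regulon$am * r * s),
    ues = sum(regulon$aw * (1 - abs(regulon$am)) * r)
  )
}

# analytical moments of (DES, UES) under the Maximum-Entropy null: targets
# i.i.d. uniform over the G observed (r, s) signature entries
null_params <- function(m, aw, am) {
  d <- aw * am
  u <- aw * (1 - abs(am))
  list(
    e_des = sum(d) * m$m_rs,
    v_des = sum(d^2) * (m$m_r2 - m$m_rs^2),
    e_ues = sum(u) * m$m_r,
    v_ues = sum(u^2) * (m$m_r2 - m$m_r^2),
    cov = sum(aw^2 * am * (1 - abs(am))) * (m$m_r2s - m$m_rs * m$m_r)
  )
}

#' Standardize enrichment scores under the Maximum-Entropy null
#'
#' Centers and scales DES and UES by their analytical null mean and
#' variance, and returns the null correlation `phi` between the two
#' standardized scores. If one branch has zero null variance (all `AM = 0`,
#' or all `|AM| = 1`) that branch is degenerate: it carries no information
#' and the final enrichment score falls back to the surviving branch.
#'
#' @inheritParams raw_scores
#' @param des,ues Raw scores from [raw_scores()]; computed if missing.
#' @return List with `ndes`, `nues`, `phi` and `degenerate`
#'   (`"none"`, `"directed"` or `"undirected"` naming the dropped branch).
#' @export
normalize_scores <- function(rss, regulon, des = NULL, ues = NULL) {
  if (is.null(des) || is.null(ues)) {
    raw <- raw_scores(rss, regulon)
    des <- raw$des
    ues <- raw$ues
  }
  np <- null_params(rss$moments, regulon$aw, regulon$am)
  dir_ok <- np$v_des > 0
  und_ok <- np$v_ues > 0
  if (!dir_ok && !und_ok) {
    stop("regulon has zero null variance on both branches", call. = FALSE)
  }
  list(
    ndes = if (dir_ok) (des - np$e_des) / sqrt(np$v_des) else NA_real_,
    nues = if (und_ok) (ues - np$e_ues) / sqrt(np$v_ues) else NA_real_,
    phi = if (dir_ok && und_ok) np$cov / sqrt(np$v_des * np$v_ues) else NA_real_,
    degenerate = if (dir_ok && und_ok) "none" else if (dir_ok) "undirected" else "directed"
  )
}

#' Combine the standardized scores into positive/negative enrichment scores
#'
#' `nes_pos = (ndes + nues) / sqrt(2 + 2*phi)` is strongly positive when the
#' regulator is more active in the test phenotype;
#' `nes_neg = (ndes - nues) / sqrt(2 - 2*phi)` is strongly negative when it
#' is less active. Under the null both are standard normal and independent.
#'
#' @param ndes,nues Standardized scores.
#' @param phi Null correlation between them, `|phi| < 1`.
#' @return List with `nes_pos` and `nes_neg`.
#' @export
combine_scores <- function(ndes, nues, phi) {
  if (!is.finite(phi) || abs(phi) >= 1) {
    stop("|phi| >= 1: degenerate regulon", call. = FALSE)
  }
  list(
    nes_pos = (ndes + nues) / sqrt(2 + 2 * phi),
    nes_neg = (ndes - nues) / sqrt(2 - 2 * phi)
  )
}

#' Final p-value and Normalized Enrichment Score
#'
#' One-tailed p-values are read off the standard normal tails,
#' `p_pos = 1 - Phi(nes_pos)` and `p_neg = Phi(nes_neg)`; picking the
#' smaller of two independent uniform p-values is corrected exactly by
#' `p = 1 - (1 - min(p_pos, p_neg))^2`, and the final NES maps `p` back
#' through the standard normal quantile with the sign of the winning tail.
#' All tail arithmetic is done in log space so extreme scores keep
#' representable, strictly positive p-values.
#'
#' @param nes_pos,nes_neg Combined scores from [combine_scores()] (vectors
#'   allowed).
#' @param ndes Optional standardized directed score used only to break exact
#'   `p_pos == p_neg` ties (the directed branch carries the directional
#'   evidence); a tie with no `ndes` resolves to the positive side.
#' @return A tibble with columns `p_pos`, `p_neg`, `p`, `nes`.
#' @export
enrichment_significance <- function(nes_pos, nes_neg, ndes = NULL) {
  lp_pos <- pnorm(nes_pos, lower.tail = FALSE, log.p = TRUE)
  lp_neg <- pnorm(nes_neg, log.p = TRUE)
  lmin <- pmin(lp_pos, lp_neg)
  # p = m * (2 - m) with m = min(p_pos, p_neg), in log space
  log_p <- lmin + log(2 - exp(lmin))
  pos_side <- lp_pos < lp_neg
  tie <- lp_pos == lp_neg
  if (any(tie)) {
    tb <- if (is.null(ndes)) rep(0, length(lp_pos)) else rep_len(ndes, length(lp_pos))
    pos_side[tie] <- tb[tie] >= 0
  }
  nes <- ifelse(pos_side,
                qnorm(log_p - log(2), lower.tail = FALSE, log.p = TRUE),
                qnorm(log_p - log(2), log.p = TRUE))
  p <- pmin(pmax(exp(log_p), .Machine$double.xmin), 1 - .Machine$double.eps)
  tibble::tibble(
    p_pos = pmin(pmax(exp(lp_pos), .Machine$double.xmin), 1 - .Machine$double.eps),
    p_neg = pmin(pmax(exp(lp_neg), .Machine$double.xmin), 1 - .Machine$double.eps),
    p = p, nes = nes
  )
}

# full scalar pipeline raw scores -> final NES given precomputed null params,
# handling single-branch degeneracy (two-sided p from the surviving branch)
score_from_raw <- function(des, ues, np) {
  dir_ok <- np$v_des > 0
  und_ok <- np$v_ues > 0
  if (!dir_ok && !und_ok) {
    stop("regulon has zero null variance on both branches", call. = FALSE)
  }
  ndes <- if (dir_ok) (des - np$e_des) / sqrt(np$v_des) else NA_real_
  nues <- if (und_ok) (ues - np$e_ues) / sqrt(np$v_ues) else NA_real_
  if (dir_ok && und_ok) {
    phi <- np$cov / sqrt(np$v_des * np$v_ues)
    cs <- combine_scores(ndes, nues, phi)
    sig <- enrichment_significance(cs$nes_pos, cs$nes_neg, ndes = ndes)
    list(ndes = ndes, nues = nues, phi = phi,
         nes_pos = cs$nes_pos, nes_neg = cs$nes_neg,
         p_pos = sig$p_pos, p_neg = sig$p_neg, p = sig$p, nes = sig$nes,
         degenerate = "none")
  } else {
    surv <- if (dir_ok) ndes else nues
    lp_hi <- pnorm(surv, lower.tail = FALSE, log.p = TRUE)
    lp_lo <- pnorm(surv, log.p = TRUE)
    log_p <- log(2) + pmin(lp_hi, lp_lo)
    p <- pmin(pmax(exp(log_p), .Machine$double.xmin), 1 - .Machine$double.eps)
    list(ndes = ndes, nues = nues, phi = NA_real_,
         nes_pos = surv, nes_neg = surv,
         p_pos = exp(lp_hi), p_neg = exp(lp_lo), p = p, nes = surv,
         degenerate = if (dir_ok) "undirected" else "directed")
  }
}

#' Lindeberg balance diagnostic
#'
#' The normal approximation for the enrichment scores requires that no
#' single target dominates the null variance of either score. This returns,
#' for each branch, the largest per-target fraction of the total null
#' variance; copula-uniform weights keep it near `1/N`.
#'
#' @inheritParams raw_scores
#' @return List with `directed`, `undirected` (per-branch maximum shares,
#'   `NA` for a zero-variance branch) and `share`, their maximum.
#' @export
lindeberg_diagnostic <- function(rss, regulon) {
  m <- rss$moments
  d2 <- (regulon$aw * regulon$am)^2 * (m$m_r2 - m$m_rs^2)
  u2 <- (regulon$aw * (1 - abs(regulon$am)))^2 * (m$m_r2 - m$m_r^2)
  dir_share <- if (sum(d2) > 0) max(d2) / sum(d2) else NA_real_
  und_share <- if (sum(u2) > 0) max(u2) / sum(u2) else NA_real_
  list(directed = dir_share, undirected = und_share,
       share = max(c(dir_share, und_share), na.rm = TRUE))
}

#' Leading-edge analysis of a significant enrichment
#'
#' Scores every regulon target by how much it supports the observed
#' enrichment direction: `les = (1-|am|)*r + am*r*s` when `nes > 0`, with a
#' minus on the signed term when `nes < 0`. Each target's one-tailed p-value
#' is the fraction of signature positions whose score (computed with the
#' same `am`) is at least as large, so `p >= 1/G` always. The Association
#' Weight is deliberately not used, keeping the a posteriori leading-edge
#' selection unbiased by the a priori target importance.
#'
#' @inheritParams raw_scores
#' @param nes Final Normalized Enrichment Score of the regulon (non-zero).
#' @param adjust Multiple-testing correction across the regulon's targets:
#'   `"bh"` (default) or `"bonferroni"`.
#' @return Tibble with columns `target`, `les`, `p`, `p_adj`, ordered by
#'   decreasing `les`.
#' @export
leading_edge <- function(rss, regulon, nes, adjust = c("bh", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!is.finite(nes) || nes == 0) {
    stop("leading edge is undefined for nes == 0", call. = FALSE)
  }
  idx <- match(regulon$target, rss$gene)
  if (anyNA(idx)) stop("target(s) missing from the signature", call. = FALSE)
  dir_sign <- if (nes > 0) 1 else -1
  g <- rss$G
  rs <- rss$r * rss$s
  n <- nrow(regulon)
  les <- numeric(n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    a <- regulon$am[i]
    pos_scores <- (1 - abs(a)) * rss$r + dir_sign * a * rs
    les[i] <- pos_scores[idx[i]]
    p[i] <- sum(pos_scores >= les[i]) / g
  }
  out <- tibble::tibble(
    target = regulon$target, les = les, p = p,
    p_adj = adjust_pvalues(p, adjust)
  )
  dplyr::arrange(out, dplyr::desc(.data$les))
}

#' Maximum-Entropy gene set enrichment analysis
#'
#' Runs the full analytical enrichment pipeline for every regulon in a
#' regulon set against a differential gene expression signature: rank/sign
#' transformation, directed/undirected scores, analytical null
#' standardization, combination into a final standard-normal Normalized
#' Enrichment Score (NES) with exact two-sided p-value, and the bounded
#' Proportional Enrichment Score (PES) effect size.
#'
#' Targets absent from the signature are dropped; regulons falling below
#' `min_size` surviving targets are skipped with a message (below roughly 30
#' targets the normal null approximation is not guaranteed). Regulons whose
#' null variance is dominated by a single target beyond
#' `lindeberg_threshold` are flagged with a warning.
#'
#' @param sig A signature tibble (`gene`, `z`) or a [rank_sign_transform()]
#'   result.
#' @param regulons A regulon set ([as_regulons()]).
#' @param min_size Minimum regulon size after intersection with the
#'   signature (default 30).
#' @param leading_edge If `TRUE`, leading-edge tables are computed for every
#'   scored regulon and attached as the `"leading_edge"` attribute (a named
#'   list of tibbles).
#' @param lindeberg_threshold Warn when a single target contributes more
#'   than this fraction of a branch's null variance (default 0.10).
#' @return A tibble of class `narnea_result` with one row per regulon and
#'   columns `regulator`, `size`, `des`, `ues`, `ndes`, `nues`, `phi`,
#'   `nes`, `pes`, `p`, `p_bh`, `p_bonf`.
#' @examples
#' sig <- synth_signature(500, seed = 1)
#' regs <- random_regulons(5, c(30, 60), sig$gene, seed = 2)
#' narnea(sig, regs)
#' @export
narnea <- function(sig, regulons, min_size = 30, leading_edge = FALSE,
                   lindeberg_threshold = 0.1) {
  rss <- if (inherits(sig, "narnea_rss")) sig else rank_sign_transform(sig)
  regulons <- as_regulons(regulons)
  if (!nrow(regulons)) stop("empty regulon set", call. = FALSE)

  keep <- regulons$target %in% rss$gene
  if (!any(keep)) stop("no regulon target overlaps the signature", call. = FALSE)
  regulons <- regulons[keep, ]

  idx_all <- match(regulons$target, rss$gene)
  rows_by_reg <- split(seq_len(nrow(regulons)), regulons$regulator)
  sizes <- lengths(rows_by_reg)
  if (any(sizes < min_size)) {
    message(sum(sizes < min_size), " regulon(s) below min_size = ",
            min_size, " skipped")
    rows_by_reg <- rows_by_reg[sizes >= min_size]
  }
  if (!length(rows_by_reg)) stop("no regulon passed the size filter", call. = FALSE)

  groups <- rss_groups(rss)
  m <- rss$moments
  lind <- numeric(length(rows_by_reg))

  stats <- vapply(seq_along(rows_by_reg), function(k) {
    rows <- rows_by_reg[[k]]
    idx <- idx_all[rows]
    aw <- regulons$aw[rows]
    am <- regulons$am[rows]
    np <- null_params(m, aw, am)
    r <- rss$r[idx]
    s <- rss$s[idx]
    des <- sum(aw * am * r * s)
    ues <- sum(aw * (1 - abs(am)) * r)
    sc <- score_from_raw(des, ues, np)
    pes <- pes_value(rss, groups, aw, am, np, sc$nes)
    d2 <- (aw * am)^2
    u2 <- (aw * (1 - abs(am)))^2
    lind[k] <<- max(c(if (sum(d2) > 0) max(d2) / sum(d2),
                      if (sum(u2) > 0) max(u2) / sum(u2)), na.rm = TRUE)
    c(length(idx), des, ues, sc$ndes, sc$nues, sc$phi, sc$nes, pes, sc$p)
  }, numeric(9))

  if (any(lind > lindeberg_threshold)) {
    warning(sum(lind > lindeberg_threshold), " regulon(s) exceed the Lindeberg ",
            "balance threshold (", lindeberg_threshold,
            "); their NES normality is not guaranteed", call. = FALSE)
  }

  out <- tibble::tibble(
    regulator = names(rows_by_reg),
    size = as.integer(stats[1L, ]),
    des = stats[2L, ], ues = stats[3L, ],
    ndes = stats[4L, ], nues = stats[5L, ], phi = stats[6L, ],
    nes = stats[7L, ], pes = stats[8L, ], p = stats[9L, ],
    p_bh = adjust_pvalues(stats[9L, ], "bh"),
    p_bonf = adjust_pvalues(stats[9L, ], "bonferroni")
  )
  class(out) <- c("narnea_result", class(out))
  attr(out, "lindeberg") <- setNames(lind, names(rows_by_reg))
  if (isTRUE(leading_edge)) {
    le <- lapply(seq_along(rows_by_reg), function(k) {
      rows <- rows_by_reg[[k]]
      leading_edge(rss, regulons[rows, ], out$nes[k])
    })
    names(le) <- names(rows_by_reg)
    attr(out, "leading_edge") <- le
  }
  out
}
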