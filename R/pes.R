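# Extremal-placement machinery behind the Proportional Enrichment Score.
#
# The combined enrichment score is linear in the placed (r, r*s) values with
# fixed per-target coefficients, so the most extreme achievable NES is found
# by a rearrangement argument: targets, taken in order of decreasing
# coefficient magnitude, greedily claim the best still-available signature
# position. Because a target's per-position score a1*(r*s) + a2*r is
# monotone in r within each sign class, the best available position is
# always one of the six extremes (largest or smallest remaining rank among
# positions with s = +1, -1, 0), so the search is O(N).

# maximize sum_g a1[g]*(r*s)[pos] + a2[g]*r[pos] over assignments of targets
# to distinct signature positions; returns the chosen position indices
# aligned with the targets. `ord` is the order in which targets claim
# positions; the caller tries several orderings since the single-pass
# greedy is not exact for strongly heterogeneous coefficient profiles.
greedy_extremal_placement <- function(rss, groups, a1, a2,
                                      ord = order(a1^2 + a2^2, decreasing = TRUE)) {
  glist <- list(groups$pos, groups$neg, groups$zero)
  lo <- c(1L, 1L, 1L)
  hi <- vapply(glist, length, integer(1))
  chosen <- integer(length(a1))
  r <- rss$r
  s <- rss$s
  for (t in ord) {
    best <- -Inf
    best_grp <- 0L
    best_end <- 0L
    for (gi in 1:3) {
      if (lo[gi] > hi[gi]) next
      for (end in 1:2) {
        pos <- if (end == 1L) glist[[gi]][lo[gi]] else glist[[gi]][hi[gi]]
        sc <- a1[t] * r[pos] * s[pos] + a2[t] * r[pos]
        if (sc > best) {
          best <- sc
          best_grp <- gi
          best_end <- end
        }
        if (lo[gi] == hi[gi]) break # single remaining element
      }
    }
    if (best_grp == 0L) stop("regulon larger than the signature", call. = FALSE)
    if (best_end == 1L) {
      chosen[t] <- glist[[best_grp]][lo[best_grp]]
      lo[best_grp] <- lo[best_grp] + 1L
    } else {
      chosen[t] <- glist[[best_grp]][hi[best_grp]]
      hi[best_grp] <- hi[best_grp] - 1L
    }
  }
  chosen
}

# NES of the extremal placement in a given direction ("max" maximizes the
# positive combined score, "min" minimizes the negative combined score);
# the null normalization constants depend only on (aw, am) and the
# signature moments, so they are identical for every placement
extremal_nes <- function(rss, groups, aw, am, np, direction) {
  c1 <- if (np$v_des > 0) aw * am / sqrt(np$v_des) else rep(0, length(aw))
  c2 <- if (np$v_ues > 0) aw * (1 - abs(am)) / sqrt(np$v_ues) else rep(0, length(aw))
  a1 <- if (direction == "max") c1 else -c1
  orders <- list(
    order(a1^2 + c2^2, decreasing = TRUE),
    order(abs(a1), decreasing = TRUE),
    order(c2, decreasing = TRUE)
  )
  best_obj <- -Inf
  best <- NULL
  for (ord in orders) {
    chosen <- greedy_extremal_placement(rss, groups, a1, c2, ord)
    obj <- sum(a1 * rss$r[chosen] * rss$s[chosen] + c2 * rss$r[chosen])
    if (obj > best_obj) {
      best_obj <- obj
      best <- chosen
    }
  }
  r <- rss$r[best]
  s <- rss$s[best]
  des <- sum(aw * am * r * s)
  ues <- sum(aw * (1 - abs(am)) * r)
  score_from_raw(des, ues, np)$nes
}

pes_value <- function(rss, groups, aw, am, np, nes) {
  if (!is.finite(nes)) return(NA_real_)
  if (nes == 0) return(0)
  if (length(aw) > rss$G) stop("regulon larger than the signature", call. = FALSE)
  if (nes > 0) {
    ref <- extremal_nes(rss, groups, aw, am, np, "max")
    ref <- max(ref, nes) # observed placement is itself feasible
  } else {
    ref <- extremal_nes(rss, groups, aw, am, np, "min")
    ref <- min(ref, nes)
  }
  nes / abs(ref)
}

#' Proportional Enrichment Score (effect size)
#'
#' Divides the observed Normalized Enrichment Score by the magnitude of the
#' most extreme NES achievable by any placement of the regulon's targets on
#' distinct positions of the observed signature (the maximal achievable NES
#' for positive enrichment, the minimal for negative). Like a rank-biserial
#' correlation, the result is bounded in `[-1, 1]`, shares the sign of the
#' NES, and has null expectation zero.
#'
#' @inheritParams raw_scores
#' @param nes The regulon's final Normalized Enrichment Score; computed from
#'   the observed placement if missing.
#' @return The PES, a single number in `[-1, 1]`.
#' @export
proportional_enrichment <- function(rss, regulon, nes = NULL) {
  np <- null_params(rss$moments, regulon$aw, regulon$am)
  if (is.null(nes)) {
    raw <- raw_scores(rss, regulon)
    nes <- score_from_raw(raw$des, raw$ues, np)$nes
  }
  pes_value(rss, rss_groups(rss), regulon$aw, regulon$am, np, nes)
}

#' Bootstrap confidence interval for the Proportional Enrichment Score
#'
#' Resamples regulon targets with replacement, recomputes the PES for each
#' replicate, and builds a normal-theory confidence interval on the Fisher
#' z-scale (the PES behaves like a correlation coefficient, so the
#' z-transform symmetrizes its sampling distribution) before
#' back-transforming.
#'
#' @inheritParams raw_scores
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed Optional integer seed for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with columns `pes`, `lower`, `upper`.
#' @export
pes_confidence_interval <- function(rss, regulon, n_boot = 200, seed = NULL,
                                    conf = 0.95) {
  if (nrow(regulon) < 2) stop("need at least 2 targets to bootstrap", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  groups <- rss_groups(rss)
  est <- proportional_enrichment(rss, regulon)
  n <- nrow(regulon)
  boots <- vapply(seq_len(n_boot), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    aw <- regulon$aw[rows]
    am <- regulon$am[rows]
    idx <- match(regulon$target[rows], rss$gene)
    np <- null_params(rss$moments, aw, am)
    r <- rss$r[idx]
    s <- rss$s[idx]
    sc <- score_from_raw(sum(aw * am * r * s), sum(aw * (1 - abs(am)) * r), np)
    pes_value(rss, groups, aw, am, np, sc$nes)
  }, numeric(1))
  zclamp <- function(x) atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
  se <- sd(zclamp(boots))
  if (!is.finite(se) || se == 0) {
    warning("all bootstrap replicates identical; zero-width interval", call. = FALSE)
    se <- 0
  }
  zcrit <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(
    pes = est,
    lower = tanh(zclamp(est) - zcrit * se),
    upper = tanh(zclamp(est) + zcrit * se)
  )
}
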