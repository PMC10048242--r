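# rank/(n+1) copula transform of each row of a matrix
copula_rows <- function(mat) {
  n <- ncol(mat)
  t(apply(mat, 1L, rank)) / (n + 1)
}

#' Adaptive-partitioning mutual information estimate
#'
#' Estimates the mutual information (in nats) between two sample vectors.
#' Both vectors are first copula-transformed (`rank/(n+1)`) to uniform
#' marginals; the unit square is then recursively partitioned at cell
#' midpoints into quadrants -- the root cell unconditionally, deeper cells
#' while a chi-squared uniformity statistic over the four quadrant counts
#' rejects uniformity (threshold `chi_crit`, the 0.95 quantile of a
#' chi-squared with 3 df by default) and the cell holds at least `min_pts`
#' points. Each leaf cell contributes its
#' marginal-count-corrected plug-in term, and the total is clamped at zero.
#'
#' @param x,y Numeric vectors of equal length `n >= 8`.
#' @param chi_crit Chi-squared split threshold (default `qchisq(0.95, 3)`).
#' @param min_pts Minimum points in a cell eligible for splitting (default 8).
#' @return Mutual information estimate in nats (`>= 0`).
#' @export
apmi <- function(x, y, chi_crit = qchisq(0.95, 3), min_pts = 8) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 8) stop("need at least 8 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector; mutual information set to 0", call. = FALSE)
    return(0)
  }
  n <- length(x)
  apmi_cpp(rank(x) / (n + 1), rank(y) / (n + 1), chi_crit, min_pts)
}

#' Null model for adaptive-partitioning mutual information
#'
#' Draws `n_pairs` APMI estimates between independently shuffled copula
#' marginals of length `n_samples` and fits a piecewise null model: the
#' empirical survival function for the body up to the 95th percentile, and
#' for the tail a linear fit of log10 tail probability against MI using a
#' Theil-Sen median-of-pairwise-slopes regressor (robust to the sparse,
#' noisy extreme tail). The tail is anchored at the junction so p-values
#' are continuous and nonincreasing in MI.
#'
#' @param n_samples Number of samples per vector (match the data the model
#'   will be applied to).
#' @param n_pairs Number of null pairs (default 1e6; reducible for testing,
#'   minimum 1000 so the tail remains fittable).
#' @param seed Optional integer seed.
#' @inheritParams apmi
#' @return An object of class `mi_null`.
#' @export
fit_mi_null <- function(n_samples, n_pairs = 1e6, seed = NULL,
                        chi_crit = qchisq(0.95, 3), min_pts = 8) {
  if (n_pairs < 1000) stop("n_pairs < 1000: tail unfittable", call. = FALSE)
  if (n_samples < 8) stop("need at least 8 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draws <- sort(apmi_null_cpp(as.integer(n_samples), as.integer(n_pairs),
                              chi_crit, min_pts))
  n <- length(draws)
  q95 <- quantile(draws, 0.95, type = 1, names = FALSE)
  surv_q95 <- mean(draws >= q95)

  tail_mi <- unique(draws[draws > q95])
  if (length(tail_mi) < 5) stop("degenerate null tail", call. = FALSE)
  # empirical survival at each distinct tail value
  tail_surv <- vapply(tail_mi, function(v) mean(draws >= v), numeric(1))
  if (length(tail_mi) > 1200) {
    pick <- unique(round(seq(1, length(tail_mi), length.out = 1200)))
    tail_mi <- tail_mi[pick]
    tail_surv <- tail_surv[pick]
  }
  slope <- theil_sen_slope(tail_mi, log10(tail_surv))
  if (!is.finite(slope) || slope >= 0) {
    stop("null tail slope is not negative; increase n_pairs", call. = FALSE)
  }
  structure(
    list(
      body = draws, n_null = n, n_samples = n_samples,
      q95 = q95, surv_q95 = surv_q95, slope = slope,
      chi_crit = chi_crit, min_pts = min_pts
    ),
    class = "mi_null"
  )
}

# median of pairwise slopes (Theil-Sen); x assumed distinct
theil_sen_slope <- function(x, y) {
  n <- length(x)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  median(dy[keep] / dx[keep])
}

#' @export
print.mi_null <- function(x, ...) {
  cat("<APMI null model> n_samples =", x$n_samples, ", n_null =", x$n_null, "\n")
  cat(sprintf("  body up to q95 = %.4g (survival %.4g), tail slope = %.4g /nat (log10)\n",
              x$q95, x$surv_q95, x$slope))
  invisible(x)
}

#' @export
glance.mi_null <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_null = x$n_null,
                 q95 = x$q95, tail_slope = x$slope)
}

#' Null p-values for mutual information estimates
#'
#' @param null An `mi_null` model from [fit_mi_null()].
#' @param mi Numeric vector of MI estimates (nats).
#' @return p-values in `(0, 1]`, continuous and nonincreasing in `mi`.
#' @export
p_mi <- function(null, mi) {
  stopifnot(inherits(null, "mi_null"))
  # empirical survival (fraction of null draws >= mi) over the sorted body
  p <- (null$n_null - findInterval(mi, null$body, left.open = TRUE)) / null$n_null
  in_tail <- mi > null$q95
  if (any(in_tail)) {
    p[in_tail] <- null$surv_q95 *
      10^(null$slope * (mi[in_tail] - null$q95))
  }
  pmin(pmax(p, 1e-300), 1)
}

#' Infer a single subnetwork from subsampled expression profiles
#'
#' Subsamples `round(n * (1 - 1/e))` (about 63.21%) of the expression
#' profiles without replacement -- matching the probability that a given
#' sample appears in a bootstrap, which decorrelates repeated runs without
#' the bias a bootstrap's replicated points add to the MI estimator --
#' estimates APMI for every regulator-target pair, converts to null-model
#' p-values and keeps the edges passing Benjamini-Hochberg control of the
#' FDR.
#'
#' @param expr Genes-by-samples expression matrix (or data frame, first
#'   column gene ids).
#' @param regulators Character vector of regulator gene ids (must be rows of
#'   `expr`).
#' @param null_model An [fit_mi_null()] model fitted at the subsample size.
#' @param fdr Target false discovery rate for edge retention (default 0.05).
#' @param seed Optional integer seed for the subsampling.
#' @param subsample If `FALSE`, use all profiles (used for the final
#'   consensus re-estimation).
#' @return Tibble with columns `regulator`, `target`, `mi`, `p`, `p_adj`.
#' @export
infer_subnetwork <- function(expr, regulators, null_model, fdr = 0.05,
                             seed = NULL, subsample = TRUE) {
  expr <- as_expression_matrix(expr)
  if (!all(regulators %in% rownames(expr))) {
    stop("regulators must be rows of the expression matrix", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(expr)
  if (subsample) {
    m <- round(n * (1 - exp(-1)))
    if (m < 8) stop("fewer than 8 subsampled profiles", call. = FALSE)
    expr <- expr[, sample.int(n, m), drop = FALSE]
  }
  if (null_model$n_samples != ncol(expr)) {
    warning("null model fitted at n = ", null_model$n_samples,
            " but data have n = ", ncol(expr), call. = FALSE)
  }
  cop <- copula_rows(expr)
  ridx <- match(regulators, rownames(expr))
  mi <- apmi_cross_cpp(cop[ridx, , drop = FALSE], cop,
                       null_model$chi_crit, null_model$min_pts)
  edges <- tidyr::expand_grid(
    regulator = regulators, target = rownames(expr)
  )
  edges$mi <- as.vector(t(mi))
  edges <- edges[edges$regulator != edges$target, ]
  edges$p <- p_mi(null_model, edges$mi)
  edges$p_adj <- adjust_pvalues(edges$p, "bh")
  tibble::as_tibble(edges[edges$p_adj < fdr, ])
}

#' Data-processing-inequality pruning
#'
#' For every three-gene clique in the (undirected view of the) edge set,
#' the minimum-MI edge is marked -- by the data-processing inequality an
#' indirect interaction X-Z mediated by Y cannot carry more information
#' than either direct edge -- and all marked edges are removed in one pass.
#' Ties at a clique minimum remove all tied edges, keeping the result
#' deterministic. The operation never adds edges and is idempotent on its
#' own output.
#'
#' @param edges Tibble with columns `regulator`, `target`, `mi` (directed
#'   regulator-to-target edges; cliques are evaluated on the undirected
#'   skeleton).
#' @return The pruned edge tibble.
#' @export
dpi_prune <- function(edges) {
  if (!nrow(edges)) return(edges)
  und_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  key <- und_key(edges$regulator, edges$target)
  # undirected skeleton with one MI per unordered pair
  und <- edges[!duplicated(key), c("regulator", "target", "mi")]
  gr <- igraph::graph_from_data_frame(und, directed = FALSE)
  tri <- igraph::triangles(gr)
  if (!length(tri)) return(edges)
  tri <- matrix(as.integer(tri), nrow = 3)
  nm <- igraph::V(gr)$name
  drop_keys <- character(0)
  for (k in seq_len(ncol(tri))) {
    a <- nm[tri[1, k]]; b <- nm[tri[2, k]]; c <- nm[tri[3, k]]
    ks <- c(und_key(a, b), und_key(b, c), und_key(a, c))
    mis <- und$mi[match(ks, und_key(und$regulator, und$target))]
    drop_keys <- c(drop_keys, ks[mis == min(mis)])
  }
  edges[!(key %in% drop_keys), ]
}

#' Consensus transcriptional regulatory network
#'
#' Repeatedly infers FDR- and DPI-pruned subnetworks from subsampled
#' profiles ([infer_subnetwork()], [dpi_prune()]) until either `max_nets`
#' subnetworks have been built or every regulator has accumulated at least
#' `min_targets` unique targets. Union edges carry their occurrence count;
#' their MI and Spearman correlation are re-estimated a final time on all
#' profiles. By default the union is then pruned by testing each occurrence
#' count against a Binomial(`n_subnetworks`, `fdr`) null of chance
#' rediscovery (BH across edges at the same `fdr`), since a plain union
#' over many FDR-controlled subnetworks would otherwise accumulate false
#' edges roughly in proportion to the number of subnetworks.
#'
#' @inheritParams infer_subnetwork
#' @param max_nets Maximum number of subnetworks (default 30).
#' @param min_targets Stop once every regulator has at least this many
#'   unique targets (default 50).
#' @param n_null Null pairs for the MI null model (default 1e6; use fewer
#'   for small analyses).
#' @param keep_all If `TRUE`, skip the consensus-level occurrence-count
#'   pruning and return the full union.
#' @return A tibble of class `narnea_network` with columns `regulator`,
#'   `target`, `count`, `mi`, `spearman`; the number of subnetworks built is
#'   attached as attribute `n_subnetworks`.
#' @export
consensus_network <- function(expr, regulators, fdr = 0.05, max_nets = 30,
                              min_targets = 50, seed = NULL, n_null = 1e6,
                              keep_all = FALSE,
                              chi_crit = qchisq(0.95, 3), min_pts = 8) {
  expr <- as_expression_matrix(expr)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(expr)
  m_sub <- round(n * (1 - exp(-1)))
  null_model <- fit_mi_null(m_sub, n_pairs = n_null,
                            chi_crit = chi_crit, min_pts = min_pts)
  counts <- new.env(parent = emptyenv())
  n_nets <- 0L
  repeat {
    n_nets <- n_nets + 1L
    sub <- infer_subnetwork(expr, regulators, null_model, fdr = fdr)
    sub <- dpi_prune(sub)
    if (nrow(sub)) {
      keys <- paste(sub$regulator, sub$target, sep = "\r")
      for (k in keys) assign(k, (get0(k, counts, ifnotfound = 0L)) + 1L, counts)
    }
    tgt_per_reg <- table(sub("\r.*", "", ls(counts)))
    done <- length(tgt_per_reg) == length(regulators) &&
      all(tgt_per_reg >= min_targets)
    if (done || n_nets >= max_nets) break
  }
  if (!done && n_nets >= max_nets) {
    warning("stopping criteria not reached within max_nets = ", max_nets,
            call. = FALSE)
  }
  keys <- ls(counts)
  if (!length(keys)) stop("no edge survived pruning", call. = FALSE)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble::tibble(
    regulator = vapply(parts, `[[`, "", 1L),
    target = vapply(parts, `[[`, "", 2L),
    count = vapply(keys, function(k) get(k, counts), integer(1), USE.NAMES = FALSE)
  )
  # final MI and Spearman on all profiles
  cop <- copula_rows(expr)
  out$mi <- vapply(seq_len(nrow(out)), function(i) {
    apmi_cpp(cop[out$regulator[i], ], cop[out$target[i], ], chi_crit, min_pts)
  }, numeric(1))
  out$spearman <- vapply(seq_len(nrow(out)), function(i) {
    cor(expr[out$regulator[i], ], expr[out$target[i], ], method = "spearman")
  }, numeric(1))
  if (!keep_all && n_nets > 1L) { # a single subnetwork is already FDR-controlled
    p_count <- pbinom(out$count - 1L, n_nets, fdr, lower.tail = FALSE)
    out <- out[adjust_pvalues(p_count, "bh") < fdr, ]
    if (!nrow(out)) stop("no edge survived consensus pruning", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$regulator, dplyr::desc(.data$count),
                        dplyr::desc(.data$mi))
  class(out) <- c("narnea_network", class(out))
  attr(out, "n_subnetworks") <- n_nets
  out
}

#' Convert a consensus network into weighted regulons
#'
#' Per regulator, targets are ordered by occurrence count with ties broken
#' by the final MI; the Association Weights are the copula transform of
#' that ordering (best target gets the largest weight) and the Association
#' Mode is the Spearman correlation between regulator and target expression.
#'
#' @param net A `narnea_network` from [consensus_network()].
#' @return A `narnea_regulons` tibble.
#' @export
network_to_regulons <- function(net) {
  stopifnot(all(c("regulator", "target", "count", "mi", "spearman") %in% names(net)))
  out <- net |>
    dplyr::group_by(.data$regulator) |>
    dplyr::mutate(aw = rank(.data$count * 1e6 + .data$mi,
                            ties.method = "average") / (dplyr::n() + 1)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$regulator, .data$target, aw = .data$aw,
                     am = .data$spearman)
  # Spearman estimates can brush the [-1, 1] boundary on small n
  out$am <- pmin(pmax(out$am, -1), 1)
  as_regulons(out)
}
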