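# Generators producing every input the tests and calibration analyses need,
# with the statistical structure the enrichment method assumes.

#' Synthetic null differential expression signature
#'
#' `G` i.i.d. draws (standard normal by default), emulating a signature in
#' which no gene set is enriched.
#'
#' @param G Number of genes.
#' @param seed Optional integer seed.
#' @param rdist Random generator taking a single count argument.
#' @return A signature tibble (`gene`, `z`).
#' @export
synth_signature <- function(G, seed = NULL, rdist = rnorm) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(gene = paste0("g", seq_len(G)), z = rdist(G))
}

#' Random (null-model) regulons
#'
#' Draws `n_sets` gene sets of uniformly random sizes with uniformly random
#' members, copula-uniform Association Weights (a random ordering passed
#' through `rank/(N+1)`) and Association Modes uniform on `[-1, 1]`. With a
#' `template` regulon set, operates in swap mode instead: each template
#' regulon's members are replaced by an equal number of genes drawn at
#' random from the complement of that regulon, keeping its `aw`/`am`
#' values. Such sets are biologically meaningless by construction and are
#' not enriched in any signature.
#'
#' @param n_sets Number of gene sets (ignored in swap mode).
#' @param size_range Length-2 integer range of set sizes (ignored in swap
#'   mode).
#' @param universe Character vector of candidate gene ids.
#' @param seed Optional integer seed.
#' @param template Optional regulon set to swap.
#' @return A `narnea_regulons` tibble.
#' @export
random_regulons <- function(n_sets, size_range, universe, seed = NULL,
                            template = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(template)) {
    template <- as_regulons(template)
    swapped <- template |>
      dplyr::group_by(.data$regulator) |>
      dplyr::mutate(target = sample(setdiff(universe, .data$target),
                                    dplyr::n())) |>
      dplyr::ungroup()
    return(as_regulons(swapped))
  }
  sizes <- sample(seq.int(size_range[1], size_range[2]), n_sets, replace = TRUE)
  sets <- lapply(seq_len(n_sets), function(i) {
    n <- sizes[i]
    tibble::tibble(
      regulator = sprintf("set%04d", i),
      target = sample(universe, n),
      aw = sample.int(n) / (n + 1),
      am = runif(n, -1, 1)
    )
  })
  as_regulons(dplyr::bind_rows(sets))
}

#' Totally-null regulons from central, non-differential genes
#'
#' Builds gene sets exclusively from genes showing no evidence of
#' differential expression, so the sets sit in the middle of the signature
#' rather than being uniformly spread. A calibrated enrichment method must
#' not flag them. The eligible pool is either the genes whose two-sided
#' Mann-Whitney p-value exceeds `p_threshold` (when `test`/`ref` expression
#' matrices are given) or, in signature-only mode, the genes with `|z|`
#' below the signature median.
#'
#' @param sig A signature tibble; if it carries a `p` column (as
#'   [mwu_signature()] output does) that is used for the pool directly.
#' @param test,ref Optional expression matrices from which the MWU
#'   signature and pool are computed.
#' @param n_sets Number of gene sets.
#' @param size_range Length-2 integer range of set sizes.
#' @param seed Optional integer seed.
#' @param p_threshold Pool threshold on the two-sided MWU p-value
#'   (default 0.50).
#' @return A `narnea_regulons` tibble whose members all come from the pool.
#' @export
tn_regulons <- function(sig = NULL, test = NULL, ref = NULL, n_sets,
                        size_range, seed = NULL, p_threshold = 0.5) {
  if (is.null(sig)) {
    if (is.null(test) || is.null(ref)) {
      stop("supply a signature or test/ref expression matrices", call. = FALSE)
    }
    sig <- mwu_signature(test, ref)
  }
  sig <- as_signature(sig)
  if ("p" %in% names(sig)) {
    pool <- sig$gene[sig$p > p_threshold]
  } else {
    pool <- sig$gene[abs(sig$z) < median(abs(sig$z))]
  }
  if (length(pool) < max(size_range)) {
    stop("central-gene pool smaller than the largest requested set", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample(seq.int(size_range[1], size_range[2]), n_sets, replace = TRUE)
  sets <- lapply(seq_len(n_sets), function(i) {
    n <- sizes[i]
    tibble::tibble(
      regulator = sprintf("tn%04d", i),
      target = sample(pool, n),
      aw = sample.int(n) / (n + 1),
      am = runif(n, -1, 1)
    )
  })
  as_regulons(dplyr::bind_rows(sets))
}

#' Inject regulator activity into a signature
#'
#' Returns a signature in which every regulon target's `z` is shifted by
#' `effect * aw * sign(am)`, the displacement a positively differentially
#' active regulator induces: positively regulated targets move toward the
#' positive extreme and negatively regulated targets toward the negative
#' extreme, in proportion to the dependence strength. `effect = 0` returns
#' the base signature unchanged; a negative `effect` emulates the negative
#' alternative.
#'
#' @param sig Base signature tibble.
#' @param regulons Regulon set whose targets receive the shift (summed over
#'   regulons if a gene is targeted repeatedly).
#' @param effect Shift magnitude in `z` units.
#' @return A signature tibble.
#' @export
active_signature <- function(sig, regulons, effect) {
  sig <- as_signature(sig)
  regulons <- as_regulons(regulons)
  shift <- regulons |>
    dplyr::mutate(delta = effect * .data$aw * sign(.data$am)) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(delta = sum(.data$delta))
  i <- match(shift$target, sig$gene)
  ok <- !is.na(i)
  sig$z[i[ok]] <- sig$z[i[ok]] + shift$delta[ok]
  sig
}

#' Ground-truth regulatory network specification
#'
#' Defines regulators, their true targets with dependence strengths in
#' `(0, 1]` and regulation directions in `{-1, +1}`, plus pure-noise decoy
#' genes, for the expression generator.
#'
#' @param n_regulators,n_targets,n_decoys Counts of regulators, true
#'   targets per regulator, and decoy genes.
#' @param strength_range Range of per-target dependence strengths (default
#'   `c(0.5, 1)`, strong enough for the dependence to be recoverable from a
#'   few hundred profiles).
#' @param seed Optional integer seed.
#' @return A tibble of class `narnea_truth` with columns `regulator`,
#'   `target`, `strength`, `direction`; decoy gene ids are attached as the
#'   `"decoys"` attribute.
#' @export
ground_truth_network <- function(n_regulators, n_targets, n_decoys,
                                 strength_range = c(0.5, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regs <- sprintf("R%02d", seq_len(n_regulators))
  truth <- tidyr::expand_grid(regulator = regs, k = seq_len(n_targets)) |>
    dplyr::mutate(
      target = sprintf("T_%s_%02d", .data$regulator, .data$k),
      strength = runif(dplyr::n(), strength_range[1], strength_range[2]),
      direction = sample(c(-1, 1), dplyr::n(), replace = TRUE)
    ) |>
    dplyr::select(-"k")
  class(truth) <- c("narnea_truth", class(truth))
  attr(truth, "decoys") <- sprintf("D%04d", seq_len(n_decoys))
  truth
}

#' Simulate expression profiles with known regulator-target dependencies
#'
#' Each regulator has a latent standard-normal activity per sample; its
#' measured expression tracks that activity closely, and each true target
#' is `direction * strength * activity + noise * eps`. Decoy genes are pure
#' noise. All values pass through a monotone `exp()` map to non-negative
#' abundances, which leaves rank-based dependence measures untouched.
#'
#' @param truth A [ground_truth_network()].
#' @param n_samples Number of profiles.
#' @param noise Additive noise standard deviation relative to the
#'   unit-variance activity (default 0.5).
#' @param seed Optional integer seed.
#' @return Genes-by-samples abundance matrix; the latent activity matrix is
#'   attached as attribute `"activity"` and the truth table as `"truth"`.
#' @export
synth_expression <- function(truth, n_samples, noise = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regs <- unique(truth$regulator)
  decoys <- attr(truth, "decoys")
  activity <- matrix(rnorm(length(regs) * n_samples), length(regs),
                     dimnames = list(regs, NULL))
  reg_expr <- activity + 0.1 * rnorm(length(activity))
  tgt_expr <- matrix(0, nrow(truth), n_samples,
                     dimnames = list(truth$target, NULL))
  for (i in seq_len(nrow(truth))) {
    tgt_expr[i, ] <- truth$direction[i] * truth$strength[i] *
      activity[truth$regulator[i], ] + noise * rnorm(n_samples)
  }
  dec_expr <- matrix(rnorm(length(decoys) * n_samples), length(decoys),
                     dimnames = list(decoys, NULL))
  out <- exp(rbind(reg_expr, tgt_expr, dec_expr))
  colnames(out) <- sprintf("s%03d", seq_len(n_samples))
  attr(out, "activity") <- activity
  attr(out, "truth") <- truth
  out
}

#' Phenotype-shuffled null signatures
#'
#' Pools the test and reference samples, randomly relabels them into null
#' phenotypes of the original group sizes, and computes an MWU signature
#' for each permutation -- the empirical phenotype-permutation procedure
#' whose null signatures this package's diagnostics interrogate. The
#' per-permutation composition of the null groups (how many original test
#' samples landed in each) is recorded, since group imbalance drives the
#' correlation between null and original signatures.
#'
#' @param test,ref Expression matrices for the two phenotypes.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return A tibble with one row per permutation: `perm`,
#'   `test_in_null_test`, `test_in_null_ref` (counts of original-test
#'   samples), `net_imbalance` (difference of original-test fractions
#'   between the null groups) and a `signature` list-column of signature
#'   tibbles.
#' @export
shuffled_null_signatures <- function(test, ref, n_perm, seed = NULL) {
  test <- as_expression_matrix(test)
  ref <- as_expression_matrix(ref)
  if (!identical(rownames(test), rownames(ref))) {
    stop("test and ref must contain the same genes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- ncol(test)
  n2 <- ncol(ref)
  pool <- cbind(test, ref)
  is_test <- c(rep(TRUE, n1), rep(FALSE, n2))
  purrr::map_dfr(seq_len(n_perm), function(b) {
    pick <- sample.int(n1 + n2, n1)
    null_test <- pool[, pick, drop = FALSE]
    null_ref <- pool[, -pick, drop = FALSE]
    k_test <- sum(is_test[pick])
    k_ref <- n1 - k_test
    suppressWarnings(
      s <- mwu_signature(null_test, null_ref)
    )
    tibble::tibble(
      perm = b,
      test_in_null_test = k_test,
      test_in_null_ref = k_ref,
      net_imbalance = k_test / n1 - k_ref / n2,
      signature = list(s)
    )
  })
}
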