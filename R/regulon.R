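#' Validate a set of weighted regulon gene sets
#'
#' A regulon set is a long tibble with one row per (regulator, target) edge
#' and two per-target parameters: the Association Weight `aw` (strictly
#' positive; quantifies how strongly the target's expression depends on the
#' regulator's activity) and the Association Mode `am` (in `[-1, 1]`;
#' quantifies the direction and monotonicity of the regulation).
#'
#' @param x A data frame with columns `regulator`, `target`, `aw`, `am`.
#' @return A tibble of class `narnea_regulons`.
#' @export
as_regulons <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("regulator", "target", "aw", "am")
  if (!all(need %in% names(x))) {
    stop("regulons need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  x$regulator <- as.character(x$regulator)
  x$target <- as.character(x$target)
  bad <- which(!is.finite(x$aw) | x$aw <= 0)
  if (length(bad)) {
    stop("Association Weight must be > 0 (row ", bad[1L], ")", call. = FALSE)
  }
  bad <- which(!is.finite(x$am) | abs(x$am) > 1)
  if (length(bad)) {
    stop("Association Mode must lie in [-1, 1] (row ", bad[1L], ")", call. = FALSE)
  }
  if (anyDuplicated(x[c("regulator", "target")])) {
    stop("duplicate (regulator, target) pairs", call. = FALSE)
  }
  class(x) <- c("narnea_regulons", class(tibble::tibble()))
  x
}

#' Copula transformation of raw association scores
#'
#' Maps strictly positive raw scores to Association Weights
#' `rank(raw) / (N + 1)` (average ranks on ties), so the weights lie in
#' `(0, 1)` with an empirically uniform distribution. Uniform weights keep
#' any single gene-set member from dominating the null variance of the
#' enrichment scores, which is what guarantees the asymptotic normality of
#' the Normalized Enrichment Score (Lindeberg's condition).
#'
#' @param raw Strictly positive numeric vector, one score per target.
#' @return Numeric vector of Association Weights in `(0, 1)`.
#' @examples
#' copula_weights(c(10, 20, 30))  # 0.25 0.50 0.75
#' copula_weights(c(5, 5, 9))     # 0.375 0.375 0.750
#' @export
copula_weights <- function(raw) {
  if (length(raw) < 1) stop("need at least one score", call. = FALSE)
  if (any(!is.finite(raw) | raw <= 0)) {
    stop("raw association scores must be strictly positive", call. = FALSE)
  }
  rank(raw, ties.method = "average") / (length(raw) + 1)
}

#' Validate regulons against a signature
#'
#' Drops targets that are absent from the signature and flags regulons whose
#' surviving size falls below `min_size`. Below roughly 30 targets the
#' normal approximation of the Normalized Enrichment Score is no longer
#' guaranteed, so small regulons are rejected (strict mode) or kept with a
#' warning.
#'
#' @param regulons A regulon set (see [as_regulons()]) or a single-regulator
#'   subset of one.
#' @param sig_genes Character vector of signature gene ids, or a signature
#'   tibble / `narnea_rss` object.
#' @param min_size Minimum surviving target count (default 30).
#' @param strict If `TRUE`, undersized regulons raise an error; otherwise
#'   they are dropped with a warning.
#' @return The validated regulon set (possibly with fewer rows).
#' @export
validate_regulons <- function(regulons, sig_genes, min_size = 30, strict = FALSE) {
  regulons <- as_regulons(regulons)
  if (inherits(sig_genes, "narnea_rss")) sig_genes <- sig_genes$gene
  if (is.data.frame(sig_genes)) sig_genes <- as_signature(sig_genes)$gene
  keep <- regulons$target %in% sig_genes
  if (!any(keep)) stop("no regulon target overlaps the signature", call. = FALSE)
  out <- regulons[keep, ]
  sizes <- table(out$regulator)
  lost <- setdiff(unique(regulons$regulator), names(sizes))
  small <- names(sizes)[sizes < min_size]
  if (length(lost)) {
    if (strict) stop("regulon(s) with no signature overlap: ",
                     paste(head(lost, 5), collapse = ", "), call. = FALSE)
    warning(length(lost), " regulon(s) had no targets in the signature and were dropped",
            call. = FALSE)
  }
  if (length(small)) {
    msg <- paste0(length(small), " regulon(s) have fewer than ", min_size,
                  " targets in the signature")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  out
}

#' Read / write regulon TSV files
#'
#' Four tab-separated columns with a header: `regulator`, `target`, `aw`,
#' `am`. Round-trips exactly. Malformed rows (non-positive `aw`, `|am| > 1`)
#' raise an error naming the offending row.
#'
#' @param path File path.
#' @return A `narnea_regulons` tibble.
#' @export
read_regulons <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_regulons(df)
}

#' @param regulons Regulon set to serialize.
#' @rdname read_regulons
#' @export
write_regulons <- function(regulons, path) {
  regulons <- as_regulons(regulons)
  write.table(regulons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a plain gene list as an unweighted regulon
#'
#' Literature gene sets carry no dependence estimates; every member is given
#' equal Association Weight 1 and Association Mode 1 (all members assumed
#' positively regulated, equally informative).
#'
#' @param path File with one gene id per line.
#' @param regulator Name for the gene set.
#' @return A `narnea_regulons` tibble.
#' @export
read_gene_list <- function(path, regulator) {
  genes <- unique(trimws(readLines(path)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene list", call. = FALSE)
  as_regulons(tibble::tibble(
    regulator = regulator, target = genes, aw = 1, am = 1
  ))
}
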