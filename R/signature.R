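#' Validate a differential gene expression signature
#'
#' A signature is a tibble with one row per gene: a unique `gene` identifier
#' and a finite real differential expression value `z`. Positive `z` means the
#' gene is more highly expressed in the test phenotype than in the reference
#' phenotype; the magnitude of `z` orders genes by their extent of
#' differential expression.
#'
#' @param x A data frame with columns `gene` and `z` (extra columns are kept).
#' @return A tibble with at least columns `gene` (character) and `z` (double).
#' @export
as_signature <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("gene", "z") %in% names(x))) {
    stop("a signature needs `gene` and `z` columns", call. = FALSE)
  }
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$gene)) stop("duplicate gene ids in signature", call. = FALSE)
  if (nrow(x) < 2) stop("a signature needs at least 2 genes", call. = FALSE)
  if (!all(is.finite(x$z))) stop("signature values must be finite", call. = FALSE)
  x
}

#' Mann-Whitney U differential expression signature
#'
#' Computes, for every gene, the tie-corrected normal approximation to the
#' two-sample Mann-Whitney U statistic comparing the test phenotype samples
#' against the reference phenotype samples:
#' `z = (U - n1*n2/2) / sd(U)`, where `U` counts (with 1/2 credit for ties)
#' the test-vs-reference sample pairs in which the test sample is larger.
#' `z > 0` iff the gene is more highly expressed in the test phenotype, and
#' `|z|` orders genes by the strength of the evidence, so the result satisfies
#' the axioms required of a differential expression signature.
#'
#' @param test,ref Expression matrices (genes x samples) with the same rownames
#'   (gene ids) in the same order, or data frames whose first column is the
#'   gene id. At least two samples each.
#' @return A signature tibble with columns `gene`, `z` and the two-sided
#'   normal-approximation p-value `p`.
#' @examples
#' test <- matrix(c(5, 6, 7), 1, dimnames = list("g1", NULL))
#' ref  <- matrix(c(1, 2, 3), 1, dimnames = list("g1", NULL))
#' mwu_signature(rbind(test, g2 = 1:3), rbind(ref, g2 = 1:3))
#' @export
mwu_signature <- function(test, ref) {
  test <- as_expression_matrix(test)
  ref <- as_expression_matrix(ref)
  if (!identical(rownames(test), rownames(ref))) {
    stop("test and ref must contain the same genes in the same order", call. = FALSE)
  }
  n1 <- ncol(test)
  n2 <- ncol(ref)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per phenotype", call. = FALSE)
  n <- n1 + n2
  comb <- cbind(test, ref)

  res <- apply(comb, 1L, function(v) {
    rk <- rank(v)
    u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tie_term <- 0
    if (anyDuplicated(v)) {
      tab <- tabulate(match(v, unique(v)))
      tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    }
    s2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (s2 <= 0) return(c(0, NA_real_))
    z <- (u - n1 * n2 / 2) / sqrt(s2)
    c(z, 2 * pnorm(-abs(z)))
  })
  z <- res[1L, ]
  p <- res[2L, ]
  if (anyNA(p)) {
    warning(sum(is.na(p)), " gene(s) constant across all samples; z set to 0",
            call. = FALSE)
    p[is.na(p)] <- 1
  }
  tibble::tibble(gene = rownames(comb), z = unname(z), p = unname(p))
}

#' Rank/sign transformation of a signature
#'
#' Replaces each signature value by the rank of its magnitude (ascending,
#' average ranks on ties) and the sign of its value, and computes the four
#' moments of the Maximum-Entropy null distribution of a gene-set member
#' placed uniformly at random over the transformed signature:
#' `m_rs = mean(r*s)`, `m_r = mean(r)`, `m_r2 = mean(r^2)` and
#' `m_r2s = mean(r^2*s)`. With no ties `m_r = (G+1)/2` and
#' `m_r2 = (2G^2 + 3G + 1)/6`; the realized vectors are always used so that
#' ties are handled exactly.
#'
#' @param sig A signature (see [as_signature()]).
#' @return An object of class `narnea_rss`: a list with `gene`, `r`, `s`,
#'   the gene count `G`, and `moments` (`m_rs`, `m_r`, `m_r2`, `m_r2s`).
#' @examples
#' rss <- rank_sign_transform(
#'   tibble::tibble(gene = paste0("g", 1:5), z = c(2, -1, 0.5, -0.2, 3)))
#' rss$moments
#' @export
rank_sign_transform <- function(sig) {
  sig <- as_signature(sig)
  r <- rank(abs(sig$z))
  s <- sign(sig$z)
  g <- length(r)
  rs <- r * s
  r2 <- r^2
  structure(
    list(
      gene = sig$gene, r = r, s = as.integer(s), G = g,
      moments = list(
        m_rs = mean(rs), m_r = mean(r),
        m_r2 = mean(r2), m_r2s = mean(r2 * s)
      )
    ),
    class = "narnea_rss"
  )
}

#' @export
print.narnea_rss <- function(x, ...) {
  cat("<rank/sign signature> G =", x$G, "\n")
  m <- x$moments
  cat(sprintf("  null moments: m_rs = %.4g, m_r = %.4g, m_r2 = %.4g, m_r2s = %.4g\n",
              m$m_rs, m$m_r, m$m_r2, m$m_r2s))
  invisible(x)
}

#' @export
tidy.narnea_rss <- function(x, ...) {
  tibble::tibble(gene = x$gene, r = x$r, s = x$s)
}

#' @export
glance.narnea_rss <- function(x, ...) {
  tibble::as_tibble(x$moments[c("m_rs", "m_r", "m_r2", "m_r2s")]) |>
    dplyr::mutate(G = x$G, .before = 1)
}

# position indices of the transformed signature grouped by sign and ordered
# by rank, used by the extremal-placement search behind the effect size
rss_groups <- function(rss) {
  by_rank_desc <- function(mask) {
    w <- which(mask)
    w[order(rss$r[w], decreasing = TRUE)]
  }
  list(
    pos = by_rank_desc(rss$s > 0),
    neg = by_rank_desc(rss$s < 0),
    zero = by_rank_desc(rss$s == 0)
  )
}

#' Read / write signature TSV files
#'
#' The on-disk format is a two-column (or more) tab-separated file with a
#' header containing at least `gene` and `z`.
#'
#' @param path File path (plain text or gzip).
#' @return A signature tibble.
#' @export
read_signature <- function(path) {
  as_signature(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' @param sig Signature tibble.
#' @rdname read_signature
#' @export
write_signature <- function(sig, path) {
  sig <- as_signature(sig)
  write.table(sig, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coerce expression data to a genes-by-samples matrix
#'
#' Accepts a numeric matrix with gene rownames, or a data frame whose first
#' column holds gene ids with samples in the remaining columns.
#'
#' @param x Matrix or data frame.
#' @return Numeric matrix with unique gene rownames.
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1L]])
    x <- as.matrix(x[-1L])
    rownames(x) <- genes
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix or a data frame", call. = FALSE)
  }
  if (is.null(rownames(x))) stop("expression matrix needs gene rownames", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids", call. = FALSE)
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(x < 0)) stop("expression abundances must be non-negative", call. = FALSE)
  x
}

#' Read an expression matrix from TSV/CSV
#'
#' First column gene ids, remaining columns samples; `.csv` files are read
#' comma-separated, anything else tab-separated. gzip is handled transparently.
#'
#' @param path File path.
#' @return Numeric genes-by-samples matrix.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  as_expression_matrix(df)
}
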