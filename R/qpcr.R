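#' geNorm reference-gene stability ranking
#'
#' Computes the geNorm stability measure M for each candidate reference
#' gene: with amplification efficiency fixed at 2, the log2 expression
#' ratio of genes j and k in a sample is \eqn{Ct_k - Ct_j}, and
#' \eqn{M_j} is the mean over the other candidates k of the standard
#' deviation of that ratio across samples. Lower M means more stable.
#' `genorm_rank()` applies the iterative scheme, repeatedly excluding the
#' least-stable gene and recomputing M, down to the final pair.
#'
#' @param ct A wide Ct table: a `gene` column plus one numeric column per
#'   sample, or a genes-by-samples matrix with gene rownames.
#' @param candidates Character vector of candidate housekeeping genes
#'   (at least 2; 3 or more for a meaningful ranking).
#' @return `genorm_stability()`: a tibble with `gene` and `m`, sorted by
#'   increasing M. `genorm_rank()`: a tibble with `gene`, `step` (the
#'   exclusion round at which the gene was dropped; `NA` for the final
#'   retained pair) and `m_at_exclusion`.
#' @export
genorm_stability <- function(ct, candidates) {
  m <- ct_to_matrix(ct)
  missing <- setdiff(candidates, rownames(m))
  if (length(missing)) {
    stop("candidates not in Ct table: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(candidates) < 2L) stop("need at least 2 candidates", call. = FALSE)
  if (ncol(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  x <- m[candidates, , drop = FALSE]
  mv <- vapply(seq_along(candidates), function(j) {
    others <- setdiff(seq_along(candidates), j)
    mean(vapply(others, function(k) {
      stats::sd(x[k, ] - x[j, ]) # log2 ratio under efficiency 2
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(gene = candidates, m = mv) %>%
    dplyr::arrange(.data$m)
}

#' @rdname genorm_stability
#' @export
genorm_rank <- function(ct, candidates) {
  remaining <- candidates
  dropped <- tibble::tibble(
    gene = character(), step = integer(), m_at_exclusion = numeric()
  )
  step <- 0L
  while (length(remaining) > 2L) {
    step <- step + 1L
    st <- genorm_stability(ct, remaining)
    worst <- st$gene[which.max(st$m)]
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      gene = worst, step = step,
      m_at_exclusion = max(st$m)
    ))
    remaining <- setdiff(remaining, worst)
  }
  final <- genorm_stability(ct, candidates) %>%
    dplyr::filter(.data$gene %in% remaining)
  dplyr::bind_rows(
    tibble::tibble(
      gene = final$gene, step = NA_integer_,
      m_at_exclusion = final$m
    ),
    dropped
  )
}

#' geNorm pairwise variation V for choosing the reference count
#'
#' V(n, n+1) is the standard deviation across samples of the log2 ratio of
#' the normalization factors computed from the n and the n+1 most stable
#' references; small V means the extra gene adds little.
#'
#' @inheritParams genorm_stability
#' @return A tibble with `n_genes` and `v` for each consecutive pair.
#' @export
genorm_pairwise_v <- function(ct, candidates) {
  if (length(candidates) < 3L) stop("need at least 3 candidates for V", call. = FALSE)
  m <- ct_to_matrix(ct)
  rk <- genorm_rank(ct, candidates)
  # most stable first: the retained pair, then exclusions latest-first
  ranked <- c(
    rk %>% dplyr::filter(is.na(.data$step)) %>%
      dplyr::arrange(.data$m_at_exclusion) %>% dplyr::pull("gene"),
    rk %>% dplyr::filter(!is.na(.data$step)) %>%
      dplyr::arrange(dplyr::desc(.data$step)) %>% dplyr::pull("gene")
  )
  nf <- function(genes) colMeans(-m[genes, , drop = FALSE]) # log2 NF per sample
  purrr::map_dfr(2:(length(ranked) - 1L), function(n) {
    tibble::tibble(
      n_genes = n,
      v = stats::sd(nf(ranked[1:n]) - nf(ranked[1:(n + 1L)]))
    )
  })
}

#' Normalize a Ct matrix by the geometric mean of housekeeping genes
#'
#' Comparative Ct normalization with efficiency fixed at 2: the per-sample
#' normalization factor is the geometric mean of the housekeeping relative
#' quantities, so the relative expression of a target gene is
#' \eqn{2^{-(Ct_{target} - \bar{Ct}_{HK})}} where \eqn{\bar{Ct}_{HK}} is the
#' arithmetic mean of the housekeeping Ct values in that sample. Samples
#' with any missing housekeeping Ct are flagged and excluded.
#'
#' @inheritParams genorm_stability
#' @param housekeeping Character vector of reference genes present in `ct`.
#' @return A long tibble with `gene`, `sample`, `rel_expr` for all
#'   non-housekeeping genes; excluded samples are reported in the
#'   `excluded_samples` attribute.
#' @export
normalize_ct <- function(ct, housekeeping) {
  m <- ct_to_matrix(ct)
  missing <- setdiff(housekeeping, rownames(m))
  if (length(missing)) {
    stop("housekeeping genes not in Ct table: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  hk <- m[housekeeping, , drop = FALSE]
  bad <- colnames(m)[colSums(is.na(hk)) > 0]
  if (length(bad)) {
    warning(
      "samples excluded for missing housekeeping Ct: ",
      paste(bad, collapse = ", ")
    )
  }
  keep <- setdiff(colnames(m), bad)
  ref <- colMeans(hk[, keep, drop = FALSE])
  targets <- setdiff(rownames(m), housekeeping)
  out <- purrr::map_dfr(targets, function(g) {
    tibble::tibble(
      gene = g,
      sample = keep,
      rel_expr = unname(2^-(m[g, keep] - ref))
    )
  })
  attr(out, "excluded_samples") <- bad
  out
}

#' Per-gene two-group comparison with BH FDR
#'
#' Compares normalized expression between two sample groups gene by gene
#' with a delegated two-sample test — the Wilcoxon rank-sum test by default,
#' or Welch's t-test when normality is asserted — and adjusts the p-values
#' by the Benjamini-Hochberg step-up procedure at the usual 5% FDR
#' convention.
#'
#' @param expression Long tibble as from [normalize_ct()] (`gene`, `sample`,
#'   `rel_expr`).
#' @param groups Tibble with `sample` and `group` (exactly 2 levels, each
#'   with at least 2 samples).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A tibble per gene: `statistic`, `p_value`, `q_value`.
#' @export
compare_groups <- function(expression, groups, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(
    all(c("gene", "sample", "rel_expr") %in% names(expression)),
    all(c("sample", "group") %in% names(groups))
  )
  d <- dplyr::inner_join(expression, groups, by = "sample")
  lev <- unique(d$group)
  if (length(lev) != 2L) stop("exactly two groups are required", call. = FALSE)
  counts <- d %>%
    dplyr::distinct(.data$sample, .data$group) %>%
    dplyr::count(.data$group)
  if (any(counts$n < 2L)) stop("each group needs at least 2 samples", call. = FALSE)
  res <- d %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::group_modify(function(g, key) {
      a <- g$rel_expr[g$group == lev[1]]
      b <- g$rel_expr[g$group == lev[2]]
      ht <- if (test == "wilcoxon") {
        stats::wilcox.test(a, b, exact = FALSE)
      } else {
        stats::t.test(a, b)
      }
      tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
    }) %>%
    dplyr::ungroup()
  res %>% dplyr::mutate(q_value = bh_adjust(.data$p_value))
}

# Accept a matrix with gene rownames or a tibble with a gene column.
ct_to_matrix <- function(ct) {
  if (is.matrix(ct)) {
    if (is.null(rownames(ct))) stop("Ct matrix needs gene rownames", call. = FALSE)
    return(ct)
  }
  stopifnot(is.data.frame(ct), "gene" %in% names(ct))
  m <- as.matrix(ct[, setdiff(names(ct), "gene"), drop = FALSE])
  rownames(m) <- ct$gene
  storage.mode(m) <- "double"
  m
}
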