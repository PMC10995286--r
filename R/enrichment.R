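#' Upper-tail hypergeometric p-value for a list/set overlap
#'
#' Probability of drawing at least `m` members of a size-`M` set when
#' sampling `n` miRNAs without replacement from a universe of `N`:
#' `p = sum_{i=m}^{min(n,M)} C(M,i) C(N-M,n-i) / C(N,n)`, inclusive of
#' the observed overlap. `m = 0` gives 1.
#'
#' @param n input-list size (after restriction to the universe).
#' @param N universe size.
#' @param M set size.
#' @param m overlap count.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(n, N, M, m) {
  if (M > N || n > N || m > min(n, M) || m < 0 || min(n, N, M) < 0) {
    stop("impossible overlap counts: n=", n, " N=", N, " M=", M, " m=", m)
  }
  if (m == 0) return(1)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment, returned in input order and capped
#' at 1.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return FDR vector of the same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis against a miRNA-set knowledge base
#'
#' Tests every set of the knowledge base for enrichment in the input
#' list with the upper-tail hypergeometric test, using the knowledge
#' base's member union as the universe. Input miRNAs outside the
#' universe are dropped from the list size (logged), duplicates are
#' removed first, and FDR correction is applied across all sets
#' jointly. A set is flagged significant when its FDR is below
#' `fdr_threshold`.
#'
#' @param input_list character vector of miRNA ids.
#' @param kb a [mirna_set_kb()].
#' @param fdr_threshold significance cutoff on the FDR (default 0.05).
#' @return data.frame with one row per set -- `set_name`, `category`,
#'   `set_size`, `overlap`, `p_value`, `fdr`, `significant` -- sorted
#'   by p-value ascending, ties by set name. The effective list size n
#'   is attached as attribute `n_input`.
#' @export
enrich <- function(input_list, kb, fdr_threshold = 0.05) {
  stopifnot(inherits(kb, "mirna_set_kb"))
  input_list <- unique(as.character(input_list))
  in_universe <- intersect(input_list, kb$universe)
  dropped <- length(input_list) - length(in_universe)
  if (dropped > 0) {
    message("dropped ", dropped, " input miRNA(s) outside the ",
            "knowledge-base universe")
  }
  if (length(in_universe) == 0L) {
    stop("no input miRNA in knowledge-base universe")
  }
  n <- length(in_universe)
  N <- length(kb$universe)
  rows <- lapply(kb$sets, function(s) {
    m <- length(intersect(in_universe, s$members))
    data.frame(set_name = s$name, category = s$category,
               set_size = length(s$members), overlap = m,
               p_value = hypergeom_pvalue(n, N, length(s$members), m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- n
  out
}

#' Hit rate of a miRNA list against a reference set
#'
#' Percentage of a reference set recovered by a list:
#' `100 * overlap / set_size`, rounded half-up to two decimals (91 of
#' 315 gives 28.89).
#'
#' @param overlap count of list members in the set.
#' @param set_size size of the reference set (> 0).
#' @return percentage with two decimals.
#' @export
hit_rate <- function(overlap, set_size) {
  if (set_size <= 0) stop("set_size must be positive")
  if (overlap < 0 || overlap > set_size) {
    stop("overlap must lie in [0, set_size]")
  }
  floor(100 * overlap / set_size * 100 + 0.5) / 100
}

#' Write an enrichment table to TSV
#' @param rows data.frame from [enrich()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path) {
  out <- rows
  out$p_value <- formatC(out$p_value, format = "e", digits = 6)
  out$fdr <- formatC(out$fdr, format = "e", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
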