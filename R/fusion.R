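#' Fuse miRNA similarity networks by per-pair averaging
#'
#' The fused network spans the union of the input networks' miRNAs. For
#' every unordered pair, the fused similarity is the mean of that
#' pair's values over the networks that contain BOTH miRNAs; similarity
#' information present in only one network is carried over unchanged,
#' and pairs covered by no network get 0. The mean is taken
#' simultaneously over all covering networks (not sequentially pairwise,
#' which would depend on network order). Diagonal is 1; symmetry and
#' the `[0, 1]` range of the inputs are preserved.
#'
#' @param networks list of two or more [sim_matrix()] objects.
#' @param mode aggregation rule; only `"mean"` is defined.
#' @return a [sim_matrix()] over the union of input ids (sorted).
#' @examples
#' a <- sim_matrix(matrix(c(1, .2, .2, 1), 2), c("m1", "m2"))
#' b <- sim_matrix(matrix(c(1, .6, .6, 1), 2), c("m1", "m2"))
#' fuse_networks(list(a, b))["m1", "m2"]  # 0.4
#' @export
fuse_networks <- function(networks, mode = "mean") {
  mode <- match.arg(mode)
  if (!is.list(networks) || length(networks) < 2L) {
    stop("need at least two networks to fuse")
  }
  for (m in networks) stopifnot(inherits(m, "sim_matrix"))
  ids <- sort(unique(unlist(lapply(networks, sim_ids))))
  n <- length(ids)
  total <- matrix(0, n, n, dimnames = list(ids, ids))
  cover <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (m in networks) {
    mi <- sim_ids(m)
    total[mi, mi] <- total[mi, mi] + unclass(m)
    cover[mi, mi] <- cover[mi, mi] + 1L
  }
  values <- ifelse(cover > 0L, total / pmax(cover, 1L), 0)
  diag(values) <- 1
  sim_matrix(values, ids)
}

#' Coverage summary of a set of networks
#'
#' Reports how many miRNAs the networks share and how many network
#' sources cover each miRNA pair -- diagnostics for deciding which
#' networks to fuse.
#'
#' @param networks list of [sim_matrix()] objects.
#' @return list with `n_networks`, `intersection_size`, `union_size`,
#'   `per_network_sizes` and `pair_coverage` (table of off-diagonal
#'   pair counts by number of covering networks).
#' @export
fusion_report <- function(networks) {
  id_sets <- lapply(networks, sim_ids)
  ids <- sort(unique(unlist(id_sets)))
  n <- length(ids)
  cover <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (mi in id_sets) cover[mi, mi] <- cover[mi, mi] + 1L
  off <- cover[upper.tri(cover)]
  list(
    n_networks = length(networks),
    intersection_size = length(Reduce(intersect, id_sets)),
    union_size = n,
    per_network_sizes = lengths(id_sets),
    pair_coverage = table(factor(off, levels = 0:length(networks)))
  )
}
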