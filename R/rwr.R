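#' Threshold a similarity network for the random walk
#'
#' Off-diagonal entries below the similarity coefficient `tau` are
#' zeroed; entries at or above it keep their similarity as edge weight
#' (entries exactly equal to `tau` are retained). The diagonal is set
#' to 0 so the walk has no self-loops.
#'
#' @param m a [sim_matrix()].
#' @param tau similarity coefficient in `[0, 1]`; 0.6 is the value at
#'   which downstream enrichment performs best.
#' @return numeric matrix (same ids) of non-negative edge weights with
#'   zero diagonal.
#' @export
threshold_network <- function(m, tau = 0.6) {
  stopifnot(inherits(m, "sim_matrix"), tau >= 0, tau <= 1)
  adj <- unclass(m)
  adj[adj < tau] <- 0
  diag(adj) <- 0
  adj
}

#' Column-stochastic transition matrix
#'
#' Scales every nonzero column of a weighted adjacency matrix to sum
#' to 1, so walks leave each node in proportion to edge weight. Columns
#' of isolated (dangling) nodes are left all-zero.
#'
#' @param adj non-negative weight matrix with zero diagonal, as from
#'   [threshold_network()].
#' @return matrix `W` with every nonzero column summing to 1.
#' @export
transition_matrix <- function(adj) {
  stopifnot(is.matrix(adj), all(adj >= 0), all(diag(adj) == 0))
  sums <- colSums(adj)
  nz <- sums > 0
  adj[, nz] <- sweep(adj[, nz, drop = FALSE], 2, sums[nz], "/")
  adj
}

#' Random walk with restart
#'
#' Iterates `r <- c W r + (1 - c) e` from `r0 = e`, where `e` is
#' uniform over the seed nodes present in the network, until the L1
#' change falls below `tol`. `c` weights the walk term, so `1 - c` is
#' the restart mass returned to the seeds each step; convergence is
#' geometric with contraction factor at most `c`.
#'
#' @param W transition matrix from [transition_matrix()], with ids as
#'   dimnames.
#' @param seeds character vector of seed node ids; at least one must be
#'   in the network.
#' @param c walk-continuation weight in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error reporting
#'   the residual.
#' @return named numeric vector of steady-state scores with attributes
#'   `iterations` and `residual`.
#' @export
rwr <- function(W, seeds, c = 0.85, tol = 1e-10, max_iter = 10000L) {
  stopifnot(c > 0, c < 1, tol > 0)
  ids <- rownames(W)
  present <- intersect(seeds, ids)
  if (length(present) == 0L) {
    stop("no seed is present in the network; missing: ",
         paste(utils::head(setdiff(seeds, ids), 10), collapse = ", "))
  }
  e <- stats::setNames(numeric(length(ids)), ids)
  e[present] <- 1 / length(present)
  r <- e
  for (iter in seq_len(max_iter)) {
    r_new <- c * as.vector(W %*% r) + (1 - c) * e
    residual <- sum(abs(r_new - r))
    r <- stats::setNames(r_new, ids)
    if (residual < tol) {
      attr(r, "iterations") <- iter
      attr(r, "residual") <- residual
      return(r)
    }
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (residual ", format(residual), ")")
}

#' Expand a miRNA list from random-walk scores
#'
#' Candidates are the non-seed nodes with positive steady-state score,
#' ranked by score descending with ties broken by lexicographic id for
#' reproducibility. The top `floor(keep_fraction * n_candidates)` are
#' added to the input list; input miRNAs absent from the network are
#' carried through untouched.
#'
#' @param scores named scores from [rwr()].
#' @param seeds seed ids used for the walk.
#' @param input_list the original user miRNA list.
#' @param keep_fraction share of ranked candidates to keep, in (0, 1];
#'   0.5 (the top half) gives the best downstream enrichment.
#' @return an `expansion_result` with elements `scores`, `seeds`,
#'   `added` and `expanded_list`.
#' @export
expand_list <- function(scores, seeds, input_list, keep_fraction = 0.5) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  candidates <- setdiff(names(scores)[scores > 0], seeds)
  ord <- candidates[order(-scores[candidates], candidates)]
  added <- utils::head(ord, floor(keep_fraction * length(ord)))
  structure(list(
    scores = scores,
    seeds = intersect(input_list, names(scores)),
    added = added,
    expanded_list = unique(c(input_list, added))
  ), class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("expansion_result:", length(x$seeds), "seeds +", length(x$added),
      "added ->", length(x$expanded_list), "miRNAs\n")
  invisible(x)
}

#' Threshold, walk and expand in one call
#'
#' Convenience wrapper chaining [threshold_network()],
#' [transition_matrix()], [rwr()] and [expand_list()].
#'
#' @param network fused [sim_matrix()].
#' @param input_list user miRNA list; members present in the network
#'   seed the walk.
#' @param c,tau,keep_fraction,tol,max_iter see the chained functions.
#' @return an `expansion_result`, see [expand_list()].
#' @export
expand_mirna_list <- function(network, input_list, c = 0.85, tau = 0.6,
                              keep_fraction = 0.5, tol = 1e-10,
                              max_iter = 10000L) {
  W <- transition_matrix(threshold_network(network, tau))
  seeds <- intersect(input_list, sim_ids(network))
  scores <- rwr(W, seeds, c = c, tol = tol, max_iter = max_iter)
  expand_list(scores, seeds, input_list, keep_fraction)
}
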