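#' Protein-protein interaction graph
#'
#' Undirected, unweighted interaction network. Self-loops and
#' duplicate/reversed edges are collapsed at construction.
#'
#' @param from,to character vectors of protein ids, one edge per pair.
#' @return a `ppin_graph` wrapping an igraph object.
#' @export
ppin_graph <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  if (length(from) == 0L) stop("PPI network has no edges")
  g <- igraph::simplify(igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE))
  structure(list(graph = g, proteins = igraph::V(g)$name),
            class = "ppin_graph")
}

#' @export
print.ppin_graph <- function(x, ...) {
  cat("ppin_graph:", length(x$proteins), "proteins,",
      igraph::ecount(x$graph), "interactions\n")
  invisible(x)
}

#' Read a PPI edge-list TSV
#' @param path two-column TSV of interacting protein pairs.
#' @return a [ppin_graph()].
#' @export
read_ppin <- function(path) {
  tab <- read_association_table(path)
  ppin_graph(tab$pairs$mirna, tab$pairs$annotation)
}

#' Shortest-path distances between two target-gene sets
#'
#' Hop-count shortest paths between every ordered pair (i in A, j in B)
#' after restricting both sets to proteins present in the network.
#' Unreachable pairs are omitted and counted.
#'
#' @param graph a [ppin_graph()].
#' @param A,B character vectors of gene ids; each must intersect the
#'   network's proteins.
#' @return list with `pairs` (data.frame i, j, dist over reachable
#'   pairs) and `unreachable` (count of omitted pairs).
#' @export
pairwise_distances <- function(graph, A, B) {
  A <- intersect(unique(A), graph$proteins)
  B <- intersect(unique(B), graph$proteins)
  if (length(A) == 0L || length(B) == 0L) {
    stop("no target gene present in the PPI network")
  }
  d <- igraph::distances(graph$graph, v = A, to = B)
  idx <- which(is.finite(d), arr.ind = TRUE)
  list(
    pairs = data.frame(i = A[idx[, 1]], j = B[idx[, 2]],
                       dist = d[idx], stringsAsFactors = FALSE),
    unreachable = sum(!is.finite(d))
  )
}

#' miRNA similarity from PPI proximity of target genes
#'
#' The reciprocal of the mean shortest-path distance between the two
#' target sets: with P the reachable target pairs, `|P| / sum of
#' distances`, capped at 1 so the score shares the `[0, 1]` scale of
#' the other networks. All-zero distances (identical single targets)
#' define similarity 1; no reachable pair defines 0.
#'
#' @param graph a [ppin_graph()].
#' @param targets1,targets2 target gene sets of the two miRNAs.
#' @return similarity in `[0, 1]`.
#' @export
mirfunsim <- function(graph, targets1, targets2) {
  pd <- pairwise_distances(graph, targets1, targets2)
  if (nrow(pd$pairs) == 0L) return(0)
  total <- sum(pd$pairs$dist)
  if (total == 0) return(1)
  min(1, nrow(pd$pairs) / total)
}

#' Build the PPI miRNA similarity network
#'
#' Scores every miRNA pair with [mirfunsim()] over their target sets.
#' miRNAs whose targets all fall outside the PPI network are excluded
#' and logged; the diagonal is set to 1.
#'
#' @param targets an [assoc_table()] of miRNA -> target gene pairs.
#' @param graph a [ppin_graph()].
#' @return a [sim_matrix()] over the eligible miRNAs.
#' @export
build_mirsn_ppi <- function(targets, graph) {
  mapped <- lapply(targets$by_mirna, intersect, y = graph$proteins)
  mapped <- mapped[lengths(mapped) > 0]
  excluded <- setdiff(names(targets$by_mirna), names(mapped))
  if (length(excluded)) {
    message("excluded ", length(excluded),
            " miRNA(s) with no target in the PPI network: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  if (length(mapped) == 0L) stop("no eligible miRNA for miRSN-PPI")
  mirnas <- names(mapped)
  n <- length(mirnas)
  # one all-pairs BFS over the union of mapped targets, reused per pair
  genes <- sort(unique(unlist(mapped)))
  d <- igraph::distances(graph$graph, v = genes, to = genes)
  values <- diag(nrow = n)
  score <- function(A, B) {
    dd <- d[A, B, drop = FALSE]
    dd <- dd[is.finite(dd)]
    if (length(dd) == 0L) return(0)
    if (sum(dd) == 0) return(1)
    min(1, length(dd) / sum(dd))
  }
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        values[i, j] <- values[j, i] <- score(mapped[[i]], mapped[[j]])
      }
    }
  }
  sim_matrix(values, mirnas)
}
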