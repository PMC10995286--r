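#' Semantic contribution profile of a disease on its ontology DAG
#'
#' For a disease d on a MeSH-like DAG, every ancestor t of d (and d
#' itself) receives a semantic contribution D_d(t): 1 for d, and for any
#' other ancestor the maximum over its children within d's ancestor
#' closure of `decay * D_d(child)`. Because each edge multiplies by the
#' same decay, this equals `decay ^ h` where h is the minimum hop count
#' from d up to t -- the shortest path carries the maximum contribution.
#' The semantic value DV(d) is the sum of contributions over the
#' closure, so DV(d) >= 1 always.
#'
#' @param ontology an [ontology_dag()].
#' @param disease term id present in the ontology.
#' @param decay semantic contribution decay factor per edge, in (0, 1).
#'   0.5 is the conventional choice.
#' @return a `dag_view` with elements `disease`, `ancestor_set`,
#'   `contribution` (named numeric) and `semantic_value`.
#' @examples
#' dag <- ontology_dag(c("d", "p"), c("p", "root"))
#' v <- dag_view(dag, "d", 0.5)
#' v$contribution   # d: 1, p: 0.5, root: 0.25
#' v$semantic_value # 1.75
#' @export
dag_view <- function(ontology, disease, decay = 0.5) {
  if (!disease %in% ontology$terms) {
    stop("disease not in ontology: ", disease)
  }
  stopifnot(decay > 0, decay < 1)
  anc <- dag_ancestors(ontology, disease)
  sub <- igraph::induced_subgraph(ontology$graph, anc)
  # bottom-up over the closure: children (in-neighbors) are finalized
  # before every parent in a topological order starting at the disease
  order_ids <- names(igraph::topo_sort(sub, mode = "out"))
  contribution <- stats::setNames(numeric(length(order_ids)), order_ids)
  contribution[[disease]] <- 1
  for (t in order_ids) {
    if (t == disease) next
    children <- names(igraph::neighbors(sub, t, mode = "in"))
    contribution[[t]] <- max(decay * contribution[children])
  }
  structure(list(disease = disease,
                 ancestor_set = order_ids,
                 contribution = contribution,
                 decay = decay,
                 semantic_value = sum(contribution)),
            class = "dag_view")
}

#' Semantic similarity between two diseases
#'
#' The shared-ancestor score: contributions of every term in the
#' intersection of the two ancestor closures, from both sides, divided
#' by the sum of the two semantic values. Bounded in `[0, 1]`,
#' symmetric, and 1 for a disease against itself.
#'
#' @param view_i,view_j [dag_view()]s built on the same ontology with
#'   the same decay.
#' @return similarity in `[0, 1]`.
#' @export
disease_similarity <- function(view_i, view_j) {
  stopifnot(inherits(view_i, "dag_view"), inherits(view_j, "dag_view"))
  if (view_i$decay != view_j$decay) {
    stop("views built with different decay factors")
  }
  shared <- intersect(view_i$ancestor_set, view_j$ancestor_set)
  if (length(shared) == 0L) return(0)
  sum(view_i$contribution[shared] + view_j$contribution[shared]) /
    (view_i$semantic_value + view_j$semantic_value)
}

#' All-pairs disease similarity matrix
#'
#' Builds each disease's DAG view once, then evaluates
#' [disease_similarity()] on every pair.
#'
#' @param ontology an [ontology_dag()].
#' @param diseases character vector of term ids (unique).
#' @param decay decay factor, see [dag_view()].
#' @return a [sim_matrix()] over `diseases`.
#' @export
disease_similarity_matrix <- function(ontology, diseases, decay = 0.5) {
  diseases <- unique(as.character(diseases))
  views <- lapply(diseases, dag_view, ontology = ontology, decay = decay)
  n <- length(diseases)
  values <- diag(nrow = n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        values[i, j] <- values[j, i] <-
          disease_similarity(views[[i]], views[[j]])
      }
    }
  }
  sim_matrix(values, diseases)
}
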