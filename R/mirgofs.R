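#' Annotate a GO graph with gene sets and information content
#'
#' Attaches to each GO term the set of genes annotated to it or to any
#' of its descendants (the true-path rule), prunes terms with no
#' annotated gene, and computes each term's information content
#' `IC(x) = -ln(|G_x| / |G_root|)` where `G_root` is the full annotated
#' gene background. True-path closure guarantees `G_child` is a subset
#' of `G_parent`, hence IC is non-decreasing from parent to child and 0
#' at the root.
#'
#' @param dag a GO [ontology_dag()].
#' @param annotations an [assoc_table()] of gene -> GO term pairs
#'   (mirna column holds gene ids, annotation column holds term ids).
#' @return an `annotated_go_graph` with elements `dag` (pruned),
#'   `gene_sets` (named list of character vectors), `background`
#'   (all annotated genes) and `ic` (named numeric, nats).
#' @export
annotated_go_graph <- function(dag, annotations) {
  direct <- lapply(annotations$by_annotation, unique)
  direct <- direct[names(direct) %in% dag$terms]
  if (length(direct) == 0L) {
    stop("no GO annotation refers to a term of the ontology")
  }
  gene_sets <- lapply(dag$terms, function(t) {
    sort(unique(unlist(direct[intersect(dag_descendants(dag, t),
                                        names(direct))])))
  })
  names(gene_sets) <- dag$terms
  keep <- names(gene_sets)[lengths(gene_sets) > 0]
  pruned <- length(dag$terms) - length(keep)
  if (pruned > 0) {
    message("pruned ", pruned, " GO term(s) with no annotated gene")
  }
  gene_sets <- gene_sets[keep]
  background <- sort(unique(unlist(gene_sets)))
  sub <- igraph::induced_subgraph(dag$graph, keep)
  edges <- igraph::as_data_frame(sub, what = "edges")
  pruned_dag <- ontology_dag(edges$from, edges$to,
                             isolated = setdiff(keep, c(edges$from, edges$to)))
  ic <- -log(lengths(gene_sets) / length(background))
  structure(list(dag = pruned_dag, gene_sets = gene_sets,
                 background = background, ic = ic),
            class = "annotated_go_graph")
}

#' @export
print.annotated_go_graph <- function(x, ...) {
  cat("annotated_go_graph:", length(x$gene_sets), "terms,",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Information content of a GO term
#'
#' `-ln` of the fraction of background genes annotated (directly or via
#' descendants) to the term. 0 at a root that covers the full
#' background; errors on terms pruned for having no annotated gene.
#'
#' @param graph an [annotated_go_graph()].
#' @param x term id.
#' @return non-negative IC in nats.
#' @export
information_content <- function(graph, x) {
  if (!x %in% names(graph$ic)) {
    stop("term has no annotated genes (pruned) or is unknown: ", x)
  }
  graph$ic[[x]]
}

#' Lowest common ancestors and highest common descendants
#'
#' For a term pair, `L` is the set of common ancestors (inclusive of
#' the terms themselves) that have no other common ancestor strictly
#' below them, and `H` the set of common descendants with no other
#' common descendant strictly above them. `H` may be empty; for
#' `x == y` both are `{x}`.
#'
#' @param graph an [annotated_go_graph()].
#' @param x,y term ids.
#' @return list with character vectors `L` and `H`.
#' @export
lca_hcd <- function(graph, x, y) {
  dag <- graph$dag
  ca <- intersect(dag_ancestors(dag, x), dag_ancestors(dag, y))
  cd <- intersect(dag_descendants(dag, x), dag_descendants(dag, y))
  # lowest = no other common ancestor strictly below (i.e. that reaches
  # it along child -> parent edges); highest = dual on descendants
  minimal <- function(cands, others_of) {
    cands[vapply(cands, function(t) {
      !any(vapply(setdiff(cands, t), function(o) t %in% others_of(o), TRUE))
    }, TRUE)]
  }
  list(
    L = minimal(ca, function(o) dag_ancestors(dag, o)),
    H = minimal(cd, function(o) dag_descendants(dag, o))
  )
}

#' Semantic similarity between two GO terms
#'
#' Combines the information content of the most informative lowest
#' common ancestor (IC_L) and, when the pair has common descendants, of
#' the most informative highest common descendant (IC_H):
#' `Sim(x, y) = min(1, (IC_L + IC_H) / (IC(x) + IC(y)))`. With no
#' common descendant this reduces to a Lin-style shared-ancestor
#' similarity; self-similarity is exactly 1 for any non-root term. When
#' both terms are roots with IC 0 the ratio is undefined and the
#' similarity is defined as 1 for identical terms, else 0.
#'
#' @param graph an [annotated_go_graph()].
#' @param x,y term ids with defined IC.
#' @return similarity in `[0, 1]`.
#' @export
go_term_similarity <- function(graph, x, y) {
  ic_x <- information_content(graph, x)
  ic_y <- information_content(graph, y)
  if (ic_x + ic_y == 0) return(if (x == y) 1 else 0)
  lh <- lca_hcd(graph, x, y)
  ic_l <- if (length(lh$L)) max(graph$ic[lh$L]) else 0
  ic_h <- if (length(lh$H)) max(graph$ic[lh$H]) else 0
  min(1, (ic_l + ic_h) / (ic_x + ic_y))
}

#' Hypergeometric surprise weight of a GO term for a miRNA
#'
#' With `N` background genes, `M` of them annotated to term x, and `n`
#' targets of the miRNA of which `k` carry the annotation, the weight is
#' `-ln P(X >= k)` for hypergeometric X -- the upper-tail surprise of
#' observing at least `k` annotated targets. Zero when `k = 0`.
#'
#' @param N background gene count.
#' @param M genes annotated to the term.
#' @param n miRNA target count.
#' @param k annotated targets.
#' @return non-negative weight in nats.
#' @export
term_weight <- function(N, M, n, k) {
  if (M > N || n > N || k > min(n, M) || k < 0 || min(N, M, n) < 0) {
    stop("impossible hypergeometric counts: N=", N, " M=", M,
         " n=", n, " k=", k)
  }
  if (k == 0) return(0)
  -stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE)
}

#' GO term weights for one miRNA's target set
#'
#' Restricts the targets to the annotated background and weights every
#' term hit by at least one target with [term_weight()].
#'
#' @param graph an [annotated_go_graph()].
#' @param targets character vector of target gene ids.
#' @return a `term_weighting`: list with `weights` (named numeric over
#'   terms with positive weight), `target_count` (n after background
#'   restriction) and `overlap_counts`.
#' @export
term_weighting <- function(graph, targets) {
  targets <- intersect(unique(targets), graph$background)
  if (length(targets) == 0L) {
    stop("no target gene is in the annotated background")
  }
  N <- length(graph$background)
  n <- length(targets)
  k <- vapply(graph$gene_sets,
              function(g) length(intersect(g, targets)), 1L)
  k <- k[k > 0]
  weights <- vapply(names(k), function(x) {
    term_weight(N, length(graph$gene_sets[[x]]), n, k[[x]])
  }, 1.0)
  weights <- weights[weights > 0]
  structure(list(weights = weights, target_count = n, overlap_counts = k),
            class = "term_weighting")
}

#' GO-annotation similarity between two miRNAs
#'
#' Best-match weighted aggregation of GO term similarities between the
#' two miRNAs' weighted term sets. Each direction scores
#' `sqrt( sum_x (Sim(x, B) * w_x)^2 / sum_x w_x^2 )` with
#' `Sim(x, B) = max_y Sim(x, y)` over the other miRNA's terms; the two
#' directions are averaged. Equal term sets with any weights give 1;
#' all-zero cross-similarities give 0.
#'
#' @param graph an [annotated_go_graph()].
#' @param weights_q,weights_t [term_weighting()]s of the two miRNAs.
#' @param term_sim optional precomputed term-similarity matrix (a
#'   [sim_matrix()] covering both term sets), to avoid recomputing
#'   [go_term_similarity()] across many miRNA pairs.
#' @return similarity in `[0, 1]`.
#' @export
mirgofs_similarity <- function(graph, weights_q, weights_t,
                               term_sim = NULL) {
  A <- names(weights_q$weights)
  B <- names(weights_t$weights)
  if (length(A) == 0L || length(B) == 0L) {
    stop("miRNA has no positively weighted GO term")
  }
  if (is.null(term_sim)) {
    terms <- union(A, B)
    values <- diag(nrow = length(terms))
    dimnames(values) <- list(terms, terms)
    if (length(terms) > 1) {
      for (i in seq_len(length(terms) - 1L)) {
        for (j in seq(i + 1L, length(terms))) {
          values[i, j] <- values[j, i] <-
            go_term_similarity(graph, terms[[i]], terms[[j]])
        }
      }
    }
    term_sim <- values
  }
  directed <- function(from, to, w) {
    best <- apply(term_sim[from, to, drop = FALSE], 1, max)
    sqrt(sum((best * w)^2) / sum(w^2))
  }
  (directed(A, B, weights_q$weights) + directed(B, A, weights_t$weights)) / 2
}

#' Build the GO-annotation miRNA similarity network
#'
#' Weights every miRNA's target set over the annotated GO graph and
#' scores all pairs with [mirgofs_similarity()]. miRNAs whose targets
#' carry no GO annotation (or only zero-weight terms) are excluded and
#' logged. Term-term similarities are computed once over the union of
#' all used terms.
#'
#' @param targets an [assoc_table()] of miRNA -> target gene pairs.
#' @param dag GO [ontology_dag()].
#' @param annotations gene -> GO term [assoc_table()].
#' @return a [sim_matrix()] over the eligible miRNAs.
#' @export
build_mirsn_goa <- function(targets, dag, annotations) {
  graph <- annotated_go_graph(dag, annotations)
  weightings <- list()
  for (m in names(targets$by_mirna)) {
    w <- tryCatch(term_weighting(graph, targets$by_mirna[[m]]),
                  error = function(e) NULL)
    if (!is.null(w) && length(w$weights) > 0) weightings[[m]] <- w
  }
  excluded <- setdiff(names(targets$by_mirna), names(weightings))
  if (length(excluded)) {
    message("excluded ", length(excluded),
            " miRNA(s) with no annotated, informative target: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  if (length(weightings) == 0L) stop("no eligible miRNA for miRSN-GOA")
  terms <- sort(unique(unlist(lapply(weightings,
                                     function(w) names(w$weights)))))
  tmat <- diag(nrow = length(terms))
  dimnames(tmat) <- list(terms, terms)
  if (length(terms) > 1) {
    for (i in seq_len(length(terms) - 1L)) {
      for (j in seq(i + 1L, length(terms))) {
        tmat[i, j] <- tmat[j, i] <-
          go_term_similarity(graph, terms[[i]], terms[[j]])
      }
    }
  }
  mirnas <- names(weightings)
  n <- length(mirnas)
  values <- diag(nrow = n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        values[i, j] <- values[j, i] <- mirgofs_similarity(
          graph, weightings[[i]], weightings[[j]], term_sim = tmat)
      }
    }
  }
  sim_matrix(values, mirnas)
}
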