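# Seeded generators for every input the pipeline consumes. Each
# generator draws from its own named pseudo-random stream derived from
# (seed, stream name), so adding a generator never perturbs the draws
# of another. All generators are pure functions of their arguments.

stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 2654435 + h) %% .Machine$integer.max)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, name))
  expr
}

#' Generate a random ontology DAG
#'
#' Terms are inserted in topological order; each new term attaches to
#' 1..`max_parents` uniformly chosen earlier terms, so the graph is
#' acyclic by construction and has a single root (the first term).
#'
#' @param n_terms number of terms (>= 1).
#' @param max_parents maximum parents per non-root term.
#' @param seed integer seed; identical seeds give identical DAGs.
#' @param prefix id prefix for the generated terms.
#' @return an [ontology_dag()].
#' @export
gen_ontology <- function(n_terms, max_parents = 2L, seed = 1L,
                         prefix = "T") {
  stopifnot(n_terms >= 1, max_parents >= 1)
  terms <- sprintf("%s%03d", prefix, seq_len(n_terms))
  if (n_terms == 1L) {
    return(ontology_dag(character(0), character(0), isolated = terms))
  }
  with_stream(seed, paste0("ontology-", prefix), {
    child <- character(0)
    parent <- character(0)
    for (i in 2:n_terms) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      for (p in sample.int(i - 1L, k)) {
        child <- c(child, terms[[i]])
        parent <- c(parent, terms[[p]])
      }
    }
    ontology_dag(child, parent)
  })
}

#' Generate a random miRNA-annotation association table
#'
#' Bernoulli sampling per (miRNA, annotation) pair at the given
#' density; any miRNA left with no annotation is given one uniformly
#' chosen annotation so every miRNA satisfies downstream preconditions.
#'
#' @param mirnas,annotations character vectors of ids.
#' @param density inclusion probability per pair, in (0, 1].
#' @param seed integer seed.
#' @return an [assoc_table()].
#' @export
gen_associations <- function(mirnas, annotations, density = 0.2,
                             seed = 1L) {
  stopifnot(density > 0, density <= 1)
  with_stream(seed, "associations", {
    grid <- expand.grid(mirna = mirnas, annotation = annotations,
                        stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < density
    pairs <- grid[keep, , drop = FALSE]
    rescue <- setdiff(mirnas, pairs$mirna)
    if (length(rescue)) {
      pairs <- rbind(pairs, data.frame(
        mirna = rescue,
        annotation = sample(annotations, length(rescue), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    assoc_table(pairs$mirna, pairs$annotation)
  })
}

#' Generate a random PPI network
#'
#' Erdos-Renyi sampling at `edge_prob` over `n_genes` proteins; only
#' the largest connected component is retained, as in curated
#' interactome snapshots.
#'
#' @param n_genes number of proteins before component filtering.
#' @param edge_prob edge probability in (0, 1].
#' @param seed integer seed.
#' @param prefix id prefix for the generated proteins.
#' @return a [ppin_graph()].
#' @export
gen_ppin <- function(n_genes, edge_prob = 0.1, seed = 1L, prefix = "G") {
  stopifnot(n_genes >= 2, edge_prob > 0, edge_prob <= 1)
  with_stream(seed, "ppin", {
    genes <- sprintf("%s%03d", prefix, seq_len(n_genes))
    idx <- utils::combn(n_genes, 2)
    keep <- stats::runif(ncol(idx)) < edge_prob
    if (!any(keep)) keep[sample.int(ncol(idx), 1L)] <- TRUE
    g <- ppin_graph(genes[idx[1, keep]], genes[idx[2, keep]])
    comp <- igraph::components(g$graph)
    main <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    sub <- igraph::induced_subgraph(g$graph, main)
    edges <- igraph::as_data_frame(sub, what = "edges")
    ppin_graph(edges$from, edges$to)
  })
}

#' Generate gene -> GO term annotations with true-path closure
#'
#' Each gene gets 1..3 uniformly chosen direct terms; the returned
#' table also contains every ancestor of each direct term (the
#' true-path rule), so any annotated term's ancestors are annotated.
#'
#' @param dag GO [ontology_dag()].
#' @param genes character vector of gene ids.
#' @param seed integer seed.
#' @return an [assoc_table()] of gene -> term pairs.
#' @export
gen_go_annotations <- function(dag, genes, seed = 1L) {
  with_stream(seed, "go-annotations", {
    gene_col <- character(0)
    term_col <- character(0)
    for (g in genes) {
      direct <- sample(dag$terms, sample.int(min(3L, length(dag$terms)), 1L))
      closed <- unique(unlist(lapply(direct, dag_ancestors, dag = dag)))
      gene_col <- c(gene_col, rep(g, length(closed)))
      term_col <- c(term_col, closed)
    }
    assoc_table(gene_col, term_col)
  })
}

#' Generate a planted-module benchmark scenario
#'
#' Emulates the evaluation design for list expansion: a module of
#' functionally coherent miRNAs receives high within-module similarity
#' in two of the three networks (uniform in `[high, high + 0.15]`) and
#' background similarity elsewhere (uniform in `[0.05, low]`); the
#' third network is background-only. The knowledge base holds the
#' module as one set plus random decoy sets, and the input list is
#' half of the module -- so successful expansion must recover unseeded
#' module members and raise the module set's hit rate.
#'
#' @param n_mirnas total miRNAs (default 60).
#' @param module_size planted module size (default 20).
#' @param seed integer seed.
#' @param high within-module similarity floor (default 0.8).
#' @param low background similarity ceiling (default 0.3).
#' @param n_decoys number of decoy knowledge-base sets (default 25).
#' @return list with `networks` (three [sim_matrix()]), `kb`
#'   ([mirna_set_kb()]), `input_list`, `module` (ground-truth members)
#'   and `held_out` (module members not in the input list).
#' @export
gen_planted_scenario <- function(n_mirnas = 60L, module_size = 20L,
                                 seed = 7L, high = 0.8, low = 0.3,
                                 n_decoys = 25L) {
  stopifnot(module_size < n_mirnas, high > low)
  with_stream(seed, "planted-scenario", {
    mirnas <- sprintf("mir-%03d", seq_len(n_mirnas))
    module <- sort(sample(mirnas, module_size))
    background_net <- function() {
      v <- matrix(stats::runif(n_mirnas^2, 0.05, low), n_mirnas)
      v <- (v + t(v)) / 2
      diag(v) <- 1
      dimnames(v) <- list(mirnas, mirnas)
      v
    }
    plant <- function(v) {
      block <- matrix(stats::runif(module_size^2, high, high + 0.15),
                      module_size)
      block <- (block + t(block)) / 2
      v[module, module] <- block
      diag(v) <- 1
      v
    }
    networks <- list(
      da = sim_matrix(plant(background_net()), mirnas),
      goa = sim_matrix(plant(background_net()), mirnas),
      ppi = sim_matrix(background_net(), mirnas)
    )
    decoy_hi <- min(15L, n_mirnas - 1L)
    decoy_lo <- min(8L, decoy_hi)
    decoys <- lapply(seq_len(n_decoys), function(i) {
      list(name = sprintf("decoy-%02d", i), category = "Decoy",
           members = sample(mirnas, sample(decoy_lo:decoy_hi, 1L)))
    })
    kb <- mirna_set_kb(c(list(list(name = "planted-module",
                                   category = "Disease",
                                   members = module)), decoys))
    input_list <- sort(sample(module, module_size %/% 2L))
    list(networks = networks, kb = kb, input_list = input_list,
         module = module, held_out = setdiff(module, input_list))
  })
}
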