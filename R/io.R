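# Readers and writers for the plain-text interchange formats: two-column
# association TSV, child->parent ontology TSV, GMT miRNA-set files and
# one-id-per-line miRNA lists. Comment lines start with "#"; blank lines
# are ignored; ids are opaque case-sensitive strings.

read_clean_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  structure(lines[keep], line_numbers = which(keep))
}

#' Association table between miRNAs and annotations
#'
#' A many-to-many map between miRNA ids and annotation ids (diseases or
#' target genes), with lookups in both directions. Duplicate pairs are
#' collapsed; lookups of absent keys yield the empty set.
#'
#' @param mirna character vector of miRNA ids.
#' @param annotation character vector of annotation ids, same length.
#' @return an `assoc_table` with elements `pairs` (data.frame),
#'   `by_mirna` and `by_annotation` (named lists of character vectors).
#' @examples
#' tab <- assoc_table(c("mir-a", "mir-a", "mir-b"), c("d1", "d1", "d2"))
#' assoc_annotations(tab, "mir-a")
#' @export
assoc_table <- function(mirna, annotation) {
  mirna <- as.character(mirna)
  annotation <- as.character(annotation)
  stopifnot(length(mirna) == length(annotation))
  pairs <- unique(data.frame(mirna = mirna, annotation = annotation,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$mirna, pairs$annotation), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    by_mirna = split(pairs$annotation, pairs$mirna),
    by_annotation = split(pairs$mirna, pairs$annotation)
  ), class = "assoc_table")
}

#' @export
print.assoc_table <- function(x, ...) {
  cat("assoc_table:", nrow(x$pairs), "pairs,", length(x$by_mirna),
      "miRNAs,", length(x$by_annotation), "annotations\n")
  invisible(x)
}

#' Annotations of one miRNA
#' @param tab an [assoc_table()].
#' @param id miRNA id.
#' @return character vector (empty if the id is absent).
#' @export
assoc_annotations <- function(tab, id) {
  out <- tab$by_mirna[[id]]
  if (is.null(out)) character(0) else out
}

#' miRNAs carrying one annotation
#' @param tab an [assoc_table()].
#' @param id annotation id.
#' @return character vector (empty if the id is absent).
#' @export
assoc_mirnas <- function(tab, id) {
  out <- tab$by_annotation[[id]]
  if (is.null(out)) character(0) else out
}

#' Read a two-column association TSV
#'
#' Each non-comment line is `mirna<TAB>annotation`; extra columns are
#' ignored. Duplicate pairs are deduplicated and the pair count logged.
#'
#' @param path file path.
#' @return an [assoc_table()].
#' @export
read_association_table <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("no association records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed association line ", attr(lines, "line_numbers")[bad[[1]]],
         " in ", path, " (need >= 2 tab-separated fields)")
  }
  tab <- assoc_table(vapply(fields, `[[`, "", 1L),
                     vapply(fields, `[[`, "", 2L))
  message("read ", nrow(tab$pairs), " association pairs from ", path)
  tab
}

#' Write an association table to TSV
#' @param tab an [assoc_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(tab, path) {
  writeLines(paste(tab$pairs$mirna, tab$pairs$annotation, sep = "\t"), path)
  invisible(path)
}

#' Ontology DAG of terms
#'
#' A directed acyclic graph of ontology terms (diseases on a MeSH-like
#' hierarchy, or GO terms) with edges pointing child -> parent. Roots
#' are the terms with no parent. Construction validates acyclicity and
#' reports one offending cycle when found.
#'
#' @param child,parent character vectors of equal length; each element
#'   pair is one child -> parent edge.
#' @param isolated optional character vector of terms with no edges.
#' @return an `ontology_dag` with elements `graph` (igraph, edges
#'   child -> parent), `terms` and `roots` (character vectors).
#' @examples
#' dag <- ontology_dag(c("b", "c"), c("a", "a"))
#' dag$roots
#' @export
ontology_dag <- function(child, parent, isolated = character(0)) {
  child <- as.character(child)
  parent <- as.character(parent)
  stopifnot(length(child) == length(parent))
  if (any(child == parent)) {
    stop("term is its own parent: ", child[child == parent][[1]])
  }
  terms <- unique(c(child, parent, isolated))
  g <- igraph::graph_from_data_frame(
    unique(data.frame(from = child, to = parent)),
    directed = TRUE, vertices = terms)
  if (length(child) && !igraph::is_dag(g)) {
    cyc <- igraph::girth(g)$circle
    stop("ontology contains a cycle: ",
         paste(names(cyc), collapse = " -> "))
  }
  roots <- terms[igraph::degree(g, mode = "out") == 0]
  structure(list(graph = g, terms = terms, roots = roots),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms,",
      igraph::ecount(x$graph), "edges, roots:",
      paste(utils::head(x$roots, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Ancestors of a term (inclusive)
#'
#' All terms reachable from `term` along child -> parent edges,
#' including `term` itself.
#'
#' @param dag an [ontology_dag()].
#' @param term term id.
#' @return character vector of term ids.
#' @export
dag_ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("term not in ontology: ", term)
  names(igraph::subcomponent(dag$graph, term, mode = "out"))
}

#' Descendants of a term (inclusive)
#' @inheritParams dag_ancestors
#' @return character vector of term ids.
#' @export
dag_descendants <- function(dag, term) {
  if (!term %in% dag$terms) stop("term not in ontology: ", term)
  names(igraph::subcomponent(dag$graph, term, mode = "in"))
}

#' Read an ontology edge TSV
#'
#' Each line is `child<TAB>parent`. Roots are inferred (terms that never
#' appear as a child of anything); the graph is validated acyclic.
#'
#' @param path file path.
#' @return an [ontology_dag()].
#' @export
read_ontology <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("no ontology edges in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed ontology line ", attr(lines, "line_numbers")[bad[[1]]],
         " in ", path)
  }
  ontology_dag(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
}

#' Write ontology edges to TSV
#' @param dag an [ontology_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(dag, path) {
  edges <- igraph::as_data_frame(dag$graph, what = "edges")
  writeLines(paste(edges$from, edges$to, sep = "\t"), path)
  invisible(path)
}

#' miRNA-set knowledge base
#'
#' Named miRNA sets with category labels (e.g. disease sets vs function
#' sets), the container behind GMT files. The universe is the union of
#' all members and is the reference collection size N of the
#' hypergeometric test.
#'
#' @param sets a list; each element a list with `name`, `category` and
#'   `members` (character vector, deduplicated here).
#' @return a `mirna_set_kb` with elements `sets` and `universe`.
#' @export
mirna_set_kb <- function(sets) {
  if (length(sets) == 0L) stop("knowledge base has no sets")
  sets <- lapply(sets, function(s) {
    s$members <- unique(as.character(s$members))
    if (length(s$members) == 0L) stop("set with 0 members: ", s$name)
    s
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in knowledge base")
  }
  structure(list(sets = sets,
                 universe = sort(unique(unlist(lapply(sets, `[[`, "members"))))),
            class = "mirna_set_kb")
}

#' @export
print.mirna_set_kb <- function(x, ...) {
  cat("mirna_set_kb:", length(x$sets), "sets,",
      length(x$universe), "miRNAs in universe\n")
  invisible(x)
}

#' Read a GMT knowledge base
#'
#' Standard GMT: `name<TAB>category<TAB>member1<TAB>member2...`. The
#' second field (usually a description URL in gene-set GMTs) carries the
#' set category here. Duplicate members within a line are deduplicated.
#'
#' @param path file path.
#' @return a [mirna_set_kb()].
#' @export
read_gmt <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("no sets in GMT file ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", attr(lines, "line_numbers")[bad[[1]]],
         " in ", path, " (need name, category and >= 1 member)")
  }
  mirna_set_kb(lapply(fields, function(f) {
    list(name = f[[1]], category = f[[2]], members = f[-(1:2)])
  }))
}

#' Write a knowledge base to GMT
#' @param kb a [mirna_set_kb()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(kb, path) {
  writeLines(vapply(kb$sets, function(s) {
    paste(c(s$name, s$category, s$members), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a plain-text miRNA list (one id per line)
#' @param path file path.
#' @return character vector of unique ids in file order.
#' @export
read_mirna_list <- function(path) {
  ids <- trimws(read_clean_lines(path))
  if (length(ids) == 0L) stop("empty miRNA list: ", path)
  unique(ids)
}

#' Apply an id mapping to an association table
#'
#' Preprocessing hook for, e.g., mature -> precursor miRNA id
#' conversion. The mapping is a two-column TSV `from<TAB>to`; miRNA ids
#' with no mapping entry are kept unchanged.
#'
#' @param tab an [assoc_table()].
#' @param mapping_path two-column TSV of id translations.
#' @return a remapped [assoc_table()].
#' @export
remap_mirna_ids <- function(tab, mapping_path) {
  map_tab <- read_association_table(mapping_path)
  map <- stats::setNames(map_tab$pairs$annotation, map_tab$pairs$mirna)
  from <- tab$pairs$mirna
  hit <- from %in% names(map)
  from[hit] <- unname(map[from[hit]])
  assoc_table(from, tab$pairs$annotation)
}
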