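#' Similarity between a disease and a disease set
#'
#' The best-match rule: the maximum pairwise semantic similarity between
#' `d` and any member of `D`.
#'
#' @param d disease id.
#' @param D non-empty character vector of disease ids.
#' @param S a [sim_matrix()] of disease similarities covering `d` and
#'   all of `D`.
#' @return similarity in `[0, 1]`.
#' @export
disease_to_set_similarity <- function(d, D, S) {
  if (length(D) == 0L) stop("disease set is empty; max undefined")
  missing <- setdiff(c(d, D), sim_ids(S))
  if (length(missing)) {
    stop("diseases absent from similarity matrix: ",
         paste(missing, collapse = ", "))
  }
  max(S[d, D])
}

#' miRNA functional similarity from shared disease associations
#'
#' The disease-association similarity of two miRNAs: every disease of
#' each miRNA is matched to its best counterpart in the other miRNA's
#' disease set, and the matches are averaged over both directions:
#' `(sum_i S(d1i, D2) + sum_j S(d2j, D1)) / (m + n)`. Symmetric by
#' construction and in `[0, 1]` whenever `S` is.
#'
#' @param m1,m2 miRNA ids; both must have at least one association
#'   whose disease is present in `S`.
#' @param assoc an [assoc_table()] of miRNA-disease pairs.
#' @param S disease [sim_matrix()].
#' @return similarity in `[0, 1]`.
#' @export
misim <- function(m1, m2, assoc, S) {
  D1 <- intersect(assoc_annotations(assoc, m1), sim_ids(S))
  D2 <- intersect(assoc_annotations(assoc, m2), sim_ids(S))
  if (length(D1) == 0L) stop("miRNA has no usable disease associations: ", m1)
  if (length(D2) == 0L) stop("miRNA has no usable disease associations: ", m2)
  cross <- S[D1, D2, drop = FALSE]
  (sum(apply(cross, 1, max)) + sum(apply(cross, 2, max))) /
    (length(D1) + length(D2))
}

#' Build the disease-association miRNA similarity network
#'
#' Computes the disease semantic similarity matrix over every disease
#' that is both associated with some miRNA and present in the ontology,
#' then scores all miRNA pairs with [misim()]. Associations to diseases
#' absent from the ontology are dropped (logged); a miRNA left with no
#' disease is excluded from the network.
#'
#' @param assoc an [assoc_table()] of miRNA-disease pairs.
#' @param ontology disease [ontology_dag()].
#' @param decay semantic decay factor, see [dag_view()].
#' @return a [sim_matrix()] over the eligible miRNAs.
#' @export
build_mirsn_da <- function(assoc, ontology, decay = 0.5) {
  usable <- lapply(assoc$by_mirna, intersect, y = ontology$terms)
  dropped <- sum(lengths(assoc$by_mirna)) - sum(lengths(usable))
  if (dropped > 0) {
    message("dropped ", dropped, " associations to diseases absent from ",
            "the ontology")
  }
  usable <- usable[lengths(usable) > 0]
  if (length(usable) == 0L) {
    stop("no miRNA has any association with an ontology disease")
  }
  excluded <- setdiff(names(assoc$by_mirna), names(usable))
  if (length(excluded)) {
    message("excluded ", length(excluded),
            " miRNA(s) with no ontology-covered disease: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  diseases <- sort(unique(unlist(usable)))
  S <- disease_similarity_matrix(ontology, diseases, decay)
  mirnas <- names(usable)
  n <- length(mirnas)
  values <- diag(nrow = n)
  if (n > 1) {
    best <- function(D1, D2) {
      cross <- S[D1, D2, drop = FALSE]
      (sum(apply(cross, 1, max)) + sum(apply(cross, 2, max))) /
        (length(D1) + length(D2))
    }
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        values[i, j] <- values[j, i] <- best(usable[[i]], usable[[j]])
      }
    }
  }
  sim_matrix(values, mirnas)
}
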