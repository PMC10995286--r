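#' Labeled similarity matrix
#'
#' A dense symmetric similarity matrix over a set of labeled entities
#' (miRNAs or diseases). This is the container for the three miRNA
#' similarity networks (disease-association, GO-annotation, PPI) and for
#' any fusion of them.
#'
#' Invariants enforced at construction: square with unique ids on both
#' margins, symmetric, unit diagonal, all entries finite and
#' non-negative. Asymmetries up to `1e-9` (numerical noise from
#' pairwise computation) are symmetrized by averaging; anything larger
#' is an error.
#'
#' @param values numeric matrix of similarity scores in `[0, 1]`.
#' @param ids character vector of entity identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @return a `sim_matrix`: a numeric matrix with ids as dimnames and
#'   class `c("sim_matrix", "matrix", "array")`.
#' @examples
#' m <- sim_matrix(matrix(c(1, 0.4, 0.4, 1), 2), c("mir-a", "mir-b"))
#' m["mir-a", "mir-b"]
#' @export
sim_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("similarity matrix must be square, got ", nrow(values), "x",
         ncol(values))
  }
  if (is.null(ids)) stop("entity ids are required (no rownames found)")
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) {
    stop("length(ids) must equal nrow(values)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("similarity values must all be finite")
  if (any(values < 0)) stop("similarity values must be non-negative")
  delta <- max(abs(values - t(values)))
  if (delta > 1e-9) {
    stop("matrix is asymmetric beyond tolerance: worst |delta| = ",
         format(delta))
  }
  if (delta > 0) {
    values <- (values + t(values)) / 2
    message("symmetrized similarity matrix (worst |delta| = ",
            format(delta), ")")
  }
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  class(values) <- c("sim_matrix", "matrix", "array")
  values
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat("sim_matrix:", nrow(x), "entities\n")
  n <- min(nrow(x), 6L)
  print(unclass(x)[seq_len(n), seq_len(n), drop = FALSE], digits = 4)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more)\n", sep = "")
  invisible(x)
}

#' Entity ids of a similarity matrix
#' @param m a [sim_matrix()].
#' @return character vector of ids in matrix order.
#' @export
sim_ids <- function(m) rownames(m)

#' Write a similarity matrix to TSV
#'
#' Tab-separated with an id header row and an id first column, `.`
#' decimal mark and 12 significant digits, so that write/read round
#' trips are stable to well below 1e-12.
#'
#' @param m a [sim_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_matrix <- function(m, path) {
  stopifnot(inherits(m, "sim_matrix"))
  ids <- sim_ids(m)
  body <- apply(unclass(m), 1, function(row) {
    paste(formatC(row, format = "g", digits = 12), collapse = "\t")
  })
  lines <- c(paste(c("id", ids), collapse = "\t"), paste(ids, body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a similarity matrix from TSV
#'
#' Inverse of [write_sim_matrix()]. Symmetry is re-validated on read:
#' asymmetries beyond 1e-9 abort with the worst deviation.
#'
#' @param path file written by [write_sim_matrix()].
#' @return a [sim_matrix()].
#' @export
read_sim_matrix <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  n <- length(ids)
  values <- matrix(NA_real_, n, n)
  row_ids <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n + 1L) {
      stop("matrix row ", i, " has ", length(fields) - 1L,
           " values, expected ", n)
    }
    row_ids[[i]] <- fields[[1]]
    values[i, ] <- as.numeric(fields[-1])
  }
  if (!identical(row_ids, ids)) {
    stop("matrix row ids do not match column ids")
  }
  sim_matrix(values, ids)
}
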