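#' Correlation matrices that inform the null model
#'
#' A correlation matrix `V` relates the rows or the columns of an incidence
#' matrix: phylogenetic relatedness of prey, spatial proximity of islands,
#' shared group membership, and so on. Builders in this file all return a
#' `correlation_matrix`: a labelled, symmetric, positive semi-definite
#' matrix with unit diagonal and a `provenance` attribute recording how it
#' was made.
#'
#' @name correlation_structures
NULL

new_correlation_matrix <- function(values, labels, provenance) {
  dimnames(values) <- list(labels, labels)
  structure(values,
            provenance = provenance,
            class = c("correlation_matrix", "matrix", "array"))
}

#' Validate a correlation matrix
#'
#' Checks symmetry, unit diagonal, off-diagonals within `[-1, 1]` and
#' positive semi-definiteness up to a numerical tolerance (smallest
#' eigenvalue at least `-1e-8`).
#'
#' @param V matrix to check.
#' @return `V`, invisibly; errors otherwise.
#' @export
validate_correlation <- function(V) {
  v <- unclass(V)
  if (nrow(v) != ncol(v)) abort("correlation matrix must be square")
  if (max(abs(v - t(v))) > 1e-8) abort("correlation matrix must be symmetric")
  if (max(abs(diag(v) - 1)) > 1e-8) abort("correlation matrix must have unit diagonal")
  if (max(abs(v)) > 1 + 1e-8) abort("correlation entries must lie in [-1, 1]")
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev))) {
    abort(sprintf("correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                  min(ev)))
  }
  invisible(V)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("<correlation_matrix> %d x %d [%s]\n", nrow(x), ncol(x),
              pr$builder %||% "unknown"))
  print(unclass(x)[seq_len(min(nrow(x), 8L)), seq_len(min(ncol(x), 8L)), drop = FALSE])
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Constant (uninformative) correlation structure
#'
#' Every element equal to 1: no differences at all between the elements.
#' A null model informed by this structure behaves exactly like the
#' uninformed swap model, which makes it a useful control.
#'
#' @param labels character vector of element labels (length >= 2).
#' @return a `correlation_matrix` flagged `"uninformative"` in provenance.
#' @export
constant_correlation <- function(labels) {
  k <- length(labels)
  if (k < 2L) abort("need at least two labels")
  new_correlation_matrix(matrix(1, k, k), labels,
                         list(builder = "constant", uninformative = TRUE))
}

#' Group-membership correlation structure
#'
#' Correlation 1 within a group and 0 between groups, with a small nugget
#' `eta` subtracted from the within-group off-diagonals so the matrix is
#' not perfectly correlated (and therefore not singular after
#' regularization).
#'
#' @param group_labels vector assigning each element to a group; element
#'   labels are taken from `names(group_labels)` if present.
#' @param eta nugget in `[0, 1)`; default 0.01.
#' @return a `correlation_matrix`.
#' @export
group_correlation <- function(group_labels, eta = 0.01) {
  k <- length(group_labels)
  if (k < 2L) abort("need at least two elements")
  check_nugget(eta)
  labels <- names(group_labels) %||% paste0("e", seq_len(k))
  same <- outer(group_labels, group_labels, "==") * 1
  v <- same * (1 - eta)
  diag(v) <- 1
  new_correlation_matrix(v, labels,
                         list(builder = "group", eta = eta,
                              groups = as.character(group_labels)))
}

check_nugget <- function(eta) {
  if (length(eta) != 1L || !is.finite(eta) || eta < 0 || eta >= 1) {
    abort("nugget eta must be a single value in [0, 1)")
  }
}

#' Exponential (distance-decay) correlation structure
#'
#' The standard way to encode spatial autocorrelation or trait similarity:
#' correlation decays exponentially with the Euclidean distance between
#' trait vectors, `v_ij = (1 - eta) * exp(-d_ij / d_max)` off the diagonal,
#' where `d_max` is the largest pairwise distance (so the decay is scale
#' free) and `eta` is the nugget keeping coincident elements from being
#' perfectly correlated.
#'
#' @param traits numeric vector, matrix, or data frame of coordinates /
#'   trait values, one row per element; labels from names/rownames.
#' @param eta nugget in `[0, 1)`; default 0.01.
#' @return a `correlation_matrix`.
#' @export
#' @examples
#' x <- c(a = 0, b = 1, c = 3)
#' exponential_correlation(x, eta = 0)
exponential_correlation <- function(traits, eta = 0.01) {
  check_nugget(eta)
  if (is.data.frame(traits)) traits <- as.matrix(traits)
  if (!is.matrix(traits)) {
    labels <- names(traits) %||% paste0("e", seq_along(traits))
    traits <- matrix(as.numeric(traits), ncol = 1L)
  } else {
    labels <- rownames(traits) %||% paste0("e", seq_len(nrow(traits)))
  }
  if (!all(is.finite(traits))) abort("traits must be finite")
  k <- nrow(traits)
  if (k < 2L) abort("need at least two elements")
  d <- as.matrix(stats::dist(traits))
  d_max <- max(d)
  if (d_max == 0) abort("degenerate distances: all trait vectors are identical")
  v <- (1 - eta) * exp(-d / d_max)
  diag(v) <- 1
  new_correlation_matrix(v, labels,
                         list(builder = "exponential", eta = eta, d_max = d_max,
                              form = "v_ij = (1 - eta) * exp(-d_ij / d_max)"))
}

#' Phylogenetic correlation structure
#'
#' Builds the Brownian-motion variance-covariance matrix of a rooted,
#' branch-length-bearing tree (shared root-to-MRCA branch length between
#' each pair of tips) and standardizes it to a correlation matrix,
#' `V_ij = C_ij / sqrt(C_ii * C_jj)`. The scale the covariance carries is
#' absorbed by the mixed model's per-row variance, so only the correlation
#' shape matters here.
#'
#' @param tree an [ape::phylo] object, a newick string, or a path to a
#'   newick file.
#' @param tip_labels optional subset/ordering of tips; defaults to all tips
#'   in the tree's order.
#' @return a `correlation_matrix` ordered by `tip_labels`.
#' @export
phylogenetic_correlation <- function(tree, tip_labels = NULL) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1L && file.exists(tree)) {
      ape::read.tree(file = tree)
    } else {
      ape::read.tree(text = tree)
    }
    if (is.null(tree)) abort("could not parse newick tree")
  }
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object or newick input")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  tip_labels <- tip_labels %||% tree$tip.label
  missing <- setdiff(tip_labels, tree$tip.label)
  if (length(missing)) {
    abort(paste0("tips not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(tip_labels) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, tip_labels)
  }
  v <- ape::vcv(tree, corr = TRUE)[tip_labels, tip_labels]
  # guard tiny asymmetries from floating point
  v <- (v + t(v)) / 2
  diag(v) <- 1
  new_correlation_matrix(v, tip_labels, list(builder = "phylogenetic"))
}

#' Symmetrically permute a correlation matrix
#'
#' The misinformed null model's scrambling step: one uniformly random
#' permutation applied to both rows and columns, so the matrix keeps its
#' eigenvalues and the multiset of its entries but the identities of the
#' elements are shuffled relative to the data. Labels stay in place; it is
#' the correlation content that moves.
#'
#' @param V a `correlation_matrix`.
#' @param seed optional integer seed for reproducibility.
#' @return a `correlation_matrix` with updated provenance.
#' @export
permute_correlation <- function(V, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(V)
  perm <- sample.int(k)
  v <- unclass(V)[perm, perm]
  new_correlation_matrix(v, rownames(V),
                         c(attr(V, "provenance"),
                           list(permuted = TRUE, permutation = perm)))
}

#' Repair a singular correlation matrix
#'
#' The constant and group structures are exactly singular; the mixed model
#' needs an invertible covariance. Near-zero (or tiny negative, from
#' floating point) eigenvalues are clipped at zero, `jitter` is added to
#' the diagonal, and the diagonal is rescaled back to 1. A genuinely
#' indefinite matrix (smallest eigenvalue below `-1e-6`) is an input
#' error, not a numerical artifact, and is rejected.
#'
#' @param V symmetric matrix.
#' @param jitter diagonal inflation; default `1e-8`.
#' @return a positive-definite `correlation_matrix`; returned unchanged if
#'   already comfortably positive definite.
#' @export
regularize_correlation <- function(V, jitter = 1e-8) {
  v <- unclass(V)
  if (max(abs(v - t(v))) > 1e-8) abort("correlation matrix must be symmetric")
  labels <- rownames(v) %||% paste0("e", seq_len(nrow(v)))
  e <- eigen((v + t(v)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(1, max(e$values))) {
    abort(sprintf("matrix is indefinite (min eigenvalue %.3g); refusing to repair",
                  min(e$values)))
  }
  if (min(e$values) > 1e-10 * max(e$values) && min(e$values) > 0) {
    if (inherits(V, "correlation_matrix")) return(V)
    return(new_correlation_matrix(v, labels, list(builder = "as-is")))
  }
  lam <- pmax(e$values, 0)
  v2 <- e$vectors %*% (lam * t(e$vectors))
  v2 <- v2 + diag(jitter, nrow(v2))
  s <- 1 / sqrt(diag(v2))
  v2 <- v2 * tcrossprod(s)
  v2 <- (v2 + t(v2)) / 2
  diag(v2) <- 1
  new_correlation_matrix(v2, labels,
                         c(attr(V, "provenance"),
                           list(regularized = TRUE, jitter = jitter)))
}

#' Read/write a labelled correlation matrix CSV
#'
#' @param path file path (labels in header and first column).
#' @return a validated `correlation_matrix`.
#' @export
read_correlation <- function(path) {
  df <- read.table(path, header = TRUE, sep = detect_sep(path), row.names = 1L,
                   check.names = FALSE)
  v <- as.matrix(df)
  V <- new_correlation_matrix(v, rownames(v), list(builder = "file", path = path))
  validate_correlation(V)
  V
}

#' @param V a `correlation_matrix`.
#' @rdname read_correlation
#' @export
write_correlation <- function(V, path) {
  out <- cbind(data.frame(" " = rownames(V), check.names = FALSE),
               as.data.frame(unclass(V), check.names = FALSE))
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
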