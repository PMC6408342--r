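#' Construct a binary incidence matrix
#'
#' An incidence matrix records presence/absence of a relation between two
#' labelled sets: species across sites, predators against prey, hosts against
#' parasites. It is the object the null models randomize and the structure
#' metrics measure.
#'
#' @param values a numeric or integer matrix containing only 0s and 1s, with
#'   at least two rows and two columns. Entries other than 0/1 are rejected,
#'   never coerced: the methods here are defined on presence/absence only and
#'   silent coercion hides data errors.
#' @param row_labels,col_labels optional character vectors of unique labels;
#'   defaults to existing dimnames, or `r1..rn` / `c1..cm`.
#'
#' @return an `incidence_matrix`: a base matrix with dimnames and class
#'   attribute, so that all of base R's matrix arithmetic keeps working.
#' @export
#' @examples
#' A <- incidence_matrix(rbind(c(1, 0), c(0, 1)))
#' rowSums(A)
incidence_matrix <- function(values, row_labels = NULL, col_labels = NULL) {
  values <- as.matrix(values)
  if (is.null(row_labels)) {
    row_labels <- rownames(values) %||% paste0("r", seq_len(nrow(values)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(values) %||% paste0("c", seq_len(ncol(values)))
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(row_labels, col_labels)
  validate_incidence(values)
  structure(values, class = c("incidence_matrix", "matrix", "array"))
}

validate_incidence <- function(values) {
  if (nrow(values) < 2L || ncol(values) < 2L) {
    abort("an incidence matrix needs at least two rows and two columns")
  }
  if (anyNA(values) || !all(values %in% c(0, 1))) {
    abort("incidence matrix entries must be exactly 0 or 1 (no coercion is applied)")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate row labels")
  if (anyDuplicated(colnames(values))) abort("duplicate column labels")
  invisible(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a directed food web
#'
#' A food web is a square binary adjacency matrix over one species set.
#' The direction convention is fixed throughout the package:
#' `values[i, j] = 1` means consumer `i` eats resource `j` (energy flows
#' from column to row). The two estimation perspectives — the predator's
#' diet and the prey's consumers — depend on this convention, so it is
#' worth stating prominently.
#'
#' @param values square binary matrix; rows = consumers, columns = resources.
#' @param labels unique species labels (shared by rows and columns).
#' @return a `food_web` (also an `incidence_matrix`).
#' @export
#' @examples
#' W <- food_web(rbind(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0)),
#'               labels = c("fish", "insect", "alga"))
#' classify_links(W)
food_web <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("a food web adjacency matrix must be square")
  if (is.null(labels)) {
    labels <- rownames(values) %||% colnames(values) %||% paste0("sp", seq_len(nrow(values)))
  }
  A <- incidence_matrix(values, row_labels = labels, col_labels = labels)
  class(A) <- c("food_web", class(A))
  A
}

#' Coerce an incidence matrix to a food web
#'
#' @param A an `incidence_matrix` with identical row and column labels.
#' @return a `food_web`.
#' @export
as_food_web <- function(A) {
  if (inherits(A, "food_web")) return(A)
  if (!identical(rownames(A), colnames(A))) {
    abort("cannot interpret as food web: row and column labels differ")
  }
  food_web(unclass(A))
}

#' @export
print.incidence_matrix <- function(x, ...) {
  kind <- if (inherits(x, "food_web")) "food_web" else "incidence_matrix"
  cat(sprintf("<%s> %d x %d, %d links (fill %.3f)\n",
              kind, nrow(x), ncol(x), sum(x), mean(x)))
  print(unclass(x)[seq_len(min(nrow(x), 10L)), seq_len(min(ncol(x), 10L)), drop = FALSE])
  if (nrow(x) > 10L || ncol(x) > 10L) cat("...\n")
  invisible(x)
}

#' Classify the links of a food web
#'
#' Decomposes the 1-entries of a directed food web into the three link
#' classes the food-web randomization preserves: cannibal self-loops,
#' double (reciprocal) links, and single (unreciprocated) links. The
#' decomposition is exact and disjoint:
#' `n_single + 2 * n_double + n_cannibal == sum(W)`.
#'
#' @param W a `food_web`.
#' @return a list with counts `n_single`, `n_double`, `n_cannibal` and
#'   tibble `degrees` of per-species in/out degrees.
#' @export
classify_links <- function(W) {
  W <- as_food_web(W)
  v <- unclass(W)
  diag_links <- diag(v)
  off <- v
  diag(off) <- 0
  mutual <- off * t(off)
  n_cannibal <- sum(diag_links)
  n_double <- sum(mutual) / 2
  n_single <- sum(off) - sum(mutual)
  degrees <- tibble(
    species = rownames(v),
    out_degree = as.integer(rowSums(v)),
    in_degree = as.integer(colSums(v))
  )
  list(
    n_single = as.integer(n_single),
    n_double = as.integer(n_double),
    n_cannibal = as.integer(n_cannibal),
    degrees = degrees
  )
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an incidence matrix from disk
#'
#' Two plain-text formats are supported. `matrix_csv` is a labelled matrix:
#' column labels in the header, row labels in the first column, comma- or
#' tab-delimited (auto-detected). `edge_list` is a header-less two-column
#' file (`row_label, col_label`), one link per line; the matrix is built
#' over the union of labels in first-appearance order. Labels are opaque
#' strings.
#'
#' @param path file path.
#' @param format `"matrix_csv"` or `"edge_list"`.
#' @param food_web if `TRUE`, return a `food_web` (matrix must be square
#'   with matching labels; edge lists use the union of both columns' labels).
#' @return an `incidence_matrix` or `food_web`.
#' @export
read_incidence <- function(path, format = c("matrix_csv", "edge_list"),
                           food_web = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  sep <- detect_sep(path)
  if (format == "matrix_csv") {
    df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                     check.names = FALSE, colClasses = NA)
    values <- as.matrix(df)
    if (anyNA(values) || !is.numeric(values) || !all(values %in% c(0, 1))) {
      abort("matrix_csv contains non-binary cells; entries must be 0 or 1")
    }
  } else {
    df <- read.table(path, header = FALSE, sep = sep, colClasses = "character")
    if (ncol(df) != 2L) abort("edge_list must have exactly two columns")
    key <- paste(df[[1]], df[[2]], sep = "\r")
    if (anyDuplicated(key)) {
      abort(paste0("duplicate link in edge list: ",
                   sub("\r", " -> ", key[duplicated(key)][1])))
    }
    if (food_web) {
      labs <- unique(c(df[[1]], df[[2]]))
      rl <- cl <- labs
    } else {
      rl <- unique(df[[1]])
      cl <- unique(df[[2]])
    }
    values <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
    values[cbind(match(df[[1]], rl), match(df[[2]], cl))] <- 1
  }
  if (food_web) food_web(values) else incidence_matrix(values)
}

#' Write an incidence matrix to disk
#'
#' Round-trips exactly with [read_incidence()] for `matrix_csv`. The
#' `edge_list` format stores links only, so rows or columns without any
#' link are lost on re-reading; a warning is emitted when that happens.
#'
#' @param A an `incidence_matrix`.
#' @inheritParams read_incidence
#' @return the path, invisibly.
#' @export
write_incidence <- function(A, path, format = c("matrix_csv", "edge_list")) {
  format <- match.arg(format)
  if (format == "matrix_csv") {
    df <- as.data.frame(unclass(A), check.names = FALSE)
    out <- cbind(data.frame(" " = rownames(A), check.names = FALSE), df)
    write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    if (any(rowSums(A) == 0) || any(colSums(A) == 0)) {
      warn("edge_list format drops rows/columns with no links; round-trip will not be exact")
    }
    idx <- which(unclass(A) == 1, arr.ind = TRUE)
    df <- data.frame(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]])
    write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}
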