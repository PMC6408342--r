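# --- three-node motif machinery -------------------------------------------
#
# A triple of nodes induces a subdigraph coded by 6 bits (the six possible
# directed edges). Isomorphism classes are found by taking the minimum code
# over the 6 vertex permutations; the 13 connected classes are labelled by
# the conventional triad nomenclature (M-A-N: counts of mutual, asymmetric
# and null dyads, plus orientation letters). Self-loops are excluded from
# classification; they constrain the randomization instead.
#
# Edge bit order for nodes (x, y, z):
#   1: x->y  2: y->x  4: x->z  8: z->x  16: y->z  32: z->y

triad_code <- function(edges) {
  # edges: 2-column matrix of directed edges on nodes 1:3
  bit <- c("12" = 1, "21" = 2, "13" = 4, "31" = 8, "23" = 16, "32" = 32)
  sum(bit[paste0(edges[, 1], edges[, 2])])
}

# representative edge lists for the 13 connected triad classes, in the
# conventional census order (the order of the full 16-class census with the
# three disconnected classes 003, 012, 102 removed)
triad_representatives <- function() {
  list(
    "021D" = rbind(c(2, 1), c(2, 3)),          # out-star: one node points to both
    "021U" = rbind(c(1, 2), c(3, 2)),          # in-star: both point to one node
    "021C" = rbind(c(1, 2), c(2, 3)),          # directed path
    "111D" = rbind(c(1, 2), c(2, 1), c(3, 1)), # mutual dyad + edge into it
    "111U" = rbind(c(1, 2), c(2, 1), c(1, 3)), # mutual dyad + edge out of it
    "030T" = rbind(c(1, 2), c(3, 2), c(1, 3)), # transitive triangle
    "030C" = rbind(c(1, 2), c(2, 3), c(3, 1)), # cyclic triangle
    "201"  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),
    "120D" = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
    "120U" = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
    "120C" = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
    "210"  = rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
    "300"  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1))
  )
}

# permutations of 3 elements
perm3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
               c(3, 1, 2), c(3, 2, 1))

canonical_code <- function(code) {
  # decode 6 bits into the 3x3 off-diagonal adjacency, permute, re-encode
  bits <- as.integer(intToBits(code))[1:6]
  a <- matrix(0L, 3, 3)
  a[rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))] <- bits
  best <- 63L
  for (r in seq_len(6)) {
    p <- perm3[r, ]
    ap <- a[p, p]
    cp <- ap[1, 2] + 2L * ap[2, 1] + 4L * ap[1, 3] + 8L * ap[3, 1] +
      16L * ap[2, 3] + 32L * ap[3, 2]
    if (cp < best) best <- cp
  }
  best
}

# lookup tables built once at load: class index (1..13, NA = disconnected)
# for every 6-bit code
triad_tables <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    reps <- triad_representatives()
    rep_codes <- vapply(reps, function(e) canonical_code(triad_code(e)), 0L)
    class_of <- rep(NA_integer_, 64)
    for (code in 0:63) {
      canon <- canonical_code(code)
      hit <- match(canon, rep_codes)
      if (!is.na(hit)) class_of[code + 1L] <- hit
    }
    tbl <<- list(class_of = class_of, labels = names(reps))
    tbl
  }
})

#' Names of the five classic food-web motifs
#'
#' Under the convention rows = consumers (`W[i, j] = 1` means `i` eats
#' `j`), the five motifs usually discussed for food webs map to triad
#' classes as: food chain = `021C` (a eats b, b eats c), exploitative
#' competition = `021U` (two consumers share one resource), apparent
#' competition = `021D` (one consumer eats two resources), omnivory =
#' `030T` (transitive triangle), three-species loop = `030C`.
#'
#' @return a named character vector mapping triad class to motif name.
#' @export
foodweb_motif_names <- function() {
  c("021C" = "food chain",
    "021U" = "exploitative competition",
    "021D" = "apparent competition",
    "030T" = "omnivory",
    "030C" = "three-species loop")
}

#' Census of connected three-node motifs
#'
#' Enumerates all `choose(n, 3)` node triples of a directed food web,
#' drops self-loops, and classifies every connected induced subdigraph
#' into one of the 13 connected triad isomorphism classes (by exhaustive
#' permutation of each triple, via a precomputed canonical-code table).
#'
#' @param W a `food_web` (n >= 3).
#' @return a tibble with columns `class` (triad label), `motif` (name of
#'   the five classic food-web motifs, NA otherwise) and `count`.
#' @export
#' @examples
#' W <- food_web(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
#' motif_census(W)
motif_census <- function(W) {
  W <- as_food_web(W)
  n <- nrow(W)
  if (n < 3) abort("motif census needs at least three species")
  v <- unclass(W)
  diag(v) <- 0
  tbl <- triad_tables()
  trip <- t(combn(n, 3L))
  i <- trip[, 1]; j <- trip[, 2]; k <- trip[, 3]
  code <- v[cbind(i, j)] + 2 * v[cbind(j, i)] +
    4 * v[cbind(i, k)] + 8 * v[cbind(k, i)] +
    16 * v[cbind(j, k)] + 32 * v[cbind(k, j)]
  cls <- tbl$class_of[code + 1L]
  counts <- tabulate(cls, nbins = 13L)
  nm <- foodweb_motif_names()
  out <- tibble(class = tbl$labels,
                motif = unname(nm[tbl$labels]),
                count = as.integer(counts))
  class(out) <- c("motif_profile", class(out))
  out
}

#' NODF nestedness
#'
#' NODF ("nestedness metric based on overlap and decreasing fill") for a
#' binary matrix, on the 0-100 scale: for every ordered pair of rows with
#' strictly decreasing marginal totals, the paired overlap is the share of
#' the poorer row's 1s that also appear in the richer row (x100); pairs
#' with equal marginals contribute 0; likewise over column pairs; NODF is
#' the mean over all row and column pairs. The decreasing-fill convention
#' means the matrix is evaluated packed by marginal totals, so the score
#' does not depend on the input's row/column order. 100 means perfectly
#' nested. Computed with the standard calculator in \pkg{vegan}
#' ([vegan::nestednodf()], unweighted, sorted by decreasing fill).
#'
#' @param A an `incidence_matrix` (or any binary matrix, n, m >= 2).
#' @return a single number in `[0, 100]`.
#' @export
#' @examples
#' nodf(incidence_matrix(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))))
nodf <- function(A) {
  v <- unclass(as.matrix(A))
  unname(vegan::nestednodf(v, order = TRUE, weighted = FALSE)$statistic["NODF"])
}

#' z-score of an observed metric against a null ensemble
#'
#' `z = (k - mean(k*)) / sd(k*)` with the sample (n-1) standard
#' deviation; `|z| >= 1.96` (the two-sided 5% normal threshold) is
#' flagged significant. A positive z means the pattern is
#' overrepresented in the observed matrix relative to the null model, a
#' negative z that it is underrepresented. When the ensemble values are
#' constant the z-score is undefined and returned as `NA` with a warning.
#'
#' @param observed observed metric value `k`.
#' @param ensemble_values numeric vector of the metric over the null
#'   ensemble (length >= 2).
#' @param threshold significance threshold on `|z|`; default
#'   [z_significance_threshold()].
#' @return a one-row tibble: `observed`, `null_mean`, `null_sd`, `z`,
#'   `significant`.
#' @export
zscore <- function(observed, ensemble_values,
                   threshold = z_significance_threshold()) {
  if (length(ensemble_values) < 2) abort("need at least two ensemble values")
  mu <- mean(ensemble_values)
  s <- sd(ensemble_values)
  if (s == 0) {
    warn("ensemble metric has zero spread; z-score undefined")
    z <- NA_real_
  } else {
    z <- (observed - mu) / s
  }
  tibble(observed = observed, null_mean = mu, null_sd = s, z = z,
         significant = !is.na(z) & abs(z) >= threshold)
}

#' Two-sided significance threshold for z-scores
#'
#' The conventional cut-off |z| >= 1.96, i.e. the upper 2.5% standard
#' normal quantile rounded to two decimals.
#'
#' @return 1.96
#' @export
z_significance_threshold <- function() 1.96

#' Motif z-score profile against a null ensemble
#'
#' Applies [motif_census()] to the observed web and to every replicate of
#' the ensemble and scores each of the 13 connected triad classes with
#' [zscore()].
#'
#' @param W the observed `food_web` (the ensemble's source).
#' @param ensemble a `null_ensemble` generated from `W`.
#' @param threshold significance threshold on `|z|`.
#' @return a tibble (class `motif_zprofile`) with one row per triad
#'   class: `class`, `motif`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `significant`, plus a `model` attribute.
#' @export
motif_zscore_profile <- function(W, ensemble,
                                 threshold = z_significance_threshold()) {
  obs <- motif_census(W)
  null_counts <- vapply(ensemble$matrices,
                        function(m) motif_census(as_food_web(m))$count,
                        integer(13))
  res <- purrr::map_dfr(seq_len(13), function(ix) {
    suppressWarnings(zscore(obs$count[ix], null_counts[ix, ], threshold))
  })
  out <- dplyr::bind_cols(obs[, c("class", "motif")], res)
  attr(out, "model") <- ensemble$model
  class(out) <- c("motif_zprofile", class(out))
  out
}

#' NODF z-score against a null ensemble
#'
#' @param A the observed `incidence_matrix` (the ensemble's source).
#' @param ensemble a `null_ensemble` generated from `A`.
#' @param threshold significance threshold on `|z|`.
#' @return a one-row tibble as [zscore()], with a `model` attribute.
#' @export
nodf_zscore <- function(A, ensemble, threshold = z_significance_threshold()) {
  vals <- vapply(ensemble$matrices, nodf, numeric(1))
  out <- zscore(nodf(A), vals, threshold)
  attr(out, "model") <- ensemble$model
  out
}

#' Link overlap between two matrices with identical marginals
#'
#' Fraction of the observed 1-cells that a randomized matrix shares with
#' the original: 1 means identical, 0 means completely displaced. Used to
#' control for how far the null models move from the data.
#'
#' @param A,A_star binary matrices of identical shape (and marginals).
#' @return a number in `[0, 1]`.
#' @export
overlap_fraction <- function(A_star, A) {
  if (!all(dim(A) == dim(A_star))) abort("matrices must have the same shape")
  sum(unclass(A) * unclass(A_star)) / sum(unclass(A))
}

#' z-profile plot for motif results
#'
#' @param object a `motif_zprofile` tibble.
#' @param ... unused.
#' @return a ggplot object: z per triad class with the +-1.96 band.
#' @method autoplot motif_zprofile
#' @export
autoplot.motif_zprofile <- function(object, ...) {
  df <- dplyr::mutate(object,
                      class = factor(.data$class, levels = object$class))
  thr <- z_significance_threshold()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$z)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::labs(x = "triad class", y = "z-score",
                  title = paste0("Motif over/under-representation (",
                                 attr(object, "model") %||% "null", " model)")) +
    ggplot2::theme_minimal()
}
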