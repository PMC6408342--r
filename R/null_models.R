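#' Swap budget for the fixed-fixed randomization
#'
#' The swap algorithm has no natural stopping point; the convention
#' followed here is to stop once the number of accepted swaps reaches
#' twice the number of 1s in the matrix, with a safety cap of 100 times
#' the number of 1s on the total number of trials (informed chains with
#' skewed probabilities can mix slowly). Hitting the cap produces a
#' warning, not an error.
#'
#' @param A an `incidence_matrix` or `food_web`.
#' @return a `swap_budget` list with `target_accepted` and `max_trials`.
#' @export
default_swap_budget <- function(A) {
  L <- sum(A)
  if (L == 1) warn("matrix has a single link; the swap chain cannot move")
  swap_budget(target_accepted = max(2 * L, 1), max_trials = max(100 * L, 1))
}

#' @param target_accepted number of accepted swaps to perform (>= 1).
#' @param max_trials cap on proposal trials (>= target_accepted).
#' @rdname default_swap_budget
#' @export
swap_budget <- function(target_accepted, max_trials = 50 * target_accepted) {
  if (target_accepted < 1) abort("target_accepted must be >= 1")
  if (max_trials < target_accepted) abort("max_trials must be >= target_accepted")
  structure(list(target_accepted = as.numeric(target_accepted),
                 max_trials = as.numeric(max_trials)),
            class = "swap_budget")
}

# Thin wrappers over the compiled swap kernels (src/chains.cpp). The
# kernels draw from R's RNG, so set.seed() fully determines a run.
chain_bipartite <- function(vals, P = NULL, target_accepted, max_trials,
                            rule = "product", record = FALSE) {
  storage.mode(vals) <- "integer"
  .chain_bipartite_cpp(vals, if (is.null(P)) NULL else unclass(P),
                       target_accepted, max_trials,
                       if (rule == "product") 0L else 1L, record)
}

chain_foodweb <- function(vals, P = NULL, target_accepted, max_trials,
                          rule = "product") {
  storage.mode(vals) <- "integer"
  .chain_foodweb_cpp(vals, if (is.null(P)) NULL else unclass(P),
                     target_accepted, max_trials,
                     if (rule == "product") 0L else 1L)
}

#' Randomize a bipartite incidence matrix by constrained swaps
#'
#' Fixed-fixed (marginal-preserving) randomization: two existing links
#' `i<-j` and `l<-m` are drawn uniformly and transformed into `i<-m` and
#' `l<-j`, provided those links are not already present. Every replicate
#' preserves all row and column sums exactly. With a probability matrix
#' `P` the chain is correlation-informed: a valid proposal is accepted
#' with probability `P[i,m] * P[l,j]`, the joint probability of the two
#' links being created (interactions treated as independent). Without
#' `P` every valid proposal is accepted (the uninformed model).
#'
#' @param A an `incidence_matrix`.
#' @param P optional `probability_matrix` matching `A`.
#' @param budget a `swap_budget`; default [default_swap_budget()].
#' @param seed optional integer seed.
#' @param rule `"product"` — accept with the raw product of the created
#'   links' probabilities — or `"metropolis"`, which divides by the
#'   probabilities of the links destroyed (a Metropolis ratio variant
#'   exposed for comparison; the product rule is the default).
#' @param quiet suppress the trial-cap warning.
#' @return a randomized `incidence_matrix` with attributes `accepted` and
#'   `trials`.
#' @export
randomize_bipartite <- function(A, P = NULL, budget = default_swap_budget(A),
                                seed = NULL, rule = c("product", "metropolis"),
                                quiet = FALSE) {
  rule <- match.arg(rule)
  check_P(A, P)
  if (!is.null(seed)) set.seed(seed)
  res <- chain_bipartite(unclass(A), P, budget$target_accepted,
                         budget$max_trials, rule)
  if (res$cap_hit && !quiet) {
    warn(sprintf("trial cap reached (%d trials, %d/%d swaps accepted)",
                 as.integer(res$trials), as.integer(res$accepted),
                 as.integer(budget$target_accepted)))
  }
  out <- incidence_matrix(res$vals, rownames(A), colnames(A))
  attr(out, "accepted") <- res$accepted
  attr(out, "trials") <- res$trials
  out
}

check_P <- function(A, P) {
  if (is.null(P)) return(invisible(NULL))
  if (!all(dim(P) == dim(A)) || !identical(dimnames(unclass(P)), dimnames(unclass(A)))) {
    abort("probability matrix does not match the incidence matrix (shape/labels)")
  }
  invisible(NULL)
}

#' Randomize a directed food web by class-preserving swaps
#'
#' As [randomize_bipartite()], but on a square directed adjacency matrix
#' with the additional constraints used for food webs: species'
#' numbers of prey and predators (in/out degrees) are conserved, and so is
#' the distribution of single, double and cannibal links. Single links
#' swap only with single links (proposals creating a self-loop or the
#' reciprocal of an existing link are invalid); double links swap as
#' atomic unordered pairs with other double links, with informed
#' acceptance equal to the product of the four created directed-link
#' probabilities; cannibal self-loops never move.
#'
#' @param W a `food_web`.
#' @inheritParams randomize_bipartite
#' @return a randomized `food_web` with attributes `accepted` and `trials`.
#' @export
randomize_foodweb <- function(W, P = NULL, budget = default_swap_budget(W),
                              seed = NULL, rule = c("product", "metropolis"),
                              quiet = FALSE) {
  rule <- match.arg(rule)
  W <- as_food_web(W)
  check_P(W, P)
  if (!is.null(seed)) set.seed(seed)
  res <- chain_foodweb(unclass(W), P, budget$target_accepted,
                       budget$max_trials, rule)
  if (res$cap_hit && !quiet) {
    warn(sprintf("trial cap reached (%d trials, %d/%d swaps accepted)",
                 as.integer(res$trials), as.integer(res$accepted),
                 as.integer(budget$target_accepted)))
  }
  out <- food_web(res$vals, rownames(W))
  attr(out, "accepted") <- res$accepted
  attr(out, "trials") <- res$trials
  out
}

#' Record the state trajectory of an uninformed bipartite swap chain
#'
#' Runs the swap chain for a fixed number of trials (counting rejected
#' proposals as steps, which is what makes the uninformed chain's
#' stationary distribution uniform over the fixed-marginal class) and
#' returns the state visited after every trial as a compact string key.
#' A mixing diagnostic, mainly useful on small matrices.
#'
#' @param A an `incidence_matrix`.
#' @param steps number of trials.
#' @param seed optional integer seed.
#' @param P optional probability matrix (informed chain).
#' @return integer vector of length `steps` of state keys (the column-major
#'   0/1 cells read as a binary number; requires `n * m <= 30`).
#' @export
swap_chain_states <- function(A, steps, seed = NULL, P = NULL) {
  check_P(A, P)
  if (nrow(A) * ncol(A) > 30) {
    abort("state recording is limited to matrices with at most 30 cells")
  }
  if (!is.null(seed)) set.seed(seed)
  res <- chain_bipartite(unclass(A), P, target_accepted = Inf,
                         max_trials = steps, rule = "product", record = TRUE)
  res$keys
}

#' Build a null ensemble
#'
#' Generates `size` randomized replicates of `source` under one of the
#' three null models:
#'
#' * `"uninformed"` — plain fixed-fixed swaps, every valid proposal
#'   accepted;
#' * `"informed"` — link probabilities are estimated once from
#'   `(source, V)` and reused for every replicate (every swap is informed
#'   relative to the original matrix);
#' * `"misinformed"` — for every replicate the correlation matrix is
#'   symmetrically permuted afresh, probabilities are re-estimated from
#'   the permuted matrix, and the chain is informed by those. This is the
#'   overfitting control: a model informed by scrambled structure should
#'   behave like the uninformed one.
#'
#' Per-replicate seeds are derived deterministically from `seed`, so the
#' same inputs and master seed reproduce the ensemble exactly.
#'
#' @param source an `incidence_matrix` or `food_web`.
#' @param model `"uninformed"`, `"informed"` or `"misinformed"`.
#' @param V a `correlation_matrix` (required for informed/misinformed).
#' @param perspective passed to [estimate_probability_matrix()].
#' @param size ensemble size (>= 2).
#' @param budget a `swap_budget`; default [default_swap_budget()].
#' @param seed master integer seed.
#' @param rule swap acceptance rule, see [randomize_bipartite()].
#' @return a `null_ensemble`: list with `matrices`, `model`, `seeds`,
#'   `accepted`, `trials`, `probability_provenance`, `source`. [tidy()]
#'   gives a per-replicate tibble including the link overlap with the
#'   source matrix.
#' @export
build_ensemble <- function(source,
                           model = c("uninformed", "informed", "misinformed"),
                           V = NULL, perspective = c("rows", "cols"),
                           size = 200, budget = NULL, seed = NULL,
                           rule = c("product", "metropolis")) {
  model <- match.arg(model)
  perspective <- match.arg(perspective)
  rule <- match.arg(rule)
  if (size < 2) abort("ensemble size must be at least 2")
  if (model != "uninformed" && is.null(V)) {
    abort(paste0("model '", model, "' requires a correlation matrix V"))
  }
  budget <- budget %||% default_swap_budget(source)
  is_web <- inherits(source, "food_web")
  randomizer <- if (is_web) randomize_foodweb else randomize_bipartite

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(2147483646L, size)

  P0 <- NULL
  if (model == "informed") {
    P0 <- estimate_probability_matrix(source, V, perspective)
  }

  mats <- vector("list", size)
  accepted <- trials <- numeric(size)
  cap_hits <- 0L
  for (r in seq_len(size)) {
    set.seed(rep_seeds[r])
    P <- P0
    if (model == "misinformed") {
      Vp <- permute_correlation(V)
      P <- estimate_probability_matrix(source, Vp, perspective)
    }
    m <- withCallingHandlers(
      randomizer(source, P = P, budget = budget, quiet = TRUE, rule = rule),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (attr(m, "accepted") < budget$target_accepted) cap_hits <- cap_hits + 1L
    accepted[r] <- attr(m, "accepted")
    trials[r] <- attr(m, "trials")
    attr(m, "accepted") <- NULL
    attr(m, "trials") <- NULL
    mats[[r]] <- m
  }
  if (cap_hits > 0) {
    warn(sprintf("%d of %d replicates hit the trial cap before reaching the swap target",
                 cap_hits, size))
  }
  structure(
    list(matrices = mats, model = model, seeds = rep_seeds,
         accepted = accepted, trials = trials,
         probability_provenance = if (model == "uninformed") NULL else
           c(attr(V, "provenance"),
             list(perspective = perspective, refit_per_replicate = model == "misinformed")),
         budget = budget, rule = rule, source = source),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s model, %d replicates of a %d x %d matrix\n",
              x$model, length(x$matrices), nrow(x$source), ncol(x$source)))
  cat(sprintf("  accepted swaps: median %d (target %d); trials: median %d\n",
              as.integer(stats::median(x$accepted)),
              as.integer(x$budget$target_accepted),
              as.integer(stats::median(x$trials))))
  invisible(x)
}

#' @method tidy null_ensemble
#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble(
    replicate = seq_along(x$matrices),
    seed = x$seeds,
    accepted = x$accepted,
    trials = x$trials,
    overlap = purrr::map_dbl(x$matrices, overlap_fraction, A = x$source)
  )
}

#' @method glance null_ensemble
#' @export
glance.null_ensemble <- function(x, ...) {
  td <- tidy(x)
  tibble(model = x$model, size = nrow(td),
         target_accepted = x$budget$target_accepted,
         mean_accepted = mean(td$accepted), mean_trials = mean(td$trials),
         mean_overlap = mean(td$overlap))
}

#' Persist an ensemble as matrix CSVs plus a JSON manifest
#'
#' @param ensemble a `null_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(ensemble$matrices))
  for (r in seq_along(ensemble$matrices)) {
    paths[r] <- file.path(dir, sprintf("replicate_%04d.csv", r))
    write_incidence(ensemble$matrices[[r]], paths[r], "matrix_csv")
  }
  manifest <- list(
    model = ensemble$model,
    size = length(ensemble$matrices),
    seeds = ensemble$seeds,
    accepted = ensemble$accepted,
    trials = ensemble$trials,
    budget = unclass(ensemble$budget),
    rule = ensemble$rule,
    probability_provenance = ensemble$probability_provenance,
    mean_overlap = mean(tidy(ensemble)$overlap),
    files = basename(paths)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
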