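#' Simulate a pure-birth tree and a Brownian trait
#'
#' A Yule (pure-birth, rate 1) phylogeny with `n_tips` tips and one
#' continuous trait evolved on it under Brownian motion (variance 1 per
#' unit branch length). The tree's standardized variance-covariance is the
#' "true" correlation structure for downstream generators.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed optional integer seed.
#' @return a list: `tree` (an [ape::phylo]), `newick` (string), `traits`
#'   (named numeric vector over tips).
#' @export
simulate_tree_and_traits <- function(n_tips, seed = NULL) {
  if (n_tips < 3) abort("need at least three tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  traits <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  list(tree = tree, newick = ape::write.tree(tree), traits = traits)
}

# solve the intercept that hits the target density given drawn effects
density_intercept <- function(b, density) {
  f <- function(a) mean(plogis(a + b)) - density
  uniroot(f, c(-30, 30))$root
}

#' Generate a phylogenetically structured food web
#'
#' Draws a food web from the informed model's own generative direction:
#' for every consumer `i` a random effect vector `b_i ~ Normal(0, beta^2
#' V_phylo)` over the resources (the tree's tips), an intercept `alpha_i`
#' solved so the expected density matches `density` given the drawn
#' effects, and links `A_ij ~ Bernoulli(logistic(alpha_i + b_ij))`.
#' `beta = 0` removes all structure and gives an Erdos-Renyi-style
#' control with the same expected density.
#'
#' With `n_consumers = NULL` (the default) the consumers are identified
#' with the tree's tips and the result is a square `food_web`, the shape
#' motif analyses need; passing a count instead yields a bipartite
#' consumers-by-tips `incidence_matrix`.
#'
#' @param world output of [simulate_tree_and_traits()] (or a list with a
#'   `tree`).
#' @param n_consumers `NULL` for a square web over the tips, or a number
#'   of consumer rows for a bipartite matrix.
#' @param beta effect strength (>= 0); the generative sigma shared by all
#'   consumers.
#' @param density target link density in (0, 1).
#' @param seed optional integer seed.
#' @return a `synthetic_world` list: `web` (a `food_web` or
#'   `incidence_matrix`), `true_correlation` (the standardized
#'   phylogenetic `correlation_matrix`), `params`.
#' @export
synthetic_foodweb <- function(world, n_consumers = NULL, beta = 2,
                              density = 0.15, seed = NULL) {
  if (beta < 0) abort("beta must be nonnegative")
  if (density <= 0 || density >= 1) abort("density must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  V <- phylogenetic_correlation(world$tree)
  m <- nrow(V)
  square <- is.null(n_consumers)
  n <- if (square) m else n_consumers
  ch <- chol(unclass(regularize_correlation(V, jitter = 1e-6)))
  vals <- matrix(0, n, m)
  for (i in seq_len(n)) {
    b <- if (beta > 0) beta * drop(crossprod(ch, rnorm(m))) else rep(0, m)
    a <- density_intercept(b, density)
    vals[i, ] <- rbinom(m, 1, plogis(a + b))
  }
  web <- if (square) {
    food_web(vals, labels = rownames(V))
  } else {
    incidence_matrix(vals, row_labels = paste0("c", seq_len(n)),
                     col_labels = rownames(V))
  }
  structure(list(web = web, true_correlation = V,
                 params = list(beta = beta, density = density, seed = seed,
                               n_consumers = n_consumers, generator = "foodweb")),
            class = "synthetic_world")
}

#' Generate a nested (or random) species assemblage
#'
#' Sites-by-species presence/absence with a geometric richness gradient:
#' site `k`'s richness target is proportional to `gamma^(k-1)`. In the
#' nested regime (positive `strength`) each site fills its quota by
#' sampling species with weights that decay exponentially with the
#' species' prevalence rank, so poor sites draw from the same common
#' species that rich sites hold; `strength = 0` samples species uniformly
#' within each site (the random regime at matched richness totals). Site
#' coordinates (uniform on a 10x10 square) and areas (log-normal) are
#' also emitted so spatial/area exponential correlation structures can be
#' built for the sites.
#'
#' @param n_sites,n_species dimensions (>= 2).
#' @param gamma richness decay ratio in (0, 1]; `gamma = 1` keeps
#'   richness flat.
#' @param strength nestedness strength (>= 0); rate of the rank-weight
#'   decay. 0 = uniform regime; around 5 gives near-perfect nesting.
#' @param max_richness richness of the richest site; default
#'   `0.6 * n_species`.
#' @param seed optional integer seed.
#' @return a `synthetic_world` list: `incidence` (sites x species
#'   `incidence_matrix`), `sites` (tibble with coordinates, area,
#'   richness), `params`.
#' @export
synthetic_assemblage <- function(n_sites, n_species, gamma = 0.9,
                                 strength = 5, max_richness = NULL,
                                 seed = NULL) {
  if (n_sites < 2 || n_species < 2) abort("need at least 2 sites and 2 species")
  if (gamma <= 0 || gamma > 1) abort("gamma must be in (0, 1]")
  if (strength < 0) abort("strength must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  max_richness <- max_richness %||% max(2, round(0.6 * n_species))
  richness <- pmax(1, round(max_richness * gamma^(seq_len(n_sites) - 1)))
  # exponentially decaying weight over species prevalence rank
  w <- exp(-strength * (seq_len(n_species) - 1) / n_species)
  vals <- matrix(0, n_sites, n_species)
  for (k in seq_len(n_sites)) {
    picked <- sample.int(n_species, size = min(richness[k], n_species),
                         prob = w)
    vals[k, picked] <- 1
  }
  sites <- tibble(
    site = paste0("s", seq_len(n_sites)),
    x = runif(n_sites, 0, 10),
    y = runif(n_sites, 0, 10),
    area = exp(rnorm(n_sites, 0, 1)),
    richness = as.integer(rowSums(vals))
  )
  A <- incidence_matrix(vals, row_labels = sites$site,
                        col_labels = paste0("sp", seq_len(n_species)))
  structure(list(incidence = A, sites = sites,
                 params = list(gamma = gamma, strength = strength,
                               max_richness = max_richness, seed = seed,
                               generator = "assemblage")),
            class = "synthetic_world")
}

#' i.i.d. Bernoulli incidence matrix
#'
#' @param n,m dimensions (>= 2).
#' @param fill Bernoulli probability, strictly inside (0, 1).
#' @param seed optional integer seed.
#' @return an `incidence_matrix`.
#' @export
random_binary_matrix <- function(n, m, fill, seed = NULL) {
  if (fill <= 0 || fill >= 1) abort("fill must be strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  incidence_matrix(matrix(rbinom(n * m, 1, fill), n, m))
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> generator = %s\n", x$params$generator))
  utils::str(x$params)
  invisible(x)
}
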