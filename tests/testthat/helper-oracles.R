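# Independent oracles and small fixture generators used across the suite.
# Everything here is deliberately written from the definitions, not by
# calling the package's own code paths.

# ---- NODF, straight from the published formula ---------------------------
# mean over all ordered row pairs (richer, poorer by strictly decreasing
# marginal) and column pairs of 100 * shared / poorer-marginal; equal
# marginals contribute 0.
nodf_oracle <- function(m) {
  m <- unclass(as.matrix(m))
  pair_scores <- function(mat) {
    n <- nrow(mat)
    scores <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fi <- sum(mat[i, ]); fj <- sum(mat[j, ])
        if (fi == fj || min(fi, fj) == 0) {
          scores <- c(scores, 0)
        } else {
          rich <- if (fi > fj) i else j
          poor <- if (fi > fj) j else i
          shared <- sum(mat[rich, ] * mat[poor, ])
          scores <- c(scores, 100 * shared / sum(mat[poor, ]))
        }
      }
    }
    scores
  }
  mean(c(pair_scores(m), pair_scores(t(m))))
}

# ---- triad census oracle via igraph --------------------------------------
# counts of the 13 connected triad classes, in conventional census order,
# from igraph's full 16-class census (self-loops removed first).
igraph_triad_oracle <- function(W) {
  v <- unclass(as.matrix(W))
  diag(v) <- 0
  g <- igraph::graph_from_adjacency_matrix(v, mode = "directed")
  as.integer(igraph::triad_census(g)[4:16])
}

random_digraph <- function(n, fill = 0.25) {
  v <- matrix(rbinom(n * n, 1, fill), n, n)
  food_web(v)
}

# ---- exact marginal likelihood oracle (Gauss-Hermite) --------------------
# For m <= 3: E_{b ~ N(0, sigma^2 V)} prod_j p_j^{y_j} (1-p_j)^{1-y_j}
# by product-rule Gauss-Hermite quadrature, plus the package's alpha
# penalty so the two objectives are comparable.
gh_nodes <- function(k = 25) {
  # Golub-Welsch from the Hermite recurrence (probabilists' weights for
  # N(0,1) after rescaling)
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values * sqrt(2)            # nodes for N(0,1)
  w <- (e$vectors[1, ])^2            # weights sum to 1
  list(x = x, w = w)
}

exact_marginal_loglik <- function(y, Vmat, alpha, sigma, k = 25) {
  m <- length(y)
  gh <- gh_nodes(k)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), m))
  Z <- matrix(gh$x[as.matrix(grids)], ncol = m)
  w <- apply(matrix(gh$w[as.matrix(grids)], ncol = m), 1, prod)
  L <- t(chol(Vmat + diag(1e-10, m)))
  B <- sigma * Z %*% t(L)
  eta <- sweep(B, 2, rep(alpha, m), `+`)
  ll <- drop(eta %*% y) - rowSums(log1p(exp(eta)))
  ls <- max(ll)
  log(sum(w * exp(ll - ls))) + ls - alpha^2 / (2 * 10^2)
}

# fit (alpha, sigma) by maximizing the exact marginal, then report the
# posterior mode probabilities under those parameters (mode found by
# generic Nelder-Mead, independent of the package's Newton code)
oracle_fit_small <- function(y, Vmat) {
  m <- length(y)
  neg <- function(par) -exact_marginal_loglik(y, Vmat, par[1], exp(par[2]))
  opt <- nlminb(c(0, log(0.5)), neg, lower = c(-30, log(1e-4)),
                upper = c(30, log(20)))
  # sigma = 0 profile; preferred on flat ridges (same tie-break as the fit)
  neg0 <- function(a) neg(c(a, log(1e-4)))
  opt0 <- optimize(neg0, c(-30, 30))
  if (-opt0$objective >= -opt$objective - 1e-8) {
    return(list(alpha = opt0$minimum, sigma = 0,
                p = rep(plogis(opt0$minimum), m)))
  }
  alpha <- opt$par[1]; sigma <- exp(opt$par[2])
  Q <- solve(Vmat + diag(1e-10, m)) / sigma^2
  negpost <- function(b) {
    eta <- alpha + b
    -(sum(y * eta - log1p(exp(eta))) - 0.5 * sum(b * (Q %*% b)))
  }
  ob <- optim(rep(0, m), negpost, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-12))
  p <- plogis(alpha + ob$par)
  list(alpha = alpha, sigma = sigma, p = p)
}

# ---- enumeration of a fixed-marginal class -------------------------------
# all 0/1 matrices of the same shape and marginals as A (feasible for
# 4 x 4); returns integer column-major bit keys, matching swap_chain_states.
enumerate_fixed_marginal <- function(A) {
  v <- unclass(as.matrix(A))
  n <- nrow(v); m <- ncol(v)
  stopifnot(n * m <= 16)
  rs <- rowSums(v); cs <- colSums(v)
  keys <- integer(0)
  for (code in 0:(2^(n * m) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n * m)]
    cand <- matrix(bits, n, m)
    if (all(rowSums(cand) == rs) && all(colSums(cand) == cs)) {
      keys <- c(keys, code)
    }
  }
  keys
}

# simulate one row from the mixed logistic generative model
simulate_row <- function(alpha, sigma, Vmat) {
  m <- nrow(Vmat)
  L <- t(chol(Vmat + diag(1e-10, m)))
  b <- sigma * drop(L %*% rnorm(m))
  rbinom(m, 1, plogis(alpha + b))
}
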