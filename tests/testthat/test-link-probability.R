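id_corr <- function(m) {
  corrnull:::new_correlation_matrix(diag(m), paste0("c", seq_len(m)),
                                    list(builder = "identity"))
}

test_that("degenerate rows return the Laplace-smoothed uniform probability", {
  V <- id_corr(10)
  f0 <- fit_row_model(rep(0, 10), V)
  expect_equal(unname(f0$p), rep(1 / 12, 10))
  expect_equal(f0$sigma, 0)
  expect_equal(f0$converged, "degenerate")
  f1 <- fit_row_model(rep(1, 10), V)
  expect_equal(unname(f1$p), rep(11 / 12, 10))
})

test_that("an all-ones correlation yields constant within-row probabilities", {
  set.seed(3)
  m <- 12
  V <- constant_correlation(paste0("c", 1:m))
  y <- rbinom(m, 1, 0.4)
  while (sum(y) %in% c(0, m)) y <- rbinom(m, 1, 0.4)
  f <- fit_row_model(y, V)
  expect_lt(diff(range(f$p)), 1e-6)
  # and the constant is the (weakly penalized) intercept-only estimate
  expect_equal(unname(f$p[1]), plogis(qlogis(mean(y))), tolerance = 0.05)
})

test_that("fitted linear predictor decomposes as alpha + b for active fits", {
  set.seed(5)
  g <- setNames(rep(c("g1", "g2"), each = 8), paste0("c", 1:16))
  V <- group_correlation(g)
  y <- c(rbinom(8, 1, 0.9), rbinom(8, 1, 0.1))
  f <- fit_row_model(y, V)
  expect_equal(unname(qlogis(f$p)), unname(f$alpha + f$b_hat), tolerance = 1e-4)
  expect_gte(f$sigma, 0)
})

test_that("Laplace fit matches the numerical-integration oracle on tiny rows", {
  cases <- list(
    list(y = c(1, 0), V = diag(2)),
    list(y = c(1, 1, 0), V = diag(3)),
    list(y = c(1, 1, 0), V = matrix(c(1, 0.5, 0.2,
                                      0.5, 1, 0.4,
                                      0.2, 0.4, 1), 3)),
    list(y = c(0, 1, 0), V = matrix(c(1, 0.5, 0.2,
                                      0.5, 1, 0.4,
                                      0.2, 0.4, 1), 3)),
    list(y = c(1, 0, 0), V = matrix(c(1, 0.8, 0,
                                      0.8, 1, 0,
                                      0, 0, 1), 3))
  )
  for (cs in cases) {
    m <- length(cs$y)
    V <- corrnull:::new_correlation_matrix(cs$V, paste0("c", 1:m),
                                           list(builder = "test"))
    fit <- fit_row_model(cs$y, V)
    ora <- oracle_fit_small(cs$y, cs$V)
    expect_equal(unname(fit$p), unname(ora$p), tolerance = 1e-2)
  }
})

test_that("links concentrated in one group raise that group's probabilities", {
  set.seed(21)
  wins <- 0L
  for (rep in 1:10) {
    g <- setNames(rep(c("g1", "g2"), each = 10), paste0("c", 1:20))
    V <- group_correlation(g)
    y <- c(rbinom(10, 1, 0.8), rbinom(10, 1, 0.1))
    if (sum(y[1:10]) <= sum(y[11:20])) next
    f <- fit_row_model(y, V)
    if (mean(f$p[1:10]) > mean(f$p[11:20])) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("parameter recovery improves with row length", {
  set.seed(314)
  alpha_true <- -1; sigma_true <- 1.5
  # group structure with enough groups that sigma has real degrees of
  # freedom (each group contributes roughly one draw of the random effect)
  med_err <- sapply(c(100, 400), function(m) {
    k <- if (m == 100) 10 else 20
    g <- setNames(rep(paste0("g", 1:k), each = m / k), paste0("c", 1:m))
    V <- group_correlation(g)
    Vm <- unclass(regularize_correlation(V))
    errs <- t(replicate(10, {
      y <- simulate_row(alpha_true, sigma_true, Vm)
      f <- fit_row_model(y, V)
      c(a = f$alpha - alpha_true, s = f$sigma - sigma_true)
    }))
    apply(abs(errs), 2, median)
  })
  expect_lt(med_err["a", 2], 0.3)
  expect_lt(med_err["s", 2], 0.4)
})

test_that("probability matrices respect perspective and labels", {
  set.seed(8)
  A <- random_binary_matrix(5, 7, 0.4)
  Vcol <- exponential_correlation(setNames(rnorm(7), colnames(A)), eta = 0.01)
  P <- estimate_probability_matrix(A, Vcol, "rows")
  expect_identical(dim(unclass(P)), dim(unclass(A)))
  expect_true(all(P > 0 & P < 1))
  expect_identical(attr(P, "perspective"), "rows")
  expect_identical(tidy(P)$unit, rownames(A))

  Vrow <- exponential_correlation(setNames(rnorm(5), rownames(A)), eta = 0.01)
  P2 <- estimate_probability_matrix(A, Vrow, "cols")
  expect_identical(dim(unclass(P2)), dim(unclass(A)))
  expect_identical(tidy(P2)$unit, colnames(A))

  expect_error(estimate_probability_matrix(A, Vrow, "rows"), "labels")
})

test_that("re-estimating under a permuted V changes p but never touches A", {
  set.seed(12)
  A <- random_binary_matrix(6, 8, 0.35)
  V <- exponential_correlation(setNames(rnorm(8), colnames(A)), eta = 0.01)
  before <- unclass(A)
  P1 <- estimate_probability_matrix(A, V)
  P2 <- estimate_probability_matrix(A, permute_correlation(V, seed = 4))
  expect_identical(unclass(A), before)
  expect_false(isTRUE(all.equal(unclass(P1), unclass(P2))))
})

test_that("tidy and glance expose fit diagnostics", {
  A <- incidence_matrix(rbind(c(1, 0, 1), c(0, 0, 0), c(1, 1, 1)))
  P <- estimate_probability_matrix(A, constant_correlation(colnames(A)))
  td <- tidy(P)
  expect_named(td, c("unit", "alpha", "sigma", "converged", "log_likelihood"))
  expect_equal(nrow(td), 3)
  gl <- glance(P)
  expect_equal(gl$n_degenerate, 2)
})
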