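test_that("the default budget follows the twice-the-links heuristic", {
  A <- incidence_matrix(rbind(c(1, 1, 1), c(1, 1, 0)))  # 5 links
  b <- default_swap_budget(A)
  expect_equal(b$target_accepted, 10)
  expect_equal(b$max_trials, 500)

  set.seed(1)
  A2 <- random_binary_matrix(10, 10, 0.5)
  L <- sum(A2)
  b2 <- default_swap_budget(A2)
  expect_equal(b2$target_accepted, 2 * L)
  expect_error(swap_budget(10, 5), "max_trials")
  expect_error(swap_budget(0), "target_accepted")
})

test_that("the 2x2 identity has a unique swap, the checkerboard flip", {
  A <- incidence_matrix(diag(2))
  out <- randomize_bipartite(A, budget = swap_budget(1), seed = 1)
  expect_equal(unclass(out), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
})

test_that("a saturated matrix cannot move and warns via the trial cap", {
  A <- incidence_matrix(matrix(1, 2, 2))
  expect_warning(out <- randomize_bipartite(A, budget = swap_budget(1, 50)),
                 "trial cap")
  expect_equal(unclass(out), unclass(A), ignore_attr = TRUE)
})

test_that("bipartite swaps preserve marginals for all three models", {
  set.seed(100)
  A <- random_binary_matrix(8, 8, 0.35)
  V <- exponential_correlation(setNames(rnorm(8), colnames(A)), eta = 0.01)
  P <- estimate_probability_matrix(A, V)
  for (s in 1:20) {
    r1 <- randomize_bipartite(A, seed = s, quiet = TRUE)
    r2 <- randomize_bipartite(A, P = P, seed = s, quiet = TRUE)
    expect_identical(rowSums(r1), rowSums(A))
    expect_identical(colSums(r1), colSums(A))
    expect_identical(rowSums(r2), rowSums(A))
    expect_identical(colSums(r2), colSums(A))
  }
})

test_that("informed acceptance has the expected geometric waiting time", {
  # two parallel links, one valid proposal, all probabilities 0.5:
  # acceptance 0.25 per (valid) trial
  A <- incidence_matrix(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)))
  P <- matrix(0.5, 3, 3, dimnames = dimnames(unclass(A)))
  set.seed(5)
  trials <- replicate(400, {
    out <- randomize_bipartite(A, P = P, budget = swap_budget(1, 10000),
                               quiet = TRUE)
    attr(out, "trials")
  })
  expect_equal(mean(trials), 4, tolerance = 0.15)
})

test_that("food-web swaps preserve degrees and link classes over many seeds", {
  set.seed(2)
  W <- random_digraph(20, 0.2)
  cl <- classify_links(W)
  for (s in 1:30) {
    r <- randomize_foodweb(W, seed = s, quiet = TRUE)
    rcl <- classify_links(r)
    expect_identical(rcl[c("n_single", "n_double", "n_cannibal")],
                     cl[c("n_single", "n_double", "n_cannibal")])
    expect_identical(rcl$degrees, cl$degrees)
  }
})

test_that("a lone double link with no partner leaves the web unchanged", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 1
  W <- food_web(v)
  out <- randomize_foodweb(W, budget = swap_budget(1, 20), seed = 1, quiet = TRUE)
  expect_equal(unclass(out), unclass(W), ignore_attr = TRUE)
})

test_that("cannibal links never move", {
  set.seed(9)
  v <- unclass(random_digraph(10, 0.25))
  diag(v) <- rbinom(10, 1, 0.4)
  W <- food_web(v)
  for (s in 1:10) {
    r <- randomize_foodweb(W, seed = s, quiet = TRUE)
    expect_identical(diag(unclass(r)), diag(unclass(W)))
  }
})

test_that("ensembles are deterministic in the master seed", {
  set.seed(42)
  A <- random_binary_matrix(7, 7, 0.4)
  e1 <- build_ensemble(A, "uninformed", size = 6, seed = 123)
  e2 <- build_ensemble(A, "uninformed", size = 6, seed = 123)
  expect_identical(lapply(e1$matrices, unclass), lapply(e2$matrices, unclass))
  expect_identical(e1$seeds, e2$seeds)

  V <- constant_correlation(colnames(A))
  m1 <- build_ensemble(A, "misinformed", V = V, size = 4, seed = 7)
  m2 <- build_ensemble(A, "misinformed", V = V, size = 4, seed = 7)
  expect_identical(lapply(m1$matrices, unclass), lapply(m2$matrices, unclass))
  e3 <- build_ensemble(A, "uninformed", size = 6, seed = 124)
  expect_false(identical(lapply(e1$matrices, unclass),
                         lapply(e3$matrices, unclass)))
})

test_that("ensemble sizes and provenance are recorded", {
  set.seed(3)
  A <- random_binary_matrix(6, 6, 0.4)
  V <- exponential_correlation(setNames(rnorm(6), colnames(A)), eta = 0.01)
  ens <- build_ensemble(A, "informed", V = V, size = 5, seed = 2)
  expect_length(ens$matrices, 5)
  expect_identical(ens$probability_provenance$builder, "exponential")
  expect_false(ens$probability_provenance$refit_per_replicate)
  td <- tidy(ens)
  expect_named(td, c("replicate", "seed", "accepted", "trials", "overlap"))
  expect_true(all(td$overlap >= 0 & td$overlap <= 1))
  expect_error(build_ensemble(A, "informed", size = 5), "requires")
  expect_error(build_ensemble(A, "uninformed", size = 1), "at least 2")
})

test_that("the uninformed chain explores the whole fixed-marginal class", {
  A <- incidence_matrix(rbind(c(1, 1, 0, 0),
                              c(1, 0, 1, 0),
                              c(0, 1, 0, 1),
                              c(0, 0, 1, 1)))  # 8 links; smoke-scale check
  states <- swap_chain_states(A, steps = 4000, seed = 31)
  class_keys <- enumerate_fixed_marginal(A)
  expect_true(all(states %in% class_keys))
  expect_equal(sort(unique(states)), sort(class_keys))
})

test_that("ensembles persist to CSVs plus a manifest", {
  withr::with_tempdir({
    set.seed(6)
    A <- random_binary_matrix(5, 5, 0.4)
    ens <- build_ensemble(A, "uninformed", size = 3, seed = 11)
    write_ensemble(ens, "ens")
    man <- jsonlite::read_json("ens/manifest.json", simplifyVector = TRUE)
    expect_equal(man$model, "uninformed")
    expect_equal(man$size, 3)
    back <- read_incidence(file.path("ens", man$files[2]))
    expect_identical(unclass(back), unclass(ens$matrices[[2]]))
  })
})
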