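test_that("single-motif webs are classified into the right triad class", {
  chain <- food_web(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
  cc <- motif_census(chain)
  expect_equal(cc$count[cc$class == "021C"], 1L)
  expect_equal(sum(cc$count), 1L)
  expect_equal(cc$motif[cc$class == "021C"], "food chain")

  # one consumer, two resources
  out_star <- food_web(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)))
  cs <- motif_census(out_star)
  expect_equal(cs$count[cs$class == "021D"], 1L)

  # two consumers, one shared resource
  in_star <- food_web(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0)))
  ci <- motif_census(in_star)
  expect_equal(ci$count[ci$class == "021U"], 1L)

  omn <- food_web(rbind(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0)))
  expect_equal(motif_census(omn)$count[6], 1L)  # 030T
  loop <- food_web(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  co <- motif_census(loop)
  expect_equal(co$count[co$class == "030C"], 1L)
})

test_that("each triad representative is its own class under the igraph oracle", {
  reps <- corrnull:::triad_representatives()
  for (ix in seq_along(reps)) {
    v <- matrix(0, 3, 3)
    v[reps[[ix]]] <- 1
    counts <- igraph_triad_oracle(food_web(v))
    expect_equal(which(counts == 1), ix, info = names(reps)[ix])
  }
})

test_that("motif census equals the igraph triad-census oracle on random digraphs", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    W <- random_digraph(n, fill = runif(1, 0.1, 0.5))
    cc <- motif_census(W)
    expect_identical(cc$count, igraph_triad_oracle(W))
    # self-loops must not affect classification
    v <- unclass(W); diag(v) <- 1
    expect_identical(motif_census(food_web(v))$count, cc$count)
  }
})

test_that("motif counts are invariant under species relabelling", {
  set.seed(5)
  W <- random_digraph(8, 0.3)
  perm <- sample(8)
  Wp <- food_web(unclass(W)[perm, perm])
  expect_identical(motif_census(Wp)$count, motif_census(W)$count)
})

test_that("NODF scores nested and anti-nested matrices at the extremes", {
  tri <- incidence_matrix(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))
  expect_equal(nodf(tri), 100)
  expect_equal(nodf(incidence_matrix(diag(2))), 0)
})

test_that("NODF agrees with the direct-formula oracle and is permutation invariant", {
  set.seed(31)
  for (rep in 1:20) {
    A <- random_binary_matrix(sample(3:8, 1), sample(3:8, 1),
                              fill = runif(1, 0.2, 0.8))
    expect_equal(nodf(A), nodf_oracle(A), tolerance = 1e-10)
    rp <- sample(nrow(A)); cp <- sample(ncol(A))
    expect_equal(nodf(incidence_matrix(unclass(A)[rp, cp])), nodf(A),
                 tolerance = 1e-10)
  }
})

test_that("z-scores follow the ensemble mean and spread", {
  r <- zscore(2, c(1, 2, 3))
  expect_equal(r$z, 0)
  expect_false(r$significant)

  set.seed(4)
  ens <- rnorm(50, 10, 2)
  k <- mean(ens) + 2 * sd(ens)
  r2 <- zscore(k, ens)
  expect_equal(r2$z, 2)
  expect_true(r2$significant)

  expect_warning(r3 <- zscore(5, rep(5, 10)), "zero spread")
  expect_true(is.na(r3$z))
})

test_that("z-scores are location-scale equivariant", {
  set.seed(9)
  ens <- rnorm(30)
  k <- 1.2
  z0 <- zscore(k, ens)$z
  for (rep in 1:5) {
    a <- rnorm(1); b <- runif(1, 0.5, 3)
    expect_equal(zscore(a + b * k, a + b * ens)$z, z0, tolerance = 1e-10)
  }
})

test_that("the significance threshold is the two-decimal normal 97.5% quantile", {
  expect_equal(z_significance_threshold(), round(qnorm(0.975), 2))
})

test_that("motif z-profiles propagate sign and degenerate ensembles", {
  set.seed(77)
  W <- random_digraph(10, 0.3)
  ens <- build_ensemble(W, "uninformed", size = 30, seed = 1)
  zp <- motif_zscore_profile(W, ens)
  expect_equal(nrow(zp), 13)
  ok <- !is.na(zp$z)
  expect_equal(sign(zp$z[ok]), sign(zp$observed[ok] - zp$null_mean[ok]))

  copies <- ens
  copies$matrices <- rep(list(W), 5)
  zp2 <- motif_zscore_profile(W, copies)
  expect_true(all(is.na(zp2$z)))
})

test_that("overlap fraction measures shared links", {
  A <- incidence_matrix(diag(2))
  expect_equal(overlap_fraction(A, A), 1)
  anti <- incidence_matrix(rbind(c(0, 1), c(1, 0)))
  expect_equal(overlap_fraction(anti, A), 0)
  expect_error(overlap_fraction(incidence_matrix(diag(3)), A), "shape")
})

test_that("autoplot returns a ggplot for z-profiles and probability matrices", {
  set.seed(15)
  W <- random_digraph(8, 0.3)
  ens <- build_ensemble(W, "uninformed", size = 10, seed = 2)
  zp <- suppressWarnings(motif_zscore_profile(W, ens))
  expect_s3_class(autoplot(zp), "ggplot")
  P <- estimate_probability_matrix(W, constant_correlation(colnames(W)))
  expect_s3_class(autoplot(P), "ggplot")
})
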