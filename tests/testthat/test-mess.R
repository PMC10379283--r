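test_that("univariate similarity matches the piecewise hand examples", {
  ref <- c(1, 2, 3, 4, 5)
  expect_equal(similarity_univariate(ref, 3), 80)    # f = 40 -> 2f
  expect_equal(similarity_univariate(ref, 1), 0)     # at the reference minimum
  expect_equal(similarity_univariate(ref, 0), -25)   # below the range
  expect_equal(similarity_univariate(ref, 6), -25)   # above the range
  expect_equal(similarity_univariate(ref, 5), 40)    # f = 80 -> 2(100 - f)
  expect_error(similarity_univariate(rep(2, 5), 1), "degenerate")
})

test_that("similarity is unimodal: non-decreasing below the median, non-increasing above", {
  set.seed(21)
  for (rep_i in 1:20) {
    ref <- rnorm(sample(5:40, 1))
    med <- median(ref)
    below <- sort(seq(min(ref) - 2, med, length.out = 50))
    above <- sort(seq(med, max(ref) + 2, length.out = 50))
    expect_true(all(diff(similarity_univariate(ref, below)) >= -1e-12))
    expect_true(all(diff(similarity_univariate(ref, above)) <= 1e-12))
  }
})

test_that("query points duplicated from the reference never score negative", {
  set.seed(33)
  for (rep_i in 1:20) {
    ref <- runif(sample(3:30, 1), -5, 5)
    expect_true(all(similarity_univariate(ref, ref) >= 0))
  }
})

test_that("compute_mess equals the brute-force oracle on random instances", {
  set.seed(101)
  for (rep_i in 1:25) {
    n_ref <- sample(5:50, 1)
    n_q <- sample(5:100, 1)
    ref <- matrix(rnorm(n_ref * 5), n_ref, 5,
                  dimnames = list(NULL, canonical_predictors()))
    q <- matrix(rnorm(n_q * 5, sd = 2), n_q, 5,
                dimnames = list(NULL, canonical_predictors()))
    got <- compute_mess(as.data.frame(ref), as.data.frame(q))
    want <- mess_oracle(ref, q)
    expect_equal(got$mess, want$mess, tolerance = 1e-12)
    expect_equal(got$per_variable, want$per_variable, tolerance = 1e-12)
  }
})

test_that("the MESS grid is the cell-wise minimum and preserves nodata", {
  st <- tiny_stack(seed = 8, nodata = cbind(c(3, 4), c(3, 4)))
  ref <- as.data.frame(sapply(canonical_predictors(),
                              function(nm) rnorm(20)))
  res <- compute_mess(ref, st)
  expect_s3_class(res$mess, "grid_layer")
  per_var <- sapply(res$per_variable, function(l) as.vector(l$values))
  mins <- apply(per_var, 1, min)
  expect_equal(as.vector(res$mess$values), mins)
  expect_true(all(is.na(res$mess$values[cbind(c(3, 4), c(3, 4))])))
  expect_true(all(res$mess$values <= 100, na.rm = TRUE))
  # negative exactly where some variable leaves its reference range
  outside <- rep(FALSE, length(mins))
  for (nm in canonical_predictors()) {
    v <- as.vector(t(st[[nm]]$values))
    outside <- outside | v < min(ref[[nm]]) | v > max(ref[[nm]])
  }
  vals <- as.vector(t(res$mess$values))
  ok <- !is.na(vals)
  expect_equal(vals[ok] < 0, outside[ok])
})

test_that("a query at every variable's median scores 100", {
  set.seed(5)
  # even reference count: the median splits the sample 50/50, so f = 50 per
  # variable and the similarity is maximal
  ref <- as.data.frame(sapply(canonical_predictors(), function(nm) rnorm(20)))
  q <- as.data.frame(lapply(ref, median))
  expect_equal(compute_mess(ref, q)$mess, 100)
})

test_that("name mismatches and constant reference columns are rejected", {
  ref <- as.data.frame(sapply(canonical_predictors(), function(nm) rnorm(10)))
  q <- ref
  names(q)[2] <- "wrong_name"
  expect_error(compute_mess(ref, q), "wrong|lacks|gpw")
  ref2 <- ref
  ref2[[3]] <- 7
  expect_error(compute_mess(ref2, ref), "degenerate.*povmap")
})

test_that("the validity mask keeps cells strictly above the median of positives", {
  g <- grid_layer(matrix(c(-10, 5, 10, 20), 2, 2), 0, 2, 0, 2)
  res <- structure(list(mess = g), class = "mess_result")
  mask <- validity_mask(res)
  expect_equal(mask$threshold, 10)
  expect_equal(sum(mask$keep$values == 1), 1)
  expect_equal(mask$keep$values[g$values == 20], 1)

  # strictness: everything at the threshold is excluded
  res2 <- structure(list(mess = grid_layer(matrix(100, 2, 2), 0, 2, 0, 2)),
                    class = "mess_result")
  mask2 <- validity_mask(res2)
  expect_equal(mask2$threshold, 100)
  expect_true(all(mask2$keep$values == 0))

  res3 <- structure(list(mess = grid_layer(matrix(c(-1, -2), 1, 2), 0, 2, 0, 1)),
                    class = "mess_result")
  expect_error(validity_mask(res3), "all MESS non-positive")
})

test_that("the even-count positive median uses the midpoint, and the mild rule keeps >= 0", {
  vals <- c(-3, 2, 4, 6, 8, NA)
  res <- structure(list(mess = vals), class = "mess_result")
  mask <- validity_mask(res)
  expect_equal(mask$threshold, 5)   # midpoint of 4 and 6
  expect_equal(mask$keep, c(FALSE, FALSE, FALSE, TRUE, TRUE, NA))
  soft <- validity_mask(res, rule = "nonnegative")
  expect_equal(soft$keep, c(FALSE, TRUE, TRUE, TRUE, TRUE, NA))
})
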