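test_that("the correlation screen recovers exact correlations and flags constants", {
  tab <- make_table(n = 30, seed = 2)
  tab$ho <- tab$GDP_per_capita_2015           # y = x exactly
  rep <- correlation_screen(tab)
  r_gdp <- rep$r[rep$predictor == "GDP_per_capita_2015"]
  expect_equal(r_gdp, 1)
  expect_lt(rep$p[rep$predictor == "GDP_per_capita_2015"], 1e-12)

  tab2 <- make_table(n = 3, seed = 3)
  tab2$povmap.grdi.v1 <- c(1, 2, 3)
  tab2$ho <- c(3, 2, 1)
  rep2 <- correlation_screen(tab2)
  expect_equal(rep2$r[rep2$predictor == "povmap.grdi.v1"], -1)

  tab3 <- make_table(n = 20, seed = 4)
  tab3$travel_time_to_ports_5_MOD <- 5
  expect_warning(rep3 <- correlation_screen(tab3), "constant")
  expect_true(is.na(rep3$r[rep3$predictor == "travel_time_to_ports_5_MOD"]))
  expect_equal(rep3$n, rep(20, 5))
})

test_that("correlations are invariant under affine rescaling of a predictor", {
  tab <- make_table(n = 40, beta = c(0.3, 0.2, 0, 0, 0), seed = 5)
  base <- correlation_screen(tab)
  tab$GDP_per_capita_2015 <- 1000 * tab$GDP_per_capita_2015 + 7
  tab$gpw_v4_population_density_2020 <- -2 * tab$gpw_v4_population_density_2020
  resc <- correlation_screen(tab)
  expect_equal(resc$r[1], base$r[1])
  expect_equal(resc$r[2], -base$r[2])  # sign flips with a negative scale
  expect_equal(resc$p, base$p)
})

test_that("PCA is a proper orthogonal decomposition of the standardized table", {
  tab <- make_table(n = 50, beta = c(0.4, 0.2, 0.1, 0, 0), seed = 6)
  pca <- run_pca(tab)
  expect_equal(sum(pca$explained), 1)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_true(all(pca$explained >= 0))
  # loadings orthonormal; scores x t(loadings) reconstructs the scaled data
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
               ignore_attr = TRUE)
  z <- scale(as.matrix(tab[pca$variables]))
  expect_equal(pca$scores %*% t(pca$loadings), z, tolerance = 1e-9,
               ignore_attr = TRUE)
  # score covariances diagonal
  cv <- cov(pca$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("two perfectly correlated variables load entirely on one component", {
  set.seed(7)
  x <- rnorm(30)
  tab <- data.frame(a = x, b = 2 * x + 1)
  fit <- prcomp(tab, center = TRUE, scale. = TRUE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  expect_equal(expl[1], 1)
})

test_that("the include_ho flag controls whether Ho is an active variable", {
  tab <- make_table(n = 30, seed = 8)
  expect_equal(run_pca(tab, include_ho = TRUE)$variables,
               c("ho", canonical_predictors()))
  expect_equal(run_pca(tab, include_ho = FALSE)$variables, canonical_predictors())
  expect_error(run_pca(make_table(n = 5)), "more localities")
})

test_that("HCPC finds two well-separated clouds and honors explicit k", {
  set.seed(10)
  n_half <- 20
  shift <- rep(c(-10, 10), each = n_half)
  tab <- make_table(n = 2 * n_half, beta = rep(0, 5), noise_sd = 0, seed = 10)
  for (nm in canonical_predictors()) {
    tab[[nm]] <- rnorm(2 * n_half, sd = 0.1) + shift
  }
  tab$ho <- pmin(pmax(0.5 + 0.01 * shift + rnorm(2 * n_half, sd = 0.001), 0), 1)
  pca <- run_pca(tab)
  cl <- hcpc(pca)
  expect_equal(cl$k, 2L)
  expect_equal(length(unique(cl$labels[1:n_half])), 1)
  expect_equal(length(unique(cl$labels[(n_half + 1):(2 * n_half)])), 1)
  expect_true(cl$labels[1] != cl$labels[2 * n_half])

  cl_n <- hcpc(pca, k = nrow(tab))
  expect_equal(sort(cl_n$labels), seq_len(nrow(tab)))
})

test_that("duplicating every point preserves co-clustering of duplicates", {
  tab <- make_table(n = 15, seed = 12)
  tab2 <- rbind(tab, tab)
  cl <- hcpc(run_pca(tab2), k = 3)
  expect_equal(cl$labels[1:15], cl$labels[16:30])
})

test_that("the island/mainland Wilcoxon test matches exact enumeration", {
  # all C(6,3) = 20 equally likely rank assignments: the observed split is the
  # most extreme, so the one-sided tail is 1/20 and the two-sided p is 0.1
  ranks <- combn(6, 3)
  w_obs <- sum(4:6) - 3 * 4 / 2
  w_all <- apply(ranks, 2, function(ix) sum(ix) - 3 * 4 / 2)
  p_exact <- 2 * mean(w_all >= w_obs)
  expect_equal(p_exact, 0.1)

  tab <- data.frame(ho = c(1, 2, 3, 4, 5, 6) / 10,
                    insularity = rep(c("mainland", "island"), each = 3))
  res <- island_mainland_test(tab)
  expect_true(res$exact)
  expect_equal(res$p_value, p_exact)

  tied <- data.frame(ho = rep(0.5, 4),
                     insularity = rep(c("island", "mainland"), each = 2))
  res2 <- island_mainland_test(tied)
  expect_false(res2$exact)
  expect_equal(res2$p_value, 1)

  expect_error(island_mainland_test(data.frame(ho = 1:3, insularity = "island")),
               "mainland")
})

test_that("the normal approximation tracks exact enumeration at n1 = n2 = 8", {
  set.seed(14)
  for (rep_i in 1:5) {
    a <- rnorm(8); b <- rnorm(8, mean = 0.5)
    p_ex <- wilcox.test(a, b, exact = TRUE)$p.value
    p_ap <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
})
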