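test_that("conservation gradient matches closed forms and the textbook formula", {
  # affine decrease of score with distance -> perfect anticorrelation
  d <- c(0, 1:10)
  s <- 5 - 0.3 * d
  g <- conservation_gradient(d, s, ref_index = 1,
                             gradient_variant(min_points = 3))
  expect_equal(as.numeric(g), -1)
  expect_equal(attr(g, "n_points"), 10L)

  # constant scores: zero variance -> missing
  gc <- conservation_gradient(d, rep(2, 11), 1, gradient_variant(min_points = 3))
  expect_true(is.na(as.numeric(gc)))

  # 5-point toy vs brute-force Pearson formula
  d5 <- c(0, 2, 5, 8, 11, 20)
  s5 <- c(99, 9, 7, 8, 4, 1)   # ref residue score ignored
  g5 <- conservation_gradient(d5, s5, 1, gradient_variant(min_points = 3))
  expect_equal(as.numeric(g5), bf_pearson(d5[-1], s5[-1]), tolerance = 1e-12)

  # spearman = pearson on ranks
  gs <- conservation_gradient(d5, s5, 1,
                              gradient_variant("spearman", min_points = 3))
  expect_equal(as.numeric(gs), bf_spearman(d5[-1], s5[-1]), tolerance = 1e-12)

  expect_error(conservation_gradient(d5, s5, 7), "out of range")
})

test_that("gradient is invariant to score shifts and distance scaling", {
  set.seed(31)
  for (rep in 1:25) {
    n <- 30L
    d <- c(0, runif(n - 1, 1, 40))
    s <- rnorm(n)
    v <- gradient_variant()
    g0 <- as.numeric(conservation_gradient(d, s, 1, v))
    expect_equal(as.numeric(conservation_gradient(d, s + 7.3, 1, v)), g0,
                 tolerance = 1e-12)
    expect_equal(as.numeric(conservation_gradient(d * 2.5, s, 1, v)), g0,
                 tolerance = 1e-12)
    # spearman invariant under strictly monotone transforms of score
    vs <- gradient_variant("spearman")
    gs0 <- as.numeric(conservation_gradient(d, s, 1, vs))
    expect_equal(as.numeric(conservation_gradient(d, exp(s), 1, vs)), gs0,
                 tolerance = 1e-12)
  }
})

test_that("distance windows apply their boundary rules exactly", {
  # distances engineered on the boundaries: 6.0 excluded from (6,30],
  # 30.0 included in both windowed variants
  d <- c(0, 5, 6, 6.0001, 15, 30, 30.0001, 35)
  s <- c(0, rnorm(7))
  v30 <- gradient_variant(window = "30", min_points = 3)
  v630 <- gradient_variant(window = "6-30", min_points = 3)
  g30 <- conservation_gradient(d, s, 1, v30)
  g630 <- conservation_gradient(d, s, 1, v630)
  expect_equal(attr(g30, "n_points"), 5L)   # 5, 6, 6.0001, 15, 30
  expect_equal(attr(g630, "n_points"), 3L)  # 6.0001, 15, 30
  expect_equal(as.numeric(g630),
               bf_pearson(d[c(4, 5, 6)], s[c(4, 5, 6)]), tolerance = 1e-12)

  # windowed point sets are subsets of the full window everywhere
  s50 <- random_structure(50, seed = 12)
  prof <- plant_conservation(s50, 7L, beta = 0.2, sigma = 1, seed = 2)
  gp_full <- gradient_profile(s50, prof, gradient_variant())
  gp_30 <- gradient_profile(s50, prof, v30)
  gp_630 <- gradient_profile(s50, prof, v630)
  expect_true(all(gp_30$n_points <= gp_full$n_points))
  expect_true(all(gp_630$n_points <= gp_30$n_points))
})

test_that("gradient profiles equal per-residue brute-force recomputation", {
  s <- random_structure(50, seed = 13)
  prof <- plant_conservation(s, c(3L, 9L), beta = 0.25, sigma = 0.8, seed = 5)
  dmat <- ca_distance_matrix(s)
  for (v in list(gradient_variant(), gradient_variant("spearman"),
                 gradient_variant(window = "30"))) {
    gp <- gradient_profile(s, prof, v)
    for (i in seq_len(50)) {
      keep <- seq_len(50) != i & dmat[i, ] > v$window[1] &
        dmat[i, ] <= v$window[2]
      expected <- if (sum(keep) < v$min_points) NA_real_ else {
        if (v$method == "pearson") bf_pearson(dmat[i, keep], prof$scores[keep])
        else bf_spearman(dmat[i, keep], prof$scores[keep])
      }
      expect_equal(gp$gradient[i], expected, tolerance = 1e-10)
    }
    expect_true(all(is.na(gp$gradient) |
                      (gp$gradient >= -1 & gp$gradient <= 1)))
  }
})

test_that("residue order does not affect a residue's gradient", {
  s <- random_structure(30, seed = 14)
  prof <- plant_conservation(s, 4L, beta = 0.3, sigma = 0.5, seed = 6)
  gp <- gradient_profile(s, prof)
  set.seed(7)
  perm <- sample(30)
  s2 <- s
  s2$residues <- s2$residues[perm, ]
  s2$residues$resi <- seq_len(30)
  prof2 <- conservation_profile(s$protein_id, prof$scores[perm])
  gp2 <- gradient_profile(s2, prof2)
  expect_equal(gp2$gradient, gp$gradient[perm], tolerance = 1e-12)
})

test_that("percolation correlation behaves at the extremes and matches brute force", {
  set.seed(41)
  ranks <- runif(30)
  expect_equal(percolation_correlation(ranks, -ranks), -1)
  g <- rnorm(30)
  expect_equal(percolation_correlation(ranks, g), bf_pearson(ranks, g),
               tolerance = 1e-12)
  expect_true(is.na(percolation_correlation(ranks[1:5], g[1:5])))  # < min_points
  # planted null: near zero at large n
  set.seed(42)
  big_r <- runif(5000); big_g <- rnorm(5000)
  expect_lt(abs(percolation_correlation(big_r, big_g)), 0.05)
})

test_that("residualization removes exactly the covariate contribution", {
  set.seed(51)
  n <- 200L
  ranks <- runif(n)
  cov <- rnorm(n, 10, 3)

  # constant covariate: nothing to subtract
  g <- rnorm(n)
  adj <- residualize_gradient(g, ranks, rep(5, n))
  expect_equal(as.numeric(adj), g)

  # gradients an exact multiple of the covariate: adjusted collapses to the
  # pooled mean
  g2 <- 0.5 * cov
  adj2 <- residualize_gradient(g2, ranks, cov)
  expect_equal(as.numeric(adj2), rep(mean(g2), n), tolerance = 1e-9)

  # general case against the normal-equation oracle
  g3 <- -0.2 - 0.5 * ranks + 0.03 * cov + rnorm(n, 0, 0.05)
  adj3 <- residualize_gradient(g3, ranks, cov)
  X <- cbind(1, ranks, cov)
  beta <- solve(t(X) %*% X, t(X) %*% g3)
  expect_equal(unname(attr(adj3, "coef")), as.numeric(beta), tolerance = 1e-8)
  expect_equal(as.numeric(adj3), g3 - beta[3] * (cov - mean(cov)),
               tolerance = 1e-8)
  # pooled mean preserved
  expect_equal(mean(adj3), mean(g3), tolerance = 1e-10)

  expect_error(residualize_gradient(g3, rep(0.5, n), cov), "zero variance")
  expect_error(residualize_gradient(g3[1:5], ranks[1:5], cov[1:5]),
               "at least 10")
})

test_that("gradient tables report signed r and positive strength", {
  s <- random_structure(25, seed = 15)
  prof <- plant_conservation(s, 2L, beta = 0.3, sigma = 0.3, seed = 8)
  gp <- gradient_profile(s, prof)
  tab <- gradient_table(gp)
  expect_equal(tab$gradient_strength, -tab$gradient_r)
  expect_equal(tab$resi, 1:25)
  expect_equal(unique(tab$window), "full")
})
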