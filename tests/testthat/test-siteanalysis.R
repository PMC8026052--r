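test_that("binned trends recover exact linear data and bin bookkeeping", {
  x <- seq(0, 1, length.out = 200)
  bt <- bin_trend(x, x, 20)
  expect_equal(bt$fit$slope, 1, tolerance = 1e-12)
  expect_equal(bt$fit$intercept, 0, tolerance = 1e-12)
  expect_equal(bt$fit$r, 1, tolerance = 1e-12)
  expect_equal(sum(bt$bins$count), 200)

  # single populated bin: global fit still defined, bin means = global means
  x1 <- runif(50, 0.52, 0.54)
  y1 <- rnorm(50)
  bt1 <- bin_trend(x1, y1, 20)
  filled <- bt1$bins[bt1$bins$count > 0, ]
  expect_equal(nrow(filled), 1L)
  expect_equal(filled$mean_x, mean(x1))
  expect_equal(filled$mean_y, mean(y1))
  expect_false(is.na(bt1$fit$slope))

  expect_error(bin_trend(c(0.5, 1.2), c(1, 2), 10), "lie in")
  expect_error(bin_trend(0.5, 1, 10), "at least 2")
})

test_that("bin means match a brute-force group-by on 1000 rows x 100 bins", {
  set.seed(61)
  x <- runif(1000)
  y <- 2 - 3 * x + rnorm(1000)
  bt <- bin_trend(x, y, 100)
  edges <- seq(0, 1, length.out = 101)
  idx <- cut(x, edges, include.lowest = TRUE, right = TRUE, labels = FALSE)
  for (b in unique(idx)) {
    expect_equal(bt$bins$mean_y[b], mean(y[idx == b]), tolerance = 1e-12)
    expect_equal(bt$bins$count[b], sum(idx == b))
  }
  expect_equal(sum(bt$bins$count), 1000)
  # global fit over residues, not bin means
  expect_equal(bt$fit$slope, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  expect_equal(bt$fit$r, bf_pearson(x, y), tolerance = 1e-12)
})

make_table <- function(n, seed, pid = "p1") {
  set.seed(seed)
  data.frame(protein_id = pid, resi = seq_len(n),
             rank = runif(n), dnds = runif(n, 0, 1.5),
             gradient_r = runif(n, -1, 1),
             sc_wcn = runif(n, 0.5, 5), dist_to_center = runif(n, 0, 25),
             stringsAsFactors = FALSE)
}

test_that("site subset resampling is seeded, uniform and mean-centered", {
  tab <- make_table(500, 71)
  sites <- data.frame(protein_id = "p1", site_id = "s1",
                      site_type = "catalytic", resi = 1:500)
  # pool of exactly subset_size: every subset is the whole pool
  sub_full <- sample_site_subsets(tab[1:250, ], sites, "catalytic",
                                  n_subsets = 5, subset_size = 250, seed = 1)
  expect_equal(length(unique(sub_full$mean_dnds)), 1L)
  expect_equal(sub_full$mean_dnds[1], mean(tab$dnds[1:250]))

  # fixed seed reproduces bitwise; different seed differs
  s1 <- sample_site_subsets(tab, sites, "catalytic", 50, 100, seed = 9)
  s2 <- sample_site_subsets(tab, sites, "catalytic", 50, 100, seed = 9)
  s3 <- sample_site_subsets(tab, sites, "catalytic", 50, 100, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1$mean_dnds, s3$mean_dnds))

  # sampling-theory check: subset means centred on the pool mean
  subs <- sample_site_subsets(tab, sites, "catalytic", 1000, 250, seed = 3)
  pool_mean <- mean(tab$dnds)
  se <- sd(subs$mean_dnds)
  expect_lt(abs(mean(subs$mean_dnds) - pool_mean), 3 * se)

  # small pool falls back to replacement with a warning
  expect_warning(
    sample_site_subsets(tab[1:50, ], sites, "catalytic", 10, 250, seed = 2),
    "with replacement")
  expect_error(sample_site_subsets(tab, sites, "allosteric", 10, 10),
               "empty residue pool")
})

test_that("top-k conserved residues come out by rank with index tie-breaks", {
  expect_equal(top_k_conserved(c(4, 9), c(0.5, 0.9), k = 3), c(4, 9))
  expect_equal(sort(top_k_conserved(1:4, c(0.9, 0.5, 0.7, 0.95), k = 3)),
               c(1, 3, 4))
  # tie on rank -> lowest residue position wins
  expect_equal(top_k_conserved(c(10, 2, 30), c(0.8, 0.8, 0.1), k = 1), 2)
  # random sites vs brute-force sort-and-slice
  set.seed(81)
  for (rep in 1:20) {
    resi <- sample(1000, 10)
    ranks <- runif(10)
    bf <- resi[order(-ranks, resi)][1:3]
    expect_equal(top_k_conserved(resi, ranks, 3), bf)
  }
})

test_that("buried non-functional pseudo-sites respect thresholds and exclusions", {
  tab <- make_table(100, 91)
  tab$sc_wcn <- seq(0.5, 5, length.out = 100)
  func <- data.frame(protein_id = "p1", site_id = "f1",
                     site_type = "catalytic", resi = 95:100)
  bn <- buried_nonfunctional_sites(tab, func, by = "sc_wcn")
  expect_true(all(tab$sc_wcn[match(bn$resi, tab$resi)] > 3.0))
  expect_false(any(bn$resi %in% 95:100))
  expect_true(all(bn$site_type == "buried_nonfunctional"))
  bd <- buried_nonfunctional_sites(tab, func, by = "dist_to_center")
  expect_true(all(tab$dist_to_center[match(bd$resi, tab$resi)] < 5.0))
})

test_that("the exact binomial test matches closed forms and stats::binom.test", {
  expect_equal(binomial_test(10, 10), 2 * (1 / 1024))
  expect_equal(binomial_test(10, 20), 1)
  expect_equal(binomial_test(0, 10), binomial_test(10, 10))  # symmetry
  expect_error(binomial_test(11, 10), "0 <= k <= n")
  expect_error(binomial_test(-1, 10), "0 <= k <= n")

  # full enumeration agreement with the independent implementation for
  # every (k, n) with n <= 25
  for (n in 1:25) {
    for (k in 0:n) {
      expect_equal(binomial_test(k, n, 0.5),
                   stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
      expect_equal(binomial_test(k, n, 0.3),
                   stats::binom.test(k, n, 0.3)$p.value, tolerance = 1e-12)
      expect_equal(binomial_test(k, n, 0.5, "greater"),
                   stats::binom.test(k, n, 0.5,
                                     alternative = "greater")$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("concordance analysis counts, tests and stays symmetric", {
  # two proteins, two sites each; construct ranks/gradients so that every
  # cross-site pair is concordant (higher rank -> more negative gradient)
  tab <- data.frame(
    protein_id = rep(c("p1", "p2"), each = 20),
    resi = rep(1:20, 2),
    rank = rep(seq(0.05, 1, by = 0.05), 2),
    gradient_r = rep(seq(0.5, -0.45, by = -0.05), 2),
    stringsAsFactors = FALSE)
  sites <- rbind(
    data.frame(protein_id = "p1", site_id = "c1", site_type = "catalytic",
               resi = 11:15),
    data.frame(protein_id = "p1", site_id = "l1", site_type = "ppi",
               resi = 1:2),
    data.frame(protein_id = "p2", site_id = "c2", site_type = "catalytic",
               resi = 16:20),
    data.frame(protein_id = "p2", site_id = "l2", site_type = "ppi",
               resi = 3:4))
  out <- concordance_analysis(tab, sites, "catalytic", "ppi")
  expect_equal(out$n_total, 20L)         # (5x2) + (5x2)
  expect_equal(out$fraction, 1)
  expect_equal(out$p_value, 2 * 0.5^20)  # all concordant at n = 20

  # symmetric in the two class filters
  out_sw <- concordance_analysis(tab, sites, "ppi", "catalytic")
  expect_equal(out_sw$fraction, out$fraction)
  expect_equal(out_sw$n_total, out$n_total)

  # a 50/50 split is exactly null
  tab2 <- tab
  flip <- tab2$protein_id == "p2"
  tab2$gradient_r[flip] <- rev(tab2$gradient_r[flip])  # p2 pairs discordant
  out2 <- concordance_analysis(tab2, sites, "catalytic", "ppi")
  expect_equal(out2$fraction, 0.5)
  expect_equal(out2$p_value, 1)

  # rank ties drop the pair
  tab3 <- tab
  tab3$rank[tab3$protein_id == "p1"] <- 0.5
  out3 <- concordance_analysis(tab3, sites, "catalytic", "ppi")
  expect_equal(out3$n_total, 10L)
  expect_equal(out3$n_dropped_ties, 10L)

  # top-1 pairing keeps one residue per site
  out_t1 <- concordance_analysis(tab, sites, "catalytic", "ppi",
                                 pairing_mode = "top1_per_site")
  expect_equal(out_t1$n_total, 2L)

  expect_error(concordance_analysis(tab, sites, "allosteric", "ppi"),
               "no cross-site")
})

test_that("planted two-class synthetic proteins give concordance above chance", {
  cfg <- synthetic_config(
    n_proteins = 12, n_residues = 100,
    sites = list(list(site_type = "catalytic", k = 4, beta = 0.35, s0 = 0),
                 list(site_type = "ppi", k = 4, beta = 0.05, s0 = 0)),
    sigma = 0.6, seed = 404)
  ds <- generate_dataset(cfg)
  gradients <- lapply(ds$structures, function(s) {
    list(gradient_profile(s, ds$profiles[[s$protein_id]]))
  })
  tab <- build_residue_table(ds$structures, ds$profiles, gradients, ds$rates)
  out <- concordance_analysis(tab, ds$sites, "catalytic", "ppi")
  expect_gte(out$n_total, 100L)
  expect_gt(out$fraction, 0.5)
  expect_lt(out$p_value, 0.01)
})

test_that("bootstrap standard errors are seeded and calibrated", {
  expect_equal(bootstrap_se(rep(3, 50), seed = 1), 0)
  v <- rnorm(100)
  expect_equal(bootstrap_se(v, 50, seed = 7), bootstrap_se(v, 50, seed = 7))
  expect_error(bootstrap_se(1), "at least 2")
  expect_error(bootstrap_se(1:10, n_rounds = 1), "n_rounds")
  # CLT reference: SE of the mean of 10,000 standard normals is ~0.01
  set.seed(8)
  big <- rnorm(10000)
  se <- bootstrap_se(big, 500, seed = 9)
  expect_lt(abs(se - 0.01) / 0.01, 0.2)
})
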