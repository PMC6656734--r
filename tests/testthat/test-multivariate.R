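test_that("correlation PCA matches closed forms", {
  # two perfectly correlated columns -> PC1 carries everything
  x <- rnorm(50)
  p1 <- pca_correlation(data.frame(a = x, b = 2 * x + 3))
  expect_equal(p1$variance_fractions[1], 1, tolerance = 1e-12)
  # eigenvalues of [[1, r], [r, 1]] are 1 + r and 1 - r
  with_seed(4, {
    z1 <- rnorm(4000); z2 <- rnorm(4000)
    a <- z1
    b <- 0.5 * z1 + sqrt(1 - 0.25) * z2
    r <- stats::cor(a, b)
    p2 <- pca_correlation(data.frame(a = a, b = b))
    expect_equal(p2$variance_fractions, c(1 + r, 1 - r) / 2, tolerance = 1e-12)
    # independent large-n columns: fractions near 1/p
    X <- as.data.frame(matrix(rnorm(4000 * 4), ncol = 4))
    p3 <- pca_correlation(X)
    expect_true(all(abs(p3$variance_fractions - 0.25) < 0.05))
  })
})

test_that("PCA fractions sum to 1 and ignore affine rescaling", {
  with_seed(9, {
    X <- as.data.frame(matrix(rnorm(60 * 5), ncol = 5))
    p1 <- pca_correlation(X)
    expect_equal(sum(p1$variance_fractions), 1)
    expect_true(all(diff(p1$variance_fractions) <= 1e-12))
    X2 <- X
    X2[[2]] <- X2[[2]] * 100 - 7
    p2 <- pca_correlation(X2)
    expect_equal(p1$variance_fractions, p2$variance_fractions,
                 tolerance = 1e-10)
  })
  expect_message(
    p <- pca_correlation(data.frame(a = rnorm(10), b = rnorm(10), c = 1)),
    "constant")
  expect_equal(p$dropped, "c")
  expect_error(pca_correlation(data.frame(a = rnorm(10), c = 1)),
               "fewer than 2")
})

test_that("spearman matches hand-computed values", {
  expect_equal(spearman_test(1:4 * 1, c(2, 4, 6, 8) * 1, n_perm = 0)$rho, 1)
  # tie at 7 gets average rank 3.5: rho = 8/sqrt(95)
  st <- spearman_test(1:5, c(5, 6, 7, 8, 7))
  expect_equal(st$rho, 8 / sqrt(95), tolerance = 1e-12)
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_test(x, -x)$rho, -1)
  # symmetry and monotone invariance
  with_seed(2, {
    a <- rnorm(30); b <- rnorm(30)
    s1 <- spearman_test(a, b); s2 <- spearman_test(b, a)
    expect_equal(s1$rho, s2$rho)
    expect_equal(s1$p_t, s2$p_t)
    s3 <- spearman_test(exp(a), b)
    expect_equal(s1$rho, s3$rho)
  })
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})

test_that("permutation p-values are seeded, valid and null-uniform", {
  with_seed(6, {
    x <- rnorm(20); y <- rnorm(20)
    s1 <- spearman_test(x, y, n_perm = 199, seed = 5)
    s2 <- spearman_test(x, y, n_perm = 199, seed = 5)
    expect_equal(s1$p_perm, s2$p_perm)
    expect_gte(s1$p_perm, 1 / 200)
    expect_lte(s1$p_perm, 1)
  })
  # under independence the permutation p-value is ~uniform
  ps <- with_seed(77, vapply(1:120, function(b) {
    spearman_test(rnorm(15), rnorm(15), n_perm = 99, seed = b)$p_perm
  }, numeric(1)))
  # permutation p-values are discrete, so ties are expected
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("divergence-rate correlation behaves under null and linked rates", {
  cfg <- simulate_config(n_taxa = 25, seed = 55, lambda = 0.6,
                         event_weights = c(T = 0.4, r = 0.4, rT = 0.2,
                                           tdrl = 0, d = 0, x = 0))
  sim <- simulate_dataset(cfg)
  orders <- suppressMessages(restrict_to_shared_genes(
    lapply(sim$records, extract_gene_order)))
  linked <- make_rate_table(sim$tree, sim$truth, cfg, mode = "linked", b = 0.5)
  rep_l <- mgo_rate_correlation(orders, rates = linked[, c("taxon_id", "rate")],
                                n_perm = 199, seed = 1)
  expect_gt(rep_l$rho[rep_l$pairing == "divergence~rate"], 0.3)
  null <- make_rate_table(sim$tree, sim$truth, cfg, mode = "null")
  rep_n <- mgo_rate_correlation(orders, rates = null[, c("taxon_id", "rate")],
                                n_perm = 199, seed = 1)
  expect_lt(abs(rep_n$rho[rep_n$pairing == "divergence~rate"]), 0.45)
})

test_that("habitat indicators are tested and degenerate inputs flagged", {
  go <- ground_pattern()
  orders <- stats::setNames(lapply(1:6, function(i) {
    g <- go; g$taxon_id <- paste0("t", i); g
  }), paste0("t", 1:6))
  rates <- data.frame(taxon_id = paste0("t", 1:6), rate = rnorm(6))
  hab <- stats::setNames(rep(c("marine", "freshwater"), 3), paste0("t", 1:6))
  rep_d <- mgo_rate_correlation(orders, rates = rates, habitat = hab,
                                n_perm = 0)
  # all taxa share the reference arrangement: divergence is constant
  expect_true(all(is.na(rep_d$rho)))
  expect_true(any(grepl("habitat:marine", rep_d$pairing)))
  rep_adj <- mgo_rate_correlation(orders, rates = rates, n_perm = 0,
                                  p_adjust = "BH")
  expect_true("p_t_adj" %in% names(rep_adj))
  expect_error(mgo_rate_correlation(orders[1:2],
                                    rates = rates[1:2, ], n_perm = 0),
               "fewer than 4")
})
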