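test_that("Stouffer combination matches the normal-CDF closed form", {
  expect_equal(stouffer(c(0, 0)), list(z_sum = 0, p_sum = 1))
  s <- stouffer(c(1.96, 1.96))
  expect_equal(s$z_sum, 3.92 / sqrt(2), tolerance = 1e-9)
  expect_equal(s$z_sum, 2.7718586, tolerance = 1e-6)
  expect_equal(s$p_sum, 2 * pnorm(-3.92 / sqrt(2)), tolerance = 1e-12)
  expect_equal(s$p_sum, 0.0055737245, tolerance = 1e-7)
  # single z is the identity
  s1 <- stouffer(1.3)
  expect_equal(s1$z_sum, 1.3)
  expect_equal(s1$p_sum, 2 * pnorm(-1.3))
  # one-sided mode takes the upper tail
  expect_equal(stouffer(1.3, two_sided = FALSE)$p_sum, pnorm(-1.3))
  expect_error(stouffer(numeric(0)), ">= 1")
})

test_that("Stouffer p-values are uniform under the null", {
  set.seed(12)
  z <- matrix(rnorm(2 * 10000), nrow = 2)
  p <- apply(z, 2, function(v) stouffer(v)$p_sum)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene score is log10(p) * beta_sum with sign antisymmetry", {
  expect_equal(gene_score(1, 5), 0)
  expect_equal(gene_score(0.01, -2), 4)
  expect_equal(gene_score(0.1, 3), -3)
  # antisymmetric in the sign of beta_sum
  p <- c(0.3, 0.01, 1e-6); b <- c(1.2, -0.5, 3)
  expect_equal(gene_score(p, -b), -gene_score(p, b))
  expect_warning(out <- gene_score(0, 1), "clamped")
  expect_equal(out, -300)
})

test_that("ranking is descending with the documented tie rules", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    gene_score = c(0, 4, -3),
                    beta_sum = c(1, 1, 1))
  expect_equal(rank_genes(tab)$gene, c("b", "a", "c"))
  expect_equal(rank_genes(tab)$rank, 1:3)

  ties <- data.frame(gene = c("late", "early"),
                     gene_score = c(2, 2),
                     beta_sum = c(1, 2))
  expect_equal(rank_genes(ties)$gene, c("early", "late"))

  # order independence
  set.seed(5)
  big <- data.frame(gene = paste0("g", 1:50),
                    gene_score = rnorm(50), beta_sum = rnorm(50))
  r1 <- rank_genes(big)
  r2 <- rank_genes(big[sample(50), ])
  expect_equal(r1, r2)
})

test_that("combining screens sums beta and Stouffer-combines z", {
  fit <- data.frame(
    gene = rep(c("a", "b"), each = 2),
    condition = rep(c("low", "high"), 2),
    beta = c(1.5, -2.5, 0.2, 0.1),
    z = c(3, -4, 0.5, 0.2),
    is_ntc_pseudo = FALSE
  )
  comb <- combine_screens(fit)
  a <- comb[comb$gene == "a", ]
  expect_equal(a$beta_sum, -1)
  expect_equal(a$z_sum, (3 - 4) / sqrt(2))
  expect_equal(a$p_sum, 2 * pnorm(-abs((3 - 4) / sqrt(2))))
  expect_equal(a$gene_score, log10(a$p_sum) * a$beta_sum)
  expect_equal(comb$rank, 1:2)
  expect_equal(attr(comb, "combination")$mode,
               "stouffer_across_all_conditions")
})

test_that("top-fraction k-means separates constructed blobs deterministically", {
  set.seed(30)
  blob <- rbind(
    matrix(rnorm(40 * 3, mean = 5), ncol = 3),
    matrix(rnorm(40 * 3, mean = -5), ncol = 3),
    matrix(rnorm(920 * 3, sd = 0.05), ncol = 3)
  )
  rownames(blob) <- paste0("g", seq_len(nrow(blob)))
  cl <- top_fraction_cluster(blob, fraction = 0.08, k = 2, seed = 4)
  up <- cl$cluster[cl$gene %in% paste0("g", 1:40)]
  down <- cl$cluster[cl$gene %in% paste0("g", 41:80)]
  expect_equal(length(unique(up)), 1)
  expect_equal(length(unique(down)), 1)
  expect_false(unique(up) == unique(down))

  # same seed twice: identical assignments
  cl2 <- top_fraction_cluster(blob, fraction = 0.08, k = 2, seed = 4)
  expect_identical(cl$cluster, cl2$cluster)

  # identical rows collapse to one effective cluster, flagged degenerate
  flat <- matrix(1, 40, 3, dimnames = list(paste0("g", 1:40), NULL))
  cf <- top_fraction_cluster(flat, fraction = 1, k = 8, seed = 1)
  expect_true(attr(cf, "degenerate"))
  expect_equal(length(unique(cf$cluster)), 1)

  expect_error(top_fraction_cluster(blob[1:5, ], fraction = 1, k = 8),
               "fewer eligible")
})

test_that("a shared regulator's combined rank is never worse than its best single screen", {
  n_runs <- 12
  res <- vapply(seq_len(n_runs), function(s) {
    sim <- simulate_screen(sim_config(n_genes = 150, n_ntc = 120,
                                      n_positive = 1, delta_positive = -1.5,
                                      cells_per_guide = 150,
                                      depth_per_guide = 300,
                                      seed = 400 + s))
    g <- sim$truth$genes$gene[sim$truth$genes$role != "null"]
    full <- median_normalize(sim$screen)
    comb <- combine_screens(
      fit_all(full, design_marker_blind(full$samples), seed = 1))
    single <- vapply(c("MHCII", "CD40", "PDL1"), function(mk) {
      one <- median_normalize(subset_screen(sim$screen, mk))
      cb <- combine_screens(
        fit_all(one, design_marker_blind(one$samples), seed = 1))
      cb$rank[cb$gene == g]
    }, 0)
    c(combined = comb$rank[comb$gene == g], best_single = min(single))
  }, c(0, 0))
  expect_gte(mean(res["combined", ] <= res["best_single", ]), 0.8)
})
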