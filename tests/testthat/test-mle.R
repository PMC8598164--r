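test_that("design matrices encode the marker-blind and marker-aware contrasts", {
  sheet <- sample_sheet(
    sample_id = c("input_r1", "input_r2",
                  paste0(rep(c("MHCII", "CD40", "PDL1"), each = 4), "_",
                         rep(c("high", "low"), 6), "_r", rep(1:2, each = 2))),
    marker = c(NA, NA, rep(c("MHCII", "CD40", "PDL1"), each = 4)),
    replicate = c(1, 2, rep(rep(1:2, each = 2), 3)),
    bin = c("input", "input", rep(c("high", "low"), 6))
  )
  d <- design_marker_blind(sheet)
  expect_equal(colnames(d), c("low", "high"))
  expect_equal(unname(colSums(d)), c(6, 6))
  expect_true(all(d[sheet$bin == "input", ] == 0))

  da <- design_marker_aware(sheet, "low")
  expect_equal(sort(colnames(da)), sort(c("MHCII", "CD40", "PDL1")))
  expect_equal(unname(colSums(da)), rep(2, 3))
  expect_true(all(rowSums(da) <= 1))

  # single marker, one replicate pair
  s1 <- tiny_sheet()
  d1 <- design_marker_aware(s1, "high")
  expect_equal(dim(d1), c(3L, 1L))

  expect_error(design_marker_blind(sample_sheet("i", NA, 1, "input")),
               "no sorted")
  s_missing <- sheet[sheet$sample_id != "CD40_high_r1" &
                       sheet$sample_id != "CD40_high_r2", ]
  expect_error(design_marker_aware(s_missing, "high"), "CD40")
})

test_that("dispersion estimation recovers the generating overdispersion", {
  set.seed(2)
  nm <- list(paste0("g", 1:2000), paste0("s", 1:8))
  pois <- matrix(rpois(2000 * 8, 500), 2000, 8, dimnames = nm)
  expect_lte(median(fit_dispersion(pois)$alpha), 0.01)

  nb <- matrix(rnbinom(2000 * 8, size = 5, mu = 500), 2000, 8, dimnames = nm)
  med <- median(fit_dispersion(nb)$alpha)
  expect_gte(med, 0.1)
  expect_lte(med, 0.4)

  const <- matrix(300, 50, 4, dimnames = list(paste0("g", 1:50),
                                              paste0("s", 1:4)))
  expect_equal(unname(fit_dispersion(const)$alpha), rep(1e-4, 50))
})

test_that("single-gene fits match closed forms", {
  des <- matrix(c(0, 1), ncol = 1, dimnames = list(c("in", "out"), "cond"))

  # identical counts everywhere: no selection
  y <- matrix(c(100, 100), nrow = 1, dimnames = list("g", c("in", "out")))
  fit <- fit_gene(y, des, c(1, 1), 1e-4)
  expect_lt(abs(fit$beta), 1e-6)

  # saturated single guide: beta = log2(25/100) = -2
  y2 <- matrix(c(100, 25), nrow = 1, dimnames = list("g", c("in", "out")))
  fit2 <- fit_gene(y2, des, c(1, 1), 1e-4)
  expect_equal(unname(fit2$beta), -2, tolerance = 0.01)
  expect_true(fit2$converged)
  # the one-sided Wald pair partitions the unit interval
  expect_equal(unname(fit2$pos_p + fit2$neg_p), 1)

  # two conditions with disjoint samples: beta = (+1, -1)
  des2 <- matrix(c(0, 1, 0, 0, 0, 1), ncol = 2,
                 dimnames = list(c("in", "a", "b"), c("up", "down")))
  y3 <- matrix(c(200, 400, 100), nrow = 1,
               dimnames = list("g", c("in", "a", "b")))
  fit3 <- fit_gene(y3, des2, c(1, 1, 1), 1e-4)
  expect_equal(unname(fit3$beta), c(1, -1), tolerance = 0.01)
})

test_that("fits agree with the exhaustive grid-search oracle", {
  set.seed(42)
  for (i in 1:25) {
    n_base <- sample(1:3, 1); n_cond <- sample(1:3, 1)
    mu <- exp(runif(1, log(20), log(2000)))
    beta <- runif(1, -4, 3)
    alpha <- runif(1, 1e-3, 0.3)
    sf <- exp(runif(n_base + n_cond, -0.3, 0.3))
    d <- c(rep(0, n_base), rep(1, n_cond))
    m <- sf * mu * 2^(d * beta)
    y <- rnbinom(length(m), size = 1 / alpha, mu = m)
    des <- matrix(d, ncol = 1, dimnames = list(NULL, "cond"))
    fit <- fit_gene(matrix(y, nrow = 1), des, sf, alpha)
    expect_lt(abs(unname(fit$beta) - grid_fit_beta(y, d, sf, alpha)), 0.011)
  }
})

test_that("beta is equivariant to depth and monotone in condition counts", {
  sim <- simulate_screen(sim_config(n_genes = 30, n_ntc = 60, n_positive = 2,
                                    markers = "MHCII", replicates = 1,
                                    cells_per_guide = 150,
                                    depth_per_guide = 300, seed = 3))
  sc <- median_normalize(sim$screen)
  disp <- fit_dispersion(sc)
  des <- design_marker_blind(sc$samples)
  fit1 <- fit_all(sc, des, dispersion = disp, ntc_pseudo = FALSE)

  # scale one sample by 3x and renormalize: the size factors absorb the
  # scaling exactly (the median-of-ratios median element is scale-stable)
  raw2 <- sim$screen$counts
  raw2[, "MHCII_high_r1"] <- raw2[, "MHCII_high_r1"] * 3
  sc2 <- median_normalize(screen_counts(raw2, sc$library, sc$samples))
  expected_sf <- sc$size_factors *
    ifelse(names(sc$size_factors) == "MHCII_high_r1", 3^(2 / 3), 3^(-1 / 3))
  expect_equal(sc2$size_factors, expected_sf, tolerance = 1e-12)
  # beta drift is bounded: tripled integer counts carry less relative
  # Poisson noise, so the NB MLE is only approximately scale-equivariant
  fit2 <- fit_all(sc2, des, dispersion = disp, ntc_pseudo = FALSE)
  bounded <- unique(fit1$gene[abs(fit1$beta) > 7.9 | abs(fit2$beta) > 7.9])
  keep <- !(fit1$gene %in% bounded)
  expect_lt(max(abs(fit2$beta - fit1$beta)[keep]), 0.05)
  expect_gt(cor(fit1$beta[keep], fit2$beta[keep]), 0.99)

  # monotonicity, single guide: raising the condition count raises beta
  des1 <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "cond"))
  betas <- vapply(c(50, 100, 200, 400), function(cc) {
    fit_gene(matrix(c(200, cc), nrow = 1), des1, c(1, 1), 0.05)$beta
  }, 0)
  expect_true(all(diff(betas) > 0))
})

test_that("genome-wide fits rank a strong depleted gene first and build an NTC null", {
  sim <- simulate_screen(sim_config(n_genes = 100, n_ntc = 100,
                                    n_positive = 1, delta_positive = -6,
                                    markers = "MHCII", replicates = 2,
                                    seed = 9))
  sc <- median_normalize(sim$screen)
  fit <- fit_all(sc, design_marker_blind(sc$samples), seed = 1)

  pseudo <- fit[fit$is_ntc_pseudo, ]
  expect_equal(length(unique(pseudo$gene)), 25)  # 100 NTC guides / groups of 4
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(fit$fdr[!fit$is_ntc_pseudo] >= 0 &
                    fit$fdr[!fit$is_ntc_pseudo] <= 1))

  planted <- sim$truth$genes$gene[1]
  high <- fit[!fit$is_ntc_pseudo & fit$condition == "high", ]
  expect_equal(high$gene[which.min(high$beta)], planted)
  expect_equal(truth_eval(fit[fit$condition == "high", ],
                          sim$truth, top_n = 1)$recall, 1)

  # the planted hit is confidently recovered
  expect_lt(high$fdr[high$gene == planted], 0.01)
  # NTC partition is reproducible for a fixed seed
  fit_b <- fit_all(sc, design_marker_blind(sc$samples), seed = 1)
  expect_identical(fit$gene, fit_b$gene)
  expect_equal(fit$beta, fit_b$beta)
})
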