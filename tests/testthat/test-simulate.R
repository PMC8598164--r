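test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(f_high = 0.6, f_low = 0.5), "<= 1")
  expect_error(sim_config(f_low = 0), "positive")
  expect_error(sim_config(n_genes = 5, n_positive = 10), "more planted")
})

test_that("identical seeds give bit-identical screens", {
  cfg <- sim_config(n_genes = 50, n_ntc = 60, seed = 123)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$screen$counts, b$screen$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_screen(sim_config(n_genes = 50, n_ntc = 60, seed = 124))
  expect_false(identical(a$screen$counts, c$screen$counts))
})

test_that("bin occupancy equals the configured gates exactly before sequencing", {
  cfg <- sim_config(n_genes = 80, n_ntc = 60, f_high = 0.15, f_low = 0.2,
                    cells_per_guide = 100, seed = 3)
  sim <- simulate_screen(cfg)
  ss <- sim$truth$sort_stats
  n_cells <- unique(ss$n_cells)
  expect_length(n_cells, 1)
  expect_true(all(ss$cells_in_bin[ss$bin == "high"] ==
                    round(0.15 * n_cells)))
  expect_true(all(ss$cells_in_bin[ss$bin == "low"] ==
                    round(0.2 * n_cells)))
})

test_that("input samples track baseline abundances within sampling error", {
  sim <- simulate_screen(sim_config(n_genes = 100, n_ntc = 100,
                                    n_positive = 0, markers = "MHCII",
                                    replicates = 1, seed = 17))
  w <- sim$truth$guides$baseline_weight
  obs <- sim$screen$counts[, "input_r1"]
  depth <- sum(obs)
  # standardized residuals: sequencing reads are drawn from a finite cell
  # pool, so the two-stage variance is depth*w*(1-w)*(1 + depth/cells)
  n_cells <- 250 * length(w)
  vr <- depth * w * (1 - w) * (1 + depth / n_cells)
  zres <- (obs - depth * w) / sqrt(vr)
  expect_gt(mean(abs(zres) < 4), 0.99)
  expect_gt(cor(obs, w), 0.9)
})

test_that("a null screen is symmetric and a strong planted gene sorts low", {
  null_sim <- simulate_screen(sim_config(n_genes = 500, n_ntc = 300,
                                         n_positive = 0, markers = "MHCII",
                                         replicates = 1,
                                         depth_per_guide = 500, seed = 19))
  sc <- median_normalize(null_sim$screen)
  lfc <- guide_lfc(sc, "MHCII", 1)
  expect_lt(abs(mean(lfc$lfc)), 0.05)

  hit_sim <- simulate_screen(sim_config(n_genes = 100, n_ntc = 100,
                                        n_positive = 1, delta_positive = -6,
                                        markers = "MHCII", replicates = 1,
                                        seed = 23))
  g <- hit_sim$truth$genes$gene[1]
  ids <- hit_sim$truth$guides$guide_id[hit_sim$truth$guides$gene == g]
  cm <- hit_sim$screen$counts
  # efficient guides are >= 4-fold enriched in the low bin over the high bin
  eff <- hit_sim$truth$guides$efficiency[match(ids, hit_sim$truth$guides$guide_id)]
  strong <- ids[eff > 0.5]
  ratio <- (sum(cm[strong, "MHCII_low_r1"]) + 1) /
    (sum(cm[strong, "MHCII_high_r1"]) + 1)
  expect_gte(ratio, 4)
})

test_that("custom per-gene deltas are planted and the proteomics stand-in is structured", {
  cfg <- sim_config(n_genes = 20, n_ntc = 40,
                    n_positive = 0, custom_deltas = c(-2, 0, 1), seed = 2)
  sim <- simulate_screen(cfg)
  tg <- sim$truth$genes
  expect_equal(tg$role[1:3], c("custom", "null", "custom"))
  expect_equal(unname(tg$MHCII[1:3]), c(-2, 0, 1))
  expect_error(sim_config(n_genes = 2, custom_deltas = 1:3, n_positive = 0),
               "custom")

  subs <- paste0("s", 1:10)
  prot <- simulate_subunit_proteomics(subs, module = subs[1:4], seed = 5)
  m <- prot$log2_ratios
  expect_equal(dim(m), c(10L, 10L))
  # knocked-out proteins are strongly depleted in their own line
  expect_true(all(diag(m) < -2))
  # members drop more under strong KOs than weak ones, off-module stays flat
  strong <- names(which.max(prot$strength))
  weak <- names(which.min(prot$strength))
  off <- setdiff(subs, c(subs[1:4], strong, weak))[1]
  expect_lt(mean(m[setdiff(subs[1:4], strong), strong]),
            mean(m[setdiff(subs[1:4], weak), weak]))
  expect_lt(abs(mean(m[setdiff(subs[5:10], off), off])), 1)
  # deterministic
  expect_identical(simulate_subunit_proteomics(subs, subs[1:4], seed = 5),
                   prot)
})

test_that("truth evaluation computes recall and NTC false discoveries", {
  truth <- list(genes = data.frame(
    gene = paste0("g", 1:100),
    role = c(rep("positive_regulator", 10), rep("null", 90))
  ))
  perfect <- data.frame(gene = paste0("g", 1:100), rank = 1:100)
  expect_equal(truth_eval(perfect, truth, top_n = 10)$recall, 1)

  # random ranking: expected recall equals the hypergeometric mean
  set.seed(31)
  recalls <- replicate(3000, {
    truth_eval(data.frame(gene = sample(paste0("g", 1:1000)),
                          rank = 1:1000),
               list(genes = data.frame(
                 gene = paste0("g", 1:1000),
                 role = c(rep("positive_regulator", 10), rep("null", 990)))),
               top_n = 10)$recall
  })
  expect_equal(mean(recalls), 0.01, tolerance = 0.25)

  # no planted regulators: recall is not applicable
  none <- list(genes = data.frame(gene = "g1", role = "null"))
  ev <- truth_eval(data.frame(gene = "g1", rank = 1), none, top_n = 1)
  expect_true(is.na(ev$recall))

  # NTC pseudo-genes in the top list are counted
  mixed <- data.frame(gene = c("NTC_pseudo_001", paste0("g", 1:9)),
                      rank = 1:10)
  ev2 <- truth_eval(mixed, truth, top_n = 10)
  expect_equal(ev2$ntc_pseudo_in_top, 1)
  expect_equal(ev2$ntc_pseudo_fdr, 0.1)
})
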