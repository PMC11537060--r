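test_that("environmental series are seasonal and reproducible", {
  e1 <- generate_env_series(seed = 5)
  e2 <- generate_env_series(seed = 5)
  expect_identical(e1, e2)
  expect_equal(which.max(e1$temperature), 3L)
  expect_true(all(e1$temperature > 10 & e1$temperature < 33))
  # DO is anti-correlated with temperature across seeds
  cors <- vapply(1:30, function(s) {
    e <- generate_env_series(seed = s)
    cor(e$temperature, e$DO)
  }, numeric(1))
  expect_lt(mean(cors), -0.5)
})

test_that("community generation is reproducible and respects the design", {
  cfg <- community_config("LMA", depth = 2000L)
  c1 <- generate_community(cfg, seed = 3, host_label = "T")
  c2 <- generate_community(cfg, seed = 3, host_label = "T")
  expect_identical(unclass(c1$table), unclass(c2$table))
  expect_equal(ncol(c1$table), 15)            # 5 time points x 3 replicates
  expect_true(all(colSums(c1$table) == 2000))
  expect_equal(nrow(c1$metadata), 15)
  expect_equal(unique(c1$metadata$habitat), "sponge")
})

test_that("without turnover the composition is stable across months", {
  cfg <- community_config("LMA", richness = 150L, evenness = 1,
                          turnover = 0, env_response = 0,
                          replicate_noise = 0, depth = 100000L)
  com <- generate_community(cfg, seed = 6, host_label = "T")
  series <- average_replicates(com$table, com$metadata$month)
  d <- bray_curtis(series)
  expect_lt(mean(d), 0.05)
})

test_that("phenotype presets order diversity and seawater sharing", {
  for (s in 1:3) {
    sw <- generate_community(community_config("seawater", depth = 5000L),
                             seed = s, host_label = "SW")
    hma <- generate_community(community_config("HMA", depth = 5000L),
                              seed = s + 10, host_label = "H",
                              seawater_pool = rownames(sw$table))
    lma <- generate_community(community_config("LMA", depth = 5000L),
                              seed = s + 20, host_label = "L",
                              seawater_pool = rownames(sw$table))
    sh <- vapply(list(sw, hma, lma), function(g) {
      mean(alpha_diversity_table(g$table, "shannon")$shannon)
    }, numeric(1))
    expect_gt(sh[1], sh[2])
    expect_gt(sh[2], sh[3])
    expect_gt(shared_asv_summary(lma$table, sw$table)$frac_of_a,
              shared_asv_summary(hma$table, sw$table)$frac_of_a)
  }
})

test_that("higher seawater sharing raises the shared-ASV fraction", {
  sw <- generate_community(community_config("seawater", depth = 5000L),
                           seed = 2, host_label = "SW")
  lo <- generate_community(community_config("LMA", seawater_share = 0.2,
                                            depth = 5000L),
                           seed = 4, host_label = "L1",
                           seawater_pool = rownames(sw$table))
  hi <- generate_community(community_config("LMA", seawater_share = 1,
                                            depth = 5000L),
                           seed = 4, host_label = "L2",
                           seawater_pool = rownames(sw$table))
  expect_gt(shared_asv_summary(hi$table, sw$table)$frac_of_a,
            shared_asv_summary(lo$table, sw$table)$frac_of_a)
})

test_that("planted correlations surface as the strongest Spearman pairs", {
  gt <- generate_ground_truth(12, 3, rho = 0.9, structure = "matching",
                              seed = 8)
  sim <- generate_correlated_counts(gt, n_samples = 60, depth = 50000L,
                                    seed = 9)
  cc <- suppressWarnings(spearman_matrix(sim$table))
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  ranked <- ut[order(abs(cc[ut]), decreasing = TRUE)[1:3], , drop = FALSE]
  top <- apply(ranked, 1L, function(ij) {
    paste(sort(rownames(cc)[ij]), collapse = "|")
  })
  truth <- apply(sim$ground_truth$edges, 1L, function(e) {
    paste(sort(c(e[["from"]], e[["to"]])), collapse = "|")
  })
  expect_setequal(top, truth)

  again <- generate_correlated_counts(gt, n_samples = 60, depth = 50000L,
                                      seed = 9)
  expect_identical(unclass(sim$table), unclass(again$table))
})

test_that("non-positive-definite edge requests are thinned with a warning", {
  gt <- generate_ground_truth(3, 3, rho = 0.9, structure = "random",
                              seed = 1)
  # force a star: two edges sharing a node at rho 0.9 is not PD
  gt$edges <- data.frame(from = c("ASV0001", "ASV0001"),
                         to = c("ASV0002", "ASV0003"),
                         sign = c(1L, 1L))
  expect_warning(
    out <- generate_correlated_counts(gt, n_samples = 20, seed = 2),
    "positive definite")
  expect_lt(nrow(out$ground_truth$edges), 2)
})

test_that("negative planted edges produce negative correlations", {
  gt <- generate_ground_truth(10, 2, rho = 0.85, frac_negative = 1,
                              structure = "matching", seed = 3)
  sim <- generate_correlated_counts(gt, n_samples = 80, depth = 50000L,
                                    seed = 4)
  cc <- suppressWarnings(spearman_matrix(sim$table))
  for (k in seq_len(nrow(sim$ground_truth$edges))) {
    e <- sim$ground_truth$edges[k, ]
    expect_lt(cc[e$from, e$to], -0.5)
  }
})

test_that("the full holobiont dataset has the study layout", {
  ds <- generate_holobiont_dataset(seed = 4, depth = 1500L)
  expect_named(ds$groups, c("Seawater", "Spongia_like", "Tedania_like",
                            "Haliclona_like"))
  expect_equal(ncol(ds$combined), 60)
  expect_equal(nrow(ds$metadata), 60)
  expect_setequal(ds$metadata$sample_id, colnames(ds$combined))
  expect_equal(sum(ds$metadata$habitat == "seawater"), 15)
  phen <- unique(ds$metadata[ds$metadata$host == "Spongia_like",
                             "phenotype"])
  expect_equal(phen, "HMA")
  ds2 <- generate_holobiont_dataset(seed = 4, depth = 1500L)
  expect_identical(unclass(ds$combined), unclass(ds2$combined))
})
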