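test_that("ARI matches hand-expanded pair counting and handles degeneracy", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)

  l1 <- c(1, 1, 2, 2, 3, 3)
  l2 <- c(1, 1, 2, 3, 3, 3)
  expect_equal(adjusted_rand_index(l1, l2), ari_bruteforce(l1, l2))

  # one-cluster partition vs anything -> 0 under the adjustment
  expect_equal(adjusted_rand_index(rep(1, 6), l1), 0)
  # both trivial and identical -> perfect agreement
  expect_equal(adjusted_rand_index(rep(1, 6), rep(2, 6)), 1)
  expect_equal(adjusted_rand_index(1:6, 6:1), 1)

  set.seed(123)
  big1 <- sample(1:5, 400, TRUE)
  big2 <- sample(1:5, 400, TRUE)
  expect_lt(abs(adjusted_rand_index(big1, big2)), 0.05)

  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI agrees with mclust on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    l1 <- sample(1:4, n, TRUE)
    l2 <- sample(1:3, n, TRUE)
    a <- adjusted_rand_index(l1, l2)
    b <- mclust::adjustedRandIndex(l1, l2)
    if (is.finite(b)) expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("crosstab off-diagonal comes from optimal matching, not labeling", {
  # diagonal (50, 40, 30) with 10 off, under scrambled cluster numbers
  l1 <- rep(1:3, c(50, 44, 36))
  l2 <- l1
  l2[1:4] <- 2       # 4 leave cluster 1
  l2[51:53] <- 3     # 3 leave cluster 2
  l2[95:97] <- 1     # 3 leave cluster 3
  relab <- c(2L, 3L, 1L)
  rep1 <- cluster_crosstab(setNames(l1, paste0("s", 1:130)),
                           setNames(relab[l2], paste0("s", 1:130)))
  expect_identical(rep1$offdiag_count, 10L)
  expect_equal(rep1$offdiag_fraction, 10 / 130)

  # enumeration oracle over all 3! matchings
  tab <- table(l1, relab[l2])
  best <- max(apply(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                          c(3, 1, 2), c(3, 2, 1)), 1,
                    function(p) sum(tab[cbind(1:3, p)])))
  expect_identical(rep1$offdiag_count, as.integer(sum(tab) - best))

  # identical labelings
  rep2 <- cluster_crosstab(l1, l1)
  expect_identical(rep2$offdiag_count, 0L)
  expect_equal(rep2$ari, 1)
  expect_identical(rep2$verdict, "homogeneous")

  # independent labelings: near-zero ARI, heterogeneous
  set.seed(42)
  r1 <- sample(1:3, 300, TRUE)
  r2 <- sample(1:3, 300, TRUE)
  rep3 <- cluster_crosstab(r1, r2)
  expect_lt(abs(rep3$ari), 0.05)
  expect_identical(rep3$verdict, "heterogeneous")

  # unequal K: unmatched cluster mass counts as off-diagonal
  l4 <- rep(1:2, each = 20)
  l5 <- c(rep(1, 20), rep(2, 10), rep(3, 10))
  rep4 <- cluster_crosstab(l4, l5)
  expect_identical(rep4$offdiag_count, 10L)

  expect_error(cluster_crosstab(setNames(l4, paste0("a", 1:40)),
                                setNames(l5, paste0("b", 1:40))),
               "different samples")
})

test_that("homogeneity verdict follows the off-diagonal threshold", {
  rep0 <- structure(list(offdiag_fraction = 0.12), class = "comparison_report")
  expect_identical(decide_homogeneity(rep0)$verdict, "homogeneous")
  rep0$offdiag_fraction <- 0.38
  expect_identical(decide_homogeneity(rep0)$verdict, "heterogeneous")
  rep0$offdiag_fraction <- 0.2
  expect_identical(decide_homogeneity(rep0)$verdict, "homogeneous")
  expect_identical(decide_homogeneity(rep0, threshold = 0.1)$verdict,
                   "heterogeneous")
})

test_that("merging two copies of one source reproduces its solution", {
  fused <- tiny_fused_sim(n = 36, p = 30, seed = 13, grid_n = 8)
  ds <- standardize_features(fused$sim$datasets[[1]])
  ds2 <- ds
  ds2$name <- "omb"
  colnames(ds2$values) <- paste0("b_", colnames(ds2$values))
  cc <- concatenate_omics(list(ds, ds2))
  emb <- embed_concat(cc)
  cfg <- run_config(grid_n = 8, k_max = 4, gap_B = 10, basis_k = 15,
                    seed = 3)
  one <- merge_and_recluster(emb, cc, "om", cfg)
  both <- merge_and_recluster(emb, cc, c("om", "omb"), cfg)
  expect_identical(both$solution$K, one$solution$K)
  expect_equal(adjusted_rand_index(both$solution$labels,
                                   one$solution$labels), 1)
})

test_that("workflow merges concordant sources and exposes discordant ones", {
  spec <- sim_spec(45, 3, list(list(name = "omA", n_features = 40),
                               list(name = "omB", n_features = 40)),
                   effect_size = 3, within_sd = 1, noise_fraction = 0.3,
                   seed = 61)
  cfg <- run_config(grid_n = 8, k_max = 4, gap_B = 10, basis_k = 15,
                    seed = 2, filter_sd_quantile = 0, filter_mean_quantile = 0)

  hom <- homogeneous_pair(spec)
  wf_hom <- run_workflow(hom$datasets, cfg)
  expect_length(wf_hom$merge_plan$merges, 1L)
  expect_length(wf_hom$merge_plan$groups, 1L)
  expect_identical(wf_hom$merge_plan$merges[[1]]$report$verdict,
                   "homogeneous")

  het <- heterogeneous_pair(spec)
  wf_het <- run_workflow(het$datasets, cfg)
  expect_length(wf_het$merge_plan$merges, 0L)
  expect_length(wf_het$merge_plan$groups, 2L)
  expect_identical(wf_het$final_reports[[1]]$verdict, "heterogeneous")
  expect_gt(wf_het$final_reports[[1]]$offdiag_fraction, 0.2)

  # every source lands in exactly one final group; <= M - 1 merges
  for (wf in list(wf_hom, wf_het)) {
    srcs <- unlist(wf$merge_plan$groups)
    expect_setequal(srcs, c("omA", "omB"))
    expect_identical(anyDuplicated(srcs), 0L)
    expect_lte(length(wf$merge_plan$merges), 1L)
  }
})

test_that("prediction reproduces training labels and transfers to a cohort", {
  fused <- tiny_fused_sim(n = 36, p = 40, seed = 17, grid_n = 8,
                          basis_k = 20)
  d <- patient_dissimilarity(fused$profiles)
  sol <- pam_cluster(d, 3, seed = 1)
  model <- trained_model(fused$embedding, fused$profiles, sol, basis_k = 20)

  ds_train <- standardize_features(fused$sim$datasets[[1]])
  pred <- predict_clusters(model, ds_train)
  expect_identical(pred[names(sol$labels)], sol$labels)

  # dropping half the features errors; dropping a few does not
  ds_half <- ds_train
  ds_half$values <- ds_half$values[, 1:15]
  ds_half$var_types <- ds_half$var_types[1:15]
  expect_error(predict_clusters(model, ds_half), "50%")

  ds_most <- ds_train
  ds_most$values <- ds_most$values[, 1:30]
  ds_most$var_types <- ds_most$var_types[1:30]
  pred_most <- predict_clusters(model, ds_most)
  expect_gt(adjusted_rand_index(pred_most[names(sol$labels)], sol$labels),
            0.8)
})
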