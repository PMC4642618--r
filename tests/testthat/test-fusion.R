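test_that("concatenation stacks sources in order and round-trips by origin", {
  a <- toy_dataset(4, 5, seed = 1, name = "mrna")
  b <- toy_dataset(4, 3, seed = 2, name = "mirna", prefix = "g")
  cc <- concatenate_omics(list(a, b))
  expect_identical(dim(cc$matrix), c(8L, 4L))
  expect_identical(cc$origin, rep(c("mrna", "mirna"), c(5L, 3L)))
  parts <- split_by_origin(cc)
  expect_equal(parts$mrna, t(a$values))
  expect_equal(parts$mirna, t(b$values))

  single <- concatenate_omics(list(a))
  expect_equal(single$matrix, t(a$values))

  b_bad <- b
  rownames(b_bad$values) <- rev(rownames(b_bad$values))
  expect_error(concatenate_omics(list(a, b_bad)), "sample-aligned")
})

test_that("mixed correlation dispatches by type pair", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.3)
  expect_equal(mixed_correlation(x, x), 1.0)
  expect_equal(mixed_correlation(x, -x), -1.0)

  # point-biserial equals Pearson on the same numbers
  bin <- c(0, 0, 1, 1)
  cont <- c(1, 2, 3, 4)
  expect_equal(mixed_correlation(bin, cont, "binary", "continuous"),
               cor(bin, cont))

  # phi of a perfectly associated 2x2 table
  expect_equal(mixed_correlation(c(0, 0, 1, 1), c(0, 0, 1, 1),
                                 "binary", "binary"), 1)

  # ordinal pairs use rank correlation
  ord <- c(1, 2, 3, 4, 5, 6)
  curved <- ord^3
  expect_equal(mixed_correlation(ord, curved, "ordinal", "continuous"),
               cor(ord, curved, method = "spearman"))

  # categorical: perfect association -> 1, sign-free
  cat3 <- c(1, 1, 2, 2, 3, 3)
  expect_equal(mixed_correlation(cat3, 4 - cat3, "categorical",
                                 "categorical"), 1)
  expect_gte(mixed_correlation(cat3, rnorm(6), "categorical",
                               "continuous"), 0)

  # pairwise-complete; too few complete pairs -> 0 with warning
  x_na <- c(1, 2, NA, 4, 5, NA)
  y_na <- c(2, 4, 6, NA, 10, 12)
  keep <- !is.na(x_na) & !is.na(y_na)
  expect_equal(mixed_correlation(x_na, y_na),
               cor(x_na[keep], y_na[keep]))
  expect_warning(r0 <- mixed_correlation(c(1, 2, NA, NA), c(NA, 2, 3, 4)),
                 "fewer than 3")
  expect_identical(r0, 0)
  expect_warning(rc <- mixed_correlation(c(1, 1, 1, 1), 1:4), "constant")
  expect_identical(rc, 0)
})

test_that("feature correlation matrix obeys the dispatch entry-wise", {
  set.seed(4)
  m <- cbind(cont1 = rnorm(30), cont2 = rnorm(30),
             ord1 = sample(1:4, 30, TRUE), bin1 = sample(0:1, 30, TRUE),
             cat1 = sample(1:3, 30, TRUE))
  rownames(m) <- sprintf("s%02d", 1:30)
  ds <- omics_dataset(m, var_types = c("continuous", "continuous", "ordinal",
                                       "binary", "categorical"))
  cc <- concatenate_omics(list(ds))
  R <- feature_correlation(cc)
  expect_equal(R["cont1", "cont2"], cor(m[, 1], m[, 2]))
  expect_equal(R["cont1", "ord1"],
               cor(m[, 1], m[, 3], method = "spearman"))
  expect_equal(R["bin1", "cont1"], cor(m[, 4], m[, 1]))
  expect_equal(R["cat1", "cont1"],
               mixed_correlation(m[, 5], m[, 1], "categorical",
                                 "continuous"))
  expect_true(isSymmetric(R))
  expect_equal(unname(diag(R)), rep(1, 5))
})

test_that("dissimilarity is the affine map of correlation onto [0, 1]", {
  R <- matrix(c(1, 1, -1, 0,
                1, 1, -1, 0,
                -1, -1, 1, 0.5,
                0, 0, 0.5, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  fd <- feature_dissimilarity(R)
  expect_equal(fd$D["a", "b"], 0)      # identical features
  expect_equal(fd$D["a", "c"], 1)      # anticorrelated, maximally distant
  expect_equal(fd$D["a", "d"], 0.5)    # uncorrelated, midpoint
  expect_equal(unname(diag(fd$D)), rep(0, 4))
  expect_true(all(fd$D >= 0 & fd$D <= 1))
  expect_error(feature_dissimilarity(R * 1.5), "\\[-1, 1\\]")
  expect_error(feature_dissimilarity(matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               "symmetric")
})

test_that("embedding preserves geometry on constructed cases", {
  # 3 equidistant features map to a (near-)equilateral triangle
  D <- matrix(0.5, 3, 3)
  diag(D) <- 0
  dimnames(D) <- list(letters[1:3], letters[1:3])
  emb <- embed_features(D)
  d12 <- dist(emb$coords_raw)      # geometry before unit-square rescaling
  expect_lt((max(d12) - min(d12)) / mean(d12), 0.05)
  expect_true(all(emb$coords >= 0 & emb$coords <= 1))

  # duplicated features co-locate
  set.seed(2)
  X <- matrix(rnorm(8 * 20), 8)
  X[2, ] <- X[1, ]
  R <- cor(t(X))
  emb2 <- embed_features(feature_dissimilarity(R))
  expect_lt(sqrt(sum((emb2$coords[1, ] - emb2$coords[2, ])^2)), 1e-3)

  # rank order of a small structured dissimilarity is preserved
  set.seed(6)
  pts <- matrix(runif(16), 8, 2)
  DY <- as.matrix(dist(pts))
  DY <- DY / (2 * max(DY))              # into [0, 1] like (1 - R)/2
  dimnames(DY) <- list(paste0("f", 1:8), paste0("f", 1:8))
  emb3 <- embed_features(DY)
  d_emb <- as.vector(dist(emb3$coords))
  d_in <- DY[lower.tri(DY)]
  expect_gt(cor(d_in, d_emb, method = "spearman"), 0.9)
  expect_lt(emb3$stress, 0.15)

  # determinism
  emb3b <- embed_features(DY)
  expect_identical(emb3$coords, emb3b$coords)
})

test_that("patient smoothing reproduces constants, planes and shifts", {
  set.seed(10)
  coords <- cbind(u1 = runif(50), u2 = runif(50))
  rownames(coords) <- paste0("f", 1:50)
  emb <- structure(list(coords = coords, stress = 0, origin = NULL),
                   class = "feature_embedding")

  const <- smooth_patient(emb, rep(2.5, 50), grid_n = 8, basis_k = 20)
  expect_lt(max(abs(const - 2.5)), 1e-6)
  expect_length(const, 81L)

  plane <- 1 + 2 * coords[, 1] - 3 * coords[, 2]
  fit <- smooth_patient(emb, plane, grid_n = 8, basis_k = 20)
  s <- rep(0:8, each = 9) / 8
  t <- rep(0:8, times = 9) / 8
  expect_lt(max(abs(fit - (1 + 2 * s - 3 * t))), 1e-3)

  y <- rnorm(50)
  f1 <- smooth_patient(emb, y, grid_n = 8, basis_k = 20)
  f2 <- smooth_patient(emb, y + 4, grid_n = 8, basis_k = 20)
  expect_lt(max(abs(f2 - (f1 + 4))), 1e-6)
})

test_that("smoothing denoises a smooth signal and skips missing features", {
  set.seed(11)
  coords <- cbind(u1 = runif(80), u2 = runif(80))
  rownames(coords) <- paste0("f", 1:80)
  emb <- structure(list(coords = coords, stress = 0, origin = NULL),
                   class = "feature_embedding")
  signal <- function(u) sin(2 * pi * u[, 1]) + cos(2 * pi * u[, 2])
  truth <- signal(coords)
  noisy <- truth + rnorm(80, sd = 0.5)
  fit <- smooth_patient(emb, noisy, grid_n = 8, basis_k = 30)
  # compare at the feature locations via the fitted surface on a fine grid
  pred_at <- function(prof, uu, n = 8) {
    g <- ftp_grid(prof, n)
    si <- pmin(pmax(round(uu[, 1] * n), 0), n) + 1
    ti <- pmin(pmax(round(uu[, 2] * n), 0), n) + 1
    g[cbind(si, ti)]
  }
  mse_fit <- mean((pred_at(fit, coords) - truth)^2)
  mse_raw <- mean((noisy - truth)^2)
  expect_lt(mse_fit, mse_raw)

  y_na <- noisy
  y_na[1:10] <- NA
  fit_na <- smooth_patient(emb, y_na, grid_n = 8, basis_k = 30)
  expect_true(all(is.finite(fit_na)))
  expect_identical(attr(fit_na, "n_features"), 70L)
  expect_error(smooth_patient(emb, rep(NA_real_, 80), grid_n = 8),
               "all intensities missing")
})

test_that("profile matrices carry the grid contract and render to grids", {
  fused <- tiny_fused_sim(n = 20, p = 30, seed = 3, grid_n = 8)
  prof <- fused$profiles
  expect_identical(dim(unclass(prof)), c(20L, 81L))
  expect_identical(attr(prof, "grid_n"), 8)
  expect_true(all(is.finite(unclass(prof))))

  g <- ftp_grid(prof[1, ], 8)
  expect_identical(dim(g), c(9L, 9L))
  expect_equal(unname(g[2, 3]), unname(prof[1, 1 * 9 + 2 + 1]))  # s=1, t=2

  # render to file without error; constant profile allowed
  f <- tempfile(fileext = ".png")
  g2 <- ftp_render(rep(1, 81), grid_n = 8, file = f)
  expect_true(file.exists(f))
  expect_equal(unique(as.vector(g2)), 1)

  # opposite cluster signals give anticorrelated rendered fields
  a <- prof[1, ]
  expect_lt(cor(as.vector(ftp_grid(a, 8)), as.vector(ftp_grid(-a, 8))), 0)
})
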