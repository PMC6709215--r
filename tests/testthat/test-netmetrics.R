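test_that("degree imbalance sums row/column weights and conserves zero", {
  C <- matrix(0, 3, 3); C[1, 2] <- 0.4
  di <- degree_imbalance(C)
  expect_equal(di$degree_imbalance, c(0.4, -0.4, 0))

  sym <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(degree_imbalance(sym)$degree_imbalance, c(0, 0))

  for (seed in 1:10) {
    set.seed(seed)
    W <- matrix(runif(36), 6); diag(W) <- 0
    expect_equal(sum(degree_imbalance(W)$degree_imbalance), 0,
                 tolerance = 1e-12)
  }
  expect_error(degree_imbalance(matrix(0, 2, 3)), "square")
})

test_that("degree of asymmetry vanishes on symmetric graphs and ignores
           symmetric additions", {
  ring <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; ring[i, j] <- 1; ring[j, i] <- 1 }
  expect_equal(degree_of_asymmetry(ring), 0)

  set.seed(2)
  W <- matrix(runif(25), 5); diag(W) <- 0
  S <- matrix(runif(25), 5); S <- S + t(S); diag(S) <- 0
  expect_equal(degree_of_asymmetry(W), degree_of_asymmetry(W + S),
               tolerance = 1e-10)
  expect_gt(degree_of_asymmetry(W), 0)
})

test_that("the global measure battery has 20 entries with sane values", {
  # single directed edge of weight w: both norms equal w
  w <- 0.7
  C1 <- matrix(0, 4, 4); C1[2, 3] <- w
  gm <- global_measures(C1)
  expect_length(gm, 20)
  expect_equal(unname(gm["frobenius_norm"]), w)
  expect_equal(unname(gm["spectral_norm"]), w, tolerance = 1e-10)

  # sum-normalized matrix: mean weighted outdegree = 1/n
  set.seed(5)
  W <- matrix(runif(36), 6); diag(W) <- 0; W <- W / sum(W)
  gm2 <- global_measures(W)
  expect_equal(unname(gm2["mean_outdegree"]), 1 / 6, tolerance = 1e-12)
  expect_gte(unname(gm2["degree_of_asymmetry"]), 0)
  expect_true(all(is.finite(gm2)))

  # symmetric ring: zero asymmetry within the battery
  ring <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; ring[i, j] <- 1; ring[j, i] <- 1 }
  expect_equal(unname(global_measures(ring)["degree_of_asymmetry"]), 0)

  # edgeless matrix: norms zero, path measures flagged missing
  gm0 <- global_measures(matrix(0, 4, 4))
  expect_equal(unname(gm0["frobenius_norm"]), 0)
  expect_true(is.na(gm0["mean_shortest_path"]))
  expect_error(global_measures(matrix(-1, 2, 2)), "nonnegative")
})

test_that("Frobenius distance is the elementwise L2 metric", {
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(frobenius_distance(A, A), 0)
  expect_equal(frobenius_distance(A, matrix(0, 2, 2)), sqrt(2))
  expect_error(frobenius_distance(A, matrix(0, 3, 3)), "shape")
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(9), 3); Y <- matrix(rnorm(9), 3); Z <- matrix(rnorm(9), 3)
    expect_lte(frobenius_distance(X, Z),
               frobenius_distance(X, Y) + frobenius_distance(Y, Z) + 1e-12)
    expect_equal(frobenius_distance(X, Y), frobenius_distance(Y, X))
  }
})

test_that("classical MDS embeds Euclidean configurations perfectly", {
  set.seed(9)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(pts))
  emb <- mds_embed(D, k = 2)
  expect_equal(emb$R2, 1, tolerance = 1e-6)

  # equilateral: all-equal distances over 3 items embed exactly in 2-D
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  expect_equal(mds_embed(D3, k = 2)$R2, 1, tolerance = 1e-6)

  # non-Euclidean 10x10 metric: goodness matches the double-centering oracle
  set.seed(10)
  base <- matrix(runif(100, 0.5, 1.5), 10, 10)
  D10 <- (base + t(base)) / 2; diag(D10) <- 0
  emb10 <- mds_embed(D10, k = 3)
  expect_equal(emb10$R, oracle_mds(D10, 3), tolerance = 1e-8)

  asym <- matrix(runif(9), 3); diag(asym) <- 0
  expect_error(mds_embed(asym), "symmetric")
})

test_that("top edges pick the strongest 5% with a documented tie rule", {
  set.seed(11)
  W <- matrix(runif(900), 30); diag(W) <- 0
  te <- top_edges(W, 5)
  expect_equal(nrow(te), 44)  # ceiling(0.05 * 870)
  expect_true(all(diff(te$weight) <= 0))
  # they are exactly the 44 largest off-diagonal weights
  offd <- sort(W[row(W) != col(W)], decreasing = TRUE)
  expect_equal(sort(te$weight, decreasing = TRUE), offd[1:44])

  # all-equal weights: ties broken by (source, target) order
  We <- matrix(1, 4, 4); diag(We) <- 0
  tee <- top_edges(We, 50)  # ceiling(0.5 * 12) = 6
  expect_equal(nrow(tee), 6)
  expect_equal(tee$source[1:3], c(1, 1, 1))
  expect_equal(tee$target[1:3], c(2, 3, 4))

  # pct = 100 returns all nonzero edges only
  Wz <- matrix(0, 3, 3); Wz[1, 2] <- 1; Wz[2, 3] <- 0.5
  expect_equal(nrow(top_edges(Wz, 100)), 2)
})

test_that("contralateral fraction reflects where the strong edges sit", {
  lay <- make_layout(5, 6)
  n <- lay$n_channels
  set.seed(12)
  W <- matrix(runif(n^2, 0, 0.1), n); diag(W) <- 0
  strong <- cbind(seq_len(n), lay$contralateral_pair)
  W[strong] <- 1
  expect_equal(contralateral_top_fraction(W, lay, 5), 1)
  W[strong] <- 0
  expect_equal(contralateral_top_fraction(W, lay, 5), 0)
})

test_that("median matrix is the elementwise median", {
  A <- matrix(1:4, 2); B <- matrix(c(10, 0, 0, 10), 2); C <- matrix(2:5, 2)
  expect_equal(median_matrix(list(A)), A)
  expect_equal(median_matrix(list(A, A, B)), A)
  med <- median_matrix(list(A, B, C))
  for (i in 1:2) for (j in 1:2)
    expect_equal(med[i, j], median(c(A[i, j], B[i, j], C[i, j])))
  expect_error(median_matrix(list(A, matrix(0, 3, 3))), "shape")
})

test_that("day28 cohorts break mirror symmetry more than day0 (recovery)", {
  lay <- make_layout(1, 6); fs <- 200
  asym <- function(stage, seed_off) {
    co <- generate_cohort(stage, 3, seed = 31 + seed_off, layout = lay,
                          fs = fs, duration_s = 6)
    vapply(seq_along(co), function(k)
      degree_of_asymmetry(quick_abs_connectivity(co[[k]], seed = 600 + k)),
      numeric(1))
  }
  a0 <- asym("day0", 0)
  a28 <- asym("day28", 100)
  expect_gt(median(a28), median(a0))
})

test_that("day0 median matrices have stronger contralateral edges than
           day28 (recovery)", {
  lay <- make_layout(1, 6); fs <- 200
  med_mat <- function(stage, seed_off) {
    co <- generate_cohort(stage, 3, seed = 77 + seed_off, layout = lay,
                          fs = fs, duration_s = 6)
    median_matrix(lapply(seq_along(co), function(k)
      quick_abs_connectivity(co[[k]], seed = 900 + seed_off + k)))
  }
  # 20% of 30 possible edges = 6 edges, matching the 6 contralateral pairs
  f0 <- contralateral_top_fraction(med_mat("day0", 0), lay, 20)
  f28 <- contralateral_top_fraction(med_mat("day28", 10), lay, 20)
  expect_gt(f0, f28)
})
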