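# GMM consensus clustering, Kabsch registration, DBSCAN, selective features

test_that("Kabsch registration is exact on self and recovers rigid motions", {
  set.seed(4)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  tf0 <- register_clouds(A, A, "paired")
  expect_lt(max(abs(tf0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf0$translation)), 1e-9)
  expect_lt(tf0$rmsd, 1e-9)
  for (i in 1:5) {
    R <- random_rotation_matrix(); v <- rnorm(3, sd = 10)
    B <- sweep(A %*% t(R), 2, v, `+`)
    tf <- register_clouds(A, B, "paired")
    expect_lt(max(abs(tf$rotation - R)), 1e-6)
    expect_lt(tf$rmsd, 1e-6)
  }
})

test_that("Kabsch agrees with an independent quaternion oracle on noisy pairs", {
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(rnorm(30, sd = 3), 10, 3)
    R <- random_rotation_matrix()
    B <- sweep(A %*% t(R), 2, rnorm(3), `+`) + matrix(rnorm(30, 0, 0.2), 10, 3)
    tf <- register_clouds(A, B, "paired")
    oracle <- horn_fit(A, B)
    expect_lt(abs(tf$rmsd - oracle$rmsd), 1e-9)
    expect_lt(max(abs(tf$rotation - oracle$R)), 1e-7)
  }
})

test_that("registration RMSD is invariant under a common rigid motion", {
  set.seed(6)
  A <- matrix(rnorm(24, sd = 3), 8, 3)
  B <- A + matrix(rnorm(24, 0, 0.3), 8, 3)
  base <- register_clouds(A, B, "paired")$rmsd
  for (i in 1:4) {
    R <- random_rotation_matrix(); v <- rnorm(3, sd = 20)
    r2 <- register_clouds(sweep(A %*% t(R), 2, v, `+`),
                          sweep(B %*% t(R), 2, v, `+`), "paired")$rmsd
    expect_lt(abs(r2 - base), 1e-9)
  }
})

test_that("nearest-neighbor (ICP) registration recovers moderate motions", {
  set.seed(8)
  A <- matrix(rnorm(36, sd = 5), 12, 3)
  ang <- 0.25
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  B <- sweep(A %*% t(R), 2, c(0.5, -0.3, 0.2), `+`)
  # shuffled rows: correspondence unknown
  tf <- register_clouds(A, B[sample(12), ], "nearest-neighbor")
  expect_lt(tf$rmsd, 1e-6)
  expect_lt(max(abs(tf$rotation - R)), 1e-5)
  expect_warning(register_clouds(cbind(1:5, 0, 0), cbind(2:6, 0, 0),
                                 "paired"), "collinear")
})

test_that("unanimous clusters return their category; consensus matches Eq-style vote", {
  set.seed(9)
  blob <- function(center, n, sd = 0.3)
    sweep(matrix(rnorm(n * 3, 0, sd), n, 3), 2, center, `+`)
  cl <- pharm_cloud(rbind(blob(c(0, 0, 0), 12), blob(c(20, 0, 0), 12)),
                    c(rep("Acceptor", 12), rep("Donor", 12)))
  res <- cluster_clouds(list(cl), k = 2, seed = 1)
  cats <- sort(as.character(res$consensus$category))
  expect_equal(cats, c("Acceptor", "Donor"))
  # component means land on the blob centroids (within 0.5 A)
  ord <- order(res$consensus$xyz[, 1])
  expect_lt(max(abs(res$consensus$xyz[ord, ] -
                      rbind(c(0, 0, 0), c(20, 0, 0)))), 0.5)
  expect_equal(res$consensus$support[ord], c(12L, 12L))
})

test_that("consensus equals exhaustive category enumeration with tie-breaks", {
  set.seed(10)
  cats8 <- pharm_categories()
  for (rep in 1:40) {
    counts <- rmultinom(1, sample(3:15, 1), prob = runif(8))[, 1]
    global <- rmultinom(1, 60, prob = runif(8))[, 1]
    got <- phoregen:::consensus_category(counts, global)
    # oracle: enumerate all 8 categories, max count, ties by global count,
    # remaining ties by alphabet order
    mx <- which(counts == max(counts))
    if (length(mx) > 1) mx <- mx[global[mx] == max(global[mx])]
    expect_equal(got, cats8[mx[1]])
  }
  # explicit majority fixture: {Aromatic:3, Donor:1} -> Aromatic
  expect_equal(phoregen:::consensus_category(c(3, 0, 0, 0, 0, 1, 0, 0),
                                             rep(1, 8)), "Aromatic")
})

test_that("BIC selects k on well-separated blobs", {
  set.seed(11)
  blob <- function(center) sweep(matrix(rnorm(45, 0, 0.3), 15, 3), 2,
                                 center, `+`)
  cl <- pharm_cloud(rbind(blob(c(0, 0, 0)), blob(c(15, 0, 0)),
                          blob(c(0, 15, 0))),
                    sample(pharm_categories(), 45, TRUE))
  res <- cluster_clouds(list(cl), k = "auto", seed = 2)
  expect_equal(res$model$k, 3L)
  expect_error(cluster_clouds(list(cl), k = 100, seed = 1), "exceeds")
})

test_that("DBSCAN matches a brute-force implementation", {
  set.seed(12)
  xyz <- rbind(matrix(rnorm(30, 0, 0.4), 10, 3),
               sweep(matrix(rnorm(30, 0, 0.4), 10, 3), 2, c(10, 0, 0), `+`),
               matrix(rnorm(9, 0, 40), 3, 3))
  labels <- dbscan_points(xyz, eps = 1.5, min_pts = 3)
  expect_equal(length(unique(labels[labels > 0])), 2L)
  # brute-force core-point check
  d <- as.matrix(dist(xyz))
  core <- rowSums(d <= 1.5) >= 3
  expect_true(all(labels[!core & rowSums(d <= 1.5) == 1] == 0))
  # points in the same tight blob share a label
  expect_equal(length(unique(labels[1:10])), 1L)
  expect_equal(length(unique(labels[11:20])), 1L)
})

test_that("selective differencing recovers planted differences and is monotone", {
  set.seed(13)
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  hom <- pharm_cloud(base, rep("Acceptor", 10))
  extra <- c(30, 30, 30)
  tgt <- pharm_cloud(rbind(base, extra), c(rep("Acceptor", 10),
                                           "Hydrophobic"))
  id_tf <- rigid_transform(diag(3), c(0, 0, 0))
  # identical clouds -> empty for any delta
  expect_warning(out0 <- selective_features(hom, hom, id_tf, delta = 1),
                 "indistinguishable")
  expect_null(out0)
  # planted single point survives (min_pts 1 keeps singletons)
  sel <- selective_features(tgt, hom, id_tf, delta = 2, dbscan_min = 1)
  expect_equal(nrow(sel$xyz), 1L)
  expect_equal(as.character(sel$category), "Hydrophobic")
  expect_equal(sel$xyz[1, ], extra)
  # monotone: larger delta never yields more survivors
  counts <- vapply(c(0.5, 1, 2, 4, 8), function(d) {
    s <- suppressWarnings(selective_features(tgt, hom, id_tf, delta = d,
                                             dbscan_min = 1))
    if (is.null(s)) 0L else nrow(s$xyz)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("two survivor groups are DBSCAN-clustered with majority categories", {
  set.seed(14)
  hom <- pharm_cloud(matrix(rnorm(30, sd = 3), 10, 3), rep("Donor", 10))
  g1 <- sweep(matrix(rnorm(30, 0, 0.4), 10, 3), 2, c(25, 0, 0), `+`)
  g2 <- sweep(matrix(rnorm(30, 0, 0.4), 10, 3), 2, c(-25, 0, 0), `+`)
  cats <- c(rep("Aromatic", 7), rep("Donor", 3),   # group 1 majority Aromatic
            rep("Acceptor", 8), rep("Donor", 2))   # group 2 majority Acceptor
  tgt <- pharm_cloud(rbind(hom$xyz, g1, g2), c(rep("Donor", 10), cats))
  sel <- selective_features(tgt, hom, rigid_transform(diag(3), c(0, 0, 0)),
                            delta = 2, dbscan_eps = 1.5, dbscan_min = 3)
  lab <- attr(sel, "cluster")
  expect_equal(length(unique(lab)), 2L)
  got <- vapply(unique(lab), function(l)
    unique(as.character(sel$category)[lab == l]), "")
  expect_setequal(got, c("Aromatic", "Acceptor"))
})

test_that("dual-target composition: registered pooled clouds give high-support shared clusters", {
  set.seed(15)
  # six well-separated shared features (octahedron, 6 A radius) with the
  # slight positional jitter real repeated sampling shows
  octa <- rbind(c(6, 0, 0), c(-6, 0, 0), c(0, 6, 0),
                c(0, -6, 0), c(0, 0, 6), c(0, 0, -6))
  jit <- function() octa + matrix(rnorm(18, 0, 0.2), 6, 3)
  R <- random_rotation_matrix(); v <- c(8, -3, 2)
  a <- pharm_cloud(jit(), rep("Acceptor", 6))
  b <- pharm_cloud(sweep(jit() %*% t(R), 2, v, `+`), rep("Acceptor", 6))
  tf <- register_clouds(b, a, "paired")
  b_in_a <- apply_transform(b, tf)
  res <- cluster_clouds(list(a, b_in_a), k = 6, seed = 3)
  expect_true(all(res$consensus$support == 2L))
  # every vertex has a consensus mean within 1 A
  nn <- apply(octa, 1, function(v)
    min(sqrt(rowSums(sweep(res$consensus$xyz, 2, v)^2))))
  expect_lt(max(nn), 1)
})
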