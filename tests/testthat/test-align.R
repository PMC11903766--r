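# Conformer embedding and rigid pharmacophore alignment

test_that("embedding produces physical geometries, n_conf conformers, reproducibly", {
  mc <- quiet(embed_conformers("CC", n_conf = 1, seed = 1))
  d <- sqrt(sum((mc$conformers[[1]][1, ] - mc$conformers[[1]][2, ])^2))
  expect_gt(d, 1.45); expect_lt(d, 1.60)   # C-C single bond length
  mc5 <- quiet(embed_conformers("CCOCC", n_conf = 5, seed = 3))
  expect_length(mc5$conformers, 5)
  mc5b <- quiet(embed_conformers("CCOCC", n_conf = 5, seed = 3))
  for (k in 1:5)
    expect_lt(max(abs(mc5$conformers[[k]] - mc5b$conformers[[k]])), 1e-6)
  expect_error(quiet(embed_conformers("not_a_molecule", 1, 1)), "parse")
})

test_that("self-cloud alignment at tolerance 0 is identity-equivalent", {
  mc <- quiet(embed_conformers("CC(=O)Nc1ccc(O)cc1", n_conf = 1, seed = 1))
  m <- mc$mol; m$xyz <- mc$conformers[[1]]
  cloud <- extract_ligand_pharmacophores(m)
  poses <- align_to_cloud(mc, cloud, tolerance = 0)
  expect_gt(length(poses), 0)
  top <- poses[[1]]
  expect_lt(top$fit_rmsd, 1e-6)
  expect_equal(top$n_unmatched, 0L)
  expect_lt(max(abs(top$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(top$transform$translation)), 1e-6)
})

test_that("an unmatched extra point is tolerated exactly as configured", {
  mc <- quiet(embed_conformers("CC(=O)Nc1ccc(O)cc1", n_conf = 1, seed = 1))
  m <- mc$mol; m$xyz <- mc$conformers[[1]]
  cloud <- extract_ligand_pharmacophores(m)
  cloud2 <- pharm_cloud(rbind(cloud$xyz, c(10, 10, 10)),
                        c(as.character(cloud$category), "Donor"))
  expect_length(align_to_cloud(mc, cloud2, tolerance = 0), 0)
  p1 <- align_to_cloud(mc, cloud2, tolerance = 1)
  expect_gt(length(p1), 0)
  expect_lt(p1[[1]]$fit_rmsd, 1e-6)
  expect_equal(p1[[1]]$n_unmatched, 1L)
})

test_that("raising tolerance never loses poses and rescoring reproduces fit_rmsd", {
  mc <- quiet(embed_conformers("O=C(Nc1ccc(O)cc1)CCN", n_conf = 2, seed = 2))
  m <- mc$mol; m$xyz <- mc$conformers[[1]]
  cloud <- extract_ligand_pharmacophores(m)
  sub <- cloud_subset(cloud, seq_len(min(4, length(cloud))))
  n_prev <- -1L
  for (tol in 0:3) {
    poses <- align_to_cloud(mc, sub, tolerance = tol, fit_cutoff = 2)
    expect_gte(length(poses), n_prev)
    n_prev <- length(poses)
  }
  poses <- align_to_cloud(mc, sub, tolerance = 1, fit_cutoff = 2)
  for (p in poses[seq_len(min(3, length(poses)))]) {
    feats <- phoregen:::detect_features({
      mm <- mc$mol; mm$xyz <- mc$conformers[[p$conformer]]; mm
    })
    fxyz <- t(vapply(feats, function(f)
      colMeans(mc$conformers[[p$conformer]][f$atoms, , drop = FALSE]),
      numeric(3)))
    moved <- apply_transform(fxyz[p$matched_pairs[, "feature"], ,
                                  drop = FALSE], p$transform)
    resid <- moved - sub$xyz[p$matched_pairs[, "cloud_point"], , drop = FALSE]
    expect_lt(abs(sqrt(mean(rowSums(resid^2))) - p$fit_rmsd), 1e-9)
  }
})

test_that("accepted poses match an independent assignment enumeration", {
  mc <- quiet(embed_conformers("CC(=O)Nc1ccc(O)cc1", n_conf = 1, seed = 4))
  m <- mc$mol; m$xyz <- mc$conformers[[1]]
  feats <- phoregen:::detect_features(m)
  fcat <- vapply(feats, function(f) f$category, "")
  fxyz <- t(vapply(feats, function(f)
    colMeans(m$xyz[f$atoms, , drop = FALSE]), numeric(3)))
  set.seed(5)
  cloud <- pharm_cloud(fxyz[1:4, , drop = FALSE] +
                         matrix(rnorm(12, 0, 0.3), 4, 3), fcat[1:4])
  tol <- 1; cutoff <- 1.2
  poses <- align_to_cloud(mc, cloud, tolerance = tol, fit_cutoff = cutoff)
  # oracle: enumerate every injective assignment explicitly via expand.grid
  nc <- 4
  cand <- lapply(seq_len(nc), function(i)
    c(which(fcat == as.character(cloud$category)[i]), 0L))  # 0 = unmatched
  grid <- do.call(expand.grid, cand)
  n_oracle <- 0
  oracle_best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    sel <- which(a > 0)
    if (length(sel) == 0) next
    if (anyDuplicated(a[sel])) next
    if (nc - length(sel) > tol) next
    tf <- suppressWarnings(phoregen:::kabsch(fxyz[a[sel], , drop = FALSE],
                                             cloud$xyz[sel, , drop = FALSE]))
    if (tf$rmsd <= cutoff) {
      n_oracle <- n_oracle + 1
      oracle_best <- min(oracle_best, tf$rmsd)
    }
  }
  expect_equal(length(poses), n_oracle)
  if (n_oracle > 0) {
    # poses rank by (n_unmatched, rmsd); the oracle tracks the global
    # minimum rmsd, so compare against the best over all accepted poses
    expect_equal(min(vapply(poses, function(p) p$fit_rmsd, 1)),
                 oracle_best, tolerance = 1e-12)
  }
})

test_that("pose RMSD is symmetry-corrected and matches the direct formula", {
  bz <- quiet(embed_conformers("c1ccccc1", 1, 1))
  xyz <- bz$conformers[[1]]
  expect_equal(pose_rmsd(bz$mol, xyz, xyz), 0)
  # rotate benzene 60 degrees about its ring normal: RMSD 0 after symmetry
  ring <- which(bz$mol$elements == "C")
  ctr <- colMeans(xyz[ring, , drop = FALSE])
  pts <- sweep(xyz, 2, ctr)
  sv <- svd(pts[ring, ])
  axis <- sv$v[, 3]
  ang <- pi / 3
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rot <- sweep(pts %*% t(R), 2, ctr, `+`)
  expect_lt(pose_rmsd(bz$mol, xyz, rot), 0.05)
  # asymmetric molecule: RMSD equals sqrt(mean d^2) directly
  mc <- quiet(embed_conformers("NCCO", 1, 1))
  a <- mc$conformers[[1]]
  set.seed(6)
  b <- a + matrix(rnorm(length(a), 0, 0.5), nrow(a), 3)
  expect_equal(pose_rmsd(mc$mol, a, b),
               sqrt(mean(rowSums((a - b)^2))), tolerance = 1e-12)
  expect_error(pose_rmsd(mc$mol, a[1:2, ], b), "heavy-atom count")
})
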