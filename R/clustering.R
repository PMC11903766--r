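# Consensus clustering of repeated diffusion samples, rigid point-cloud
# registration, and selective-feature differencing between two pockets.

#' Rigid transform container
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation Length-3 numeric.
#' @param rmsd Residual RMSD in Angstrom.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation, rmsd = NA_real_) {
  rotation <- as.matrix(rotation)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-6)
    stop("rotation is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = rmsd), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.1f deg, |t| = %.3f A, RMSD %.4f A\n",
              ang, sqrt(sum(x$translation^2)), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to points or a cloud
#'
#' @param x An n x 3 matrix or a [pharm_cloud()].
#' @param tf A [rigid_transform()].
#' @return Transformed object of the same type.
#' @export
apply_transform <- function(x, tf) {
  if (inherits(x, "pharm_cloud")) {
    x$xyz <- apply_transform(x$xyz, tf)
    return(x)
  }
  sweep(as.matrix(x) %*% t(tf$rotation), 2, tf$translation, `+`)
}

# Kabsch least-squares superposition of paired point sets: returns the
# rigid transform minimizing ||R a_i + t - b_i||.
kabsch <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  if (nrow(A) >= 3 && sv$d[2] < 1e-9 * max(sv$d[1], 1))
    warning("Degenerate (collinear) point configuration; ",
            "rotation is not uniquely determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.numeric(R %*% ca)
  resid <- sweep(A %*% t(R), 2, tr, `+`) - B
  rigid_transform(R, tr, sqrt(mean(rowSums(resid^2))))
}

#' Register one pharmacophore cloud onto another
#'
#' Least-squares rigid superposition (Kabsch 3D best fit). In `paired` mode
#' the clouds must be equal-sized with corresponding rows; in
#' `nearest-neighbor` mode (default, suited to unpaired diffusion samples)
#' an ICP-style loop alternates nearest-neighbor assignment and Kabsch
#' refitting until the RMSD stabilizes.
#'
#' @param cloud_a,cloud_b [pharm_cloud()]s (or bare n x 3 matrices); the
#'   returned transform maps `cloud_a`'s frame onto `cloud_b`'s.
#' @param correspondence `"nearest-neighbor"` or `"paired"`.
#' @param max_iter,tol ICP iteration controls.
#' @return A [rigid_transform()] carrying the final residual RMSD.
#' @export
register_clouds <- function(cloud_a, cloud_b,
                            correspondence = c("nearest-neighbor", "paired"),
                            max_iter = 100, tol = 1e-10) {
  correspondence <- match.arg(correspondence)
  A <- if (inherits(cloud_a, "pharm_cloud")) cloud_a$xyz else as.matrix(cloud_a)
  B <- if (inherits(cloud_b, "pharm_cloud")) cloud_b$xyz else as.matrix(cloud_b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("Cannot register empty clouds")
  if (correspondence == "paired") {
    if (nrow(A) != nrow(B))
      stop("paired registration needs equal-sized clouds")
    return(kabsch(A, B))
  }
  tf <- rigid_transform(diag(3), c(0, 0, 0), Inf)
  last <- Inf
  for (it in seq_len(max_iter)) {
    Am <- apply_transform(A, tf)
    d2 <- outer(rowSums(Am^2), rowSums(B^2), `+`) - 2 * Am %*% t(B)
    nn <- max.col(-d2, ties.method = "first")
    tf_new <- kabsch(A, B[nn, , drop = FALSE])
    if (is.finite(last) && abs(last - tf_new$rmsd) < tol) {
      tf <- tf_new
      break
    }
    last <- tf_new$rmsd
    tf <- tf_new
  }
  tf
}

# Eq-style consensus: most probable feature of one cluster = argmax over
# categories of the summed per-sample feature indicators, with the global
# category frequency (then pinned alphabet order) breaking ties.
consensus_category <- function(cluster_counts, global_counts) {
  best <- which(cluster_counts == max(cluster_counts))
  if (length(best) > 1) {
    g <- global_counts[best]
    best <- best[g == max(g)]
  }
  pharm_categories()[best[1]]
}

#' Consensus-cluster pooled pharmacophore clouds
#'
#' Pools the points of repeated diffusion samples, fits a Gaussian mixture
#' on the 3D coordinates (covariance family selected by BIC, full
#' covariance among the candidates), and assigns each mixture
#' component the most probable pharmacophore category: the category
#' maximizing the summed per-point indicators within the cluster, with the
#' global category frequency breaking ties. The consensus cloud has one
#' point per component at the component mean, with the cluster size as
#' support.
#'
#' @param clouds A list of [pharm_cloud()]s (or a single cloud).
#' @param k Number of mixture components, or `"auto"` to select by BIC over
#'   1..min(8, n/3).
#' @param seed Integer seed (mixture fitting is seeded for reproducibility).
#' @return List with `model` (class `pharm_cluster_model`: k, means,
#'   covariances, weights, assignments, per-cluster feature table, global
#'   feature frequencies, BIC) and `consensus` (a `pharm_cloud`).
#' @export
cluster_clouds <- function(clouds, k = "auto", seed = 1) {
  if (inherits(clouds, "pharm_cloud")) clouds <- list(clouds)
  if (length(clouds) < 1) stop("Need at least one cloud")
  X <- do.call(rbind, lapply(clouds, function(cl) cl$xyz))
  cats <- unlist(lapply(clouds, function(cl) as.character(cl$category)))
  n <- nrow(X)
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k > n) stop("k = ", k, " exceeds the ", n, " pooled points")
    G <- k
  } else {
    G <- seq_len(max(1, min(8, floor(n / 3))))
  }
  # Mclust() resolves mclustBIC in the caller's environment; make it
  # visible without requiring the package to be attached
  mclustBIC <- mclust::mclustBIC
  fit <- with_seed(seed, {
    # BIC selects the covariance family as well as k: with the few points
    # per component typical of pooled diffusion samples, a forced
    # full-covariance fit is overparameterized and prone to degenerate
    # local optima, so the family is chosen from the data (the full
    # covariance model remains among the candidates)
    f <- tryCatch(mclust::Mclust(X, G = G, verbose = FALSE),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning("Mixture fit failed (singular covariance); ",
              "refitting with a regularizing prior")
      f <- tryCatch(
        mclust::Mclust(X, G = G, verbose = FALSE,
                       prior = mclust::priorControl()),
        error = function(e) NULL)
    }
    if (is.null(f)) {
      f <- tryCatch(
        mclust::Mclust(X, G = seq_len(min(max(G), 3)), modelNames = "EII",
                       verbose = FALSE, prior = mclust::priorControl()),
        error = function(e) NULL)
    }
    f
  })
  if (is.null(fit)) stop("Gaussian mixture fitting failed")
  kk <- fit$G
  assign <- fit$classification
  cat_f <- factor(cats, levels = pharm_categories())
  global_counts <- as.numeric(table(cat_f))
  tab <- table(factor(assign, levels = seq_len(kk)), cat_f)
  feature_table <- sweep(unclass(tab), 1, pmax(rowSums(tab), 1), `/`)
  cons_cat <- vapply(seq_len(kk), function(i)
    consensus_category(as.numeric(tab[i, ]), global_counts), "")
  means <- t(fit$parameters$mean)  # k x 3
  model <- structure(list(
    k = kk,
    means = means,
    covariances = fit$parameters$variance$sigma,
    weights = fit$parameters$pro,
    assignments = as.integer(assign),
    feature_table = feature_table,
    global_freq = global_counts / sum(global_counts),
    bic = fit$BIC,
    consensus_category = cons_cat
  ), class = "pharm_cluster_model")
  consensus <- pharm_cloud(means, cons_cat,
                           support = as.integer(table(factor(assign,
                             levels = seq_len(kk)))),
                           provenance = "clustered")
  list(model = model, consensus = consensus)
}

#' @export
print.pharm_cluster_model <- function(x, ...) {
  cat(sprintf("<pharm_cluster_model> k=%d components over %d points\n",
              x$k, length(x$assignments)))
  for (i in seq_len(x$k)) {
    cat(sprintf("  C%d: %s (n=%d) at (%.2f, %.2f, %.2f)\n", i,
                x$consensus_category[i],
                sum(x$assignments == i),
                x$means[i, 1], x$means[i, 2], x$means[i, 3]))
  }
  invisible(x)
}

#' Density-based clustering of 3D points (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distance: core points have at least
#' `min_pts` neighbors (self included) within `eps`; clusters grow through
#' core points; non-reachable points are noise.
#'
#' @param xyz n x 3 matrix.
#' @param eps Neighborhood radius (Angstrom).
#' @param min_pts Minimum neighborhood size for a core point.
#' @return Integer vector of cluster labels, 0 for noise.
#' @export
dbscan_points <- function(xyz, eps = 1.5, min_pts = 3) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nbr, length, 1L) >= min_pts
  labels <- integer(n)  # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, setdiff(nbr[[j]], j))
      }
    }
  }
  labels
}

#' Extract selectivity-driving pharmacophore features
#'
#' After registering a homolog pocket's sampled cloud onto the target
#' pocket's frame, keeps the target points lying farther than `delta` from
#' every transformed homolog point ("space sampled by the target but not by
#' the homolog"), then DBSCAN-clusters the survivors, drops noise, and
#' relabels each retained cluster with its majority category (global
#' frequencies break ties).
#'
#' @param target_cloud,homolog_cloud [pharm_cloud()]s in their own frames.
#' @param transform A [rigid_transform()] mapping the homolog frame onto the
#'   target frame; when NULL it is computed with [register_clouds()]
#'   (nearest-neighbor mode).
#' @param delta Exclusion distance in Angstrom (default 2).
#' @param dbscan_eps,dbscan_min DBSCAN parameters (defaults 1.5 A, 3).
#' @return A `pharm_cloud` of the retained survivor points (provenance
#'   `"selective"`), or NULL with a warning when no point survives.
#' @export
selective_features <- function(target_cloud, homolog_cloud, transform = NULL,
                               delta = 2, dbscan_eps = 1.5, dbscan_min = 3) {
  stopifnot(inherits(target_cloud, "pharm_cloud"),
            inherits(homolog_cloud, "pharm_cloud"))
  if (is.null(transform))
    transform <- register_clouds(homolog_cloud, target_cloud)
  Hm <- apply_transform(homolog_cloud$xyz, transform)
  Tx <- target_cloud$xyz
  d2 <- outer(rowSums(Tx^2), rowSums(Hm^2), `+`) - 2 * Tx %*% t(Hm)
  nn_d <- sqrt(pmax(apply(d2, 1, min), 0))
  surv <- which(nn_d > delta)
  if (length(surv) == 0) {
    warning("No selective features: the two clouds are indistinguishable ",
            "at delta = ", delta, " A")
    return(NULL)
  }
  sub <- cloud_subset(target_cloud, surv)
  labels <- dbscan_points(sub$xyz, eps = dbscan_eps, min_pts = dbscan_min)
  keep <- labels > 0
  if (!any(keep)) {
    warning("All survivor points are DBSCAN noise; no selective cluster")
    return(NULL)
  }
  sub <- cloud_subset(sub, which(keep))
  labels <- labels[keep]
  global_counts <- as.numeric(table(factor(as.character(target_cloud$category),
                                           levels = pharm_categories())))
  newcat <- as.character(sub$category)
  for (cl in unique(labels)) {
    idx <- labels == cl
    counts <- as.numeric(table(factor(as.character(sub$category)[idx],
                                      levels = pharm_categories())))
    newcat[idx] <- consensus_category(counts, global_counts)
  }
  out <- pharm_cloud(sub$xyz, newcat, sub$support, provenance = "selective")
  attr(out, "cluster") <- labels
  out
}
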