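# Conformer embedding and rigid pharmacophore alignment: pose generated
# molecules inside a sampled cloud by matching their 3D features onto the
# cloud points and solving the Kabsch superposition on the matched pairs.

# mean bond length (Angstrom) applied to the unit-bond structure diagram
.embed_bond_scale <- 1.52

#' Embed conformers for a molecule
#'
#' Builds a topology-faithful, deterministic base conformer from the
#' molecule's structure diagram (the rule-based 2D layout, which places
#' rings — including fused systems — consistently), scaled to a mean bond
#' length of 1.52 Angstrom; additional conformers resample torsion angles
#' around rotatable bonds, which takes the geometry out of plane. The
#' whole construction is exactly reproducible given `seed` — the
#' force-field conformer searches available in the backend are not — at
#' the cost of idealized local geometry (no energy minimization; ring
#' puckering is not modeled). At pharmacophore-centroid resolution this
#' is sufficient for rigid alignment; see the methods vignette.
#'
#' @param smiles A single SMILES string.
#' @param n_conf Number of conformers (default 1).
#' @param seed Integer seed for the torsional resampling.
#' @return Object of class `mol_conformers`: the parsed molecule (`mol`,
#'   heavy atoms) and a list `conformers` of heavy-atom coordinate
#'   matrices (Angstrom).
#' @export
embed_conformers <- function(smiles, n_conf = 1, seed = 1) {
  stopifnot(n_conf >= 1)
  if (isTRUE(n_atom_tokens(smiles) == 1L)) {
    mol <- single_atom_mol(smiles)
  } else {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
      error = function(e) NULL)
    if (is.null(sdf) || length(sdf) < 1)
      stop("Embedding failed: cannot parse SMILES ", smiles, call. = FALSE)
    mol <- mol_from_sdf(sdf[[1]])
  }
  if (mol$n_heavy < 1)
    stop("Embedding failed: no heavy atoms in ", smiles, call. = FALSE)
  mol$xyz <- mol$xyz * .embed_bond_scale
  mol$smiles <- smiles
  confs <- vector("list", n_conf)
  confs[[1]] <- mol$xyz
  if (n_conf > 1) {
    rb <- rotatable_bond_list(mol)
    with_seed(seed, {
      for (k in 2:n_conf) {
        xyz <- mol$xyz
        if (nrow(rb) > 0) {
          for (b in seq_len(nrow(rb))) {
            ang <- stats::runif(1, -pi, pi)
            xyz <- rotate_about_bond(xyz, mol, rb[b, 1], rb[b, 2], ang)
          }
        } else {
          # rigid molecule: conformers are identical
        }
        confs[[k]] <- xyz
      }
    })
  }
  structure(list(mol = mol, conformers = confs, smiles = smiles),
            class = "mol_conformers")
}

#' @export
print.mol_conformers <- function(x, ...) {
  cat(sprintf("<mol_conformers> %s: %d heavy atoms, %d conformer(s)\n",
              x$smiles, x$mol$n_heavy, length(x$conformers)))
  invisible(x)
}

# rotatable bonds as an m x 2 index matrix (reuses the panel definition)
rotatable_bond_list <- function(mol) {
  if (nrow(mol$bonds) == 0) return(matrix(integer(0), 0, 2))
  deg <- integer(mol$n_heavy)
  for (k in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds[k, 1]] <- deg[mol$bonds[k, 1]] + 1L
    deg[mol$bonds[k, 2]] <- deg[mol$bonds[k, 2]] + 1L
  }
  g <- igraph::make_empty_graph(mol$n_heavy, directed = FALSE)
  g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  is_bridge <- logical(nrow(mol$bonds))
  is_bridge[as.integer(igraph::bridges(g))] <- TRUE
  sel <- mol$bonds[, 3] == 1 & is_bridge &
    deg[mol$bonds[, 1]] > 1 & deg[mol$bonds[, 2]] > 1
  mol$bonds[sel, 1:2, drop = FALSE]
}

# rotate the smaller fragment on the j-side of bond (i, j) about the bond
# axis by `angle`
rotate_about_bond <- function(xyz, mol, i, j, angle) {
  g <- igraph::make_empty_graph(mol$n_heavy, directed = FALSE)
  eb <- mol$bonds[, 1:2, drop = FALSE]
  keep <- !((eb[, 1] == i & eb[, 2] == j) | (eb[, 1] == j & eb[, 2] == i))
  g <- igraph::add_edges(g, t(eb[keep, , drop = FALSE]))
  comp <- igraph::components(g)$membership
  side_j <- which(comp == comp[j])
  if (length(side_j) > mol$n_heavy / 2) {
    side <- which(comp == comp[i]); origin <- xyz[j, ]; axis <- xyz[i, ] - xyz[j, ]
  } else {
    side <- side_j; origin <- xyz[i, ]; axis <- xyz[j, ] - xyz[i, ]
  }
  nax <- sqrt(sum(axis^2))
  if (nax < 1e-9) return(xyz)  # degenerate bond geometry: leave unchanged
  axis <- axis / nax
  # Rodrigues rotation
  Kx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * Kx + (1 - cos(angle)) * (Kx %*% Kx)
  pts <- sweep(xyz[side, , drop = FALSE], 2, origin)
  xyz[side, ] <- sweep(pts %*% t(R), 2, origin, `+`)
  xyz
}

#' Align conformers onto a pharmacophore cloud
#'
#' For each conformer, extracts the molecule's 3D pharmacophore features
#' and searches every injective, category-consistent assignment of cloud
#' points to features, allowing up to `tolerance` cloud points to remain
#' unmatched. Each assignment with at least one matched pair is solved by
#' Kabsch superposition of the feature centroids onto the cloud points;
#' poses with `fit_rmsd <= fit_cutoff` are kept and ranked by
#' (n_unmatched ascending, fit_rmsd ascending). Conformers stay rigid.
#'
#' @param mol_conf A [embed_conformers()] result.
#' @param cloud A [pharm_cloud()] hypothesis.
#' @param tolerance Maximum number of unmatched cloud points (default 0).
#' @param fit_cutoff Maximum accepted RMSD over matched pairs (default 1.5).
#' @param max_assignments Search bound; exceeding it raises an error
#'   suggesting a smaller cloud or larger tolerance (default 1e6).
#' @return List of `pose_result` objects (possibly empty): each has
#'   `conformer`, `transform` (molecule frame onto cloud frame),
#'   `matched_pairs` (2-column matrix: cloud point, feature), `n_unmatched`,
#'   `fit_rmsd`.
#' @export
align_to_cloud <- function(mol_conf, cloud, tolerance = 0, fit_cutoff = 1.5,
                           max_assignments = 1e6) {
  stopifnot(inherits(mol_conf, "mol_conformers"),
            inherits(cloud, "pharm_cloud"), tolerance >= 0)
  nc <- nrow(cloud$xyz)
  ccat <- as.character(cloud$category)
  poses <- list()
  for (ci in seq_along(mol_conf$conformers)) {
    mol <- mol_conf$mol
    mol$xyz <- mol_conf$conformers[[ci]]
    feats <- detect_features(mol)
    if (length(feats) == 0) next
    fcat <- vapply(feats, function(f) f$category, "")
    fxyz <- t(vapply(feats, function(f)
      colMeans(mol$xyz[f$atoms, , drop = FALSE]), numeric(3)))
    if (!all(is.finite(fxyz))) next
    cand <- lapply(seq_len(nc), function(i) which(fcat == ccat[i]))
    # search-space estimate
    est <- prod(pmax(vapply(cand, length, 1L), 1) + 1)
    if (est > max_assignments)
      stop("Assignment search space too large (", format(est), " > ",
           format(max_assignments),
           "); reduce the cloud size or raise the tolerance cap")
    assign <- integer(nc)
    recurse <- function(i, unmatched) {
      if (unmatched > tolerance) return(invisible())
      if (i > nc) {
        sel <- which(assign > 0)
        if (length(sel) == 0) return(invisible())
        tf <- suppressWarnings(
          kabsch(fxyz[assign[sel], , drop = FALSE],
                 cloud$xyz[sel, , drop = FALSE]))
        if (tf$rmsd <= fit_cutoff) {
          poses[[length(poses) + 1L]] <<- structure(list(
            conformer = ci,
            transform = tf,
            matched_pairs = cbind(cloud_point = sel,
                                  feature = assign[sel]),
            n_unmatched = nc - length(sel),
            fit_rmsd = tf$rmsd), class = "pose_result")
        }
        return(invisible())
      }
      for (f in cand[[i]]) {
        if (!(f %in% assign)) {
          assign[i] <<- f
          recurse(i + 1, unmatched)
          assign[i] <<- 0L
        }
      }
      recurse(i + 1, unmatched + 1L)
      invisible()
    }
    recurse(1L, 0L)
  }
  ord <- order(vapply(poses, function(p) p$n_unmatched, 1L),
               vapply(poses, function(p) p$fit_rmsd, 1))
  poses[ord]
}

#' @export
print.pose_result <- function(x, ...) {
  cat(sprintf(
    "<pose_result> conformer %d: %d matched, %d unmatched, fit RMSD %.4f A\n",
    x$conformer, nrow(x$matched_pairs), x$n_unmatched, x$fit_rmsd))
  invisible(x)
}

#' Heavy-atom coordinates of a pose in the cloud frame
#'
#' @param mol_conf The [embed_conformers()] result the pose came from.
#' @param pose A `pose_result`.
#' @return n_heavy x 3 matrix of posed coordinates.
#' @export
pose_coordinates <- function(mol_conf, pose) {
  apply_transform(mol_conf$conformers[[pose$conformer]], pose$transform)
}

#' Symmetry-corrected heavy-atom RMSD between two poses
#'
#' In-place comparison (no refitting) of two coordinate sets of the same
#' molecule, minimized over the molecular graph's automorphisms (element
#' labels respected) so that, e.g., a benzene ring rotated by 60 degrees
#' scores zero.
#'
#' @param mol A `pg_mol` (defines elements and bonds).
#' @param xyz_a,xyz_b n_heavy x 3 coordinate matrices.
#' @param max_maps Cap on enumerated automorphisms (default 1e4).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(mol, xyz_a, xyz_b, max_maps = 1e4) {
  xyz_a <- as.matrix(xyz_a); xyz_b <- as.matrix(xyz_b)
  if (nrow(xyz_a) != mol$n_heavy || nrow(xyz_b) != mol$n_heavy)
    stop("Coordinate sets do not match the molecule's heavy-atom count")
  g <- igraph::make_empty_graph(mol$n_heavy, directed = FALSE)
  if (nrow(mol$bonds) > 0)
    g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  colors <- as.integer(factor(mol$elements))
  n_auto <- tryCatch(
    igraph::count_isomorphisms(g, g, method = "vf2",
                               vertex.color1 = colors,
                               vertex.color2 = colors),
    error = function(e) 1)
  if (n_auto > max_maps) {
    warning("More than ", max_maps, " automorphisms; using identity mapping")
    maps <- list(seq_len(mol$n_heavy))
  } else {
    maps <- tryCatch(
      igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = colors,
                                         vertex.color2 = colors),
      error = function(e) list(seq_len(mol$n_heavy)))
    if (length(maps) == 0) maps <- list(seq_len(mol$n_heavy))
  }
  best <- Inf
  for (m in maps) {
    perm <- as.integer(m)
    r <- sqrt(mean(rowSums((xyz_a - xyz_b[perm, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  best
}
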