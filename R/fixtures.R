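# Synthetic fixtures: desk-scale stand-ins for pocket-ligand pharmacophore
# training pairs and for a drug-like SMILES corpus. Everything is a pure
# function of its spec and seed.

# evaluate expr under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# uniform random rotation matrix (QR of Gaussian with sign fix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Specification of a synthetic pocket-pharmacophore fixture set
#'
#' Defines the statistical structure of generated training pairs: each pair
#' has a pocket of points on a noisy spherical shell (radius ~8 A) with a
#' marked "anchor" cap of residues on one face, and a ligand pharmacophore
#' cloud drawn i.i.d. Gaussian around the pocket center displaced by `offset`
#' toward the anchor face. Pairs are randomly oriented; the anchor cap makes
#' the displacement direction recoverable by a rotation-equivariant model.
#'
#' @param n_pairs Number of pocket-cloud pairs (default 200).
#' @param pocket_points Pocket points per pair (default 24).
#' @param cloud_points Pharmacophore points per pair (default 6).
#' @param category_marginals Length-8 nonnegative vector summing to 1 over
#'   the pinned category alphabet; default weights H-bonding features most.
#' @param offset 3-vector (Angstrom): canonical-frame displacement from the
#'   pocket center to the cloud centroid (default `c(0, 0, 3)`).
#' @param spatial_sigma Isotropic cloud spread around its centroid (default 1).
#' @param shell_radius Pocket shell radius (default 8).
#' @param corrupt_frac Fraction of pairs whose cloud is displaced by an extra
#'   4-8 A (emulating mis-docked conformations); default 0.
#' @param seed Integer RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pairs = 200, pocket_points = 24, cloud_points = 6,
                         category_marginals = c(0.15, 0.15, 0.05, 0.05,
                                                0.25, 0.25, 0.05, 0.05),
                         offset = c(0, 0, 3), spatial_sigma = 1,
                         shell_radius = 8, corrupt_frac = 0, seed = 1) {
  category_marginals <- as.numeric(category_marginals)
  if (length(category_marginals) != 8L || any(category_marginals < 0) ||
      abs(sum(category_marginals) - 1) > 1e-9)
    stop("category_marginals must be 8 nonnegative values summing to 1")
  if (n_pairs < 1 || pocket_points < 4 || cloud_points < 1)
    stop("n_pairs, pocket_points, cloud_points out of range")
  structure(list(n_pairs = n_pairs, pocket_points = pocket_points,
                 cloud_points = cloud_points,
                 category_marginals = category_marginals,
                 offset = as.numeric(offset), spatial_sigma = spatial_sigma,
                 shell_radius = shell_radius, corrupt_frac = corrupt_frac,
                 seed = seed), class = "fixture_spec")
}

# residue alphabet used by fixture pockets; TRP marks the anchor cap
.fixture_residues <- c("ALA", "GLY", "LEU", "SER")
.fixture_anchor <- "TRP"

#' Generate synthetic pocket-pharmacophore training pairs
#'
#' Each pair is built in a canonical frame (anchor cap toward +z, cloud
#' centroid at `offset`) and then given a random rigid orientation, as real
#' deposited complexes have. The realized displacement vector and rotation
#' are attached to each pair as attributes `offset` and `rotation`.
#'
#' @param spec A [fixture_spec()].
#' @return List of length `n_pairs`; each element is
#'   `list(pocket = pocket_cloud, cloud = pharm_cloud)` with attributes
#'   `offset` (realized 3-vector), `rotation`, and `corrupted` (logical).
#' @export
make_complex_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  cats <- pharm_categories()
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_pairs), function(i) {
      R <- random_rotation()
      # pocket: noisy shell; the first 5 points form a tight "anchor" cap
      # around canonical +z (binding-face residues), making the cloud
      # displacement direction sharply recoverable from the pocket alone
      n_anchor <- 5L
      z <- matrix(stats::rnorm(spec$pocket_points * 3), ncol = 3)
      z <- z / sqrt(rowSums(z^2))
      for (j in seq_len(n_anchor)) {
        u <- stats::runif(1, 0.94, 1); ang <- stats::runif(1, 0, 2 * pi)
        r <- sqrt(1 - u^2)
        z[j, ] <- c(r * cos(ang), r * sin(ang), u)
      }
      pxyz <- z * (spec$shell_radius + stats::rnorm(spec$pocket_points, 0, 0.5))
      resid <- c(rep(.fixture_anchor, n_anchor),
                 sample(.fixture_residues, spec$pocket_points - n_anchor,
                        replace = TRUE))
      corrupted <- stats::runif(1) < spec$corrupt_frac
      centroid <- spec$offset
      if (corrupted) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        centroid <- centroid + dir * stats::runif(1, 4, 8)
      }
      cxyz <- matrix(stats::rnorm(spec$cloud_points * 3, 0,
                                  spec$spatial_sigma), ncol = 3)
      cxyz <- sweep(cxyz, 2, centroid, `+`)
      cat_idx <- sample.int(8, spec$cloud_points, replace = TRUE,
                            prob = spec$category_marginals)
      # apply the pair's orientation
      pxyz <- pxyz %*% t(R)
      cxyz <- cxyz %*% t(R)
      off <- as.numeric(R %*% centroid)
      pair <- list(
        pocket = pocket_cloud(pxyz, resid, mode = "calpha",
                              center = c(0, 0, 0),
                              radius = spec$shell_radius + 3),
        cloud = pharm_cloud(cxyz, cats[cat_idx],
                            provenance = "ligand-derived")
      )
      attr(pair, "offset") <- off
      attr(pair, "rotation") <- R
      attr(pair, "corrupted") <- corrupted
      pair
    })
  })
}

#' Anchor-face direction of a fixture pocket
#'
#' Unit vector from the pocket center toward the centroid of its anchor
#' (TRP) points; the direction along which fixture clouds are displaced.
#'
#' @param pocket A fixture `pocket_cloud`.
#' @return Unit 3-vector.
#' @export
pocket_anchor_direction <- function(pocket) {
  anc <- pocket$feature == .fixture_anchor
  if (!any(anc)) stop("Pocket has no anchor residues")
  v <- colMeans(pocket$xyz[anc, , drop = FALSE]) - pocket$center
  v / sqrt(sum(v^2))
}

#' Screen fixture pairs by cloud-centroid deviation
#'
#' Mirrors the training-data quality rule of discarding poses whose
#' conformation deviates too far: drops pairs whose cloud centroid lies more
#' than `max_dev` from the expected anchor-directed offset position.
#'
#' @param pairs Output of [make_complex_fixtures()].
#' @param offset_length Expected centroid displacement length (Angstrom).
#' @param max_dev Maximum tolerated deviation (default 2).
#' @return Filtered list of pairs.
#' @export
filter_fixture_pairs <- function(pairs, offset_length = 3, max_dev = 2) {
  keep <- vapply(pairs, function(p) {
    expect <- p$pocket$center +
      offset_length * pocket_anchor_direction(p$pocket)
    dev <- sqrt(sum((colMeans(p$cloud$xyz) - expect)^2))
    dev <= max_dev
  }, logical(1))
  pairs[keep]
}

# corpus templates: sprintf patterns with two substituent slots.
# symmetric = the two slots are chemically equivalent (unordered pairs only)
.corpus_templates <- list(
  list(pat = "c1cc(%s)ccc1%s",                 symmetric = TRUE),
  list(pat = "c1ncc(%s)cc1%s",                 symmetric = FALSE),
  list(pat = "C1CN(%s)CCN1%s",                 symmetric = TRUE),
  list(pat = "O=C(Nc1ccc(%s)cc1)%s",           symmetric = FALSE),
  list(pat = "O=S(=O)(N%s)c1ccc(%s)cc1",       symmetric = FALSE),
  list(pat = "OC(=O)c1ccc(%s)cc1%s",           symmetric = FALSE),
  list(pat = "O=C(OC%s)c1ccc(%s)cc1",          symmetric = FALSE),
  list(pat = "c1cc(NC(=O)C%s)ccc1%s",          symmetric = FALSE)
)

.corpus_substituents <- c(
  "C", "CC", "CCC", "CC(C)C", "CCCC", "F", "Cl", "Br", "O", "OC", "OCC",
  "N", "NC", "N(C)C", "C#N", "C(=O)O", "C(=O)N", "C(F)(F)F", "CCO",
  "CCN(C)C", "S(=O)(=O)C", "c3ccccc3", "C3CC3"
)

#' Generate a deterministic drug-like SMILES corpus
#'
#' Enumerates scaffold x substituent templates (disubstituted benzenes and
#' pyridines, piperazines, anilides, sulfonamides, benzoates) over a fixed
#' substituent set, shuffles the enumeration with `seed`, and returns the
#' first `n` molecules. All emitted strings are valid, mutually distinct
#' molecules rich in pharmacophore features, with molecular weight well
#' under the 800 Da corpus cap.
#'
#' @param n Number of molecules (at most the enumerable space, ~4800).
#' @param seed Integer RNG seed controlling the shuffle.
#' @return Character vector of `n` SMILES.
#' @export
make_smiles_corpus <- function(n, seed = 1) {
  stopifnot(n >= 1)
  subs <- .corpus_substituents
  all <- unlist(lapply(.corpus_templates, function(tp) {
    idx <- expand.grid(a = seq_along(subs), b = seq_along(subs))
    if (tp$symmetric) idx <- idx[idx$a <= idx$b, ]
    sprintf(tp$pat, subs[idx$a], subs[idx$b])
  }))
  all <- unique(all)
  if (n > length(all))
    stop("Requested ", n, " molecules but the template space holds only ",
         length(all))
  with_seed(seed, all[sample.int(length(all), n)])
}

#' Write a pocket cloud as a minimal PDB file
#'
#' Emits standards-conformant ATOM records that [extract_pocket_cloud()] can
#' re-read: one CA atom per point in `calpha` mode (residue type = feature),
#' or one atom per point named by its element in `full_atom` mode.
#'
#' @param pocket A [pocket_cloud()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(pocket, path) {
  stopifnot(inherits(pocket, "pocket_cloud"))
  n <- nrow(pocket$xyz)
  if (pocket$mode == "calpha") {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(pocket$xyz)),
                     resno = seq_len(n), resid = pocket$feature,
                     eleno = seq_len(n), elety = rep("CA", n),
                     chain = rep("A", n))
  } else {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(pocket$xyz)),
                     resno = seq_len(n), resid = rep("UNK", n),
                     eleno = seq_len(n), elety = pocket$feature,
                     chain = rep("A", n))
  }
  invisible(path)
}

#' Write a molecule to an SDF file
#'
#' @param mol A `ChemmineR::SDFset`/`SDF` (e.g. from [embed_conformers()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_sdf <- function(mol, path) {
  if (inherits(mol, "SDF")) mol <- methods::as(mol, "SDFset")
  ChemmineR::write.SDF(mol, path)
  invisible(path)
}

#' Build a synthetic peptide PDB file
#'
#' A format-valid toy poly-alanine chain (N, CA, C, O, CB per residue laid
#' out along x) for exercising pocket extraction; not a physical structure.
#'
#' @param path Output path.
#' @param n_res Number of residues (default 3).
#' @return Invisibly, the number of heavy atoms written.
#' @export
make_fixture_peptide <- function(path, n_res = 3) {
  # per-residue template offsets (Angstrom), ~3.8 A CA-CA spacing
  tmpl <- rbind(N  = c(0.0, 0.3, 0.0),
                CA = c(1.2, 1.0, 0.0),
                C  = c(2.6, 0.5, 0.0),
                O  = c(2.9, -0.7, 0.0),
                CB = c(1.3, 2.1, 1.1))
  xyz <- NULL; elety <- c(); resno <- c()
  for (r in seq_len(n_res)) {
    xyz <- rbind(xyz, sweep(tmpl, 2, c((r - 1) * 3.8, 0, 0), `+`))
    elety <- c(elety, rownames(tmpl))
    resno <- c(resno, rep(r, nrow(tmpl)))
  }
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = resno, resid = rep("ALA", n),
                   eleno = seq_len(n), elety = elety, chain = rep("A", n))
  invisible(n)
}
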