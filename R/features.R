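# Pharmacophore feature detection and pocket point-cloud extraction.
#
# Feature families are detected with explicit graph rules on the heavy-atom
# molecular graph rather than a SMARTS engine; the rules are deliberately
# compact, deterministic, and documented below. Each detected family becomes
# one cloud point at the unweighted centroid of its member atoms.

# Detect pharmacophore features of a parsed molecule.
# Returns a list of features: list(category=, atoms=<heavy atom indices>).
#
# Rules (per category):
#  * Aromatic          one feature per perceived aromatic ring.
#  * Donor             N or O carrying at least one hydrogen.
#  * Acceptor          any O not positively charged and not the -OH/=O of a
#                      detected acid group's duplicate (kept anyway, acids are
#                      separate NegIonizable features); N with a free lone
#                      pair: not positively charged, not an aromatic N-H, and
#                      not an amide nitrogen.
#  * PosIonizable      aliphatic amine N (all neighbors carbon, none of them
#                      a carbonyl carbon), amidine/guanidine carbon groups,
#                      and any positively charged atom.
#  * NegIonizable      carboxylic / sulfonic / phosphonic acid groups
#                      (central atom plus its acid oxygens), and any
#                      negatively charged atom not already in such a group.
#  * Hydrophobic       connected component of 1-3 aliphatic carbons having
#                      no N/O/S/P neighbor, plus heavy halogens (Cl,Br,I).
#  * LumpedHydrophobe  such a component with 4 or more atoms (e.g. an
#                      aliphatic carbocycle or a long chain), taken as one
#                      lumped feature.
#  * Other             sulfur atoms outside acid groups (thioether/thiol
#                      environments) - the catch-all class.
detect_features <- function(mol) {
  stopifnot(inherits(mol, "pg_mol"))
  n <- mol$n_heavy
  el <- mol$elements
  adj <- mol_adjacency(mol)
  feats <- list()
  add <- function(category, atoms) {
    feats[[length(feats) + 1L]] <<- list(category = category,
                                         atoms = as.integer(atoms))
  }

  # bond order lookup (aromatic SDF code 4 treated as 1.5)
  bond_order <- function(i, j) {
    if (nrow(mol$bonds) == 0) return(0)
    hit <- (mol$bonds[, 1] == i & mol$bonds[, 2] == j) |
           (mol$bonds[, 1] == j & mol$bonds[, 2] == i)
    if (!any(hit)) return(0)
    o <- mol$bonds[which(hit)[1], 3]
    if (o == 4) 1.5 else o
  }
  has_double_O <- function(i) {
    any(vapply(adj[[i]], function(j) el[j] == "O" && bond_order(i, j) == 2,
               logical(1)))
  }

  # Aromatic rings
  for (ring in mol$arom_rings) add("Aromatic", ring)

  # acid groups (NegIonizable): C/S/P center with >=1 double-bonded O and
  # >=1 single-bonded O (protonated or anionic)
  in_acid <- logical(n)
  for (i in which(el %in% c("C", "S", "P"))) {
    o_nb <- adj[[i]][el[adj[[i]]] == "O"]
    if (length(o_nb) < 2) next
    dbl <- o_nb[vapply(o_nb, function(j) bond_order(i, j) == 2, logical(1))]
    sgl <- o_nb[vapply(o_nb, function(j) bond_order(i, j) == 1, logical(1))]
    # single-bonded O must be terminal (hydroxyl or anion), not an ester O
    sgl <- sgl[vapply(sgl, function(j) length(adj[[j]]) == 1L, logical(1))]
    if (length(dbl) >= 1 && length(sgl) >= 1) {
      grp <- c(i, dbl, sgl)
      add("NegIonizable", grp)
      in_acid[grp] <- TRUE
    }
  }
  for (i in which(mol$charge < 0)) {
    if (!in_acid[i]) add("NegIonizable", i)
  }

  # amidine / guanidine carbon (PosIonizable): non-aromatic C with >=2 N
  # neighbors, at least one via double bond
  amidine_n <- logical(n)
  for (i in which(el == "C" & !mol$aromatic)) {
    n_nb <- adj[[i]][el[adj[[i]]] == "N"]
    if (length(n_nb) >= 2 &&
        any(vapply(n_nb, function(j) bond_order(i, j) == 2, logical(1)))) {
      add("PosIonizable", c(i, n_nb))
      amidine_n[n_nb] <- TRUE
    }
  }

  carbonyl_c <- which(el == "C" & vapply(seq_len(n), function(i)
    has_double_O(i), logical(1)))
  for (i in which(el == "N")) {
    nb <- adj[[i]]
    amide <- any(nb %in% carbonyl_c)
    # aliphatic amine: every neighbor is a non-carbonyl carbon
    if (!mol$aromatic[i] && !amidine_n[i] && !amide &&
        length(nb) > 0 && all(el[nb] == "C") && !any(nb %in% carbonyl_c) &&
        mol$charge[i] >= 0) {
      add("PosIonizable", i)
    } else if (mol$charge[i] > 0 && !amidine_n[i]) {
      add("PosIonizable", i)
    }
  }

  # Donors and acceptors
  for (i in which(el %in% c("N", "O"))) {
    if (mol$n_h[i] >= 1 && mol$charge[i] >= 0) add("Donor", i)
    if (el[i] == "O") {
      if (mol$charge[i] <= 0) add("Acceptor", i)
    } else {
      aromatic_nh <- mol$aromatic[i] && mol$n_h[i] >= 1
      amide <- any(adj[[i]] %in% carbonyl_c)
      if (mol$charge[i] <= 0 && !aromatic_nh && !amide) add("Acceptor", i)
    }
  }

  # Hydrophobic components: aliphatic carbons with no polar neighbor,
  # plus heavy halogens
  polar <- el %in% c("N", "O", "S", "P")
  hydro <- (el == "C" & !mol$aromatic &
              !vapply(seq_len(n), function(i) any(polar[adj[[i]]]),
                      logical(1))) |
           el %in% c("Cl", "Br", "I")
  if (any(hydro)) {
    idx <- which(hydro)
    g <- igraph::make_empty_graph(length(idx), directed = FALSE)
    if (nrow(mol$bonds) > 0) {
      eb <- mol$bonds[mol$bonds[, 1] %in% idx & mol$bonds[, 2] %in% idx, ,
                      drop = FALSE]
      if (nrow(eb) > 0) {
        g <- igraph::add_edges(g, rbind(match(eb[, 1], idx),
                                        match(eb[, 2], idx)))
      }
    }
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      atoms <- idx[comp == cid]
      add(if (length(atoms) >= 4) "LumpedHydrophobe" else "Hydrophobic",
          atoms)
    }
  }

  # catch-all: sulfur outside acid groups
  for (i in which(el == "S")) if (!in_acid[i]) add("Other", i)

  feats
}

#' Extract a ligand's pharmacophore point cloud
#'
#' Runs the package's pharmacophore feature rules (aromatic rings, H-bond
#' donors/acceptors, positive/negative ionizable groups, hydrophobic and
#' lumped-hydrophobic carbon clusters, and a sulfur catch-all) on a molecule
#' with one 3D conformer. Each detected feature family becomes one cloud
#' point at the unweighted centroid of its member atoms.
#'
#' @param mol A `pg_mol` (see [parse_smiles()], [mol_from_sdf()]), a
#'   `ChemmineR::SDF`/`SDFset`, or a path to an SDF/MOL file with one record.
#' @return A [pharm_cloud()] with provenance `"ligand-derived"`.
#' @export
#' @examples
#' \donttest{
#' mol <- embed_conformers("c1ccc(O)cc1", n_conf = 1, seed = 1)
#' extract_ligand_pharmacophores(mol)
#' }
extract_ligand_pharmacophores <- function(mol) {
  mol <- as_pg_mol(mol)
  if (all(mol$xyz == 0))
    warning("Molecule appears to lack 3D coordinates; centroids may be flat")
  feats <- detect_features(mol)
  if (length(feats) == 0L)
    stop("No pharmacophore features detected: cannot build an empty cloud",
         call. = FALSE)
  xyz <- t(vapply(feats, function(f)
    colMeans(mol$xyz[f$atoms, , drop = FALSE]), numeric(3)))
  pharm_cloud(xyz,
              vapply(feats, function(f) f$category, ""),
              vapply(feats, function(f) length(f$atoms), 1L),
              provenance = "ligand-derived")
}

# Coerce the accepted molecule inputs to pg_mol
as_pg_mol <- function(mol) {
  if (inherits(mol, "pg_mol")) return(mol)
  if (inherits(mol, "SDFset")) {
    if (length(mol) != 1L) stop("Expected a single-molecule SDFset")
    return(mol_from_sdf(mol[[1]]))
  }
  if (inherits(mol, "SDF")) return(mol_from_sdf(mol))
  if (is.character(mol) && length(mol) == 1L && file.exists(mol)) {
    sdfs <- ChemmineR::read.SDFset(mol)
    if (length(sdfs) != 1L) stop("Expected exactly one record in ", mol)
    return(mol_from_sdf(sdfs[[1]]))
  }
  stop("Cannot interpret `mol` as a molecule (pg_mol, SDF, SDFset or path)")
}

#' Extract a protein pocket point cloud from a PDB structure
#'
#' Selects the pocket around `center` and converts it to the conditioning
#' point cloud used by the diffusion sampler. In `full_atom` mode every
#' non-hydrogen, non-water atom within `radius` becomes a point carrying its
#' element symbol; in `calpha` mode one point per residue (its C-alpha, if
#' within `radius`) carrying the residue type.
#'
#' @param structure Path to a PDB file or a `bio3d` pdb object.
#' @param center Numeric 3-vector (Angstrom), typically the reference-ligand
#'   centroid.
#' @param radius Selection radius in Angstrom (default 10).
#' @param mode `"full_atom"` or `"calpha"`.
#' @return A [pocket_cloud()].
#' @export
extract_pocket_cloud <- function(structure, center, radius = 10,
                                 mode = c("full_atom", "calpha")) {
  mode <- match.arg(mode)
  if (is.character(structure)) {
    structure <- bio3d::read.pdb(structure, verbose = FALSE)
  }
  at <- structure$atom
  ele <- tryCatch(bio3d::atom2ele(structure),
                  error = function(e) substr(trimws(at$elety), 1, 1))
  keep <- ele != "H" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  if (nrow(at) == 0L) stop("Structure contains no heavy non-water atoms")
  xyz <- cbind(at$x, at$y, at$z)
  center <- as.numeric(center)
  d <- sqrt(colSums((t(xyz) - center)^2))

  if (mode == "full_atom") {
    sel <- d <= radius
    if (!any(sel))
      stop(sprintf(
        "Empty pocket selection: no heavy atom within %.2f A of (%.2f, %.2f, %.2f)",
        radius, center[1], center[2], center[3]), call. = FALSE)
    pocket_cloud(xyz[sel, , drop = FALSE], ele[sel], mode = "full_atom",
                 center = center, radius = radius)
  } else {
    ca <- at$elety == "CA" & d <= radius
    if (!any(ca))
      stop(sprintf(
        "Empty pocket selection: no C-alpha within %.2f A of (%.2f, %.2f, %.2f)",
        radius, center[1], center[2], center[3]), call. = FALSE)
    pocket_cloud(xyz[ca, , drop = FALSE], at$resid[ca], mode = "calpha",
                 center = center, radius = radius)
  }
}
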