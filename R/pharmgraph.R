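# Pharmacophore hypothesis graphs: the conditioning object consumed by the
# molecule generator. At training time node distances are topological
# (shortest bond path x 1.5 A/bond, a metric surrogate); at inference they
# are Euclidean distances of a sampled 3D cloud.

.max_phar <- 8L
.bond_unit <- 1.5  # Angstrom per bond, mean single-bond length

#' Construct a pharmacophore hypothesis graph
#'
#' @param nodes Character vector of category labels (1..8 nodes).
#' @param edge_dist Symmetric nonnegative matrix of pairwise distances
#'   (Angstrom) with zero diagonal.
#' @param source `"euclidean-3d"` (inference, from a sampled cloud) or
#'   `"graph-topological"` (training, bond-path surrogate).
#' @return Object of class `pharm_graph`.
#' @export
pharm_graph <- function(nodes, edge_dist,
                        source = c("euclidean-3d", "graph-topological")) {
  source <- match.arg(source)
  nodes <- canonical_category(as.character(nodes))
  n <- length(nodes)
  if (n < 1 || n > .max_phar)
    stop("pharm_graph needs 1..", .max_phar, " nodes")
  edge_dist <- as.matrix(edge_dist)
  if (!all(dim(edge_dist) == c(n, n)))
    stop("edge_dist must be ", n, " x ", n)
  if (max(abs(edge_dist - t(edge_dist))) > 1e-9 ||
      any(diag(edge_dist) != 0) || any(edge_dist < 0))
    stop("edge_dist must be symmetric, nonnegative, zero-diagonal")
  structure(list(nodes = nodes, edge_dist = unname(edge_dist),
                 source = source), class = "pharm_graph")
}

#' @export
print.pharm_graph <- function(x, ...) {
  cat(sprintf("<pharm_graph> %d nodes (%s): %s\n", length(x$nodes),
              x$source, paste(x$nodes, collapse = ", ")))
  invisible(x)
}

#' Convert a pharmacophore cloud to a hypothesis graph
#'
#' Takes the Euclidean pairwise distances of the cloud points. Clouds with
#' more than 8 points are reduced to the 8 highest-support points.
#'
#' @param cloud A [pharm_cloud()].
#' @return A [pharm_graph()] with `source = "euclidean-3d"`.
#' @export
cloud_to_pharm_graph <- function(cloud) {
  stopifnot(inherits(cloud, "pharm_cloud"))
  idx <- seq_len(nrow(cloud$xyz))
  if (length(idx) > .max_phar) {
    idx <- order(-cloud$support)[seq_len(.max_phar)]
  }
  xyz <- cloud$xyz[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  pharm_graph(as.character(cloud$category)[idx], d, source = "euclidean-3d")
}

#' Build a training pair from a molecule
#'
#' Detects the molecule's 2D pharmacophore features, samples a random
#' feature subset (the infilling noise that teaches the generator to
#' complete partial hypotheses), computes topological node distances
#' (shortest bond path between member atoms x 1.5 A/bond), and records the
#' node-to-atom mapping supervised by the mapping loss.
#'
#' @param smiles A SMILES string.
#' @param infill_rate In [0, 1]: 0 keeps all detected features
#'   (deterministic); larger values sample smaller random subsets.
#' @param max_phar Maximum hypothesis size (default 8).
#' @return NULL (with a message) when the molecule has fewer than 2
#'   features; otherwise a list with `phar` (a `pharm_graph`,
#'   `graph-topological`), `tokens`, `mapping` (max_phar x (n_atoms + 1)
#'   one-hot matrix: each node row marks its representative member atom,
#'   unused rows mark the trailing "unmapped" column), and `n_atoms`.
#' @export
mol_to_training_pair <- function(smiles, infill_rate = 0.5,
                                 max_phar = .max_phar) {
  mol <- parse_smiles(smiles, strict = FALSE)
  if (is.null(mol)) {
    message("Skipping unparseable molecule: ", smiles)
    return(NULL)
  }
  feats <- detect_features(mol)
  if (length(feats) < 2) {
    message("Skipping molecule with < 2 pharmacophore features: ", smiles)
    return(NULL)
  }
  nf <- length(feats)
  k_max <- min(nf, max_phar)
  if (infill_rate <= 0) {
    sel <- seq_len(k_max)
  } else {
    k <- sample(2:k_max, 1)
    sel <- sort(sample.int(nf, k))
  }
  feats <- feats[sel]
  bd <- bond_distances(mol) * .bond_unit
  k <- length(feats)
  dmat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j)
      dmat[i, j] <- min(bd[feats[[i]]$atoms, feats[[j]]$atoms])
  }
  phar <- pharm_graph(vapply(feats, function(f) f$category, ""), dmat,
                      source = "graph-topological")
  mapping <- matrix(0, max_phar, mol$n_heavy + 1)
  for (i in seq_len(k)) mapping[i, min(feats[[i]]$atoms)] <- 1
  if (k < max_phar)
    mapping[(k + 1):max_phar, mol$n_heavy + 1] <- 1
  list(phar = phar, tokens = tokenize(smiles), mapping = mapping,
       n_atoms = mol$n_heavy)
}
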