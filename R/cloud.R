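#' Pharmacophore category alphabet
#'
#' The fixed eight-class feature alphabet used throughout the package:
#' Aromatic, Hydrophobic, PosIonizable, NegIonizable, Acceptor, Donor,
#' LumpedHydrophobe and Other. The label/index bijection (indices 0-7) is
#' pinned and serialized with every artifact so that one-hot encodings are
#' portable across models and files. `PosIonizable`/`NegIonizable` also accept
#' the historical aliases `Localizable`/`Negativable` on input.
#'
#' @return Character vector of the 8 canonical labels, in pinned order.
#' @export
#' @examples
#' pharm_categories()
pharm_categories <- function() {
  c("Aromatic", "Hydrophobic", "PosIonizable", "NegIonizable",
    "Acceptor", "Donor", "LumpedHydrophobe", "Other")
}

# Aliases accepted on input (old-style ionizable names and plural catch-all).
.category_aliases <- c(
  Localizable = "PosIonizable",
  Negativable = "NegIonizable",
  Others      = "Other"
)

#' Resolve category labels to canonical form
#'
#' @param label Character vector of labels (canonical or alias).
#' @return Character vector of canonical labels.
#' @export
canonical_category <- function(label) {
  cats <- pharm_categories()
  out <- ifelse(label %in% names(.category_aliases),
                unname(.category_aliases[label]), label)
  bad <- setdiff(unique(out), cats)
  if (length(bad) > 0) {
    stop("Unknown pharmacophore category label(s): ",
         paste(bad, collapse = ", "),
         ". Valid labels are: ", paste(cats, collapse = ", "), call. = FALSE)
  }
  out
}

#' Zero-based index of a category label
#' @param label Character vector of (canonical or alias) labels.
#' @return Integer vector of indices in 0..7.
#' @export
category_index <- function(label) {
  match(canonical_category(label), pharm_categories()) - 1L
}

#' Construct a pharmacophore point cloud
#'
#' The central data structure of the package: a set of labeled 3D points,
#' each carrying one of the 8 feature categories and a support count (how
#' many underlying atoms/samples the point summarizes).
#'
#' @param xyz Numeric matrix, n x 3, coordinates in Angstrom.
#' @param category Character vector of length n of category labels.
#' @param support Integer vector of length n (default all 1).
#' @param provenance Free-text tag, e.g. "ligand-derived", "diffusion-sampled",
#'   "clustered", "selective".
#' @return An object of class `pharm_cloud` with fields `xyz`, `category`
#'   (factor over the pinned alphabet), `support`, `provenance`.
#' @export
#' @examples
#' pharm_cloud(matrix(rnorm(9), 3, 3), c("Aromatic", "Donor", "Acceptor"))
pharm_cloud <- function(xyz, category, support = NULL,
                        provenance = "ligand-derived") {
  xyz <- as.matrix(xyz)
  if (length(xyz) == 0L) stop("A pharmacophore cloud needs at least one point")
  if (ncol(xyz) != 3L) stop("xyz must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz))) stop("Cloud coordinates must be finite")
  category <- canonical_category(as.character(category))
  if (length(category) != nrow(xyz))
    stop("category length must match the number of points")
  if (is.null(support)) support <- rep(1L, nrow(xyz))
  support <- as.integer(support)
  if (any(support < 1L)) stop("support must be >= 1 for every point")
  structure(list(
    xyz = unname(xyz),
    category = factor(category, levels = pharm_categories()),
    support = support,
    provenance = provenance
  ), class = "pharm_cloud")
}

#' @export
print.pharm_cloud <- function(x, ...) {
  cat(sprintf("<pharm_cloud> %d points (%s)\n", nrow(x$xyz), x$provenance))
  tab <- table(x$category)
  tab <- tab[tab > 0]
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.pharm_cloud <- function(x) nrow(x$xyz)

#' One-hot feature matrix of a cloud
#' @param cloud A `pharm_cloud`.
#' @return n x 8 numeric one-hot matrix, columns in pinned category order.
#' @export
cloud_onehot <- function(cloud) {
  n <- nrow(cloud$xyz)
  h <- matrix(0, n, 8L, dimnames = list(NULL, pharm_categories()))
  h[cbind(seq_len(n), as.integer(cloud$category))] <- 1
  h
}

#' Subset a pharmacophore cloud
#' @param cloud A `pharm_cloud`.
#' @param i Index vector of points to keep (at least one).
#' @return A `pharm_cloud` with the selected points.
#' @export
cloud_subset <- function(cloud, i) {
  pharm_cloud(cloud$xyz[i, , drop = FALSE],
              as.character(cloud$category)[i],
              cloud$support[i], cloud$provenance)
}

#' Construct a protein pocket point cloud
#'
#' A pocket is represented either by its heavy atoms (`full_atom` mode;
#' features are element symbols) or by one C-alpha point per residue
#' (`calpha` mode; features are residue types).
#'
#' @param xyz Numeric n x 3 matrix of coordinates (Angstrom).
#' @param feature Character vector of length n (element symbols or residue
#'   types, depending on mode).
#' @param mode `"full_atom"` or `"calpha"`.
#' @param center 3-vector, the pocket center used for selection (Angstrom).
#' @param radius Selection radius (Angstrom).
#' @return An object of class `pocket_cloud`. The feature alphabet (sorted
#'   unique features) is stored in `$alphabet`; its size is the conditioning
#'   feature dimension d_P.
#' @export
pocket_cloud <- function(xyz, feature, mode = c("full_atom", "calpha"),
                         center = c(0, 0, 0), radius = Inf) {
  mode <- match.arg(mode)
  xyz <- as.matrix(xyz)
  if (length(xyz) == 0L) stop("A pocket cloud needs at least one point")
  if (ncol(xyz) != 3L) stop("xyz must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  feature <- as.character(feature)
  if (length(feature) != nrow(xyz))
    stop("feature length must match the number of points")
  structure(list(
    xyz = unname(xyz),
    feature = feature,
    alphabet = sort(unique(feature)),
    mode = mode,
    center = as.numeric(center),
    radius = as.numeric(radius)
  ), class = "pocket_cloud")
}

#' @export
print.pocket_cloud <- function(x, ...) {
  cat(sprintf("<pocket_cloud> %d points, mode=%s, d_P=%d, radius=%.1f A\n",
              nrow(x$xyz), x$mode, length(x$alphabet), x$radius))
  invisible(x)
}

#' @export
length.pocket_cloud <- function(x) nrow(x$xyz)

#' One-hot pocket feature matrix
#' @param pocket A `pocket_cloud`.
#' @param alphabet Optional fixed alphabet (defaults to the pocket's own).
#' @return n x d_P one-hot matrix.
#' @export
pocket_onehot <- function(pocket, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- pocket$alphabet
  idx <- match(pocket$feature, alphabet)
  if (anyNA(idx)) stop("pocket features outside the supplied alphabet")
  h <- matrix(0, nrow(pocket$xyz), length(alphabet),
              dimnames = list(NULL, alphabet))
  h[cbind(seq_along(idx), idx)] <- 1
  h
}

#' Write a pharmacophore cloud to JSON
#'
#' Canonical single-object format:
#' `{"format":"pharm_cloud","categories":[...8 labels...],`
#' `"points":[{"xyz":[x,y,z],"category":"Aromatic","support":1},...],`
#' `"provenance":"..."}`. The category alphabet is serialized with every file
#' so the label/index bijection travels with the artifact.
#'
#' @param cloud A `pharm_cloud`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "pharm_cloud"))
  pts <- lapply(seq_len(nrow(cloud$xyz)), function(i) {
    list(xyz = as.numeric(cloud$xyz[i, ]),
         category = as.character(cloud$category[i]),
         support = cloud$support[i])
  })
  obj <- list(format = "pharm_cloud",
              categories = pharm_categories(),
              points = pts,
              provenance = cloud$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pharmacophore cloud from JSON
#'
#' @param path Path to a JSON file written by [write_cloud()] (alias category
#'   labels are accepted and canonicalized).
#' @return A `pharm_cloud`.
#' @export
read_cloud <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$points) || length(obj$points) == 0L)
    stop("No points found in cloud file: ", path)
  xyz <- t(vapply(obj$points, function(p) as.numeric(unlist(p$xyz)),
                  numeric(3)))
  cat_lab <- vapply(obj$points, function(p) as.character(p$category), "")
  supp <- vapply(obj$points, function(p) {
    if (is.null(p$support)) 1L else as.integer(p$support)
  }, 1L)
  prov <- if (is.null(obj$provenance)) "unknown" else obj$provenance
  pharm_cloud(xyz, cat_lab, supp, prov)
}
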