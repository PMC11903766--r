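# Molecule handling built on ChemmineR / ChemmineOB (OpenBabel backend).
# Internal representation `pg_mol`: elements, coordinates (possibly all-zero
# for connectivity-only parses), bond list with orders, aromatic ring list,
# and per-atom hydrogen counts (explicit H are folded into heavy-atom counts).

# default valences of the SMILES organic subset, used to infer implicit H
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

# build a pg_mol for a single-heavy-atom SMILES (e.g. "C", "[NH4+]")
single_atom_mol <- function(smiles) {
  m <- regmatches(smiles,
                  regexpr("^\\[?([A-Z][a-z]?|[cnosp])", smiles, perl = TRUE))
  el <- sub("^\\[", "", m)
  el <- paste0(toupper(substr(el, 1, 1)), substr(el, 2, nchar(el)))
  chg <- 0
  if (grepl("\\+", smiles)) chg <- 1
  if (grepl("-", smiles)) chg <- -1
  val <- .default_valence[el]
  if (is.na(val)) val <- 0
  nh <- max(0, val + if (el %in% c("N", "P", "O", "S")) chg else -abs(chg))
  structure(list(elements = el, xyz = matrix(0, 1, 3),
                 bonds = matrix(numeric(0), 0, 3), n_h = as.integer(nh),
                 aromatic = FALSE, arom_rings = list(), charge = chg,
                 n_heavy = 1L, smiles = smiles), class = "pg_mol")
}

# number of heavy-atom tokens in a SMILES string (NA if untokenizable)
n_atom_tokens <- function(smiles) {
  tryCatch(sum(.is_atom_token(tokenize(smiles))), error = function(e) NA)
}

#' Parse a SMILES string into an internal molecule object
#'
#' @param smiles A single SMILES string.
#' @param strict If TRUE (default) parse failures raise an error; otherwise
#'   NULL is returned.
#' @return A `pg_mol` object (or NULL when `strict = FALSE` and parsing fails).
#' @export
parse_smiles <- function(smiles, strict = TRUE) {
  stopifnot(length(smiles) == 1L)
  if (isTRUE(n_atom_tokens(smiles) == 1L)) return(single_atom_mol(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) {
    if (strict) stop("Could not parse SMILES: ", smiles, call. = FALSE)
    return(NULL)
  }
  m <- tryCatch(mol_from_sdf(sdf[[1]]), error = function(e) NULL)
  if (is.null(m) || m$n_heavy < 1L) {
    if (strict) stop("Could not parse SMILES: ", smiles, call. = FALSE)
    return(NULL)
  }
  m$smiles <- smiles
  m
}

#' Build the internal molecule object from a ChemmineR SDF record
#'
#' Hydrogens are folded into per-heavy-atom hydrogen counts; the heavy-atom
#' order of the input record is preserved.
#'
#' @param sdf A `ChemmineR::SDF` object.
#' @return A `pg_mol` list with fields `elements`, `xyz`, `bonds` (m x 3
#'   matrix: i, j, order over heavy atoms), `n_h` (per-heavy-atom hydrogen
#'   count), `aromatic` (logical per atom), `arom_rings` (list of atom index
#'   vectors), `charge` (formal charges), `n_heavy`.
#' @export
mol_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || ncol(ab) < 3 || !any(grepl("_", rownames(ab)))) {
    # ChemmineR mangles single-atom records (the element is lost); such
    # molecules are handled upstream from their SMILES
    stop("Degenerate single-atom SDF record; construct from SMILES instead",
         call. = FALSE)
  }
  elements <- gsub("_.*$", "", rownames(ab))
  xyz <- unname(ab[, 1:3, drop = FALSE])
  n <- length(elements)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    matrix(numeric(0), 0, 3)
  } else {
    unname(cbind(bb[, 1], bb[, 2], bb[, 3]))
  }

  charge <- numeric(n)
  # formal charges from the SDF atom-line charge field (5th numeric column
  # in the ChemmineR atom block): 0=none, 1..7 code +3..-3
  if (ncol(ab) >= 5) {
    code <- ab[, 5]
    chgmap <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
    nz <- which(code %in% as.numeric(names(chgmap)))
    charge[nz] <- chgmap[as.character(code[nz])]
  }

  # aromatic ring perception (ChemmineR ring finder + aromaticity flag)
  ring_atoms <- list()
  if (n >= 3 && nrow(bonds) >= 3) {
    r <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 10, type = "all",
                                        arom = TRUE, inner = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(r) && length(r$RINGS) > 0) {
      arom_flags <- r$AROMATIC
      for (k in seq_along(r$RINGS)) {
        if (isTRUE(arom_flags[k])) {
          ring_atoms[[length(ring_atoms) + 1L]] <-
            as.integer(sub(".*_", "", r$RINGS[[k]]))
        }
      }
    }
  }

  heavy <- which(elements != "H")
  hmap <- integer(n); hmap[heavy] <- seq_along(heavy)
  n_h_explicit <- integer(length(heavy))
  hb <- matrix(numeric(0), 0, 3)
  if (nrow(bonds) > 0) {
    keep <- elements[bonds[, 1]] != "H" & elements[bonds[, 2]] != "H"
    hbonds <- bonds[!keep, , drop = FALSE]
    if (nrow(hbonds) > 0) {
      for (k in seq_len(nrow(hbonds))) {
        i <- hbonds[k, 1]; j <- hbonds[k, 2]
        hv <- if (elements[i] == "H") j else i
        if (elements[hv] != "H") {
          n_h_explicit[hmap[hv]] <- n_h_explicit[hmap[hv]] + 1L
        }
      }
    }
    hb <- bonds[keep, , drop = FALSE]
    hb[, 1] <- hmap[hb[, 1]]
    hb[, 2] <- hmap[hb[, 2]]
  }

  el <- elements[heavy]
  xyzh <- xyz[heavy, , drop = FALSE]
  chg_h <- charge[heavy]
  arom <- logical(length(heavy))
  arings <- list()
  for (ring in ring_atoms) {
    ring_h <- hmap[ring[elements[ring] != "H"]]
    arom[ring_h] <- TRUE
    arings[[length(arings) + 1L]] <- ring_h
  }

  # implicit H from default valence - bond order sum - |charge adjustment|
  bosum <- numeric(length(heavy))
  if (nrow(hb) > 0) {
    ord <- hb[, 3]
    ord[ord == 4] <- 1.5  # aromatic bond order code
    for (k in seq_len(nrow(hb))) {
      bosum[hb[k, 1]] <- bosum[hb[k, 1]] + ord[k]
      bosum[hb[k, 2]] <- bosum[hb[k, 2]] + ord[k]
    }
  }
  val <- .default_valence[el]
  val[is.na(val)] <- 0
  # effective valence under formal charge (N+ 4, O- 1, O+ 3, C- 3, ...)
  val_eff <- val + ifelse(el %in% c("N", "P", "O", "S"), chg_h, -abs(chg_h))
  n_h_impl <- pmax(0, round(val_eff - bosum))
  n_h <- ifelse(n_h_explicit > 0 | bosum + n_h_explicit >= val_eff,
                n_h_explicit, as.integer(n_h_impl))

  structure(list(
    elements = el,
    xyz = xyzh,
    bonds = hb,
    n_h = as.integer(n_h),
    aromatic = arom,
    arom_rings = arings,
    charge = chg_h,
    n_heavy = length(heavy)
  ), class = "pg_mol")
}

#' @export
print.pg_mol <- function(x, ...) {
  cat(sprintf("<pg_mol> %d heavy atoms, %d bonds, %d aromatic ring(s)\n",
              x$n_heavy, nrow(x$bonds), length(x$arom_rings)))
  invisible(x)
}

# adjacency list over heavy atoms
mol_adjacency <- function(mol) {
  adj <- vector("list", mol$n_heavy)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' All-pairs topological distances on the heavy-atom bond graph
#'
#' Breadth-first shortest path length in bond counts between every pair of
#' heavy atoms; disconnected pairs get Inf.
#'
#' @param mol A `pg_mol`.
#' @return n x n numeric matrix of bond-count distances.
#' @export
bond_distances <- function(mol) {
  n <- mol$n_heavy
  if (n == 1L) return(matrix(0, 1, 1))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds) > 0)
    g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  d <- igraph::distances(g)
  unname(d)
}

# maximum allowed valence per element (hypervalent S/P allowed)
.max_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
                  F = 1, Cl = 1, Br = 1, I = 1)

# TRUE when every heavy atom's explicit bond-order sum respects its
# element's maximum valence (charge-adjusted)
check_valences <- function(mol) {
  el <- mol$elements
  bosum <- numeric(mol$n_heavy)
  if (nrow(mol$bonds) > 0) {
    ord <- mol$bonds[, 3]
    ord[ord == 4] <- 1.5
    for (k in seq_len(nrow(mol$bonds))) {
      bosum[mol$bonds[k, 1]] <- bosum[mol$bonds[k, 1]] + ord[k]
      bosum[mol$bonds[k, 2]] <- bosum[mol$bonds[k, 2]] + ord[k]
    }
  }
  vmax <- .max_valence[el]
  if (anyNA(vmax)) return(FALSE)  # exotic element: treat as invalid
  vmax <- vmax + ifelse(el %in% c("N", "P", "O", "S"), mol$charge,
                        -abs(mol$charge))
  # explicit hydrogens were folded into n_h at parse time only when present
  all(bosum <= vmax + 1e-9)
}

#' Canonicalize SMILES strings
#'
#' Parses each string, applies a valence sanity check (the underlying
#' OpenBabel parser accepts hypervalent atoms that a generative model may
#' emit), and returns the canonical SMILES.
#'
#' @param smiles Character vector of SMILES.
#' @param check_valence Reject chemically impossible valences (default TRUE).
#' @return Character vector of canonical SMILES; NA for invalid inputs.
#' @export
canonical_smiles <- function(smiles, check_valence = TRUE) {
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  for (i in which(ok)) {
    res <- tryCatch({
      single <- isTRUE(n_atom_tokens(smiles[i]) == 1L)
      if (!single) {
        sdf <- suppressWarnings(ChemmineR::smiles2sdf(
          stats::setNames(smiles[i], "m")))
        if (check_valence) {
          mol <- mol_from_sdf(sdf[[1]])
          if (mol$n_heavy < 1 || !check_valences(mol)) stop("bad valence")
        }
      }
      p <- suppressWarnings(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[i], "\n"))
      )
      s <- strsplit(trimws(p), "[ \t\n]")[[1]][1]
      if (is.na(s) || !nzchar(s)) NA_character_ else s
    }, error = function(e) NA_character_)
    out[i] <- res
  }
  out
}

#' Is each SMILES chemically valid?
#'
#' Valid means: parseable and passing the valence sanity check.
#' @param smiles Character vector.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) !is.na(canonical_smiles(smiles))

# quiet OpenBabel's C-level perception chatter for a code block
quiet_ob <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}
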