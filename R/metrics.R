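# Evaluation suite: generation metrics, pharmacophore match score, the
# physicochemical property panel (MW, LogP, QED, SAS, RotBonds, TPSA) and
# ligand efficiency.

# --- QED (Bickerton et al. 2012): asymmetric double sigmoid desirability ---

.qed_ads <- list(
  MW     = c(A = 2.817065973, B = 392.5754953, C = 290.7489764,
             D = 2.419764353, E = 49.22325677, F = 65.37051707,
             DMAX = 104.9805561),
  ALOGP  = c(A = 3.172690585, B = 137.8624751, C = 2.534937431,
             D = 4.581497897, E = 0.822739154, F = 0.576295591,
             DMAX = 131.3186604),
  HBA    = c(A = 2.948620388, B = 160.4605972, C = 3.615294657,
             D = 4.435986202, E = 0.290141953, F = 1.300669958,
             DMAX = 148.7763046),
  HBD    = c(A = 1.618662227, B = 1010.051101, C = 0.985094388,
             D = 1e-09, E = 0.713820843, F = 0.920922555,
             DMAX = 258.1632616),
  PSA    = c(A = 1.876861559, B = 125.2232657, C = 62.90773554,
             D = 87.83366614, E = 12.01999824, F = 28.51324732,
             DMAX = 104.5686167),
  ROTB   = c(A = 0.01, B = 272.4121427, C = 2.55837997,
             D = 1.565547684, E = 1.271567166, F = 2.758063707,
             DMAX = 105.4420403),
  AROM   = c(A = 3.21778897, B = 957.7374108, C = 2.274627939,
             D = 1e-09, E = 1.317690384, F = 0.375760881,
             DMAX = 312.337261),
  ALERTS = c(A = 0.01, B = 1199.094025, C = -0.09002883,
             D = 1e-09, E = 0.185904477, F = 0.875193782,
             DMAX = 417.725314)
)
.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  d <- p["A"] + p["B"] / (1 + exp(-(x - p["C"] + p["D"] / 2) / p["E"])) *
    (1 - 1 / (1 + exp(-(x - p["C"] - p["D"] / 2) / p["F"])))
  unname(pmax(d / p["DMAX"], 1e-6))
}

# count structural alerts per molecule of an SDFset (vectorized over mols)
count_alerts <- function(sdfset) {
  n <- length(sdfset)
  total <- numeric(n)
  for (p in .qed_alert_smarts) {
    if (grepl(".", p, fixed = TRUE)) {
      parts <- strsplit(p, ".", fixed = TRUE)[[1]]
      cnt <- tryCatch(
        suppressWarnings(ChemmineR::smartsSearchOB(sdfset, parts[1],
                                                    uniqueMatches = TRUE)),
        error = function(e) numeric(n))
      hit <- cnt >= length(parts)
    } else {
      cnt <- tryCatch(
        suppressWarnings(ChemmineR::smartsSearchOB(sdfset, p,
                                                    uniqueMatches = TRUE)),
        error = function(e) numeric(n))
      hit <- cnt >= 1
    }
    total <- total + as.numeric(hit)
  }
  total
}

# rotatable bonds: acyclic single bonds between two non-terminal heavy atoms,
# excluding bonds adjacent to a triple bond
count_rotatable <- function(mol) {
  if (nrow(mol$bonds) == 0) return(0L)
  deg <- integer(mol$n_heavy)
  for (k in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds[k, 1]] <- deg[mol$bonds[k, 1]] + 1L
    deg[mol$bonds[k, 2]] <- deg[mol$bonds[k, 2]] + 1L
  }
  in_triple <- logical(mol$n_heavy)
  tr <- mol$bonds[, 3] == 3
  in_triple[mol$bonds[tr, 1]] <- TRUE
  in_triple[mol$bonds[tr, 2]] <- TRUE
  g <- igraph::make_empty_graph(mol$n_heavy, directed = FALSE)
  g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  br <- igraph::bridges(g)  # acyclic bonds
  is_bridge <- logical(nrow(mol$bonds))
  is_bridge[as.integer(br)] <- TRUE
  rot <- mol$bonds[, 3] == 1 & is_bridge &
    deg[mol$bonds[, 1]] > 1 & deg[mol$bonds[, 2]] > 1 &
    !in_triple[mol$bonds[, 1]] & !in_triple[mol$bonds[, 2]]
  sum(rot)
}

# Ertl-style synthetic-accessibility heuristic, self-contained.
# Keeps the published complexity-penalty structure (size, ring, stereo,
# macrocycle penalties, 1-10 scaling); the database-derived fragment
# contribution of the original method is replaced by a compact atom
# environment familiarity term, so absolute values are comparable but not
# identical to the reference implementation.
sa_score <- function(mol, smiles = NULL) {
  el <- mol$elements
  n <- mol$n_heavy
  deg <- integer(n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      deg[mol$bonds[k, 1]] <- deg[mol$bonds[k, 1]] + 1L
      deg[mol$bonds[k, 2]] <- deg[mol$bonds[k, 2]] + 1L
    }
  }
  fam <- numeric(n)
  common <- el %in% c("C", "N", "O")
  fam[common] <- 0.3
  fam[el %in% c("F", "Cl", "Br", "S")] <- 0.1
  fam[!common & !el %in% c("F", "Cl", "Br", "S", "I", "P")] <- -2
  fam[el %in% c("I", "P")] <- -0.5
  fam[mol$charge != 0] <- fam[mol$charge != 0] - 1
  fam[deg >= 4] <- fam[deg >= 4] - 0.5
  frag_score <- mean(fam)

  size_pen <- n^1.005 - n
  n_chiral <- if (!is.null(smiles)) lengths(regmatches(
    smiles, gregexpr("@", smiles, fixed = TRUE))) else 0
  stereo_pen <- log10(n_chiral + 1)
  ring_sizes <- vapply(mol$arom_rings, length, 1L)
  macro_pen <- if (any(ring_sizes > 8)) log10(2) else 0
  # ring complexity from ring-bond density
  nring_bonds <- if (nrow(mol$bonds) > 0) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
    nrow(mol$bonds) - length(igraph::bridges(g))
  } else 0
  ring_pen <- log10(max(nring_bonds - n * 0.5, 0) + 1) * 0.5

  raw <- frag_score - size_pen * 0.05 - stereo_pen - macro_pen - ring_pen
  # map raw (~[-4, 1]) to the published 1..10 scale, high = hard to make
  sc <- 11 - (raw + 4) / 5 * 9
  if (sc > 8) sc <- 8 + log(sc + 1 - 8)
  min(max(sc, 1), 10)
}

#' Physicochemical property panel
#'
#' Computes the standard panel used to gate and evaluate generated
#' molecules: molecular weight, Wildman-Crippen LogP and Ertl TPSA (via the
#' OpenBabel descriptor engine), QED (Bickerton desirability product over
#' MW/ALOGP/HBA/HBD/PSA/ROTB/AROM/ALERTS), a self-contained Ertl-style
#' synthetic-accessibility score on the 1-10 scale, and the rotatable-bond
#' count (acyclic single bonds between non-terminal heavy atoms).
#'
#' @param smiles Character vector of valid SMILES.
#' @return data.frame with columns `smiles`, `MW`, `LogP`, `QED`, `SAS`,
#'   `RotBonds`, `TPSA` (one row per input).
#' @export
#' @examples
#' \donttest{property_panel(c("c1ccccc1", "CCO"))}
property_panel <- function(smiles) {
  if (length(smiles) == 0) stop("No molecules supplied")
  named <- stats::setNames(smiles, paste0("m", seq_along(smiles)))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(named)),
                  error = function(e)
                    stop("Invalid SMILES in input: ", conditionMessage(e),
                         call. = FALSE))
  if (length(sdf) != length(smiles))
    stop("Some SMILES failed to parse (",
         length(smiles) - length(sdf), " of ", length(smiles), ")")
  pr <- ChemmineR::propOB(sdf)
  mols <- lapply(seq_along(smiles), function(i) mol_from_sdf(sdf[[i]]))
  rotb <- vapply(mols, count_rotatable, 1)
  arom <- vapply(mols, function(m) length(m$arom_rings), 1L)
  alerts <- count_alerts(sdf)
  hba <- as.numeric(pr$HBA1)
  hbd <- as.numeric(pr$HBD)
  d <- cbind(
    MW     = .ads(as.numeric(pr$MW), .qed_ads$MW),
    ALOGP  = .ads(as.numeric(pr$logP), .qed_ads$ALOGP),
    HBA    = .ads(hba, .qed_ads$HBA),
    HBD    = .ads(hbd, .qed_ads$HBD),
    PSA    = .ads(as.numeric(pr$TPSA), .qed_ads$PSA),
    ROTB   = .ads(rotb, .qed_ads$ROTB),
    AROM   = .ads(arom, .qed_ads$AROM),
    ALERTS = .ads(alerts, .qed_ads$ALERTS)
  )
  qed <- exp(as.numeric(log(d) %*% .qed_weights) / sum(.qed_weights))
  sas <- vapply(seq_along(mols), function(i)
    sa_score(mols[[i]], smiles[i]), 1)
  data.frame(smiles = smiles,
             MW = as.numeric(pr$MW),
             LogP = as.numeric(pr$logP),
             QED = qed,
             SAS = sas,
             RotBonds = rotb,
             TPSA = as.numeric(pr$TPSA),
             stringsAsFactors = FALSE)
}

#' Generation quality metrics
#'
#' Validity is the fraction of parseable strings; uniqueness the fraction
#' of distinct canonical SMILES among the valid ones; novelty the fraction
#' of unique molecules absent from the reference corpus; and the available
#' ratio the fraction of all generated strings that are simultaneously
#' valid, unique and novel.
#'
#' @param generated Character vector of generated SMILES.
#' @param reference_corpus Character vector of reference SMILES (canonical
#'   or not; canonicalized internally).
#' @return Object of class `generation_report`: counts, the four ratios and
#'   a per-molecule table.
#' @export
generation_metrics <- function(generated, reference_corpus = character(0)) {
  if (length(generated) == 0) stop("No generated molecules to evaluate")
  can <- canonical_smiles(generated)
  valid <- !is.na(can)
  n_total <- length(generated)
  n_valid <- sum(valid)
  canv <- can[valid]
  first <- !duplicated(canv)
  uniq <- unique(canv)
  n_unique <- length(uniq)
  ref <- unique(canonical_smiles(reference_corpus))
  ref <- ref[!is.na(ref)]
  novel_flag <- !(uniq %in% ref)
  n_novel <- sum(novel_flag)
  tab <- data.frame(
    smiles = generated,
    canonical = can,
    valid = valid,
    first_occurrence = replace(logical(n_total), which(valid)[first], TRUE),
    novel = ifelse(valid, !(can %in% ref), NA),
    stringsAsFactors = FALSE)
  structure(list(
    n_total = n_total, n_valid = n_valid, n_unique = n_unique,
    n_novel = n_novel,
    validity = n_valid / n_total,
    uniqueness = if (n_valid > 0) n_unique / n_valid else NA_real_,
    novelty = if (n_unique > 0) n_novel / n_unique else NA_real_,
    available_ratio = n_novel / n_total,
    table = tab), class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf(
    "<generation_report> n=%d  validity %.3f  uniqueness %.3f  novelty %.3f  available %.3f\n",
    x$n_total, x$validity, x$uniqueness, x$novelty, x$available_ratio))
  invisible(x)
}

#' Attach per-molecule properties and match scores to a generation report
#'
#' Augments the report's table with the property panel (MW, LogP, QED,
#' SAS, RotBonds, TPSA) and, when a hypothesis is given, the pharmacophore
#' match score of every valid molecule.
#'
#' @param report A [generation_metrics()] result.
#' @param phar Optional [pharm_graph()] hypothesis for match scoring.
#' @param tau Match-score distance tolerance (default 1.5 Angstrom).
#' @return The report with an augmented `$table`.
#' @export
augment_report <- function(report, phar = NULL, tau = 1.5) {
  stopifnot(inherits(report, "generation_report"))
  tab <- report$table
  cols <- c("MW", "LogP", "QED", "SAS", "RotBonds", "TPSA")
  for (cl in cols) tab[[cl]] <- NA_real_
  if (!is.null(phar)) tab$match_score <- NA_real_
  vi <- which(tab$valid)
  if (length(vi) > 0) {
    pp <- property_panel(tab$canonical[vi])
    for (cl in cols) tab[[cl]][vi] <- pp[[cl]]
    if (!is.null(phar)) {
      tab$match_score[vi] <- vapply(tab$canonical[vi], function(s)
        tryCatch(match_score(s, phar, tau), error = function(e) NA_real_),
        1)
    }
  }
  report$table <- tab
  report
}

#' Pharmacophore match score of a molecule against a hypothesis
#'
#' Extracts the molecule's 2D pharmacophore features and their pairwise
#' topological distances (bond count x 1.5 Angstrom; feature-to-feature
#' distance is the minimum over member-atom pairs) and searches all
#' injective category-consistent assignments of hypothesis nodes to
#' molecule features. The score is the largest attainable fraction of
#' hypothesis nodes whose every incident assigned edge agrees with the
#' molecule distance within `tau`.
#'
#' @param smiles A single SMILES string.
#' @param phar A [pharm_graph()] hypothesis.
#' @param tau Distance tolerance in Angstrom (default 1.5, one bond unit).
#' @return Score in [0, 1].
#' @export
match_score <- function(smiles, phar, tau = 1.5) {
  stopifnot(inherits(phar, "pharm_graph"))
  np <- length(phar$nodes)
  if (np == 0) stop("Empty pharmacophore hypothesis")
  mol <- parse_smiles(smiles)
  feats <- detect_features(mol)
  if (length(feats) == 0) return(0)
  fcat <- vapply(feats, function(f) f$category, "")
  bd <- bond_distances(mol) * 1.5
  nf <- length(feats)
  fdist <- matrix(0, nf, nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (i != j)
      fdist[i, j] <- min(bd[feats[[i]]$atoms, feats[[j]]$atoms])
  }
  cand <- lapply(seq_len(np), function(i) which(fcat == phar$nodes[i]))

  best <- 0L
  assign <- integer(np)  # 0 = unassigned
  recurse <- function(i) {
    if (i > np) {
      sel <- which(assign > 0)
      ok <- 0L
      for (a in sel) {
        good <- TRUE
        for (b in sel) {
          if (a == b) next
          if (abs(phar$edge_dist[a, b] - fdist[assign[a], assign[b]]) > tau) {
            good <- FALSE
            break
          }
        }
        if (good) ok <- ok + 1L
      }
      if (ok > best) best <<- ok
      return(invisible())
    }
    for (c in cand[[i]]) {
      if (!(c %in% assign)) {
        assign[i] <<- c
        recurse(i + 1)
        assign[i] <<- 0L
      }
    }
    recurse(i + 1)  # leave node i unassigned
    invisible()
  }
  recurse(1L)
  best / np
}

#' Ligand efficiency
#'
#' Binding score normalized by heavy-atom count, oriented so that larger is
#' better: `-score / n_heavy` for a docking-style score in kcal/mol.
#'
#' @param score Numeric score (kcal/mol, negative = stronger binding).
#' @param smiles SMILES of the molecule.
#' @return kcal/mol per heavy atom.
#' @export
ligand_efficiency <- function(score, smiles) {
  mol <- parse_smiles(smiles)
  if (mol$n_heavy < 1) stop("Molecule has no heavy atoms")
  -score / mol$n_heavy
}
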