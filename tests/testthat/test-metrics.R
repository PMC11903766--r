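# Evaluation metrics: properties, generation report, match score, ligand
# efficiency

test_that("property panel reproduces formula-forced values", {
  p <- quiet(property_panel(c("c1ccccc1", "CCO")))
  expect_equal(p$MW[1], 78.11, tolerance = 0.01)
  expect_equal(p$RotBonds[1], 0)
  expect_equal(p$TPSA[1], 0)
  expect_equal(p$TPSA[2], 20.23, tolerance = 0.01)  # Ertl fragment sum
  expect_true(all(p$QED >= 0 & p$QED <= 1))
  expect_true(all(p$SAS >= 1 & p$SAS <= 10))
  expect_error(quiet(property_panel(character(0))), "No molecules")
})

test_that("rotatable bond counts follow the acyclic non-terminal definition", {
  p <- quiet(property_panel(c("CCCC", "CC(C)(C)C", "c1ccccc1CCc1ccccc1",
                              "CC#N")))
  expect_equal(p$RotBonds, c(1, 0, 3, 0))
})

test_that("generation metrics reproduce hand counts on the 10-string fixture", {
  generated <- c("c1ccccc1",      # valid, in reference
                 "CCO",           # valid, in reference
                 "CCO",           # duplicate
                 "xq!",           # invalid
                 "C1CC",          # invalid (open ring)
                 "CCN", "CCC(=O)O", "c1ccncc1", "CCOC", "CCCC")  # novel
  rep <- quiet(generation_metrics(generated, c("c1ccccc1", "OCC")))
  expect_equal(rep$n_total, 10L)
  expect_equal(rep$n_valid, 8L)
  expect_equal(rep$n_unique, 7L)
  expect_equal(rep$n_novel, 5L)
  expect_equal(rep$validity, 0.8)
  expect_equal(rep$uniqueness, 0.875)
  expect_equal(rep$novelty, 5 / 7)
  expect_equal(rep$available_ratio, 0.5)
  # invariant chain: n_novel <= n_unique <= n_valid <= n_total
  expect_true(rep$n_novel <= rep$n_unique &&
                rep$n_unique <= rep$n_valid &&
                rep$n_valid <= rep$n_total)
  # identity: available = validity * uniqueness * novelty
  expect_equal(rep$available_ratio,
               rep$validity * rep$uniqueness * rep$novelty)
})

test_that("generation metrics handle degenerate inputs", {
  # all-identical novel molecule
  r1 <- quiet(generation_metrics(rep("CCN", 4), c("c1ccccc1")))
  expect_equal(r1$uniqueness, 1 / 4)
  expect_equal(r1$available_ratio, 1 / 4)
  # generated entirely inside the reference
  r2 <- quiet(generation_metrics(c("CCO", "c1ccccc1"),
                                 c("CCO", "c1ccccc1")))
  expect_equal(r2$novelty, 0)
  expect_equal(r2$available_ratio, 0)
  expect_error(generation_metrics(character(0)), "No generated")
  # metrics invariant under pre-canonicalization of inputs
  g <- c("OCC", "c1ccccc1", "CCN")
  r3 <- quiet(generation_metrics(g, "CCO"))
  r4 <- quiet(generation_metrics(quiet(canonical_smiles(g)), "CCO"))
  expect_equal(r3$available_ratio, r4$available_ratio)
  expect_equal(r3$n_novel, r4$n_novel)
})

test_that("match score is 1 on self-hypotheses and single feasible nodes", {
  smi <- "CC(=O)Nc1ccc(O)cc1"
  tp <- quiet(with_seed(1, mol_to_training_pair(smi, infill_rate = 0)))
  expect_equal(quiet(match_score(smi, tp$phar)), 1.0)
  phar1 <- pharm_graph("Aromatic", matrix(0, 1, 1))
  expect_equal(quiet(match_score("c1ccccc1", phar1)), 1.0)
  expect_error(match_score("CCO", structure(list(nodes = character(0)),
                                            class = "pharm_graph")))
})

test_that("a hypothesis category absent from the molecule caps the score", {
  smi <- "CCO"
  tp <- quiet(with_seed(1, mol_to_training_pair(smi, infill_rate = 0)))
  k <- length(tp$phar$nodes)
  aug <- pharm_graph(c(tp$phar$nodes, "NegIonizable"),
                     rbind(cbind(tp$phar$edge_dist, 5),
                           c(rep(5, k), 0)))
  s <- quiet(match_score(smi, aug))
  expect_lt(s, 1)
  expect_equal(s, k / (k + 1))
})

test_that("match score equals an independent exhaustive assignment search", {
  set.seed(20)
  corpus <- make_smiles_corpus(30, seed = 7)
  oracle_match <- function(smiles, phar, tau = 1.5) {
    mol <- quiet(parse_smiles(smiles))
    feats <- phoregen:::detect_features(mol)
    if (length(feats) == 0) return(0)
    fcat <- vapply(feats, function(f) f$category, "")
    bd <- bond_distances(mol) * 1.5
    nf <- length(feats)
    fd <- matrix(0, nf, nf)
    for (i in seq_len(nf)) for (j in seq_len(nf))
      if (i != j) fd[i, j] <- min(bd[feats[[i]]$atoms, feats[[j]]$atoms])
    np <- length(phar$nodes)
    cand <- lapply(seq_len(np), function(i)
      c(which(fcat == phar$nodes[i]), 0L))
    grid <- do.call(expand.grid, cand)
    best <- 0
    for (r in seq_len(nrow(grid))) {
      a <- as.integer(grid[r, ])
      sel <- which(a > 0)
      if (anyDuplicated(a[sel])) next
      ok <- 0
      for (i in sel) {
        good <- TRUE
        for (j in sel) {
          if (i == j) next
          if (abs(phar$edge_dist[i, j] - fd[a[i], a[j]]) > tau) {
            good <- FALSE; break
          }
        }
        if (good) ok <- ok + 1
      }
      best <- max(best, ok)
    }
    best / np
  }
  n_checked <- 0
  for (smi in corpus) {
    tp <- quiet(with_seed(n_checked + 1, mol_to_training_pair(smi)))
    if (is.null(tp)) next
    # perturb distances so matches are nontrivial
    k <- length(tp$phar$nodes)
    pert <- tp$phar$edge_dist +
      with_seed(n_checked + 50, {
        m <- matrix(runif(k * k, -1.2, 1.2), k, k)
        m <- (m + t(m)) / 2; diag(m) <- 0; m
      })
    pert[pert < 0] <- 0
    phar <- pharm_graph(tp$phar$nodes, pert, "graph-topological")
    expect_equal(quiet(match_score(smi, phar)), oracle_match(smi, phar))
    n_checked <- n_checked + 1
    if (n_checked >= 12) break
  }
  expect_gte(n_checked, 10)
})

test_that("match score never rises when adding unmatched categories", {
  smi <- "CC(=O)Nc1ccc(O)cc1"
  tp <- quiet(with_seed(3, mol_to_training_pair(smi, infill_rate = 0)))
  s0 <- quiet(match_score(smi, tp$phar))
  k <- length(tp$phar$nodes)
  prev <- s0
  for (add in 1:2) {
    kk <- k + add
    d <- matrix(4, kk, kk); diag(d) <- 0
    d[seq_len(k), seq_len(k)] <- tp$phar$edge_dist
    phar <- pharm_graph(c(tp$phar$nodes, rep("NegIonizable", add)), d)
    s <- quiet(match_score(smi, phar))
    expect_lte(s, prev)
    prev <- s
  }
})

test_that("augmented reports carry per-molecule properties and match scores", {
  gen <- c("CCO", "c1ccccc1", "xq!", "CCN")
  rep <- quiet(generation_metrics(gen, "CCO"))
  phar <- pharm_graph("Aromatic", matrix(0, 1, 1))
  aug <- quiet(augment_report(rep, phar))
  tab <- aug$table
  expect_true(all(c("MW", "QED", "TPSA", "match_score") %in% names(tab)))
  expect_true(is.na(tab$MW[3]))                       # invalid row
  expect_equal(tab$MW[1], 46.07, tolerance = 0.01)
  expect_equal(tab$match_score[2], 1)                 # benzene vs Aromatic
  expect_equal(tab$match_score[1], 0)                 # ethanol has no ring
})

test_that("ligand efficiency is -score per heavy atom and monotone in size", {
  expect_equal(quiet(ligand_efficiency(-10, "CCCCCCCCCCCCCCCCCCCC")), 0.5)
  expect_equal(quiet(ligand_efficiency(0, "CCO")), 0)
  le_small <- quiet(ligand_efficiency(-8, "CCO"))
  le_big <- quiet(ligand_efficiency(-8, "CCCCCCO"))
  expect_gt(le_small, le_big)
})
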