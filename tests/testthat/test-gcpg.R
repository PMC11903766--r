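# Gated conditional SMILES generator: training pairs, losses, gradients,
# determinism

test_that("training pairs use bond-path distances scaled to Angstrom", {
  # ethanol: donor/acceptor O two bonds from the terminal hydrophobic C
  tp <- quiet(with_seed(1, mol_to_training_pair("OCC", infill_rate = 0)))
  expect_s3_class(tp$phar, "pharm_graph")
  cats <- tp$phar$nodes
  io <- which(cats == "Donor")[1]
  ic <- which(cats == "Hydrophobic")[1]
  expect_equal(tp$phar$edge_dist[io, ic], 3.0)  # 2 bonds x 1.5 A
  # benzene has a single feature -> skipped
  expect_message(
    out <- with_seed(1, mol_to_training_pair("c1ccccc1")), "Skipping")
  expect_null(out)
})

test_that("aspirin pairwise distances equal an independent BFS x 1.5", {
  smi <- "CC(=O)Oc1ccccc1C(=O)O"
  tp <- quiet(with_seed(2, mol_to_training_pair(smi, infill_rate = 0)))
  mol <- quiet(parse_smiles(smi))
  feats <- phoregen:::detect_features(mol)
  bd <- bond_distances(mol)
  k <- length(tp$phar$nodes)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    expect_equal(tp$phar$edge_dist[i, j],
                 min(bd[feats[[i]]$atoms, feats[[j]]$atoms]) * 1.5)
  }
  # mapping rows are one-hot over atoms + unmapped slot
  expect_true(all(rowSums(tp$mapping) == 1))
})

test_that("loss terms take their closed-form values in degenerate settings", {
  corpus <- c("CCO", "CCN", "CCOC", "CCC(=O)O")
  cfg <- gcpg_config(hidden_dim = 12, n_blocks = 2, latent_dim = 4,
                     emb_dim = 8, seed = 1, infill_rate = 0)
  vocab <- phoregen:::build_vocab(corpus)
  props <- quiet(property_panel(corpus))
  stats_tab <- c(lapply(c(MW = "MW", LogP = "LogP", QED = "QED",
                          SAS = "SAS", RotBonds = "RotBonds",
                          TPSA = "TPSA"),
                        function(cl) c(mean = 100, sd = 20)),
                 list(DockScore = c(mean = 0, sd = 1)))
  params <- with_seed(1, phoregen:::gcpg_init(vocab$size, cfg))
  ex <- quiet(with_seed(2, phoregen:::gcpg_prepare("CCC(=O)O", vocab, cfg,
                                                   props[4, ])))
  # posterior forced to N(0, I) -> KL = 0
  p0 <- params
  p0$Wmu[] <- 0; p0$bmu[] <- 0; p0$Wlv[] <- 0; p0$blv[] <- 0
  fw <- phoregen:::gcpg_forward(p0, ex, rnorm(cfg$latent_dim), cfg, vocab,
                                stats_tab)
  expect_lt(abs(fw$kl), 1e-9)
  # uniform decoder -> LM loss = ln V per token
  pu <- params; pu$Wout[] <- 0; pu$bout[] <- 0
  fwu <- phoregen:::gcpg_forward(pu, ex, rnorm(cfg$latent_dim), cfg, vocab,
                                 stats_tab)
  expect_lt(abs(fwu$lm - log(vocab$size)), 1e-6)
  # KL matches the closed form evaluated independently
  fw2 <- phoregen:::gcpg_forward(params, ex, rnorm(cfg$latent_dim), cfg,
                                 vocab, stats_tab)
  mu <- fw2$cache$mu; lv <- fw2$cache$lv
  expect_equal(fw2$kl, 0.5 * sum(mu^2 + exp(lv) - 1 - lv),
               tolerance = 1e-9)
  expect_gte(fw2$kl, 0)
})

test_that("generator gradients match numerical differentiation", {
  corpus <- c("CCO", "CCOC")
  cfg <- gcpg_config(hidden_dim = 10, n_blocks = 2, latent_dim = 3,
                     emb_dim = 6, seed = 1, infill_rate = 0)
  vocab <- phoregen:::build_vocab(corpus)
  props <- quiet(property_panel(corpus))
  stats_tab <- c(lapply(c(MW = "MW", LogP = "LogP", QED = "QED",
                          SAS = "SAS", RotBonds = "RotBonds",
                          TPSA = "TPSA"),
                        function(cl) c(mean = 50, sd = 10)),
                 list(DockScore = c(mean = 0, sd = 1)))
  params <- with_seed(3, phoregen:::gcpg_init(vocab$size, cfg))
  ex <- quiet(with_seed(4, phoregen:::gcpg_prepare(
    "CCOC", vocab, cfg, props[2, ],
    open_mask = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))))
  zeps <- with_seed(5, rnorm(cfg$latent_dim))
  fw <- phoregen:::gcpg_forward(params, ex, zeps, cfg, vocab, stats_tab, 0.8)
  g <- phoregen:::gcpg_backward(params, ex, fw, cfg, vocab, 0.8)
  lossf <- function(p)
    phoregen:::gcpg_forward(p, ex, zeps, cfg, vocab, stats_tab, 0.8)$total
  set_in <- function(p, path, v) {
    if (length(path) == 1) p[[path[[1]]]] <- v
    else p[[path[[1]]]] <- set_in(p[[path[[1]]]], path[-1], v)
    p
  }
  get_in <- function(p, path) Reduce(function(x, k) x[[k]], path, p)
  set.seed(6)
  for (path in list(list("Temb"), list("Wp1"), list("Wv"), list("Nv"),
                    list("Wr1"), list("Wlv"), list("dec", 1L, "W"),
                    list("dec", 2L, "W"), list("Wout"), list("Wmap"),
                    list("none_vec"), list("empty_node"))) {
    v <- get_in(params, path); gv <- get_in(g, path)
    for (k in sample(length(v), min(3, length(v)))) {
      vp <- v; vp[k] <- v[k] + 1e-6
      vm <- v; vm[k] <- v[k] - 1e-6
      num <- (lossf(set_in(params, path, vp)) -
                lossf(set_in(params, path, vm))) / 2e-6
      expect_lt(abs(num - gv[k]) / max(1e-7, abs(num) + abs(gv[k])), 1e-4)
    }
  }
})

test_that("gating condition API validates channels and closed gates carry no value", {
  gc1 <- gating_condition(MW = 400, QED = 0.6)
  expect_equal(unname(gc1$gate["MW"]), "open")
  expect_equal(unname(gc1$value[["MW"]]), 400)
  expect_true(is.na(gc1$value[["TPSA"]]))
  expect_equal(unname(gc1$gate["DockScore"]), "closed")
  expect_error(gating_condition(Foo = 1), "Unknown gating channel")
})

test_that("short training runs are seed-deterministic", {
  corpus <- toy_corpus()[1:60]
  props <- toy_corpus_props()[1:60, ]
  cfg <- gcpg_config(hidden_dim = 16, n_blocks = 2, latent_dim = 4,
                     emb_dim = 8, lr = 2e-3, batch_size = 16, seed = 99,
                     context = 4)
  m1 <- quiet(train_gcpg(corpus, cfg, epochs = 2, properties = props))
  m2 <- quiet(train_gcpg(corpus, cfg, epochs = 2, properties = props))
  expect_lt(max(abs(m1$loss_trace - m2$loss_trace)), 1e-6)
  expect_identical(phoregen:::gcpg_flat(m1$params),
                   phoregen:::gcpg_flat(m2$params))
  # epochs = 0 returns the seeded initialization
  m0 <- quiet(train_gcpg(corpus, cfg, epochs = 0, properties = props))
  expect_equal(m0$epochs_trained, 0L)
  expect_error(gcpg_generate(m0, pharm_graph("Donor", matrix(0, 1, 1))),
               "untrained")
  expect_error(quiet(train_gcpg(character(0), cfg)), "Empty corpus")
})

test_that("generation respects n, seeds and empty requests", {
  m <- toy_gcpg()
  phar <- pharm_graph(c("Aromatic", "Donor"),
                      matrix(c(0, 4.5, 4.5, 0), 2, 2))
  expect_identical(gcpg_generate(m, phar, n = 0), character(0))
  g1 <- gcpg_generate(m, phar, n = 8, seed = 5)
  g2 <- gcpg_generate(m, phar, n = 8, seed = 5)
  expect_identical(g1, g2)
  expect_length(g1, 8)
})

test_that("fine-tuning on scores preserves the vocabulary and 0 epochs is a no-op", {
  m <- toy_gcpg()
  scored <- data.frame(smiles = toy_corpus()[1:40],
                       score_kcal_mol = -seq(5, 13, length.out = 40))
  m0 <- finetune_with_scores(m, scored, epochs = 0)
  expect_identical(phoregen:::gcpg_flat(m0$params),
                   phoregen:::gcpg_flat(m$params))
  mf <- quiet(finetune_with_scores(m, scored, epochs = 1))
  expect_identical(mf$vocab$tokens, m$vocab$tokens)
  expect_error(finetune_with_scores(m, scored[0, ], 1), "Empty score table")
})
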