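# Synthetic fixture generators

test_that("fixture specs validate their invariants", {
  expect_error(fixture_spec(category_marginals = rep(1, 8)), "summing to 1")
  expect_error(fixture_spec(n_pairs = 0), "out of range")
  sp <- fixture_spec(n_pairs = 5, cloud_points = 4, seed = 2)
  expect_s3_class(sp, "fixture_spec")
})

test_that("complex fixtures have the requested shapes and metadata", {
  sp <- fixture_spec(n_pairs = 10, pocket_points = 20, cloud_points = 5,
                     seed = 3)
  pairs <- make_complex_fixtures(sp)
  expect_length(pairs, 10)
  for (p in pairs) {
    expect_equal(length(p$cloud), 5L)
    expect_equal(length(p$pocket), 20L)
    expect_equal(sum(p$pocket$feature == "TRP"), 5L)  # anchor cap
    off <- attr(p, "offset")
    expect_equal(sqrt(sum(off^2)), 3, tolerance = 1e-9)
    # anchor direction aligns with the realized offset
    u <- pocket_anchor_direction(p$pocket)
    expect_gt(sum(u * off) / sqrt(sum(off^2)), 0.95)
  }
})

test_that("degenerate marginals give a single category; empirical marginals match", {
  sp1 <- fixture_spec(n_pairs = 4, category_marginals = c(1, rep(0, 7)),
                      seed = 4)
  for (p in make_complex_fixtures(sp1))
    expect_true(all(p$cloud$category == "Aromatic"))
  marg <- c(0.3, 0.1, 0.05, 0.05, 0.2, 0.2, 0.05, 0.05)
  sp2 <- fixture_spec(n_pairs = 100, cloud_points = 20,
                      category_marginals = marg, seed = 5)
  pairs <- make_complex_fixtures(sp2)
  cats <- unlist(lapply(pairs, function(p) as.character(p$cloud$category)))
  emp <- table(factor(cats, levels = pharm_categories())) / length(cats)
  se <- sqrt(marg * (1 - marg) / length(cats))
  expect_true(all(abs(as.numeric(emp) - marg) <= pmax(3 * se, 1e-12)))
})

test_that("fixture generation is a pure function of its fixture_spec", {
  a <- make_complex_fixtures(fixture_spec(n_pairs = 6, seed = 11))
  b <- make_complex_fixtures(fixture_spec(n_pairs = 6, seed = 11))
  expect_identical(a, b)
  set.seed(123); runif(5)  # generator must not disturb or read global RNG
  c2 <- make_complex_fixtures(fixture_spec(n_pairs = 6, seed = 11))
  expect_identical(a, c2)
})

test_that("the corruption filter removes displaced pairs", {
  sp <- fixture_spec(n_pairs = 60, corrupt_frac = 0.3, seed = 6)
  pairs <- make_complex_fixtures(sp)
  corrupted <- vapply(pairs, function(p) attr(p, "corrupted"), logical(1))
  expect_gt(sum(corrupted), 5)
  kept <- filter_fixture_pairs(pairs)
  kept_flags <- vapply(kept, function(p) attr(p, "corrupted"), logical(1))
  # screening keeps the clean pairs and drops the displaced ones
  expect_lt(mean(kept_flags), 0.05)
  expect_gt(length(kept), sum(!corrupted) * 0.8)
})

test_that("the SMILES corpus is valid, unique and feature-rich", {
  corpus <- make_smiles_corpus(1000, seed = 8)
  expect_length(corpus, 1000)
  expect_equal(anyDuplicated(corpus), 0L)
  set.seed(1)
  sub <- sample(corpus, 60)
  can <- quiet(canonical_smiles(sub))
  expect_true(all(!is.na(can)))
  expect_equal(anyDuplicated(can), 0L)
  n_ok <- sum(vapply(sub, function(s) {
    tp <- quiet(with_seed(1, mol_to_training_pair(s)))
    !is.null(tp) && length(tp$phar$nodes) >= 2
  }, logical(1)))
  expect_gte(n_ok / length(sub), 0.95)
  expect_error(make_smiles_corpus(1e6), "template space")
  # property spread wide enough for gate-shift effect sizes
  props <- quiet(property_panel(sub))
  expect_gt(diff(range(props$MW)), 100)
  expect_gt(stats::sd(props$LogP), 0.5)
})

test_that("fixture PDB files are column-conformant and round-trip", {
  sp <- fixture_spec(n_pairs = 1, pocket_points = 15, seed = 9)
  pk <- make_complex_fixtures(sp)[[1]]$pocket
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(pk, path)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  expect_length(lines, 15)
  for (ln in lines[1:5]) {
    expect_equal(substr(ln, 1, 4), "ATOM")
    expect_true(grepl("^[A-Z]{3}$", substr(ln, 18, 20)))  # resName cols
    x <- as.numeric(substr(ln, 31, 38))                   # x cols
    expect_false(is.na(x))
  }
  pk2 <- extract_pocket_cloud(path, c(0, 0, 0), radius = 50, mode = "calpha")
  expect_equal(length(pk2), length(pk))
  expect_lt(max(abs(pk2$xyz - pk$xyz)), 1e-3)
  expect_equal(pk2$feature, pk$feature)
})

test_that("fixture SDF files round-trip atom counts and bonds", {
  mc <- quiet(embed_conformers("CC(=O)Nc1ccc(O)cc1", 1, 1))
  sdf <- quiet(ChemmineR::smiles2sdf(
    stats::setNames("CC(=O)Nc1ccc(O)cc1", "m")))
  sdf3 <- quiet(ChemmineR::generate3DCoords(sdf))
  path <- tempfile(fileext = ".sdf")
  write_fixture_sdf(sdf3, path)
  back <- ChemmineR::read.SDFset(path)
  m1 <- mol_from_sdf(sdf3[[1]]); m2 <- mol_from_sdf(back[[1]])
  expect_equal(m2$n_heavy, m1$n_heavy)
  expect_equal(nrow(m2$bonds), nrow(m1$bonds))
  expect_lt(max(abs(m2$xyz - m1$xyz)), 1e-3)
})
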