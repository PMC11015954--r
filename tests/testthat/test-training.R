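# Labels, losses, splits, metrics, and the training loop.

test_that("kd_to_pkd converts nM-scale constants", {
  expect_equal(kd_to_pkd(1e9), 0)
  expect_equal(kd_to_pkd(1), 9)
  expect_equal(kd_to_pkd(1000), 6)
  expect_error(kd_to_pkd(0), "positive")
  expect_error(kd_to_pkd(-5), "positive")
})

test_that("encode_region_labels places the affinity inside the interval", {
  rec <- pair_record("CC", strrep("A", 20), 7.2, region = c(3, 7))
  v <- encode_region_labels(rec, 10)
  expect_equal(v, c(0, 0, 0, 7.2, 7.2, 7.2, 7.2, 0, 0, 0))
  expect_equal(max(v), rec$affinity)
  # truncation beyond capacity
  rec2 <- pair_record("CC", strrep("A", 20), 5, region = c(8, 12))
  v2 <- encode_region_labels(rec2, 10)
  expect_equal(which(v2 != 0), c(9L, 10L))
  # empty-width region rejected at construction
  expect_error(pair_record("CC", strrep("A", 20), 5, region = c(4, 4)),
               "half-open")
  expect_error(encode_region_labels(pair_record("CC", strrep("A", 20), 5), 10),
               "no region")
})

test_that("rwing_loss has a dead zone, continuity, and the log branch value", {
  r <- 0.1; w <- 2; eps <- 0.5
  expect_equal(rwing_loss(c(0, 0.05, -0.09), r, w, eps), 0)
  # x = r + eps*(e - 1) makes the log branch equal exactly w
  x_star <- r + eps * (exp(1) - 1)
  expect_equal(rwing_loss(x_star, r, w, eps), w, tolerance = 1e-12)
  # continuity at both branch points
  for (bp in c(r, w)) {
    lo <- rwing_loss(bp - 1e-9, r, w, eps)
    hi <- rwing_loss(bp + 1e-9, r, w, eps)
    expect_lt(abs(hi - lo), 1e-6)
  }
  # symmetric in the sign of the residual
  expect_equal(rwing_loss(-1.3, r, w, eps), rwing_loss(1.3, r, w, eps))
  expect_error(rwing_loss(1, r_thresh = 2, w = 1), "w > r_thresh")
  expect_error(rwing_loss(1, eps = 0), "eps")
})

test_that("combined_loss is the stated convex combination", {
  expect_equal(combined_loss(3, 100, psi = 1), 3)
  expect_equal(combined_loss(100, 7, psi = 0), 7)
  expect_equal(combined_loss(1, 2, psi = 0.4), 1.6)
  withr::with_seed(2, {
    for (trial in 1:10) {
      a <- rnorm(1); b <- rnorm(1); p <- runif(1)
      expect_equal(combined_loss(a, b, p), p * a + (1 - p) * b)
    }
  })
  expect_error(combined_loss(1, 2, psi = 1.2), "psi")
})

make_records <- function(n_lig, n_prot, n_pairs, seed = 1) {
  withr::with_seed(seed, {
    ligs <- vapply(seq_len(n_lig), function(i)
      paste(sample(c("C", "N", "O"), sample(4:8, 1), replace = TRUE),
            collapse = ""), "")
    prots <- vapply(seq_len(n_prot), function(i)
      paste(sample(c("A", "H", "W", "K", "R"), 12, replace = TRUE),
            collapse = ""), "")
    lapply(seq_len(n_pairs), function(i)
      pair_record(sample(ligs, 1), sample(prots, 1), rnorm(1, 6)))
  })
}

test_that("random split gives the 4:1:1 partition", {
  recs <- make_records(40, 20, 600)
  sp <- split_dataset(recs, split_spec("random", seed = 3))
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 400L, val = 100L, test = 100L))
  expect_setequal(unlist(sp$idx), seq_len(600))
})

test_that("cold splits have provably zero entity overlap", {
  recs <- make_records(100, 10, 400)
  for (mode in c("cold_ligand", "cold_target")) {
    key <- if (mode == "cold_ligand") "ligand_smiles" else "protein_seq"
    for (seed in 1:5) {
      sp <- split_dataset(recs, split_spec(mode, seed = seed))
      train_e <- unique(vapply(sp$train, `[[`, "", key))
      val_e <- unique(vapply(sp$val, `[[`, "", key))
      test_e <- unique(vapply(sp$test, `[[`, "", key))
      expect_length(intersect(train_e, val_e), 0)
      expect_length(intersect(train_e, test_e), 0)
      expect_length(intersect(val_e, test_e), 0)
    }
  }
  # exactly 100 distinct ligands: 5 validation and 10 test entities
  ligs <- vapply(1:100, function(i)
    paste(rep(c("C", "N", "O"), length.out = 4 + i %% 5), collapse = ""), "")
  ligs <- make.unique(ligs)
  recs100 <- unlist(lapply(ligs, function(l) list(
    pair_record(l, strrep("AHWKR", 4), 5),
    pair_record(l, strrep("RHWKA", 4), 6))), recursive = FALSE)
  sp <- split_dataset(recs100, split_spec("cold_ligand", seed = 9))
  expect_equal(length(unique(vapply(sp$val, `[[`, "", "ligand_smiles"))), 5L)
  expect_equal(length(unique(vapply(sp$test, `[[`, "", "ligand_smiles"))), 10L)
  two <- list(pair_record("CC", strrep("A", 10), 5),
              pair_record("CO", strrep("A", 10), 6))
  expect_error(split_dataset(two, split_spec("cold_ligand", seed = 1)),
               "too few")
})

test_that("clean_pairs drops contradictory labels and deduplicates", {
  r <- function(l, p, a) pair_record(l, strrep(p, 5), a)
  recs <- list(r("CC", "AHWKR", 5), r("CC", "AHWKR", 5),   # exact duplicate
               r("CO", "AHWKR", 5), r("CO", "AHWKR", 6),   # contradictory
               r("CN", "AHWKR", 7))
  out <- clean_pairs(recs)
  keys <- vapply(out, `[[`, "", "ligand_smiles")
  expect_setequal(keys, c("CC", "CN"))
})

test_that("concordance_index counts ordered pairs", {
  expect_equal(concordance_index(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(concordance_index(rep(2, 5), c(1, 2, 3, 4, 5)), 0.5)
  expect_equal(concordance_index(c(1, 3, 2), c(1, 2, 3)), 2 / 3)
  expect_error(concordance_index(1:3, c(2, 2, 2)), "undefined")
  withr::with_seed(21, {
    pred <- rnorm(30); truth <- rnorm(30)
    ci <- concordance_index(pred, truth)
    # invariant under strictly increasing transforms
    expect_equal(concordance_index(exp(pred), truth), ci)
    expect_equal(concordance_index(rank(pred), truth), ci)
    # anti-symmetry for tie-free predictions
    expect_equal(ci + concordance_index(-pred, truth), 1)
  })
})

test_that("rm2_score follows the through-origin penalty", {
  x <- c(1, 2, 3, 4, 5)
  # sqrt amplifies float error in |r2 - r0^2|, hence the 1e-4 tolerance
  expect_equal(rm2_score(x, x), 1, tolerance = 1e-4)
  expect_equal(rm2_score(x, 2 * x), 1, tolerance = 1e-4)  # r2 = r0^2 = 1
  withr::with_seed(22, {
    pred <- rnorm(12, 5); truth <- 0.8 * pred + rnorm(12, 0, 0.5)
    got <- rm2_score(pred, truth)
    expect_equal(got, oracle_rm2(pred, truth), tolerance = 1e-10)
    r2 <- stats::cor(pred, truth)^2
    expect_lte(got, r2)
  })
  expect_error(rm2_score(rep(1, 5), 1:5), "variance")
})

test_that("aupr_score integrates precision stepwise over recall", {
  # perfect separation
  expect_equal(aupr_score(c(0.9, 0.8, 0.2, 0.1), c(9, 8, 3, 2), 7), 1)
  # constant predictions recover the positive prevalence
  expect_equal(aupr_score(rep(1, 10), c(rep(9, 3), rep(2, 7)), 7), 0.3)
  withr::with_seed(23, {
    for (trial in 1:10) {
      pred <- rnorm(15); truth <- rnorm(15, 7, 1)
      if (all(truth >= 7) || all(truth < 7)) next
      expect_equal(aupr_score(pred, truth, 7), oracle_aupr(pred, truth, 7),
                   tolerance = 1e-10)
    }
  })
  expect_error(aupr_score(1:3, c(8, 9, 10), 7), "both classes")
})

test_that("region_accuracy counts interval intersections", {
  # midpoint exactly on the true site
  regs <- list(c(10, 15), c(0, 5))
  expect_equal(region_accuracy(regs, list(12, 2)), 1)
  # site exactly R away from the midpoint misses the half-open window
  expect_equal(region_accuracy(list(c(10, 20)), list(25)), 0)
  # offsets {0, 2, 7, 20} with R = 10 windows centered at 50
  regs4 <- replicate(4, c(45, 55), simplify = FALSE)
  sites <- list(50, 52, 57, 70)
  expect_equal(region_accuracy(regs4, sites), 0.5)
  # interval-valued truth
  expect_equal(region_accuracy(list(c(10, 20)), list(c(19, 25))), 1)
  expect_equal(region_accuracy(list(c(10, 20)), list(c(20, 25))), 0)
  expect_error(region_accuracy(list(c(1, 2)), list(1, 2)), "aligned")
})

test_that("training runs, descends on one batch, and freezes at lr = 0", {
  cfg <- mg_config_small(dim = 8, max_protein = 16)
  recs <- withr::with_seed(31, {
    scfg <- sim_config(n_pairs = 8, n_ligands = 6, n_proteins = 4,
                       protein_len_range = c(10L, 14L),
                       ligand_len_range = c(5L, 8L), seed = 31)
    generate_dataset(scfg)$records
  })
  # lr = 0: weights unchanged after an epoch
  tc0 <- train_config(lr = 0, epochs = 1, batch_size = 4, patience = Inf)
  init <- mg_init(cfg, seed = 5)
  fit0 <- train_model(recs, cfg, "affinity_only", tc0, seed = 5)
  expect_equal(fit0$weights$gat$W_go, init$gat$W_go, tolerance = 1e-12)
  expect_equal(fit0$weights$inter$W_a, init$inter$W_a, tolerance = 1e-12)
  # overfit-one-batch sanity descent
  tc <- train_config(lr = 5e-3, epochs = 4, batch_size = 8, patience = Inf)
  fit <- train_model(recs, cfg, "affinity_only", tc, seed = 5)
  expect_lt(fit$history$train_loss[4], fit$history$train_loss[1])
  # joint regime requires at least one region label
  norgn <- lapply(recs, function(r) { r$region <- NULL; r })
  expect_error(train_model(norgn, cfg, "joint", tc, seed = 1), "region label")
})

test_that("cross_validate produces one metric row per repeat and fold", {
  cfg <- mg_config_small(dim = 8, max_protein = 16)
  recs <- withr::with_seed(35, {
    generate_dataset(sim_config(n_pairs = 10, n_ligands = 8, n_proteins = 5,
                                protein_len_range = c(10L, 14L),
                                ligand_len_range = c(5L, 8L), seed = 35))$records
  })
  tc <- train_config(lr = 1e-3, epochs = 1, batch_size = 5, patience = Inf)
  cv <- cross_validate(recs, cfg, "affinity_only", tc, seed = 2,
                       n_repeats = 1, n_folds = 2)
  expect_equal(nrow(cv), 2L)
  expect_true(all(c("mse", "ci", "rm2") %in% names(cv)))
  expect_true(all(is.finite(cv$mse)))
  expect_error(cross_validate(recs[1:3], cfg, n_folds = 5), "fewer records")
})

test_that("training is reproducible for a fixed seed", {
  cfg <- mg_config_small(dim = 8, max_protein = 16)
  recs <- withr::with_seed(33, {
    generate_dataset(sim_config(n_pairs = 6, n_ligands = 5, n_proteins = 3,
                                protein_len_range = c(10L, 14L),
                                ligand_len_range = c(5L, 8L), seed = 33))$records
  })
  tc <- train_config(lr = 1e-3, epochs = 2, batch_size = 4, patience = Inf)
  f1 <- train_model(recs, cfg, "joint", tc, seed = 7)
  f2 <- train_model(recs, cfg, "joint", tc, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})
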