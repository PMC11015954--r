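# Featurization: molecular graphs, character codes, sub-structure
# tokenization, protein 3-mers.

test_that("smiles_to_graph builds padded symmetric graphs", {
  g <- smiles_to_graph("CC", max_atoms = 4)
  expect_equal(g$n_real_atoms, 2L)
  expect_setequal(apply(g$edges, 1, paste, collapse = ","), c("0,1", "1,0"))
  expect_true(all(g$node_features[3:4, ] == 0))

  g1 <- smiles_to_graph("C", max_atoms = 4)
  expect_equal(g1$n_real_atoms, 1L)
  expect_equal(nrow(g1$edges), 0L)

  # adjacency implied by edges equals its transpose for assorted molecules
  for (smi in c("CCO", "CC(C)C", "C1CCCCC1", "CC(=O)O", "c1ccccc1", "N#C")) {
    g <- smiles_to_graph(smi, max_atoms = 20)
    adj <- matrix(0, g$n_real_atoms, g$n_real_atoms)
    adj[g$edges + 1L] <- 1
    expect_identical(adj, t(adj), label = smi)
  }
})

test_that("smiles_to_graph CCO descriptors match hand enumeration", {
  g <- smiles_to_graph("CCO", max_atoms = 8)
  expect_equal(g$n_real_atoms, 3L)
  f <- g$node_features
  elements <- ad(".ELEMENTS")
  # element one-hot: atoms 1,2 carbon (slot 1), atom 3 oxygen (slot 3)
  expect_equal(which(f[1, 1:44] == 1), match("C", elements))
  expect_equal(which(f[3, 1:44] == 1), match("O", elements))
  expect_false(isTRUE(all.equal(f[1, 1:44], f[3, 1:44])))
  # degree one-hot (offset 44, slots 0..10): C(1), C(2), O(1)
  expect_equal(which(f[1, 45:55] == 1) - 1L, 1L)
  expect_equal(which(f[2, 45:55] == 1) - 1L, 2L)
  expect_equal(which(f[3, 45:55] == 1) - 1L, 1L)
  # total-H one-hot (offset 55): CH3 = 3, CH2 = 2, OH = 1
  expect_equal(which(f[1, 56:66] == 1) - 1L, 3L)
  expect_equal(which(f[2, 56:66] == 1) - 1L, 2L)
  expect_equal(which(f[3, 56:66] == 1) - 1L, 1L)
  # aromatic flag off
  expect_equal(unname(f[1:3, 78]), c(0, 0, 0))
})

test_that("smiles_to_graph truncates, validates, and reports parse errors", {
  g <- smiles_to_graph("CCCCCC", max_atoms = 3)
  expect_equal(g$n_real_atoms, 3L)
  expect_true(all(g$edges < 3))
  expect_error(smiles_to_graph("CC", max_atoms = 0), "max_atoms")
  expect_error(smiles_to_graph("C(C", 10), "unmatched")
  expect_error(smiles_to_graph("CC)C", 10), "position 3")
  expect_error(smiles_to_graph("C1CC", 10), "ring")
  expect_error(smiles_to_graph("CQ", 10), "position 2")
})

test_that("smiles_to_codes reproduces the documented code pattern", {
  cc <- smiles_to_codes("COC1", max_len = 8)
  expect_equal(cc$codes[1:4], c(42L, 48L, 42L, 35L))
  expect_equal(cc$codes[5:8], rep(0L, 4))
  expect_equal(cc$n_real, 4L)
  # ')' and 'l' anchors
  v <- default_smiles_vocab()
  expect_equal(unname(v[c("C", "O", "1", ")", "l")]), c(42L, 48L, 35L, 31L, 25L))
  expect_equal(length(v), 64L)
  # map determinism: repeated characters encode identically
  cc2 <- smiles_to_codes("CCOCC", max_len = 10)
  expect_equal(cc2$codes[1], cc2$codes[2])
  expect_equal(cc2$codes[1], cc2$codes[4])
  # padding with a custom map
  cc3 <- smiles_to_codes("CC", vocab = c(C = 1L), max_len = 4)
  expect_equal(cc3$codes, c(1L, 1L, 0L, 0L))
  expect_error(smiles_to_codes("CN", vocab = c(C = 1L)), "'N'")
  expect_equal(smiles_to_codes("CN", vocab = c(C = 1L), unknown = 64L)$codes[2], 64L)
})

test_that("build_substructure_vocab ranks by frequency with stable ties", {
  v <- build_substructure_vocab(c("CC", "CC"), max_token_len = 2, vocab_size = 10)
  expect_true(all(c("C", "CC") %in% v$tokens))
  v1 <- build_substructure_vocab(c("CCO", "OCN"), max_token_len = 1, vocab_size = 99)
  expect_setequal(v1$tokens, c("C", "O", "N"))
  # CC occurs twice, CO and CN once each; with one multi-token slot CC wins
  v2 <- build_substructure_vocab(c("CCO", "CCN"), max_token_len = 2, vocab_size = 4)
  expect_setequal(v2$tokens, c("C", "O", "N", "CC"))
  expect_error(build_substructure_vocab(character(0), 2, 10), "non-empty")
})

test_that("tokenization is greedy longest-match and round-trips", {
  vocab <- structure(list(tokens = c("C", "O", "CC"), max_token_len = 2L,
                          frequency_floor = 1L), class = "substructure_vocab")
  tk <- tokenize_substructures("CCO", vocab, max_tokens = 8)
  expect_equal(vocab$tokens[tk$token_ids[seq_len(tk$n_real)]], c("CC", "O"))
  expect_equal(tk$token_lengths[seq_len(tk$n_real)], c(2L, 1L))
  tk1 <- tokenize_substructures("C", vocab, max_tokens = 4)
  expect_equal(vocab$tokens[tk1$token_ids[1]], "C")
  expect_equal(tk1$n_real, 1L)
  expect_error(tokenize_substructures("CN", vocab, 4), "'N'")
  # round trip over random strings on the corpus alphabet
  corpus <- c("CCOC(N)CC", "NCC(O)=O", "C1CC1N")
  v <- build_substructure_vocab(corpus, max_token_len = 3, vocab_size = 40)
  withr::with_seed(2, {
    for (i in 1:20) {
      s <- paste(sample(strsplit(paste(corpus, collapse = ""), "")[[1]],
                        sample(3:12, 1), replace = TRUE), collapse = "")
      tk <- tokenize_substructures(s, v, max_tokens = 20)
      expect_identical(decode_substructures(tk, v), s)
    }
  })
})

test_that("protein 3-mers match the worked example and pad correctly", {
  expect_equal(protein_kmer_strings("MTVKTE"), c("MTV", "TVK", "VKT", "KTE"))
  tail_kmers <- utils::tail(protein_kmer_strings("MTVKTEQADSFL"), 2)
  expect_equal(tail_kmers, c("DSF", "SFL"))
  expect_equal(length(protein_kmer_strings("AAA")), 1L)

  pk <- protein_to_kmers("MTVKTE", max_len = 10, embed_dim = 8)
  expect_equal(pk$n_real, 4L)
  expect_true(all(pk$kmer_features[5:10, ] == 0))
  expect_equal(dim(pk$kmer_features), c(10L, 8L))
  # truncation
  pk2 <- protein_to_kmers("MTVKTE", max_len = 2, embed_dim = 8)
  expect_equal(pk2$n_real, 2L)
  expect_error(protein_to_kmers("MT", 10, 8), "length >= 3")
  expect_error(protein_kmer_ids("MTZ"), "illegal residue")
})

test_that("featurization is deterministic", {
  a <- smiles_to_graph("CC(N)CO", 10)
  b <- smiles_to_graph("CC(N)CO", 10)
  expect_identical(a, b)
  expect_identical(protein_to_kmers("MTVKTEW", 8, 4), protein_to_kmers("MTVKTEW", 8, 4))
})
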