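# Seeded synthetic-data generator: ligands with countable pharmacophores,
# proteins with planted binding motifs, affinities from an additive
# motif-pharmacophore rule plus Gaussian noise, and ground-truth regions.

#' Simulation configuration
#'
#' The affinity rule is
#' affinity = base_affinity + effect_per_unit * 1\[motif planted\] *
#' min(k, max_effect_units) + Normal(0, noise_sd), where k is the number of
#' pharmacophore atoms in the ligand. The region label is the planted motif
#' interval.
#'
#' @param n_pairs number of (ligand, protein) pairs
#' @param n_ligands,n_proteins distinct entity counts
#' @param motif planted amino-acid motif (default "HWKH")
#' @param pharmacophore counted atom symbol (default "N")
#' @param base_affinity baseline pKd (default 4.0)
#' @param effect_per_unit pKd gain per pharmacophore unit (default 2.0)
#' @param max_effect_units saturation of the pharmacophore count (default 3)
#' @param noise_sd Gaussian label noise (default 0.3)
#' @param protein_len_range,ligand_len_range length ranges (residues, atoms)
#' @param motif_prob fraction of proteins carrying the planted motif
#' @param seed RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_pairs = 2000L, n_ligands = 200L, n_proteins = 100L,
                       motif = "HWKH", pharmacophore = "N",
                       base_affinity = 4.0, effect_per_unit = 2.0,
                       max_effect_units = 3L, noise_sd = 0.3,
                       protein_len_range = c(80L, 120L),
                       ligand_len_range = c(10L, 24L),
                       motif_prob = 0.5, seed = 0L) {
  stopifnot(noise_sd >= 0, n_pairs >= 1,
            nchar(motif) < protein_len_range[1],
            protein_len_range[1] <= protein_len_range[2],
            ligand_len_range[1] >= 4L,
            ligand_len_range[1] <= ligand_len_range[2],
            motif_prob >= 0, motif_prob <= 1)
  structure(list(n_pairs = as.integer(n_pairs), n_ligands = as.integer(n_ligands),
                 n_proteins = as.integer(n_proteins), motif = motif,
                 pharmacophore = pharmacophore, base_affinity = base_affinity,
                 effect_per_unit = effect_per_unit,
                 max_effect_units = as.integer(max_effect_units),
                 noise_sd = noise_sd,
                 protein_len_range = as.integer(protein_len_range),
                 ligand_len_range = as.integer(ligand_len_range),
                 motif_prob = motif_prob, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate one random ligand SMILES with a known pharmacophore count
#'
#' Emits a branched chain over C/O skeleton atoms (optionally containing one
#' ring) in the supported SMILES dialect, then converts exactly `k` chain
#' atoms into the pharmacophore symbol. Uses the current RNG stream.
#'
#' @param cfg a [sim_config()]
#' @param k pharmacophore count; when NULL drawn uniformly from
#'   0..(max_effect_units + 1)
#' @return list with `smiles` and `k`
#' @export
generate_ligand <- function(cfg, k = NULL) {
  n_atoms <- sample(cfg$ligand_len_range[1]:cfg$ligand_len_range[2], 1L)
  if (is.null(k)) k <- sample(0:(cfg$max_effect_units + 1L), 1L)
  k <- min(k, n_atoms - 2L)
  # skeleton: backbone chain with optional single-atom branches and one ring
  backbone <- rep("C", n_atoms)
  use_ring <- stats::runif(1) < 0.3 && n_atoms >= 8L
  ring_at <- 0L
  if (use_ring) ring_at <- sample(seq_len(n_atoms - 6L), 1L)
  # branch flags: interior backbone atoms may carry a single-atom branch
  branch <- rep(FALSE, n_atoms)
  if (n_atoms > 6L) {
    nb <- sample(0:2, 1L)
    cand <- setdiff(2:(n_atoms - 1L), if (use_ring) ring_at:(ring_at + 5L) else integer(0))
    if (nb > 0L && length(cand) > 0L)
      branch[sample(cand, min(nb, length(cand)))] <- TRUE
  }
  # pharmacophore placement: plain chain atoms (no branch point, not ring
  # openers) keep valence legal for N
  elig <- which(!branch)
  if (use_ring) elig <- setdiff(elig, c(ring_at, ring_at + 5L))
  k <- min(k, length(elig))
  atoms <- backbone
  if (k > 0L) atoms[sample(elig, k)] <- cfg$pharmacophore
  # decorate some remaining plain carbons as O (never the pharmacophore)
  rest <- setdiff(which(atoms == "C" & !branch), if (use_ring) c(ring_at, ring_at + 5L) else integer(0))
  if (length(rest) > 0L) {
    no <- sample(0:min(2L, length(rest)), 1L)
    if (no > 0L) atoms[sample(rest, no)] <- "O"
  }
  out <- character(0)
  for (i in seq_len(n_atoms)) {
    out <- c(out, atoms[i])
    if (use_ring && i == ring_at) out <- c(out, "1")
    if (use_ring && i == ring_at + 5L) out <- c(out, "1")
    if (branch[i]) out <- c(out, "(", "C", ")")
  }
  list(smiles = paste(out, collapse = ""), k = as.integer(k))
}

#' Generate one random protein sequence, optionally with a planted motif
#'
#' @param cfg a [sim_config()]
#' @param plant_motif write the motif at a uniform random admissible position
#' @return list with `seq` and `motif_position` (0-based start, or NA)
#' @export
generate_protein <- function(cfg, plant_motif = TRUE) {
  aa20 <- setdiff(.AA_ALPHABET, "X")
  len <- sample(cfg$protein_len_range[1]:cfg$protein_len_range[2], 1L)
  chars <- sample(aa20, len, replace = TRUE)
  pos <- NA_integer_
  m <- nchar(cfg$motif)
  if (plant_motif) {
    pos <- sample(0:(len - m), 1L)
    chars[(pos + 1L):(pos + m)] <- strsplit(cfg$motif, "")[[1]]
  }
  list(seq = paste(chars, collapse = ""), motif_position = pos)
}

#' Generate a full synthetic dataset with ground truth
#'
#' Draws `n_ligands` ligands and `n_proteins` proteins (a `motif_prob`
#' fraction of proteins carry the motif), samples `n_pairs` combinations,
#' and labels each pair by the affinity rule. Bit-identical for a fixed
#' configuration (the seed lives in the config).
#'
#' @param cfg a [sim_config()]
#' @return list with `records` (list of [pair_record()]; region = motif
#'   interval when planted) and `truth` (data.frame: ligand_id, protein_id,
#'   k, motif_planted, motif_position, noiseless, affinity)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  ligands <- lapply(seq_len(cfg$n_ligands), function(i) generate_ligand(cfg))
  n_motif <- round(cfg$n_proteins * cfg$motif_prob)
  proteins <- lapply(seq_len(cfg$n_proteins), function(i)
    generate_protein(cfg, plant_motif = i <= n_motif))
  li <- sample.int(cfg$n_ligands, cfg$n_pairs, replace = TRUE)
  pi <- sample.int(cfg$n_proteins, cfg$n_pairs, replace = TRUE)
  noise <- stats::rnorm(cfg$n_pairs, 0, cfg$noise_sd)
  m <- nchar(cfg$motif)
  records <- vector("list", cfg$n_pairs)
  truth <- data.frame(ligand_id = li, protein_id = pi, k = 0L,
                      motif_planted = FALSE, motif_position = NA_integer_,
                      noiseless = 0, affinity = 0)
  for (i in seq_len(cfg$n_pairs)) {
    lig <- ligands[[li[i]]]; prot <- proteins[[pi[i]]]
    planted <- !is.na(prot$motif_position)
    noiseless <- cfg$base_affinity +
      cfg$effect_per_unit * as.numeric(planted) * min(lig$k, cfg$max_effect_units)
    aff <- noiseless + noise[i]
    region <- if (planted) c(prot$motif_position, prot$motif_position + m) else NULL
    records[[i]] <- pair_record(lig$smiles, prot$seq, aff, region)
    truth$k[i] <- lig$k
    truth$motif_planted[i] <- planted
    truth$motif_position[i] <- prot$motif_position
    truth$noiseless[i] <- noiseless
    truth$affinity[i] <- aff
  }
  list(records = records, truth = truth)
}
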