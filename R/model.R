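# Full model assembly: configuration, weight initialization, featurization
# of pair records, and the end-to-end forward pass.

#' Full model configuration
#'
#' Bundles the encoder configurations and the sequence capacities. Defaults
#' are the production capacities (100 atoms, 100 characters, 50 tokens, 1000
#' protein positions); desk-scale work passes smaller values.
#'
#' @param max_atoms ligand graph capacity (theta_g)
#' @param max_chars ligand character capacity (theta_c)
#' @param max_tokens sub-structure token capacity (theta_t)
#' @param max_protein protein 3-mer capacity (theta_p)
#' @param kmer_dim 3-mer embedding width D_p
#' @param kmer_vocab rows of the learnable 3-mer embedding table; the
#'   21^3 distinct 3-mers are hashed (modulo) into this many rows, so the
#'   full 9261-row table is collision-free while smaller tables trade a few
#'   collisions for training speed
#' @param gat,cnn,mt,vae,interaction encoder configurations (see
#'   [gat_config()], [cnn_config()], [mt_config()], [vae_config()],
#'   [interaction_config()])
#' @param top_fraction fraction of positions marked in the original binding
#'   area s
#' @return list of class `mg_config`
#' @export
mg_config <- function(max_atoms = 100L, max_chars = 100L, max_tokens = 50L,
                      max_protein = 1000L, kmer_dim = 64L, kmer_vocab = 9261L,
                      gat = gat_config(), cnn = cnn_config(), mt = mt_config(),
                      vae = vae_config(), interaction = interaction_config(),
                      top_fraction = 0.1) {
  mt$max_tokens <- as.integer(max_tokens)
  structure(list(max_atoms = as.integer(max_atoms), max_chars = as.integer(max_chars),
                 max_tokens = as.integer(max_tokens), max_protein = as.integer(max_protein),
                 kmer_dim = as.integer(kmer_dim),
                 kmer_vocab = as.integer(kmer_vocab), gat = gat, cnn = cnn, mt = mt,
                 vae = vae, interaction = interaction, top_fraction = top_fraction),
            class = "mg_config")
}

#' A small configuration for desk-scale experiments and tests
#' @param dim common encoder width (<= 64 in the scaled-down protocol)
#' @param max_protein protein capacity
#' @return an [mg_config()]
#' @export
mg_config_small <- function(dim = 24L, max_protein = 120L) {
  mg_config(
    max_atoms = 26L, max_chars = 36L, max_tokens = 20L,
    max_protein = as.integer(max_protein), kmer_dim = 16L, kmer_vocab = 1024L,
    gat = gat_config(embed_dim = dim, out_dim = dim, n_heads = 2L),
    cnn = cnn_config(embed_dim = dim, n_filters = dim, kernel_size = 5L, out_dim = dim),
    mt = mt_config(embed_dim = dim, n_heads = 2L, n_blocks = 2L, out_dim = dim,
                   vocab_size = 64L),
    vae = vae_config(n_filters = 8L, kernel_en = 5L, n_filters_de = 16L,
                     kernel_de = 5L, latent_dim = dim, pool_width = 4L),
    interaction = interaction_config(kernel_len = 9L, channels = 16L, out_dim = 48L)
  )
}

#' Initialize all model weights
#' @param cfg an [mg_config()]
#' @param seed RNG seed for reproducible initialization
#' @return nested list of plain matrices (convert with `ad_params()` to train)
#' @export
mg_init <- function(cfg, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dims <- list(L_g = cfg$gat$out_dim, L_c = cfg$cnn$out_dim, L_t = cfg$mt$out_dim,
               d_p = 3L * cfg$vae$n_filters,
               cap_g = cfg$max_atoms, cap_c = cfg$max_chars, cap_t = cfg$max_tokens)
  list(
    kmer_embed = matrix(stats::rnorm(cfg$kmer_vocab * cfg$kmer_dim, sd = 1 / sqrt(cfg$kmer_dim)),
                        cfg$kmer_vocab, cfg$kmer_dim),
    gat = init_gat_weights(cfg$gat),
    cnn = init_cnn_weights(cfg$cnn),
    mt = init_mt_weights(cfg$mt),
    vae = init_vae_weights(cfg$vae, d_in = cfg$kmer_dim, max_len = cfg$max_protein),
    inter = init_interaction_weights(cfg$interaction, dims)
  )
}

#' Featurize pair records once for repeated forward passes
#'
#' @param records list of pair records (see [pair_record()])
#' @param cfg an [mg_config()]
#' @param subvocab a [build_substructure_vocab()] result; built from the
#'   record SMILES when NULL
#' @return list with per-record `graph`, `codes`, `tokens`, `kmer_ids`,
#'   `protein_n`, plus the `subvocab` used
#' @export
featurize_pairs <- function(records, cfg, subvocab = NULL) {
  smiles <- vapply(records, `[[`, "", "ligand_smiles")
  if (is.null(subvocab)) {
    subvocab <- build_substructure_vocab(unique(smiles), max_token_len = 3L,
                                         vocab_size = cfg$mt$vocab_size)
  }
  feats <- lapply(records, function(rec) {
    list(graph = smiles_to_graph(rec$ligand_smiles, cfg$max_atoms),
         codes = smiles_to_codes(rec$ligand_smiles, max_len = cfg$max_chars),
         tokens = tokenize_substructures(rec$ligand_smiles, subvocab, cfg$max_tokens),
         kmer_ids = {
           ids <- protein_kmer_ids(rec$protein_seq)
           ids <- ids[seq_len(min(length(ids), cfg$max_protein))]
           (ids - 1L) %% cfg$kmer_vocab + 1L
         })
  })
  list(feats = feats, subvocab = subvocab)
}

#' End-to-end forward pass for one featurized pair
#'
#' @param weights from [mg_init()] (plain) or its `ad_params()` conversion
#' @param feat one element of `featurize_pairs()$feats`
#' @param cfg an [mg_config()]
#' @param deterministic if TRUE the VAE uses z = mu (evaluation mode)
#' @param region_scale width R used for the reported interval
#' @return list with `affinity` (scalar), `r`, `s`, `br` (length
#'   `cfg$max_protein`), `region`, `v_out`, `mu`, `log_var`, `recon`,
#'   `protein_n`, and the loss-relevant nodes when training
#' @export
mg_forward <- function(weights, feat, cfg, deterministic = TRUE,
                       region_scale = 10L, want_region = TRUE) {
  n_p <- length(feat$kmer_ids)
  km <- ad_rows(weights$kmer_embed, feat$kmer_ids)
  # encoders
  eg <- gat_encode(feat$graph, cfg$gat, weights$gat)
  ec <- cnn_encode(feat$codes, cfg$cnn, weights$cnn)
  et <- mt_encode(feat$tokens, cfg$mt, weights$mt)
  # protein VAE: run on the (possibly trainable) embedded k-mers
  penc <- .vae_encode_node(km, n_p, cfg$vae, weights$vae, deterministic)
  recon <- vae_decode(penc$z, cfg$vae, weights$vae)
  # interaction
  enc <- list(x_g = eg$x_g, x_c = ec$x_c, x_t = et$x_t)
  K_l <- make_ligand_kernel(enc, weights$inter$kernel_proj)
  r <- response_vector(K_l, penc$feature_map, weights$inter$w_bs,
                       mode = cfg$interaction$response_mode)
  if (want_region) {
    s <- reconstruction_binding_profile(recon, cfg$top_fraction)
    r_full <- numeric(cfg$max_protein)
    r_full[seq_len(n_p)] <- as.numeric(ad_val(r))
    # proteins shorter than the window get a full-protein region
    br <- assemble_binding_region(r_full, s, R = min(region_scale, n_p),
                                  mode = cfg$interaction$br_mode,
                                  n_real = n_p)
  } else {
    s <- NULL; r_full <- NULL; br <- list(br = NULL, region = NULL)
  }
  I_pg <- bilinear_map(penc$feature_map, eg$map_g, weights$inter$bil_g$U,
                       weights$inter$bil_g$V, weights$inter$bil_g$q)
  I_pc <- bilinear_map(penc$feature_map, ec$map_c, weights$inter$bil_c$U,
                       weights$inter$bil_c$V, weights$inter$bil_c$q)
  I_pt <- bilinear_map(penc$feature_map, et$map_t, weights$inter$bil_t$U,
                       weights$inter$bil_t$V, weights$inter$bil_t$q)
  fus <- fuse_interactions(I_pg, I_pc, I_pt, weights$inter,
                           caps = c(cfg$max_atoms, cfg$max_chars, cfg$max_tokens))
  aff <- predict_affinity(fus$v_out, weights$inter$head)
  list(affinity = aff, r = r, r_full = r_full, s = s, br = br$br,
       region = br$region, v_out = fus$v_out, mu = penc$mu,
       log_var = penc$log_var, recon = recon, protein_n = n_p,
       kmer_node = km)
}

# vae_encode over an (adnode) embedded k-mer matrix rather than the plain
# container; shares all weight math with vae_encode
.vae_encode_node <- function(km, n_real, cfg, weights, deterministic) {
  Ke <- cfg$kernel_en
  h1 <- ad_relu(.gated_conv(km, weights$g1, Ke))
  h2 <- ad_relu(.gated_conv(h1, weights$g2, Ke))
  fm <- .gated_conv(h2, weights$g3, Ke)
  pw <- min(cfg$pool_width, n_real)
  pooled <- ad_maxpool1d(fm, pw)
  gap <- ad_meanpool_cols(pooled)
  mu <- ad_add_rowvec(ad_matmul(gap, weights$fc_mu$W), weights$fc_mu$b)
  lv <- ad_add_rowvec(ad_matmul(gap, weights$fc_lv$W), weights$fc_lv$b)
  Lp <- ncol(ad_val(mu))
  if (deterministic) {
    z <- mu
    eps <- matrix(0, 1L, Lp)
  } else {
    eps <- matrix(stats::rnorm(Lp), 1L, Lp)
    z <- ad_add(mu, ad_mul(ad_exp(ad_scale(lv, 0.5)), eps))
  }
  list(mu = mu, log_var = lv, z = z, epsilon = eps, feature_map = fm,
       n_real = n_real)
}

#' Predict affinities (and regions) for a list of records
#'
#' @param weights plain weight tree from [mg_init()] or [train_model()]
#' @param records list of [pair_record()]s
#' @param cfg the [mg_config()] used to train
#' @param subvocab the sub-structure vocabulary used to train
#' @param region_scale region width R
#' @return data.frame with `affinity`, `region_start`, `region_end`,
#'   `region_score` per record
#' @export
mg_predict <- function(weights, records, cfg, subvocab = NULL,
                       region_scale = 10L) {
  fz <- featurize_pairs(records, cfg, subvocab)
  out <- lapply(fz$feats, function(feat) {
    fw <- mg_forward(weights, feat, cfg, deterministic = TRUE,
                     region_scale = region_scale)
    c(as.numeric(ad_val(fw$affinity)), fw$region[1], fw$region[2],
      max(fw$br))
  })
  m <- do.call(rbind, out)
  data.frame(affinity = m[, 1], region_start = as.integer(m[, 2]),
             region_end = as.integer(m[, 3]), region_score = m[, 4])
}
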