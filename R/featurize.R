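# Featurization: SMILES -> molecular graph / integer codes / sub-structure
# tokens, and amino-acid sequence -> overlapping 3-mer feature matrix.

# Supported SMILES dialect: organic-subset atoms (B C N O P S F Cl Br I and
# aromatic b c n o p s), bracket atoms [..], bonds - = # :, branches (), ring
# closures 1-9 and %nn.  No stereochemistry, no isotopes.

.ELEMENTS <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na",
               "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb",
               "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H", "Li", "Ge",
               "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr", "Pt", "Hg",
               "Pb", "Unknown")

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, F = 1,
                      Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into atoms and bonds
#'
#' Internal recursive-descent parser for the supported dialect. Atom indices
#' are 0-based in the order of appearance.
#'
#' @param smiles a SMILES string
#' @return list with `atoms` (data.frame: element, aromatic, explicit_h,
#'   charge, bracket) and `bonds` (data.frame: i, j, order; 0-based, i < j
#'   order of creation, undirected)
#' @keywords internal
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || nchar(smiles) == 0L)
    stop("smiles must be a single non-empty string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  stack <- integer(0)       # branch stack of atom indices (1-based internal)
  prev <- 0L                # previous atom index, 0 = none
  ring <- list()            # ring-closure digit -> c(atom, order)
  pend_bond <- NA_real_     # bond order pending for the next atom/ring
  i <- 1L
  err <- function(msg, pos) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, substr(smiles, pos, pos), msg), call. = FALSE)
  }
  add_atom <- function(element, aromatic, explicit_h = NA_integer_,
                       charge = 0L, bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         explicit_h = explicit_h, charge = charge,
                                         bracket = bracket)
    idx <- length(atoms)
    if (prev > 0L) {
      ord <- pend_bond
      if (is.na(ord)) {
        ord <- if (aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    pend_bond <<- NA_real_
    prev <<- idx
    idx
  }
  close_ring <- function(digit, pos) {
    if (prev == 0L) err("ring closure before any atom", pos)
    key <- as.character(digit)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- c(prev, if (is.na(pend_bond)) -1 else pend_bond)
      pend_bond <<- NA_real_
    } else {
      open <- ring[[key]]
      ord <- pend_bond
      if (is.na(ord)) ord <- if (open[2] > 0) open[2] else NA_real_
      if (is.na(ord)) {
        ord <- if (atoms[[open[1]]]$aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      }
      bonds[[length(bonds) + 1L]] <<- c(open[1], prev, ord)
      ring[[key]] <<- NULL
      pend_bond <<- NA_real_
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (prev == 0L) err("branch before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) err("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-") { pend_bond <- 1; i <- i + 1L
    } else if (ch == "=") { pend_bond <- 2; i <- i + 1L
    } else if (ch == "#") { pend_bond <- 3; i <- i + 1L
    } else if (ch == ":") { pend_bond <- 1.5; i <- i + 1L
    } else if (grepl("[1-9]", ch)) {
      close_ring(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("[0-9]{2}", substr(smiles, i + 1L, i + 2L)))
        err("'%' must be followed by two digits", i)
      close_ring(as.integer(substr(smiles, i + 1L, i + 2L)), i)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) err("unterminated bracket atom", i)
      body <- substr(smiles, i + 1L, j - 1L)
      m <- regmatches(body, regexec("^([A-Z][a-z]?|[cnobps])(H([0-9]?))?([+-][0-9]?)?$", body))[[1]]
      if (length(m) == 0L) err(sprintf("cannot parse bracket atom '[%s]'", body), i)
      sym <- m[2]
      aromatic <- sym %in% c("c", "n", "o", "b", "p", "s")
      element <- if (aromatic) toupper(sym) else sym
      hcount <- if (m[3] == "") 0L else if (m[4] == "") 1L else as.integer(m[4])
      charge <- 0L
      if (m[5] != "") {
        sgn <- if (substr(m[5], 1L, 1L) == "+") 1L else -1L
        mag <- if (nchar(m[5]) > 1L) as.integer(substr(m[5], 2L, 2L)) else 1L
        charge <- sgn * mag
      }
      add_atom(element, aromatic, explicit_h = hcount, charge = charge, bracket = TRUE)
      i <- j + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE)
        i <- i + 1L
      } else err("unknown element (use brackets for non-organic-subset atoms)", i)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else err("unexpected character", i)
  }
  if (length(stack) > 0L) stop("SMILES parse error: unmatched '('", call. = FALSE)
  if (length(ring) > 0L) stop("SMILES parse error: unclosed ring bond(s)", call. = FALSE)
  at <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    explicit_h = vapply(atoms, `[[`, NA_integer_, "explicit_h"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE
  )
  bd <- if (length(bonds)) {
    b <- do.call(rbind, bonds)
    data.frame(i = as.integer(b[, 1]) - 1L, j = as.integer(b[, 2]) - 1L, order = b[, 3])
  } else data.frame(i = integer(0), j = integer(0), order = numeric(0))
  list(atoms = at, bonds = bd)
}

.one_hot <- function(value, choices) {
  v <- numeric(length(choices))
  k <- match(value, choices)
  if (is.na(k)) k <- length(choices)  # last slot = Unknown / overflow
  v[k] <- 1
  v
}

# 78-dim atom descriptor: element one-hot (44) + degree 0..10 (11) +
# total H 0..10 (11) + implicit valence 0..10 (11) + aromatic flag (1)
.atom_features <- function(atom, degree, bond_order_sum) {
  elem <- .one_hot(atom$element, .ELEMENTS)
  if (atom$bracket) {
    h <- atom$explicit_h
    impv <- 0L
  } else {
    dv <- .DEFAULT_VALENCE[atom$element]
    if (is.na(dv)) dv <- 0
    h <- max(0L, as.integer(round(dv - bond_order_sum)))
    impv <- h
  }
  c(elem,
    .one_hot(min(degree, 10L), 0:10),
    .one_hot(min(h, 10L), 0:10),
    .one_hot(min(impv, 10L), 0:10),
    as.numeric(atom$aromatic))
}

#' Convert a SMILES string to a padded molecular graph
#'
#' Atoms become rows of a `max_atoms` x 78 feature matrix (element one-hot,
#' degree, total hydrogens, implicit valence, aromaticity, following the
#' GraphDTA descriptor convention); bonds become symmetric undirected edges.
#' Molecules with more than `max_atoms` atoms are truncated; smaller ones are
#' zero-padded.
#'
#' @param smiles a SMILES string over the supported dialect
#' @param max_atoms maximum number of atom rows (capacity), >= 1
#' @return object of class `molecular_graph`: list with `node_features`
#'   (`max_atoms` x 78 matrix), `edges` (m x 2 integer matrix, 0-based, both
#'   directions), `n_real_atoms`
#' @examples
#' g <- smiles_to_graph("CCO", max_atoms = 8)
#' g$n_real_atoms
#' @export
smiles_to_graph <- function(smiles, max_atoms = 100L) {
  if (!is.numeric(max_atoms) || max_atoms < 1) stop("max_atoms must be >= 1")
  max_atoms <- as.integer(max_atoms)
  p <- parse_smiles(smiles)
  n_atoms <- nrow(p$atoms)
  n_real <- min(n_atoms, max_atoms)
  keep_bonds <- p$bonds[p$bonds$i < n_real & p$bonds$j < n_real, , drop = FALSE]
  degree <- integer(n_real)
  bsum <- numeric(n_real)
  if (nrow(keep_bonds)) {
    for (r in seq_len(nrow(keep_bonds))) {
      i <- keep_bonds$i[r] + 1L; j <- keep_bonds$j[r] + 1L
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      bsum[i] <- bsum[i] + keep_bonds$order[r]
      bsum[j] <- bsum[j] + keep_bonds$order[r]
    }
  }
  nf <- matrix(0, max_atoms, 78L)
  for (i in seq_len(n_real)) {
    nf[i, ] <- .atom_features(p$atoms[i, ], degree[i], bsum[i])
  }
  edges <- if (nrow(keep_bonds)) {
    e <- as.matrix(keep_bonds[, c("i", "j")])
    rbind(e, e[, 2:1, drop = FALSE])
  } else matrix(integer(0), 0L, 2L)
  dimnames(edges) <- NULL
  structure(list(node_features = nf, edges = edges, n_real_atoms = n_real),
            class = "molecular_graph")
}

# ---- 64-letter character codes ----

# Fixed 64-character vocabulary with the documented anchor codes
# C -> 42, O -> 48, '1' -> 35, ')' -> 31, 'l' -> 25.
.build_default_smiles_charset <- function() {
  base <- c("#", "%", "(", ")", "+", "-", ".", "/", "\\", "=", "@", "[", "]",
            as.character(0:9),
            "A", "B", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "O", "P", "R", "S", "T", "U", "V", "W", "X", "Y", "Z",
            "a", "b", "c", "d", "e", "f", "g", "h", "i", "l", "n", "o", "r",
            "s", "t", "u", ":")
  stopifnot(length(base) == 64L, !anyDuplicated(base))
  pins <- c("C" = 42L, "O" = 48L, "1" = 35L, ")" = 31L, "l" = 25L)
  for (ch in names(pins)) {
    want <- pins[[ch]]
    cur <- match(ch, base)
    if (cur != want) {
      tmp <- base[want]; base[want] <- ch; base[cur] <- tmp
    }
  }
  base
}

#' The packaged 64-letter SMILES character vocabulary
#'
#' A fixed, versioned character-to-integer map (codes 1-64, 0 reserved for
#' padding) consistent with the documented anchor pairs C=42, O=48, '1'=35,
#' ')'=31, 'l'=25.
#'
#' @return named integer vector mapping character to code
#' @export
default_smiles_vocab <- function() {
  chars <- .build_default_smiles_charset()
  stats::setNames(seq_along(chars), chars)
}

#' Encode a SMILES string as a padded integer code vector
#'
#' @param smiles a SMILES string
#' @param vocab named integer vector character -> code in 1..64
#'   (default [default_smiles_vocab()])
#' @param max_len capacity; longer strings truncated, shorter padded with 0
#' @param unknown `"error"` (default) or an integer code to substitute for
#'   characters absent from `vocab`
#' @return object of class `ligand_codes`: list with `codes` (length
#'   `max_len`), `n_real`
#' @export
smiles_to_codes <- function(smiles, vocab = default_smiles_vocab(),
                            max_len = 100L, unknown = "error") {
  if (!is.character(smiles) || length(smiles) != 1L) stop("smiles must be a single string")
  if (max_len < 1) stop("max_len must be >= 1")
  max_len <- as.integer(max_len)
  chars <- strsplit(smiles, "")[[1]]
  n_real <- min(length(chars), max_len)
  chars <- chars[seq_len(n_real)]
  codes <- unname(vocab[chars])
  if (anyNA(codes)) {
    bad <- chars[which(is.na(codes))[1]]
    if (identical(unknown, "error"))
      stop(sprintf("character '%s' is not in the SMILES vocabulary", bad))
    codes[is.na(codes)] <- as.integer(unknown)
  }
  if (any(codes > 64L)) stop("vocabulary codes must be <= 64")
  out <- integer(max_len)
  out[seq_len(n_real)] <- as.integer(codes)
  structure(list(codes = out, n_real = n_real), class = "ligand_codes")
}

# ---- sub-structure vocabulary / tokenizer ----

#' Build a frequency-ranked consecutive sub-structure vocabulary
#'
#' Enumerates all consecutive substrings of length 1..`max_token_len` in the
#' corpus. Single characters are always included (so any string over the
#' corpus alphabet tokenizes); multi-character tokens are ranked by corpus
#' frequency, ties broken by longer-first then lexicographic order, and
#' capped at `vocab_size`.
#'
#' @param corpus character vector of SMILES strings (non-empty)
#' @param max_token_len maximum token length l, >= 1
#' @param vocab_size maximum vocabulary size
#' @return object of class `substructure_vocab`: list with `tokens` (ordered;
#'   ids are positions), `max_token_len`, `frequency_floor`
#' @export
build_substructure_vocab <- function(corpus, max_token_len = 3L, vocab_size = 256L) {
  if (length(corpus) == 0L || all(nchar(corpus) == 0L)) stop("corpus must be non-empty")
  if (max_token_len < 1) stop("max_token_len must be >= 1")
  counts <- new.env(parent = emptyenv())
  for (s in corpus) {
    n <- nchar(s)
    for (len in seq_len(min(max_token_len, n))) {
      for (start in seq_len(n - len + 1L)) {
        tok <- substr(s, start, start + len - 1L)
        counts[[tok]] <- (if (is.null(counts[[tok]])) 0L else counts[[tok]]) + 1L
      }
    }
  }
  toks <- ls(counts)
  freq <- vapply(toks, function(t) counts[[t]], 0L)
  single <- toks[nchar(toks) == 1L]
  multi <- toks[nchar(toks) > 1L]
  mfreq <- freq[nchar(toks) > 1L]
  ord <- order(-mfreq, -nchar(multi), multi, method = "radix")
  multi <- multi[ord]; mfreq <- mfreq[ord]
  n_multi <- max(0L, min(length(multi), vocab_size - length(single)))
  kept <- c(sort(single, method = "radix"), multi[seq_len(n_multi)])
  floor_freq <- if (n_multi > 0L) mfreq[n_multi] else 1L
  structure(list(tokens = kept, max_token_len = as.integer(max_token_len),
                 frequency_floor = as.integer(floor_freq)),
            class = "substructure_vocab")
}

#' Tokenize a SMILES string by greedy longest-match over a vocabulary
#'
#' @param smiles string over the vocabulary alphabet
#' @param vocab a [build_substructure_vocab()] result
#' @param max_tokens capacity; excess tokens truncated, shortfall padded with 0
#' @return object of class `substructure_tokens`: list with `token_ids`
#'   (length `max_tokens`, 0 = padding), `token_lengths`, `n_real`
#' @export
tokenize_substructures <- function(smiles, vocab, max_tokens = 50L) {
  stopifnot(inherits(vocab, "substructure_vocab"))
  if (max_tokens < 1) stop("max_tokens must be >= 1")
  max_tokens <- as.integer(max_tokens)
  idx <- stats::setNames(seq_along(vocab$tokens), vocab$tokens)
  n <- nchar(smiles)
  ids <- integer(0); lens <- integer(0)
  pos <- 1L
  while (pos <= n && length(ids) < max_tokens) {
    hit <- NA_integer_; hlen <- 0L
    for (len in seq(min(vocab$max_token_len, n - pos + 1L), 1L)) {
      tok <- substr(smiles, pos, pos + len - 1L)
      k <- idx[tok]
      if (!is.na(k)) { hit <- unname(k); hlen <- len; break }
    }
    if (is.na(hit)) {
      stop(sprintf("character '%s' at position %d is not in the sub-structure vocabulary",
                   substr(smiles, pos, pos), pos))
    }
    ids <- c(ids, hit); lens <- c(lens, hlen)
    pos <- pos + hlen
  }
  n_real <- length(ids)
  token_ids <- integer(max_tokens); token_ids[seq_len(n_real)] <- ids
  token_lengths <- integer(max_tokens); token_lengths[seq_len(n_real)] <- lens
  structure(list(token_ids = token_ids, token_lengths = token_lengths,
                 n_real = n_real), class = "substructure_tokens")
}

#' Decode tokens back to the covered SMILES prefix
#' @param tokens a [tokenize_substructures()] result
#' @param vocab the vocabulary used to tokenize
#' @return the concatenated string
#' @export
decode_substructures <- function(tokens, vocab) {
  stopifnot(inherits(tokens, "substructure_tokens"),
            inherits(vocab, "substructure_vocab"))
  paste(vocab$tokens[tokens$token_ids[seq_len(tokens$n_real)]], collapse = "")
}

# ---- protein 3-mers ----

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Overlapping 3-mer strings of an amino-acid sequence
#' @param seq amino-acid string, length >= 3
#' @return character vector of the len-2 overlapping 3-mers
#' @examples protein_kmer_strings("MTVKTE")
#' @export
protein_kmer_strings <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) stop("protein sequence must have length >= 3")
  vapply(seq_len(n - 2L), function(i) substr(seq, i, i + 2L), "")
}

#' Integer indices of overlapping 3-mers over the 21-letter alphabet
#'
#' Index = 1 + sum of 0-based letter codes in base 21 (alphabet
#' ACDEFGHIKLMNPQRSTVWY + X for unknown), so indices lie in 1..21^3.
#' @param seq amino-acid string, length >= 3
#' @return integer vector of length len-2
#' @export
protein_kmer_ids <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) stop("protein sequence must have length >= 3")
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, .AA_ALPHABET)
  if (anyNA(codes)) {
    bad <- chars[which(is.na(codes))[1]]
    stop(sprintf("illegal residue character '%s' (alphabet is %s)",
                 bad, paste(.AA_ALPHABET, collapse = "")))
  }
  codes <- codes - 1L
  m <- n - 2L
  1L + codes[1:m] + 21L * codes[2:(m + 1L)] + 441L * codes[3:(m + 2L)]
}

#' Deterministic random 3-mer embedding table
#' @param embed_dim embedding dimension D_p
#' @param seed RNG seed for reproducibility
#' @return 21^3 x embed_dim matrix
#' @export
make_kmer_embedding <- function(embed_dim = 64L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  matrix(stats::rnorm(21L^3 * embed_dim, sd = 1 / sqrt(embed_dim)), 21L^3, embed_dim)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Embed a protein as a padded overlapping-3-mer feature matrix
#'
#' Row i embeds residues i..i+2; the number of real rows is
#' min(len - 2, max_len) and the remainder is zero padding.
#'
#' @param seq amino-acid string (20-letter alphabet plus X), length >= 3
#' @param max_len capacity (number of 3-mer rows)
#' @param embed_dim embedding dimension (used when `embedding` is NULL)
#' @param embedding 21^3 x D_p matrix mapping 3-mer index to vector; default a
#'   deterministic table from [make_kmer_embedding()]
#' @return object of class `protein_kmer_matrix`: list with `kmer_features`
#'   (`max_len` x D_p), `n_real`, `kmer_ids` (length `n_real`)
#' @export
protein_to_kmers <- function(seq, max_len = 1000L, embed_dim = 64L,
                             embedding = NULL) {
  if (max_len < 1) stop("max_len must be >= 1")
  max_len <- as.integer(max_len)
  ids <- protein_kmer_ids(seq)
  n_real <- min(length(ids), max_len)
  ids <- ids[seq_len(n_real)]
  if (is.null(embedding)) embedding <- make_kmer_embedding(embed_dim)
  feat <- matrix(0, max_len, ncol(embedding))
  feat[seq_len(n_real), ] <- embedding[ids, , drop = FALSE]
  structure(list(kmer_features = feat, n_real = n_real, kmer_ids = ids),
            class = "protein_kmer_matrix")
}
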