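# Shared fixtures and independent oracles.  The oracles deliberately use
# plain loops and environments (no joins) so they cannot share a defect
# with the implementation under test.

# Brute-force occurrence scan: for each NOG at each rank, list the taxa
# containing it; a NOG is taxon-specific iff exactly one taxon at that
# rank carries it.  Genomes of unknown lineage at a rank are scanned as a
# sentinel pseudo-taxon: they block uniqueness but never own a NOG, and
# they contribute no totals.
oracle_db <- function(profiles, lineages, min_genes = 0) {
  profiles <- profiles[profiles$gene_count >= min_genes, , drop = FALSE]
  unknown <- "<unknown>"
  out_total <- list()
  out_unique <- list()
  for (rk in tax_ranks()) {
    keys <- taxnog:::taxon_key_safe(lineages, rk)
    names(keys) <- lineages$genome_id
    occ <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(profiles))) {
      key <- keys[[profiles$genome_id[i]]]
      if (is.na(key)) key <- unknown
      for (n in profiles$nogs[[i]]) {
        occ[[n]] <- union(get0(n, envir = occ, ifnotfound = character(0)), key)
      }
    }
    nogs <- ls(occ)
    for (n in nogs) {
      taxa <- occ[[n]]
      for (tk in setdiff(taxa, unknown)) {
        out_total[[length(out_total) + 1L]] <- c(rk, tk, n)
      }
      if (length(taxa) == 1L && taxa != unknown) {
        out_unique[[length(out_unique) + 1L]] <- c(rk, taxa, n)
      }
    }
  }
  to_tbl <- function(rows) {
    if (length(rows) == 0L) {
      return(tibble::tibble(rank = character(0), taxon_key = character(0),
                            nog = character(0)))
    }
    m <- do.call(rbind, rows)
    df <- tibble::tibble(rank = m[, 1], taxon_key = m[, 2], nog = m[, 3])
    df[order(match(df$rank, tax_ranks()), df$taxon_key, df$nog), ]
  }
  list(unique = to_tbl(out_unique), total = to_tbl(out_total))
}

sorted_pairs <- function(df) {
  df <- df[order(match(df$rank, tax_ranks()), df$taxon_key, df$nog), ]
  rownames(df) <- NULL
  tibble::as_tibble(df)
}

# Random reference taxonomy drawn directly (not through the simulator):
# random lineage strings, random NOG sets from a small shared universe,
# and a fraction of genomes left unknown below a random rank.
random_reference <- function(seed, max_genomes = 50, universe = 200) {
  set.seed(seed)
  n_genomes <- sample(5:max_genomes, 1)
  nog_universe <- paste0("N", sprintf("%03d", seq_len(universe)))
  n_phyla <- sample(2:4, 1)
  lin <- tibble::tibble(genome_id = paste0("g", seq_len(n_genomes)))
  labels <- function(parent, breadth, tag) {
    paste0(parent, tag, sample.int(breadth, length(parent), replace = TRUE))
  }
  ph <- paste0("ph", sample.int(n_phyla, n_genomes, replace = TRUE))
  cl <- labels(ph, 2, "c"); or <- labels(cl, 2, "o")
  fa <- labels(or, 2, "f"); ge <- labels(fa, 2, "g"); sp <- labels(ge, 2, "s")
  lin$phylum <- ph; lin$class <- cl; lin$order <- or
  lin$family <- fa; lin$genus <- ge; lin$species <- sp
  # truncate some lineages below a random rank (no-gap by construction)
  for (i in seq_len(n_genomes)) {
    if (runif(1) < 0.3) {
      cut <- sample(2:6, 1)
      lin[i, tax_ranks()[cut:6]] <- NA_character_
    }
  }
  sets <- lapply(seq_len(n_genomes), function(i) {
    sample(nog_universe, sample(3:40, 1))
  })
  prof <- new_profiles(lin$genome_id, vapply(sets, length, integer(1)) + 5L,
                       1, sets)
  list(profiles = prof, lineages = lin)
}

# Three-genome, two-phylum worked example used across db tests.
tiny_reference <- function() {
  prof <- new_profiles(
    c("G1", "G2", "G3"), c(3L, 2L, 2L), 1,
    list(c("n1", "n2", "n3"), c("n2", "n4"), c("n3", "n5")))
  lin <- tibble::tibble(
    genome_id = c("G1", "G2", "G3"),
    phylum = c("A", "A", "B"),
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, species = NA_character_)
  list(profiles = prof, lineages = lin)
}

# Exact two-sided hypergeometric p by direct enumeration of binomial
# coefficients (independent of stats::dhyper).
enum_hyper_p <- function(k_unique, n_unique, k_total, n_total) {
  if (n_unique == 0 || n_total == 0 || k_total == 0 || k_total == n_total) {
    return(1)
  }
  xs <- max(0, n_unique - (n_total - k_total)):min(k_total, n_unique)
  pr <- vapply(xs, function(x) {
    choose(k_total, x) * choose(n_total - k_total, n_unique - x) /
      choose(n_total, n_unique)
  }, numeric(1))
  p_obs <- pr[xs == k_unique]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

shuffle_profiles <- function(profiles, seed) {
  set.seed(seed)
  profiles <- profiles[sample.int(nrow(profiles)), ]
  profiles$nogs <- lapply(profiles$nogs, sample)
  profiles
}
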