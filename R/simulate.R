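#' Configuration for the synthetic taxonomy simulator
#'
#' The simulator emulates the pan-genome structure the classifier relies
#' on: every node of a six-rank taxonomy tree owns a disjoint pool of
#' node-specific NOGs, all genomes share a universal core pool, and each
#' genome is the union of sampled fractions of its six ancestor pools,
#' the core, and (optionally) cross-lineage noise drawn uniformly from
#' other nodes' pools — the adversarial contamination for a unique-set
#' method.
#'
#' @param children Integer vector of length 6: children per node at each
#'   rank (default `c(4, 3, 2, 2, 2, 2)` — 4 phyla down to 192 species).
#' @param genomes_per_species Genomes sampled per species leaf
#'   (default 3).
#' @param pool_size Node-specific NOGs per tree node (default 20).
#' @param core_size Universal core NOGs shared by all genomes
#'   (default 200).
#' @param genes_per_genome Nominal pre-dedup gene total recorded per
#'   genome (default 2000; comfortably above the 475-gene reference
#'   filter).
#' @param sample_frac Fraction of each ancestor pool sampled into a
#'   genome (default 1).
#' @param noise_rate Proportion of a genome's NOG set drawn from
#'   off-lineage pools (default 0).
#' @param seed Integer seed; everything downstream is deterministic in
#'   it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(children = c(4L, 3L, 2L, 2L, 2L, 2L),
                       genomes_per_species = 3L, pool_size = 20L,
                       core_size = 200L, genes_per_genome = 2000L,
                       sample_frac = 1, noise_rate = 0, seed = 1L) {
  stopifnot(length(children) == 6L, all(children >= 1L),
            genomes_per_species >= 1L, pool_size >= 1L, core_size >= 0L,
            genes_per_genome >= 1L, sample_frac > 0, sample_frac <= 1,
            noise_rate >= 0, noise_rate < 1)
  structure(list(children = as.integer(children),
                 genomes_per_species = as.integer(genomes_per_species),
                 pool_size = as.integer(pool_size),
                 core_size = as.integer(core_size),
                 genes_per_genome = as.integer(genes_per_genome),
                 sample_frac = sample_frac, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Enumerate the tree: one row per node with rank, label (globally
# unique), taxon_key (full path) and parent_key.
sim_tree <- function(children) {
  letters_rk <- c("P", "C", "O", "F", "G", "S")
  nodes <- tibble::tibble(rank = "phylum",
                          label = paste0("P", seq_len(children[1])),
                          taxon_key = paste0("P", seq_len(children[1])),
                          parent_key = NA_character_)
  all_nodes <- list(nodes)
  for (d in 2:6) {
    parents <- all_nodes[[d - 1L]]
    kids <- purrr::map(seq_len(nrow(parents)), function(i) {
      lab <- paste0(parents$label[i], letters_rk[d], seq_len(children[d]))
      tibble::tibble(rank = tax_ranks()[d], label = lab,
                     taxon_key = paste(parents$taxon_key[i], lab, sep = .key_sep),
                     parent_key = parents$taxon_key[i])
    })
    all_nodes[[d]] <- dplyr::bind_rows(kids)
  }
  dplyr::bind_rows(all_nodes)
}

sample_frac_of <- function(pool, frac) {
  if (frac >= 1) return(pool)
  n <- max(1L, round(frac * length(pool)))
  sample(pool, n)
}

# Category letters for a batch of NOGs; node-pool NOGs get the
# function-unknown letter "S" upweighted 1.5x so functional enrichment in
# taxon-specific sets is planted and testable.
sim_categories <- function(nog_ids, s_weight) {
  cats <- cog_categories()
  w <- rep(1, length(cats))
  w[cats == "S"] <- s_weight
  vapply(seq_along(nog_ids), function(i) {
    k <- if (stats::runif(1) < 0.8) 1L else 2L
    paste(sort(sample(cats, k, prob = w)), collapse = "")
  }, character(1))
}

#' Simulate a reference taxonomy with planted taxon-specific NOGs
#'
#' @param cfg A [sim_config()].
#' @return An object of class `taxnog_sim`: list with `profiles` (a
#'   profiles tibble), `lineages`, `pools` (ground truth: tibble `rank`,
#'   `taxon_key`, `nog` of each node's planted pool), `catalog`
#'   (members/categories tibble usable by the funcat stage), `nodes`
#'   (the tree) and `cfg`.  Byte-identical across runs for a given
#'   config.
#' @export
#' @examples
#' sim <- simulate_taxonomy(sim_config(children = c(2, 2, 1, 1, 1, 1),
#'   genomes_per_species = 2, seed = 42))
#' sim$profiles
simulate_taxonomy <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    nodes <- sim_tree(cfg$children)
    pools <- stats::setNames(
      purrr::map(nodes$label, function(lab) {
        paste0("NOG_", lab, "_", sprintf("%03d", seq_len(cfg$pool_size)))
      }), nodes$taxon_key)
    core <- if (cfg$core_size > 0L) {
      paste0("NOG_CORE_", sprintf("%04d", seq_len(cfg$core_size)))
    } else character(0)

    species <- nodes[nodes$rank == "species", , drop = FALSE]
    ancestors_of <- function(key) {
      parts <- strsplit(key, .key_sep, fixed = TRUE)[[1]]
      vapply(seq_along(parts), function(d) {
        paste(parts[seq_len(d)], collapse = .key_sep)
      }, character(1))
    }
    all_pool_nogs <- unlist(pools, use.names = FALSE)

    genomes <- purrr::map(seq_len(nrow(species)), function(i) {
      sp <- species$taxon_key[i]
      anc <- ancestors_of(sp)
      own <- unlist(pools[anc], use.names = FALSE)
      purrr::map(seq_len(cfg$genomes_per_species), function(g) {
        specific <- unlist(purrr::map(anc, function(a) {
          sample_frac_of(pools[[a]], cfg$sample_frac)
        }), use.names = FALSE)
        base <- c(specific, core)
        noise <- character(0)
        if (cfg$noise_rate > 0) {
          n_noise <- round(cfg$noise_rate / (1 - cfg$noise_rate) * length(base))
          foreign <- setdiff(all_pool_nogs, own)
          noise <- sample(foreign, min(n_noise, length(foreign)))
        }
        tibble::tibble(genome_id = paste0(species$label[i], "_g", g),
                       species_key = sp,
                       nogs = list(sort(unique(c(base, noise)))))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()

    key_parts <- strsplit(genomes$species_key, .key_sep, fixed = TRUE)
    lineages <- tibble::tibble(genome_id = genomes$genome_id)
    for (d in seq_along(tax_ranks())) {
      lineages[[tax_ranks()[d]]] <- vapply(key_parts, `[[`, character(1), d)
    }

    profiles <- new_profiles(
      genomes$genome_id,
      pmax(cfg$genes_per_genome, lengths(genomes$nogs)),
      1, genomes$nogs)

    pool_tbl <- tibble::tibble(
      rank = rep(nodes$rank, each = cfg$pool_size),
      taxon_key = rep(nodes$taxon_key, each = cfg$pool_size),
      nog = unlist(pools, use.names = FALSE))

    all_ids <- c(all_pool_nogs, core)
    catalog <- tibble::tibble(
      member_id = paste0(all_ids, ".m1"),
      nog_id = all_ids,
      categories = c(sim_categories(all_pool_nogs, s_weight = 1.5),
                     sim_categories(core, s_weight = 1)))

    structure(list(profiles = profiles, lineages = lineages,
                   pools = pool_tbl, catalog = catalog, nodes = nodes,
                   cfg = cfg),
              class = "taxnog_sim")
  })
}

#' @export
print.taxnog_sim <- function(x, ...) {
  cat("<taxnog_sim>", nrow(x$profiles), "genomes,",
      nrow(x$nodes), "taxa,", nrow(x$pools), "planted specific NOGs",
      paste0("(seed ", x$cfg$seed, ")\n"))
  invisible(x)
}

resolve_sim_lineage <- function(sim, lineage) {
  if (is.character(lineage) && length(lineage) == 1L) {
    if (lineage %in% sim$lineages$genome_id) {
      row <- sim$lineages[sim$lineages$genome_id == lineage, , drop = FALSE]
      return(taxon_key(row, "species"))
    }
    if (lineage %in% sim$nodes$taxon_key[sim$nodes$rank == "species"]) {
      return(lineage)
    }
    stop("unknown lineage: '", lineage,
         "' is neither a simulated genome_id nor a species taxon key",
         call. = FALSE)
  }
  taxon_key(as_lineage_tbl(lineage), "species")
}

#' Generate a novel query genome from a simulated lineage
#'
#' Draws a fresh genome from the stated species' ancestor pools (never a
#' copy of a reference genome) and optionally degrades it by dropping a
#' fraction of its lineage-specific NOGs, rank-selectively.
#'
#' @param sim A `taxnog_sim`.
#' @param lineage A species taxon key (e.g. `"P1|P1C1|...|...S1"`), a
#'   simulated `genome_id` (its lineage is used), or a one-row lineage
#'   tibble complete to species.
#' @param drop_frac Fraction of specific NOGs removed (default 0).
#' @param drop_ranks Ranks whose pool contributions are subject to the
#'   drop (default all six; pass `tax_ranks()[-1]` to degrade only
#'   sub-phylum evidence).
#' @param noise_rate Cross-lineage noise proportion for the query
#'   (defaults to the simulation's own rate).
#' @param seed Integer seed for the query draw.
#' @return A one-row profiles tibble (genome id `"query_<species>"`).
#' @export
make_query <- function(sim, lineage, drop_frac = 0,
                       drop_ranks = tax_ranks(),
                       noise_rate = sim$cfg$noise_rate, seed = 1L) {
  stopifnot(inherits(sim, "taxnog_sim"), drop_frac >= 0, drop_frac <= 1,
            all(drop_ranks %in% tax_ranks()))
  sp_key <- resolve_sim_lineage(sim, lineage)
  cfg <- sim$cfg
  parts <- strsplit(sp_key, .key_sep, fixed = TRUE)[[1]]
  anc_keys <- vapply(seq_along(parts), function(d) {
    paste(parts[seq_len(d)], collapse = .key_sep)
  }, character(1))
  pool_of <- split(sim$pools$nog, sim$pools$taxon_key)
  core <- setdiff(unique(sim$catalog$nog_id), sim$pools$nog)
  withr::with_seed(seed, {
    specific <- purrr::map(seq_along(anc_keys), function(d) {
      s <- sample_frac_of(pool_of[[anc_keys[d]]], cfg$sample_frac)
      if (drop_frac > 0 && tax_ranks()[d] %in% drop_ranks) {
        n_keep <- round((1 - drop_frac) * length(s))
        s <- if (n_keep == 0L) character(0) else sample(s, n_keep)
      }
      s
    })
    base <- c(unlist(specific, use.names = FALSE), core)
    noise <- character(0)
    if (noise_rate > 0) {
      foreign <- setdiff(sim$pools$nog, unlist(pool_of[anc_keys]))
      n_noise <- round(noise_rate / (1 - noise_rate) * length(base))
      noise <- sample(foreign, min(n_noise, length(foreign)))
    }
    new_profiles(paste0("query_", parts[6]),
                 max(cfg$genes_per_genome, length(unique(c(base, noise)))),
                 1, list(c(base, noise)))
  })
}

#' Engineer a query that lands in the phylum tie branch
#'
#' Constructs a query whose phylum-rank match counts against a database
#' built from the noise-free, full-coverage simulation are exactly
#' (`n_best`, `n_second`): `n_best - n_class` NOGs from the best phylum's
#' own pool plus `n_class` from its first class's pool (which also count
#' for the phylum), and `n_second` from the decoy phylum's pool.  With
#' `n_second / n_best` at or above the tie threshold, the deferral branch
#' fires and the class-level counts (`n_class` vs 0) resolve it to the
#' planted truth.
#'
#' @param sim A `taxnog_sim` generated with `noise_rate = 0` and
#'   `sample_frac = 1` and at least two phyla.
#' @param n_best,n_second Planted phylum match counts (defaults 10 and 4,
#'   a 0.4 ratio).
#' @param n_class Portion of `n_best` contributed by the resolving class
#'   pool (default 4).
#' @param seed Seed for which pool members are picked.
#' @return List: `query` (one-row profiles tibble), `truth` (one-row
#'   lineage tibble known to class, deeper ranks `NA`), `expected`
#'   (planted counts and taxon keys).
#' @export
make_ambiguous_pair <- function(sim, n_best = 10L, n_second = 4L,
                                n_class = 4L, seed = 1L) {
  stopifnot(inherits(sim, "taxnog_sim"), sim$cfg$noise_rate == 0,
            sim$cfg$sample_frac == 1, sim$cfg$children[1] >= 2L,
            n_best > n_second, n_class < n_best,
            n_class <= sim$cfg$pool_size, n_second <= sim$cfg$pool_size,
            n_best - n_class <= sim$cfg$pool_size)
  phyla <- sim$nodes$taxon_key[sim$nodes$rank == "phylum"]
  a <- phyla[1]; b <- phyla[2]
  c1 <- sim$nodes$taxon_key[sim$nodes$rank == "class" &
                              sim$nodes$parent_key == a][1]
  pool_of <- split(sim$pools$nog, sim$pools$taxon_key)
  withr::with_seed(seed, {
    nogs <- c(sample(pool_of[[a]], n_best - n_class),
              sample(pool_of[[c1]], n_class),
              sample(pool_of[[b]], n_second))
  })
  truth <- tibble::tibble(genome_id = "ambiguous_query",
                          phylum = last_label(a), class = last_label(c1),
                          order = NA_character_, family = NA_character_,
                          genus = NA_character_, species = NA_character_)
  list(query = new_profiles("ambiguous_query", length(nogs), 1, list(nogs)),
       truth = truth,
       expected = list(best_phylum = a, second_phylum = b,
                       resolving_class = c1, best_count = n_best,
                       second_count = n_second, class_count = n_class))
}

#' Write a simulation to the pipeline's interchange formats
#'
#' Emits the same dialects the real pipeline reads: `gene2nog.tsv`
#' (one synthetic gene per genome-NOG pair), `lineages.tsv`, and
#' `catalog.tsv`.
#'
#' @param sim A `taxnog_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- tidyr::unnest(sim$profiles[c("genome_id", "nogs")], cols = "nogs")
  g2n <- tibble::tibble(
    genome_id = long$genome_id,
    gene_id = paste0(long$genome_id, "_gene_",
                     sprintf("%05d", stats::ave(seq_len(nrow(long)),
                                                long$genome_id, FUN = seq_along))),
    nog_id = long$nogs)
  readr::write_tsv(g2n, file.path(dir, "gene2nog.tsv"), progress = FALSE)
  readr::write_tsv(sim$lineages, file.path(dir, "lineages.tsv"), progress = FALSE)
  readr::write_tsv(sim$catalog, file.path(dir, "catalog.tsv"), progress = FALSE)
  invisible(dir)
}
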