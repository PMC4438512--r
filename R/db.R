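#' Per-taxon total NOG sets at a rank
#'
#' Unions the NOG sets of all member genomes of each taxon at `rank`.
#' Genomes whose lineage is unknown at `rank` are skipped at that rank
#' (they still contribute at shallower ranks where their lineage is
#' known).
#'
#' @param profiles A profiles tibble (see [new_profiles()]).
#' @param lineages A validated lineage tibble covering the profiled
#'   genomes.
#' @param rank One of [tax_ranks()].
#' @return Tibble with columns `taxon_key`, `nog` (one row per pair),
#'   sorted.
#' @export
total_nogs_per_taxon <- function(profiles, lineages, rank) {
  stopifnot(nrow(profiles) > 0L)
  keys <- taxon_key_safe(lineages, rank)
  key_of <- stats::setNames(keys, lineages$genome_id)
  long <- tidyr::unnest(profiles[c("genome_id", "nogs")],
                        cols = "nogs") |>
    dplyr::rename(nog = "nogs")
  long$taxon_key <- unname(key_of[long$genome_id])
  long |>
    dplyr::filter(!is.na(.data$taxon_key)) |>
    dplyr::distinct(.data$taxon_key, .data$nog) |>
    dplyr::arrange(.data$taxon_key, .data$nog)
}

#' Taxon-specific (unique) NOGs from per-taxon totals
#'
#' A NOG is specific to a taxon at a rank when it occurs in that taxon and
#' in no other taxon at the same rank — the subtraction is global across
#' the whole rank, not restricted to sibling taxa.
#'
#' @param totals Tibble `taxon_key`, `nog` as returned by
#'   [total_nogs_per_taxon()].
#' @param exclude Optional character vector of NOGs subtracted from every
#'   taxon's specific set.  [build_db()] passes the NOGs of genomes whose
#'   lineage is unknown at the rank: such genomes cannot be placed in any
#'   taxon, so no taxon may claim a NOG they carry as its own.  This keeps
#'   specific sets nested along the hierarchy even when reference
#'   lineages are incomplete.
#' @return Tibble of the same shape keeping only taxon-specific pairs.
#' @export
unique_nogs_per_taxon <- function(totals, exclude = NULL) {
  totals |>
    dplyr::distinct(.data$taxon_key, .data$nog) |>
    dplyr::group_by(.data$nog) |>
    dplyr::filter(dplyr::n_distinct(.data$taxon_key) == 1L) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$nog %in% exclude) |>
    dplyr::arrange(.data$taxon_key, .data$nog)
}

#' Build the taxon-specific NOG database
#'
#' Applies the minimum-gene filter, drops invalid lineages, and computes
#' for every taxon at every rank both its total NOG set (union over
#' member genomes) and its taxon-specific set (NOGs absent from every
#' other taxon at the same rank).  The build is deterministic: permuting
#' genome order or NOG order leaves the serialized database byte-identical.
#'
#' @param profiles A profiles tibble.
#' @param lineages A lineage tibble for the profiled genomes (validated
#'   internally).
#' @param min_genes Minimum gene count for a reference genome
#'   (default 475, see [filter_genomes()]).
#' @return An object of class `nog_db`: list with tibbles `unique` and
#'   `total` (columns `rank`, `taxon_key`, `nog`) and a `meta` list
#'   (`n_genomes`, `min_genes`, `version`).
#' @export
#' @examples
#' prof <- new_profiles(c("G1", "G2", "G3"), c(3L, 2L, 2L), 1,
#'   list(c("n1", "n2", "n3"), c("n2", "n4"), c("n3", "n5")))
#' lin <- tibble::tibble(genome_id = c("G1", "G2", "G3"),
#'   phylum = c("A", "A", "B"), class = NA, order = NA, family = NA,
#'   genus = NA, species = NA)
#' db <- build_db(prof, lin, min_genes = 0)
#' db_summary(db)
build_db <- function(profiles, lineages, min_genes = 475L) {
  lineages <- validate_lineages(lineages)
  flt <- filter_genomes(profiles, min_genes)
  kept <- dplyr::filter(flt$kept, .data$genome_id %in% lineages$genome_id)
  if (nrow(kept) == 0L) {
    stop("no reference genomes left after the min-gene filter and lineage validation",
         call. = FALSE)
  }
  long <- tidyr::unnest(kept[c("genome_id", "nogs")], cols = "nogs")
  per_rank <- function(rank) {
    tot <- total_nogs_per_taxon(kept, lineages, rank)
    keys <- stats::setNames(taxon_key_safe(lineages, rank), lineages$genome_id)
    unknown_nogs <- unique(long$nogs[is.na(keys[long$genome_id])])
    uni <- unique_nogs_per_taxon(tot, exclude = unknown_nogs)
    list(total = dplyr::mutate(tot, rank = rank, .before = 1L),
         unique = dplyr::mutate(uni, rank = rank, .before = 1L))
  }
  parts <- purrr::map(tax_ranks(), per_rank)
  db <- structure(list(
    unique = dplyr::bind_rows(purrr::map(parts, "unique")),
    total = dplyr::bind_rows(purrr::map(parts, "total")),
    meta = list(n_genomes = nrow(kept), min_genes = as.integer(min_genes),
                version = as.character(utils::packageVersion("taxnog")))
  ), class = "nog_db")
  db
}

#' @export
print.nog_db <- function(x, ...) {
  s <- db_summary(x)
  cat("<nog_db> built from", x$meta$n_genomes, "genomes (min_genes =",
      paste0(x$meta$min_genes, ")\n"))
  per <- dplyr::count(s, .data$rank)
  cat("  taxa per rank:",
      paste(per$rank, per$n, sep = "=", collapse = ", "), "\n")
  cat("  taxon-specific NOG rows:", nrow(x$unique), "\n")
  invisible(x)
}

#' Check the structural invariants of a built database
#'
#' Verifies, for every rank: `unique ⊆ total`; taxon-specific sets of
#' distinct taxa are pairwise disjoint; and each taxon's specific set is
#' contained in its parent's specific set (a NOG confined to one class is
#' necessarily confined to that class's phylum).
#'
#' @param db A `nog_db`.
#' @return `TRUE` invisibly if all invariants hold; otherwise errors with
#'   the first violated invariant.
#' @export
check_db <- function(db) {
  stopifnot(inherits(db, "nog_db"))
  extra <- dplyr::anti_join(db$unique, db$total,
                            by = c("rank", "taxon_key", "nog"))
  if (nrow(extra) > 0L) stop("unique set not contained in total set", call. = FALSE)
  dup <- db$unique |>
    dplyr::distinct(.data$rank, .data$taxon_key, .data$nog) |>
    dplyr::count(.data$rank, .data$nog) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("taxon-specific sets not pairwise disjoint at rank ", dup$rank[1],
         call. = FALSE)
  }
  deep <- dplyr::filter(db$unique, .data$rank != "phylum")
  if (nrow(deep) > 0L) {
    deep$parent_rank <- tax_ranks()[rank_depth(deep$rank)]
    deep$parent_key <- parent_key(deep$taxon_key)
    orphan <- dplyr::anti_join(
      deep, db$unique,
      by = c(parent_rank = "rank", parent_key = "taxon_key", "nog"))
    if (nrow(orphan) > 0L) {
      stop("child-specific NOG missing from parent-specific set (e.g. ",
           orphan$nog[1], " of ", orphan$taxon_key[1], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Summarise a taxon-specific NOG database
#'
#' @param db A `nog_db`.
#' @return Tibble with one row per (rank, taxon): `n_total`, `n_unique`,
#'   and `unique_fraction = n_unique / n_total`.
#' @export
db_summary <- function(db) {
  stopifnot(inherits(db, "nog_db"))
  tot <- dplyr::count(db$total, .data$rank, .data$taxon_key, name = "n_total")
  uni <- dplyr::count(db$unique, .data$rank, .data$taxon_key, name = "n_unique")
  out <- dplyr::left_join(tot, uni, by = c("rank", "taxon_key")) |>
    dplyr::mutate(n_unique = dplyr::coalesce(.data$n_unique, 0L),
                  unique_fraction = .data$n_unique / .data$n_total,
                  rank = factor(.data$rank, levels = tax_ranks())) |>
    dplyr::arrange(.data$rank, .data$taxon_key) |>
    dplyr::mutate(rank = as.character(.data$rank))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of a `nog_db`
#'
#' @param x A `nog_db`.
#' @param ... Unused.
#' @return The per-taxon summary table of [db_summary()].
#' @method tidy nog_db
#' @export
tidy.nog_db <- function(x, ...) db_summary(x)

#' One-row overview of a `nog_db`
#'
#' @param x A `nog_db`.
#' @param ... Unused.
#' @return Tibble with `n_genomes`, `min_genes`, `n_taxa`,
#'   `n_unique_pairs`, `n_total_pairs`.
#' @method glance nog_db
#' @export
glance.nog_db <- function(x, ...) {
  tibble::tibble(
    n_genomes = x$meta$n_genomes,
    min_genes = x$meta$min_genes,
    n_taxa = nrow(dplyr::distinct(x$total, .data$rank, .data$taxon_key)),
    n_unique_pairs = nrow(x$unique),
    n_total_pairs = nrow(x$total)
  )
}

#' Plot unique-NOG fractions per rank
#'
#' Box/jitter display of the fraction of each taxon's NOG repertoire that
#' is specific to it, by rank — deeper ranks typically carry smaller
#' specific fractions.
#'
#' @param object A `nog_db`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot nog_db
#' @export
autoplot.nog_db <- function(object, ...) {
  s <- db_summary(object)
  s$rank <- factor(s$rank, levels = tax_ranks())
  ggplot2::ggplot(s, ggplot2::aes(x = .data$rank, y = .data$unique_fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "taxon-specific fraction of NOG repertoire") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Write a database to a directory
#'
#' One TSV per rank and table (`unique_<rank>.tsv`, `total_<rank>.tsv`,
#' columns `rank`, `taxon_key`, `nog_id`) plus `meta.json`.  Output is
#' byte-deterministic for a given database.
#'
#' @param db A `nog_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_db <- function(db, dir) {
  stopifnot(inherits(db, "nog_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tbl in c("unique", "total")) {
    for (rk in tax_ranks()) {
      part <- dplyr::filter(db[[tbl]], .data$rank == rk) |>
        dplyr::arrange(.data$taxon_key, .data$nog) |>
        dplyr::rename(nog_id = "nog")
      readr::write_tsv(part, file.path(dir, paste0(tbl, "_", rk, ".tsv")),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(db$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a database written by [write_db()]
#'
#' @param dir Database directory.
#' @return A `nog_db`; its invariants are re-checked on load.
#' @export
read_db <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a taxon-specific NOG database directory (missing ", meta_path, ")",
         call. = FALSE)
  }
  read_part <- function(tbl) {
    purrr::map(tax_ranks(), function(rk) {
      readr::read_tsv(file.path(dir, paste0(tbl, "_", rk, ".tsv")),
                      col_types = "ccc", progress = FALSE)
    }) |>
      dplyr::bind_rows() |>
      dplyr::rename(nog = "nog_id")
  }
  db <- structure(list(unique = read_part("unique"), total = read_part("total"),
                       meta = jsonlite::read_json(meta_path, simplifyVector = TRUE)),
                  class = "nog_db")
  check_db(db)
  db
}
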