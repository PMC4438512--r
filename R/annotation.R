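#' Genome profiles
#'
#' A genome profile records the deduplicated set of orthologous-group
#' (NOG) identifiers observed in a genome, plus the pre-deduplication gene
#' total and the fraction of genes that received a NOG.  Profiles travel as
#' a tibble with one row per genome and columns:
#'
#' * `genome_id` — genome identifier,
#' * `gene_count` — number of protein-coding genes (pre-dedup),
#' * `assigned_fraction` — proportion of genes with a mapped NOG,
#' * `nogs` — list-column of character vectors (each a set, no duplicates).
#'
#' @param genome_id,gene_count,assigned_fraction,nogs Per-genome fields;
#'   `nogs` is a list of character vectors and is deduplicated and sorted.
#' @return A profiles tibble.
#' @export
new_profiles <- function(genome_id, gene_count, assigned_fraction, nogs) {
  nogs <- purrr::map(nogs, function(v) sort(unique(as.character(v))))
  out <- tibble::tibble(
    genome_id = as.character(genome_id),
    gene_count = as.integer(gene_count),
    assigned_fraction = as.numeric(assigned_fraction),
    nogs = nogs
  )
  bad <- lengths(out$nogs) > out$gene_count
  if (any(bad)) {
    stop("profile(s) with more NOGs than genes: ",
         paste(out$genome_id[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Read NCBI BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column tabular alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) and returns the hit columns the best-hit selector
#' needs.
#'
#' @param path Path to an uncompressed outfmt-6 file (no header).
#' @return Tibble with columns `gene_id`, `subject_id`, `e_value`,
#'   `bit_score`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- readr::read_tsv(path, col_names = cols,
                        col_types = "ccdiiiiiiidd", progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop("malformed alignment row at line ", probs$row[1], " of ", path,
         call. = FALSE)
  }
  tibble::tibble(gene_id = df$qseqid, subject_id = df$sseqid,
                 e_value = df$evalue, bit_score = df$bitscore)
}

#' Read a NOG members/functions catalog
#'
#' The catalog maps subject protein ids to NOG ids and NOG ids to COG
#' functional-category letters.  Expected TSV columns: `member_id`,
#' `nog_id`, `categories` (a string of single-letter codes; may be empty
#' or missing — missing stays missing, the placeholder "S" is never
#' auto-assigned).
#'
#' @param path Path to the tab-separated catalog with a header row.
#' @return Tibble with columns `member_id`, `nog_id`, `categories`.
#' @export
read_nog_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("member_id", "nog_id")
  if (!all(need %in% names(df))) {
    stop("catalog must have columns member_id and nog_id", call. = FALSE)
  }
  if (!"categories" %in% names(df)) df$categories <- NA_character_
  df$categories[!is.na(df$categories) & df$categories == ""] <- NA_character_
  tibble::as_tibble(df[c("member_id", "nog_id", "categories")])
}

#' Assign NOGs to one genome from best alignment hits
#'
#' For each gene, the hit with the maximal bit score is kept (ties broken
#' by lower e-value, then lexicographically smallest subject id, so the
#' result is a pure function of the hit multiset) and the subject's NOG is
#' transferred.  Each NOG enters the genome's set only once.
#'
#' @param hits Tibble of alignment hits with columns `gene_id`,
#'   `subject_id`, `bit_score`, `e_value` (e.g. from [read_blast_tab()]).
#' @param catalog Members catalog from [read_nog_catalog()].
#' @param genome_id Genome identifier for the resulting profile.
#' @param gene_count Total protein-coding genes in the genome (must be at
#'   least the number of distinct genes in `hits`).
#' @param max_evalue Optional e-value ceiling applied before best-hit
#'   selection (default `1e-5`; set `Inf` to disable).
#' @return A one-row profiles tibble (see [new_profiles()]);
#'   `assigned_fraction` is the share of genes whose best hit mapped to a
#'   catalog NOG.  Genes whose best subject is absent from the catalog are
#'   counted unassigned and reported in a message.
#' @export
assign_nogs <- function(hits, catalog, genome_id, gene_count,
                        max_evalue = 1e-5) {
  stopifnot(is.finite(gene_count), gene_count >= 0)
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) > 0L) {
    stopifnot(all(is.finite(hits$bit_score)), all(hits$e_value >= 0))
    hits <- dplyr::filter(hits, .data$e_value <= max_evalue)
  }
  n_genes_hit <- dplyr::n_distinct(hits$gene_id)
  if (gene_count < n_genes_hit) {
    stop("gene_count (", gene_count, ") below number of distinct genes with hits (",
         n_genes_hit, ")", call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(new_profiles(genome_id, gene_count, 0, list(character(0))))
  }
  best <- hits |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$bit_score),
                   .data$e_value, .data$subject_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  mapped <- dplyr::left_join(best, catalog[c("member_id", "nog_id")],
                             by = c(subject_id = "member_id"))
  n_unmapped <- sum(is.na(mapped$nog_id))
  if (n_unmapped > 0L) {
    message(genome_id, ": ", n_unmapped,
            " gene(s) with best hits absent from the catalog; counted unassigned")
  }
  nogs <- unique(mapped$nog_id[!is.na(mapped$nog_id)])
  new_profiles(genome_id, gene_count,
               (nrow(mapped) - n_unmapped) / max(gene_count, 1L),
               list(nogs))
}

#' Filter genomes by minimum gene count
#'
#' Reference genomes below a minimum gene total are excluded from database
#' construction.  The default of 475 is the smallest gene repertoire known
#' for a free-living bacterium (*Mycoplasma genitalium*); the boundary is
#' inclusive (a genome with exactly 475 genes is kept).
#'
#' @param profiles A profiles tibble.
#' @param min_genes Inclusive lower bound on `gene_count` (default 475).
#' @return List with elements `kept` (a profiles tibble) and `dropped`
#'   (the excluded rows plus a `reason` column).
#' @export
filter_genomes <- function(profiles, min_genes = 475L) {
  keep <- profiles$gene_count >= min_genes
  dropped <- profiles[!keep, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    dropped$reason <- paste0("gene_count ", dropped$gene_count, " < ", min_genes)
  } else {
    dropped$reason <- character(0)
  }
  list(kept = profiles[keep, , drop = FALSE], dropped = dropped)
}

#' Read a gene-to-NOG table
#'
#' The simplest annotation interchange: one row per gene with its assigned
#' NOG.  TSV columns: `genome_id`, `gene_id`, `nog_id` (header row).
#'
#' @param path Path to the tab-separated file.
#' @return Tibble with the three columns.  Malformed rows (wrong field
#'   count) error with the offending line number; duplicate
#'   `(genome_id, gene_id)` rows carrying conflicting NOGs error.
#' @export
read_gene2nog <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop("malformed gene2nog row at line ", which(nf != 3L)[1], " of ", path,
         ": expected 3 tab-separated columns, found ", nf[nf != 3L][1],
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  df <- tibble::tibble(genome_id = m[, 1], gene_id = m[, 2], nog_id = m[, 3])
  if (identical(unname(unlist(df[1, ])), c("genome_id", "gene_id", "nog_id"))) {
    df <- df[-1, , drop = FALSE]
  }
  conflict <- df |>
    dplyr::distinct() |>
    dplyr::count(.data$genome_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflict) > 0L) {
    stop("conflicting NOG assignments for gene(s): ",
         paste(paste0(conflict$genome_id, "/", conflict$gene_id)[
           seq_len(min(5L, nrow(conflict)))], collapse = ", "),
         call. = FALSE)
  }
  dplyr::distinct(df)
}

#' Build genome profiles from a gene-to-NOG table
#'
#' Collapses per-gene assignments into per-genome NOG sets (each NOG
#' counted once per genome).  The result is deterministic regardless of
#' input row order.
#'
#' @param gene2nog Tibble with columns `genome_id`, `gene_id`, `nog_id`
#'   (e.g. from [read_gene2nog()]).
#' @param gene_counts Optional tibble `genome_id`, `gene_count` giving the
#'   true pre-annotation gene totals; when absent, the number of distinct
#'   annotated genes is used and `assigned_fraction` is 1.
#' @return A profiles tibble sorted by `genome_id`.
#' @export
profiles_from_gene2nog <- function(gene2nog, gene_counts = NULL) {
  per <- gene2nog |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(n_genes_assigned = dplyr::n_distinct(.data$gene_id),
                     nogs = list(sort(unique(.data$nog_id))),
                     .groups = "drop")
  if (is.null(gene_counts)) {
    per$gene_count <- per$n_genes_assigned
  } else {
    per <- dplyr::left_join(per, gene_counts, by = "genome_id")
    if (anyNA(per$gene_count)) {
      stop("gene_counts missing for genome(s): ",
           paste(per$genome_id[is.na(per$gene_count)], collapse = ", "),
           call. = FALSE)
    }
  }
  per <- dplyr::arrange(per, .data$genome_id)
  new_profiles(per$genome_id, per$gene_count,
               per$n_genes_assigned / pmax(per$gene_count, 1L), per$nogs)
}

#' Load genome profiles from a file
#'
#' One entry point over the two supported annotation dialects.
#'
#' @param path For `"gene2nog-tsv"`, the gene-to-NOG TSV.  For
#'   `"blast-tab"`, a single-genome outfmt-6 alignment file.
#' @param format `"gene2nog-tsv"` (default) or `"blast-tab"`.
#' @param catalog Members catalog, required for `"blast-tab"`.
#' @param genome_id,gene_count Required for `"blast-tab"` (the alignment
#'   file carries neither).
#' @param ... Passed on to [assign_nogs()] (e.g. `max_evalue`).
#' @return A profiles tibble.
#' @export
load_profiles <- function(path, format = c("gene2nog-tsv", "blast-tab"),
                          catalog = NULL, genome_id = NULL,
                          gene_count = NULL, ...) {
  format <- match.arg(format)
  if (format == "gene2nog-tsv") {
    profiles_from_gene2nog(read_gene2nog(path))
  } else {
    if (is.null(catalog) || is.null(genome_id) || is.null(gene_count)) {
      stop("blast-tab loading needs catalog, genome_id and gene_count",
           call. = FALSE)
    }
    assign_nogs(read_blast_tab(path), catalog, genome_id, gene_count, ...)
  }
}

#' Count sequences in a protein FASTA file
#'
#' Convenience reader used to obtain `gene_count` for alignment-based
#' annotation; also validates that ids are unique.
#'
#' @param path Uncompressed FASTA file.
#' @return Integer count of records.
#' @export
count_fasta_genes <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  ids <- sub("^>(\\S+).*$", "\\1", lines[startsWith(lines, ">")])
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  length(ids)
}
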