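#' The six taxonomic ranks, shallowest first
#'
#' The classifier operates over a fixed six-rank bacterial hierarchy from
#' phylum down to species.  Rank depth is the 0-based position in this
#' vector (phylum = 0, species = 5).
#'
#' @return Character vector `c("phylum", "class", "order", "family",
#'   "genus", "species")`.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c("phylum", "class", "order", "family", "genus", "species")
}

#' Depth of a rank (phylum = 0)
#'
#' @param rank Character vector of rank names.
#' @return Integer vector of depths 0..5.
#' @export
rank_depth <- function(rank) {
  d <- match(rank, tax_ranks()) - 1L
  if (anyNA(d)) {
    stop("unknown rank(s): ", paste(setdiff(rank, tax_ranks()), collapse = ", "),
         call. = FALSE)
  }
  d
}

next_rank <- function(rank) {
  d <- rank_depth(rank)
  if (d >= 5L) NA_character_ else tax_ranks()[d + 2L]
}

# Separator used inside taxon keys.  Taxon identity is the full lineage
# prefix, so two genera with the same name under different families are
# distinct taxa.
.key_sep <- "|"

#' Taxon key for a lineage at a rank
#'
#' A taxon is identified by its full lineage prefix (labels from phylum
#' through `rank`, joined by `"|"`), never by the bare name: homonymous
#' taxon names under different parents stay distinct.
#'
#' @param lineages A lineage tibble (columns `genome_id`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`; `NA` marks an
#'   unknown rank) or a named character vector / one-row data frame.
#' @param rank One of [tax_ranks()].
#' @return Character vector of keys such as `"Firmicutes|Bacilli"`.
#' @details Errors if any lineage is unknown at `rank` (a missing-rank
#'   condition).  Use the internal NA-tolerant variant when skipping
#'   partially classified genomes is intended.
#' @export
#' @examples
#' lin <- tibble::tibble(genome_id = "g1", phylum = "Firmicutes",
#'   class = "Bacilli", order = NA, family = NA, genus = NA, species = NA)
#' taxon_key(lin, "class")
taxon_key <- function(lineages, rank) {
  keys <- taxon_key_safe(lineages, rank)
  if (anyNA(keys)) {
    stop("lineage unknown at rank '", rank, "' for ",
         sum(is.na(keys)), " genome(s)", call. = FALSE)
  }
  keys
}

# NA-tolerant taxon key: NA where the lineage is unknown at `rank`.
taxon_key_safe <- function(lineages, rank) {
  lineages <- as_lineage_tbl(lineages)
  d <- rank_depth(rank)
  cols <- tax_ranks()[seq_len(d + 1L)]
  m <- as.matrix(lineages[cols])
  keys <- apply(m, 1L, function(r) paste(r, collapse = .key_sep))
  keys[rowSums(is.na(m)) > 0L] <- NA_character_
  unname(keys)
}

parent_key <- function(key) {
  parts <- strsplit(key, .key_sep, fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) <= 1L) NA_character_ else paste(p[-length(p)], collapse = .key_sep)
  }, character(1))
}

last_label <- function(key) {
  vapply(strsplit(key, .key_sep, fixed = TRUE),
         function(p) p[length(p)], character(1))
}

as_lineage_tbl <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble::as_tibble(as.list(x))
  }
  x <- tibble::as_tibble(x)
  missing <- setdiff(tax_ranks(), names(x))
  for (col in missing) x[[col]] <- NA_character_
  x
}

#' Validate a lineage table
#'
#' Enforces the structural rules a reference lineage table must satisfy:
#' every genome has a known phylum, and unknown ranks have no gaps (once a
#' rank is unknown, all deeper ranks are unknown too).  Taxon names are
#' whitespace-normalized (trimmed, internal runs collapsed) and compared
#' case-sensitively.
#'
#' @param lineages Tibble with columns `genome_id` plus the six rank
#'   columns; `NA` or empty strings mark unknown ranks.
#' @return The valid rows as a tibble, with rejected rows (and a `reason`
#'   column) attached as attribute `"rejected"`.  A warning reports the
#'   rejected count.
#' @export
validate_lineages <- function(lineages) {
  lineages <- as_lineage_tbl(lineages)
  if (!"genome_id" %in% names(lineages)) {
    stop("lineage table must have a 'genome_id' column", call. = FALSE)
  }
  for (col in tax_ranks()) {
    v <- stringr::str_squish(as.character(lineages[[col]]))
    v[!is.na(v) & v == ""] <- NA_character_
    lineages[[col]] <- v
  }

  m <- as.matrix(lineages[tax_ranks()])
  known <- !is.na(m)
  # no-gap: the known flags must be non-increasing left to right
  gap <- apply(known, 1L, function(r) any(diff(as.integer(r)) > 0L))
  no_phylum <- !known[, 1L]
  dup_id <- duplicated(lineages$genome_id) |
    duplicated(lineages$genome_id, fromLast = TRUE)

  reason <- dplyr::case_when(
    no_phylum ~ "unknown phylum",
    gap ~ "gap in lineage (known rank below an unknown one)",
    dup_id ~ "duplicate genome_id",
    .default = NA_character_
  )
  bad <- !is.na(reason)
  rejected <- dplyr::mutate(lineages[bad, ], reason = reason[bad])
  if (any(bad)) {
    warning(sum(bad), " lineage row(s) rejected (",
            paste(unique(reason[bad]), collapse = "; "), ")", call. = FALSE)
  }
  out <- lineages[!bad, c("genome_id", tax_ranks())]
  attr(out, "rejected") <- rejected
  out
}

#' Parse Greengenes-style lineage strings
#'
#' Converts rank-prefixed strings such as
#' `"p__Firmicutes; c__Bacilli; o__Bacillales"` into the package's wide
#' lineage layout.  Prefixes with empty values (`"g__"`) and missing
#' ranks become `NA`.
#'
#' @param genome_id Character vector of genome identifiers.
#' @param lineage_string Character vector of the same length.
#' @return A lineage tibble (columns `genome_id` + the six ranks),
#'   validated with [validate_lineages()].
#' @export
#' @examples
#' parse_greengenes("g1", "p__Firmicutes; c__Bacilli")
parse_greengenes <- function(genome_id, lineage_string) {
  stopifnot(length(genome_id) == length(lineage_string))
  prefixes <- c(phylum = "p", class = "c", order = "o",
                family = "f", genus = "g", species = "s")
  rows <- purrr::map2(genome_id, lineage_string, function(id, s) {
    fields <- stringr::str_split_1(s, ";")
    fields <- stringr::str_squish(fields)
    fields <- fields[fields != ""]
    labels <- stats::setNames(rep(NA_character_, 6L), names(prefixes))
    for (f in fields) {
      m <- stringr::str_match(f, "^([a-zA-Z])__(.*)$")
      if (is.na(m[1, 1])) next
      rk <- names(prefixes)[prefixes == tolower(m[1, 2])]
      if (length(rk) == 1L && nzchar(m[1, 3])) labels[rk] <- m[1, 3]
    }
    tibble::as_tibble_row(c(genome_id = id, as.list(labels)))
  })
  validate_lineages(dplyr::bind_rows(rows))
}

#' Read a lineage table from TSV
#'
#' Expects columns `genome_id, phylum, class, order, family, genus,
#' species`, or the two-column form `genome_id, lineage` holding
#' Greengenes-style strings.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A validated lineage tibble.
#' @export
read_lineages <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (all(c("genome_id", "lineage") %in% names(df)) &&
      !all(tax_ranks() %in% names(df))) {
    return(parse_greengenes(df$genome_id, df$lineage))
  }
  validate_lineages(df)
}
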