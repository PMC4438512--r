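#' Classifier configuration
#'
#' Tunables of the hierarchical maximum-match descent.
#'
#' @param tie_threshold Runner-up/best match-count ratio at or above which
#'   the decision is deferred to the next rank (default 0.30; must lie
#'   strictly between 0 and 1).
#' @param lookahead_depth How many ranks a deferred decision may descend
#'   before falling back to the raw maximum (default 1, the stepwise
#'   rule).  Regardless of depth, a deferral chain starting at phylum or
#'   class never scores below the order rank.
#' @param min_matches Minimum taxon-specific NOG matches required to
#'   assign a rank at all (default 1); below it the rank — and every
#'   deeper rank — is `UNCLASSIFIED`.
#' @param tie_ranks Ranks at which the deferral rule is active.  Default
#'   phylum through genus; set `c("phylum", "class")` for the literal
#'   two-rank behaviour.  Species never defers (it has no child rank).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(tie_threshold = 0.30, lookahead_depth = 1L,
                              min_matches = 1L,
                              tie_ranks = tax_ranks()[1:5]) {
  stopifnot(tie_threshold > 0, tie_threshold < 1,
            lookahead_depth >= 1L, min_matches >= 1L,
            all(tie_ranks %in% tax_ranks()))
  structure(list(tie_threshold = tie_threshold,
                 lookahead_depth = as.integer(lookahead_depth),
                 min_matches = as.integer(min_matches),
                 tie_ranks = tie_ranks),
            class = "classifier_config")
}

#' Label used for ranks without an assignment
#' @export
UNCLASSIFIED <- "UNCLASSIFIED"

# Fast lookup structure: idx$unique[[rank]][[taxon_key]] -> character
# vector of taxon-specific NOGs; idx$taxa[[rank]] -> all taxon keys known
# at that rank (from the total table, so zero-evidence taxa still appear
# as candidates).
db_index <- function(db) {
  stopifnot(inherits(db, "nog_db"))
  uni <- lapply(split(db$unique, db$unique$rank), function(d) {
    split(d$nog, d$taxon_key)
  })
  taxa <- lapply(split(db$total, db$total$rank), function(d) {
    sort(unique(d$taxon_key))
  })
  structure(list(unique = uni, taxa = taxa), class = "nog_db_index")
}

as_db_index <- function(db) {
  if (inherits(db, "nog_db_index")) db else db_index(db)
}

#' Match counts of a query against taxon-specific sets at a rank
#'
#' For every candidate taxon at `rank` (optionally restricted to the
#' children of a parent taxon), counts how many of the query's NOGs fall
#' in that taxon's specific set.  Taxa known at the rank but with no
#' specific NOGs matched score 0 and are still listed.
#'
#' @param query_nogs Character vector (set) of query NOG ids.
#' @param db A `nog_db` (or a prebuilt internal index).
#' @param rank One of [tax_ranks()].
#' @param restrict_to Optional parent taxon key; only its children are
#'   scored.
#' @return Tibble `taxon_key`, `match_count`, sorted by count descending
#'   then key ascending (a deterministic order).
#' @export
match_counts <- function(query_nogs, db, rank, restrict_to = NULL) {
  idx <- as_db_index(db)
  cand <- idx$taxa[[rank]]
  if (is.null(cand)) cand <- character(0)
  if (!is.null(restrict_to)) {
    cand <- cand[startsWith(cand, paste0(restrict_to, .key_sep))]
  }
  if (length(cand) == 0L) {
    return(tibble::tibble(taxon_key = character(0), match_count = integer(0)))
  }
  usets <- idx$unique[[rank]]
  counts <- vapply(cand, function(k) {
    s <- usets[[k]]
    if (is.null(s)) 0L else sum(s %in% query_nogs)
  }, integer(1))
  tibble::tibble(taxon_key = cand, match_count = unname(counts)) |>
    dplyr::arrange(dplyr::desc(.data$match_count), .data$taxon_key)
}

# Deferred decision: score the children of all tied parents jointly at
# the next rank; the winning child elects its own parent.  Returns NULL
# when there is no child evidence (caller falls back to the raw best),
# otherwise list(parent=, resolved_rank=).
lookahead_winner <- function(query_nogs, idx, rank, parents, cfg,
                             depth_left, start_rank) {
  nr <- next_rank(rank)
  if (is.na(nr)) return(NULL)
  mc <- dplyr::bind_rows(lapply(parents, function(p) {
    match_counts(query_nogs, idx, nr, restrict_to = p)
  })) |>
    dplyr::arrange(dplyr::desc(.data$match_count), .data$taxon_key)
  if (nrow(mc) == 0L || mc$match_count[1] < 1L) return(NULL)
  c1 <- mc$match_count[1]
  c2 <- if (nrow(mc) >= 2L) mc$match_count[2] else 0L
  still_tied <- c2 / c1 >= cfg$tie_threshold
  # a chain starting at phylum/class stops scoring at the order rank
  capped <- rank_depth(start_rank) <= 1L && rank_depth(nr) >= 2L
  if (still_tied && depth_left > 1L && !capped) {
    deeper <- lookahead_winner(query_nogs, idx, nr, mc$taxon_key[1:2], cfg,
                               depth_left - 1L, start_rank)
    if (!is.null(deeper)) {
      # lift the deep winner back to the rank being decided
      key <- deeper$parent
      while (length(strsplit(key, .key_sep, fixed = TRUE)[[1]]) >
             rank_depth(rank) + 1L) {
        key <- parent_key(key)
      }
      return(list(parent = key, resolved_rank = deeper$resolved_rank))
    }
  }
  if (still_tied && c1 == c2) {
    warning("exact match-count tie at rank ", nr,
            " resolved lexicographically (", mc$taxon_key[1], ")",
            call. = FALSE)
  }
  list(parent = parent_key(mc$taxon_key[1]), resolved_rank = nr)
}

#' Decide one rank of the descent
#'
#' Scores all candidate taxa at `rank` (children of `parent`, or all taxa
#' at phylum) and applies the deferral rule: when the runner-up's match
#' count reaches `tie_threshold` of the best (second/best ratio, default
#' ≥ 0.30), the children of both candidates are scored at the next rank
#' and the winning child's parent is chosen.  With no child evidence the
#' raw best stands; exact count ties break lexicographically with a
#' warning.  Below `min_matches` the rank is `UNCLASSIFIED`.
#'
#' @inheritParams match_counts
#' @param parent Taxon key chosen at the previous rank (`NULL` at
#'   phylum).
#' @param cfg A [classifier_config()].
#' @return List: `candidates` (the match-count table), `chosen` (taxon
#'   key or `UNCLASSIFIED`), `match_count`, `runner_up`,
#'   `runner_up_count`, `tie_triggered`, `resolved_by` (the rank whose
#'   counts settled the decision).
#' @export
resolve_rank <- function(query_nogs, db, rank, parent = NULL,
                         cfg = classifier_config()) {
  idx <- as_db_index(db)
  mc <- match_counts(query_nogs, idx, rank, restrict_to = parent)
  out <- list(candidates = mc, chosen = UNCLASSIFIED, match_count = 0L,
              runner_up = NA_character_, runner_up_count = 0L,
              tie_triggered = FALSE, resolved_by = rank)
  if (nrow(mc) == 0L || mc$match_count[1] < cfg$min_matches) {
    return(out)
  }
  out$match_count <- mc$match_count[1]
  if (nrow(mc) >= 2L) {
    out$runner_up <- mc$taxon_key[2]
    out$runner_up_count <- mc$match_count[2]
  }
  ratio <- out$runner_up_count / out$match_count
  defer <- ratio >= cfg$tie_threshold && rank %in% cfg$tie_ranks &&
    !is.na(next_rank(rank))
  if (defer) {
    out$tie_triggered <- TRUE
    la <- lookahead_winner(query_nogs, idx, rank, mc$taxon_key[1:2], cfg,
                           cfg$lookahead_depth, start_rank = rank)
    if (!is.null(la)) {
      out$chosen <- la$parent
      out$resolved_by <- la$resolved_rank
      out$match_count <- mc$match_count[match(out$chosen, mc$taxon_key)]
      other <- setdiff(mc$taxon_key[1:2], out$chosen)
      out$runner_up <- other[1]
      out$runner_up_count <- mc$match_count[match(other[1], mc$taxon_key)]
      return(out)
    }
    if (out$runner_up_count == out$match_count) {
      warning("exact match-count tie at rank ", rank,
              " resolved lexicographically (", mc$taxon_key[1], ")",
              call. = FALSE)
    }
    out$chosen <- mc$taxon_key[1]
    return(out)
  }
  if (nrow(mc) >= 2L && mc$match_count[1] == mc$match_count[2]) {
    warning("exact match-count tie at rank ", rank,
            " resolved lexicographically (", mc$taxon_key[1], ")",
            call. = FALSE)
  }
  out$chosen <- mc$taxon_key[1]
  out
}

classify_one <- function(genome_id, nogs, idx, cfg) {
  rows <- vector("list", 6L)
  parent <- NULL
  dead <- FALSE
  for (i in seq_along(tax_ranks())) {
    rk <- tax_ranks()[i]
    if (dead) {
      dec <- list(chosen = UNCLASSIFIED, match_count = 0L,
                  runner_up = NA_character_, runner_up_count = 0L,
                  tie_triggered = FALSE, resolved_by = rk)
    } else {
      dec <- resolve_rank(nogs, idx, rk, parent, cfg)
    }
    rows[[i]] <- tibble::tibble(
      genome_id = genome_id, rank = rk, assigned = dec$chosen,
      assigned_name = if (identical(dec$chosen, UNCLASSIFIED))
        UNCLASSIFIED else last_label(dec$chosen),
      match_count = as.integer(dec$match_count),
      runner_up = dec$runner_up,
      runner_up_count = as.integer(dec$runner_up_count),
      tie_triggered = dec$tie_triggered, resolved_by = dec$resolved_by)
    if (identical(dec$chosen, UNCLASSIFIED)) dead <- TRUE else parent <- dec$chosen
  }
  dplyr::bind_rows(rows)
}

#' Classify query genomes against a taxon-specific NOG database
#'
#' Hierarchical maximum-match descent: the phylum whose specific NOG set
#' shares the most members with the query is selected, then — within it —
#' the best class, order, family, genus and species in turn.  At each
#' rank the deferral rule of [resolve_rank()] guards against close
#' runner-ups.  Descent stops at the first rank with fewer than
#' `min_matches` specific-NOG matches; that rank and all deeper ranks are
#' reported `UNCLASSIFIED`.  The species assignment names the closest
#' known species by gene content and is best treated as advisory;
#' assignments down to genus are the method's reliable range.
#'
#' @param profiles A profiles tibble (one row per query genome).
#' @param db A `nog_db`.
#' @param cfg A [classifier_config()].
#' @return Tibble with one row per genome and rank: `genome_id`, `rank`,
#'   `assigned` (full taxon key or `"UNCLASSIFIED"`), `assigned_name`
#'   (the rank's own label), `match_count`, `runner_up`,
#'   `runner_up_count`, `tie_triggered`, `resolved_by`.
#' @export
#' @examples
#' sim <- simulate_taxonomy(sim_config(children = c(2, 2, 1, 1, 1, 1),
#'   genomes_per_species = 2, seed = 7))
#' db <- build_db(sim$profiles, sim$lineages, min_genes = 0)
#' classify(sim$profiles[1, ], db)
classify <- function(profiles, db, cfg = classifier_config()) {
  idx <- as_db_index(db)
  empty <- lengths(profiles$nogs) == 0L
  if (any(empty)) {
    warning("query genome(s) with empty NOG set are fully UNCLASSIFIED: ",
            paste(profiles$genome_id[empty], collapse = ", "), call. = FALSE)
  }
  purrr::map2(profiles$genome_id, profiles$nogs,
              function(id, nogs) classify_one(id, nogs, idx, cfg)) |>
    dplyr::bind_rows()
}

#' Per-rank accuracy of classifications against known lineages
#'
#' Compares assignments with truth taxon keys rank by rank.  Accuracy is
#' the fraction of queries (with known truth at the rank) whose assigned
#' taxon equals the truth; `UNCLASSIFIED` queries count as incorrect and
#' are also tallied separately.
#'
#' @param results Classification tibble from [classify()].
#' @param truth Lineage tibble for the query genomes.
#' @return Tibble per rank: `n`, `n_correct`, `n_unclassified`,
#'   `accuracy`.
#' @export
evaluate_classification <- function(results, truth) {
  truth <- as_lineage_tbl(truth)
  truth_long <- purrr::map(tax_ranks(), function(rk) {
    tibble::tibble(genome_id = truth$genome_id, rank = rk,
                   truth_key = taxon_key_safe(truth, rk))
  }) |>
    dplyr::bind_rows()
  results |>
    dplyr::inner_join(truth_long, by = c("genome_id", "rank")) |>
    dplyr::filter(!is.na(.data$truth_key)) |>
    dplyr::group_by(rank = factor(.data$rank, levels = tax_ranks())) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(.data$assigned == .data$truth_key),
      n_unclassified = sum(.data$assigned == UNCLASSIFIED),
      accuracy = .data$n_correct / .data$n,
      .groups = "drop") |>
    dplyr::arrange(.data$rank) |>
    dplyr::mutate(rank = as.character(.data$rank))
}

#' Plot per-rank classification accuracy
#'
#' @param eval_tbl Output of [evaluate_classification()].
#' @return A ggplot bar chart of accuracy by rank.
#' @export
plot_accuracy <- function(eval_tbl) {
  eval_tbl$rank <- factor(eval_tbl$rank, levels = tax_ranks())
  ggplot2::ggplot(eval_tbl, ggplot2::aes(x = .data$rank, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "classification accuracy") +
    ggplot2::theme_minimal()
}

#' Write a classification report as TSV
#'
#' @param results Tibble from [classify()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_classification <- function(results, path) {
  readr::write_tsv(dplyr::arrange(results, .data$genome_id,
                                  match(.data$rank, tax_ranks())),
                   path, progress = FALSE)
  invisible(path)
}
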