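#' The 23 COG functional category letters
#'
#' Single-letter functional classes attached to orthologous groups
#' (e.g. `U` = intracellular trafficking and secretion, `S` = function
#' unknown).
#'
#' @return Character vector of the 23 letters.
#' @export
cog_categories <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M",
    "N", "O", "P", "Q", "S", "T", "U", "V", "W", "Z")
}

# nog_id -> categories lookup from a members catalog (which may list the
# same NOG on many member rows).
nog_category_map <- function(catalog) {
  catalog |>
    dplyr::filter(!is.na(.data$categories)) |>
    dplyr::distinct(.data$nog_id, .data$categories)
}

#' Functional-category profile of a NOG set
#'
#' Distributes the NOGs of a set over the 23 COG categories.  In the
#' default fractional mode a NOG annotated with `k` letters contributes
#' `1/k` to each, so proportions over categorized NOGs sum to exactly 1;
#' in `"each"` mode every letter receives a full count (proportions are
#' then over the letter total).  NOGs absent from the catalog, or present
#' without category letters, are counted as uncategorized and excluded
#' from the proportions.
#'
#' @param nogs Character vector (set) of NOG ids.
#' @param catalog Members catalog with `nog_id`, `categories` columns
#'   (see [read_nog_catalog()]).
#' @param mode `"fractional"` (default) or `"each"`.
#' @return Tibble `category`, `count`, `proportion` (only categories with
#'   nonzero weight), with attributes `set_size` (number of categorized
#'   NOGs) and `n_uncategorized`.
#' @export
#' @examples
#' cat <- tibble::tibble(member_id = c("m1", "m2"),
#'   nog_id = c("NOG_A", "NOG_B"), categories = c("U", "S"))
#' category_profile(c("NOG_A", "NOG_B"), cat)
category_profile <- function(nogs, catalog, mode = c("fractional", "each")) {
  mode <- match.arg(mode)
  nogs <- unique(as.character(nogs))
  cmap <- nog_category_map(catalog)
  hit <- cmap[cmap$nog_id %in% nogs, , drop = FALSE]
  letters_per_nog <- strsplit(hit$categories, "", fixed = TRUE)
  letters_per_nog <- purrr::map(letters_per_nog,
                                function(l) intersect(unique(l), cog_categories()))
  keep <- lengths(letters_per_nog) > 0L
  letters_per_nog <- letters_per_nog[keep]
  set_size <- length(letters_per_nog)
  n_uncat <- length(nogs) - set_size
  if (set_size == 0L) {
    out <- tibble::tibble(category = character(0), count = numeric(0),
                          proportion = numeric(0))
  } else {
    w <- if (mode == "fractional") 1 / lengths(letters_per_nog)
         else rep(1, length(letters_per_nog))
    out <- tibble::tibble(
      category = unlist(letters_per_nog),
      count = rep(w, lengths(letters_per_nog))) |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
      dplyr::arrange(.data$category)
  }
  attr(out, "set_size") <- set_size
  attr(out, "n_uncategorized") <- n_uncat
  out
}

#' Category overabundance in a taxon-specific set
#'
#' Ratio of each category's proportion in the taxon-specific NOG set to
#' its proportion in the taxon-total set.  A ratio above 1 means the
#' category is overrepresented among the taxon's specific genes; ratios
#' are scale-invariant (doubling all counts changes nothing).  Categories
#' absent from the total set have an undefined ratio (`NA`).
#'
#' @param unique_profile,total_profile Category profiles from
#'   [category_profile()] for the taxon-specific and taxon-total sets.
#' @return Tibble `category`, `prop_unique`, `prop_total`, `ratio`, over
#'   all categories present in either profile.
#' @export
overabundance <- function(unique_profile, total_profile) {
  u <- dplyr::select(tibble::as_tibble(unique_profile),
                     "category", prop_unique = "proportion")
  t <- dplyr::select(tibble::as_tibble(total_profile),
                     "category", prop_total = "proportion")
  dplyr::full_join(u, t, by = "category") |>
    dplyr::mutate(
      prop_unique = dplyr::coalesce(.data$prop_unique, 0),
      ratio = dplyr::if_else(is.na(.data$prop_total) | .data$prop_total == 0,
                             NA_real_, .data$prop_unique / .data$prop_total)) |>
    dplyr::arrange(.data$category)
}

#' Count taxa whose category ratio exceeds a threshold
#'
#' For each category, how many taxa (typically phyla) show an
#' overabundance ratio strictly greater than `threshold` (default 1.2).
#'
#' @param ratios Long tibble with columns `taxon_key`, `category`,
#'   `ratio` — e.g. [funcat_table()] output.
#' @param threshold Strict lower bound on the ratio (default 1.2).
#' @return Tibble `category`, `n_taxa`, `n_above`.
#' @export
flag_abundant <- function(ratios, threshold = 1.2) {
  ratios |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_taxa = dplyr::n(),
                     n_above = sum(.data$ratio > threshold, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$category)
}

#' Exact enrichment test for one category
#'
#' Models the taxon-specific set as a draw (without replacement) from the
#' taxon-total set and asks whether the observed number of
#' category-carrying NOGs among the specific ones departs from the
#' hypergeometric expectation.  Two-sided: the p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param k_unique Category-carrying NOGs in the taxon-specific set.
#' @param n_unique Size of the taxon-specific set.
#' @param k_total Category-carrying NOGs in the taxon-total set.
#' @param n_total Size of the taxon-total set.
#' @return p-value in \[0, 1\]; degenerate tables (empty sets or a
#'   category absent from / filling the total set) give 1.
#' @export
#' @examples
#' enrichment_test(20, 20, 30, 300)  # all specific NOGs in a 10% category
enrichment_test <- function(k_unique, n_unique, k_total, n_total) {
  stopifnot(k_unique >= 0, n_unique >= 0, k_total >= 0, n_total >= 0,
            k_unique <= n_unique, k_total <= n_total,
            n_unique <= n_total, k_unique <= k_total)
  if (n_unique == 0L || n_total == 0L || k_total == 0L || k_total == n_total) {
    return(1)
  }
  x <- max(0L, n_unique - (n_total - k_total)):min(k_total, n_unique)
  d <- stats::dhyper(x, k_total, n_total - k_total, n_unique)
  d_obs <- stats::dhyper(k_unique, k_total, n_total - k_total, n_unique)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Per-taxon functional overabundance table
#'
#' For every taxon at `rank`, profiles both its total and its
#' taxon-specific NOG set over the 23 COG categories, forms the
#' specific/total proportion ratio, and attaches the exact enrichment
#' p-value (computed on whole-NOG membership counts: a NOG counts for a
#' category if any of its letters is that category).
#'
#' @param db A `nog_db`.
#' @param catalog Members catalog with category annotations.
#' @param rank Rank whose taxa are analysed (default `"phylum"`).
#' @param mode Category counting mode, see [category_profile()].
#' @return Tibble `taxon_key`, `category`, `prop_total`, `prop_unique`,
#'   `ratio`, `p_value`.
#' @export
funcat_table <- function(db, catalog, rank = "phylum",
                         mode = c("fractional", "each")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "nog_db"))
  cmap <- nog_category_map(catalog)
  taxa <- sort(unique(db$total$taxon_key[db$total$rank == rank]))
  purrr::map(taxa, function(tk) {
    tot_nogs <- db$total$nog[db$total$rank == rank & db$total$taxon_key == tk]
    uni_nogs <- db$unique$nog[db$unique$rank == rank & db$unique$taxon_key == tk]
    oa <- overabundance(category_profile(uni_nogs, catalog, mode),
                        category_profile(tot_nogs, catalog, mode))
    if (nrow(oa) == 0L) return(NULL)
    # membership counts for the exact test
    tot_m <- cmap[cmap$nog_id %in% tot_nogs, , drop = FALSE]
    uni_m <- cmap[cmap$nog_id %in% uni_nogs, , drop = FALSE]
    n_total <- nrow(tot_m)
    n_unique <- nrow(uni_m)
    oa$p_value <- vapply(oa$category, function(cc) {
      k_total <- sum(stringr::str_detect(tot_m$categories, stringr::fixed(cc)))
      k_unique <- sum(stringr::str_detect(uni_m$categories, stringr::fixed(cc)))
      enrichment_test(k_unique, n_unique, k_total, n_total)
    }, numeric(1))
    dplyr::mutate(oa, taxon_key = tk, .before = 1L)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("taxon_key", "category", "prop_total", "prop_unique",
                  "ratio", "p_value")
}

#' Plot specific-vs-total category proportions
#'
#' Side-by-side bars of each category's proportion in the taxon-total and
#' taxon-specific NOG sets, faceted by taxon.
#'
#' @param fc A [funcat_table()] tibble.
#' @return A ggplot object.
#' @export
plot_overabundance <- function(fc) {
  long <- tidyr::pivot_longer(fc, c("prop_total", "prop_unique"),
                              names_to = "set", names_prefix = "prop_",
                              values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$proportion,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$taxon_key)) +
    ggplot2::labs(x = "COG functional category", y = "proportion of NOGs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
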