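#' Run the simulate / build / classify / evaluate chain in one call
#'
#' Convenience wrapper over the individual stages, mirroring the
#' command-line pipeline: simulate a reference taxonomy, build the
#' taxon-specific database from it, classify either the training genomes
#' (self-test) or freshly drawn hold-out queries, and score per-rank
#' accuracy.
#'
#' @param cfg A [sim_config()].
#' @param holdout_frac Fraction of genomes excluded from the build and
#'   used as queries (0 = self-test on all training genomes).
#' @param drop_frac Specific-NOG drop applied to hold-out queries (see
#'   [make_query()]); ignored for the self-test.
#' @param query_noise Noise rate for hold-out queries (defaults to the
#'   simulation's own rate).
#' @param cfg_classifier A [classifier_config()].
#' @param min_genes Reference genome filter for the build (default 0 —
#'   synthetic genomes record a nominal gene total).
#' @param seed Seed for the hold-out split and query draws.
#' @return List: `sim`, `db`, `results` (classification tibble),
#'   `accuracy` (per-rank evaluation tibble).
#' @export
#' @examples
#' out <- run_pipeline(sim_config(children = c(2, 2, 1, 1, 1, 1),
#'   genomes_per_species = 2, seed = 3))
#' out$accuracy
run_pipeline <- function(cfg = sim_config(), holdout_frac = 0,
                         drop_frac = 0, query_noise = NULL,
                         cfg_classifier = classifier_config(),
                         min_genes = 0L, seed = cfg$seed) {
  sim <- simulate_taxonomy(cfg)
  if (is.null(query_noise)) query_noise <- cfg$noise_rate
  if (holdout_frac > 0) {
    n_out <- max(1L, round(holdout_frac * nrow(sim$profiles)))
    held <- withr::with_seed(seed, sample(sim$profiles$genome_id, n_out))
    train <- dplyr::filter(sim$profiles, !.data$genome_id %in% held)
    db <- build_db(train, sim$lineages, min_genes = min_genes)
    queries <- purrr::map(seq_along(held), function(i) {
      q <- make_query(sim, held[i], drop_frac = drop_frac,
                      noise_rate = query_noise, seed = seed + i)
      q$genome_id <- held[i]  # keep truth join trivial
      q
    }) |> dplyr::bind_rows()
  } else {
    db <- build_db(sim$profiles, sim$lineages, min_genes = min_genes)
    queries <- sim$profiles
  }
  results <- classify(queries, db, cfg_classifier)
  acc <- evaluate_classification(
    results, dplyr::filter(sim$lineages, .data$genome_id %in% queries$genome_id))
  list(sim = sim, db = db, results = results, accuracy = acc)
}
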