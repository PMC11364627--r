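#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end analysis. Any field left `NULL`
#' keeps its default.
#'
#' @param responses Path to the respondent CSV (see [read_responses()]).
#' @param indices Optional path to a country-index CSV
#'   (see [read_index_table()]); when absent the correlation screen is
#'   skipped.
#' @param out_dir Output directory; created if needed.
#' @param preprocess A [preprocess_config()].
#' @param k_range Candidate numbers of response types; default 2..12.
#' @param B Gap-statistic reference draws; default 50.
#' @param min_country_n Minimum respondents per country for fingerprinting;
#'   default 25.
#' @param seed Master seed; seeds the gap-statistic reference draws and, if
#'   the preprocess config carries no seed of its own, the jitter stream.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(responses, indices = NULL, out_dir = tempdir(),
                            preprocess = preprocess_config(),
                            k_range = 2:12, B = 50L, min_country_n = 25L,
                            seed = 20200901) {
  structure(list(responses = responses, indices = indices, out_dir = out_dir,
                 preprocess = preprocess, k_range = k_range,
                 B = as.integer(B), min_country_n = as.integer(min_country_n),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(log, stage, ...) {
  line <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  c(log, line)
}

#' Run the full response-type fingerprinting analysis
#'
#' Executes the pipeline end to end: read responses, impute missing items
#' (co-observed KNN), engineer the 6-dimensional features, jitter, select
#' the number of response types by the gap statistic, Ward-cluster, extract
#' profiles (on un-jittered features), compute country fingerprints and
#' their Ward dendrogram, and — when an index table is given — run the
#' Spearman screen. All artefacts are written to `out_dir` as CSV/Newick
#' together with a run log echoing the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param k Optional fixed number of response types; when given, gap-based
#'   model selection is skipped (the curve is still not computed).
#' @return List with `matrix`, `features`, `gap`, `k`, `labels`, `profiles`,
#'   `fingerprints`, `tree`, `association` (NULL without indices), `log`.
#' @export
run_pipeline <- function(config, k = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  log <- log_stage(log, "config", "seed=", config$seed, " B=", config$B,
                   " k_range=", paste(range(config$k_range), collapse = ".."),
                   " min_country_n=", config$min_country_n)

  mat <- read_responses(config$responses)
  log <- log_stage(log, "read", nrow(mat$items), " respondents, ",
                   sum(is.na(mat$items)), " missing cells")

  mat <- impute_knn(mat, config$preprocess)
  features <- engineer_features(mat)
  jittered <- jitter_features(features, config$preprocess)
  log <- log_stage(log, "preprocess", "k_nn=", config$preprocess$n_neighbors,
                   " jitter_var=", config$preprocess$jitter_variance)

  gap <- NULL
  if (is.null(k)) {
    gap <- gap_statistic(jittered, config$k_range, config$B,
                         seed = config$seed)
    k <- gap$selected_k
    utils::write.csv(data.frame(k = gap$k, log_W = gap$log_W,
                                gap = gap$gap, s = gap$s),
                     file.path(config$out_dir, "gap_curve.csv"),
                     row.names = FALSE)
    log <- log_stage(log, "model-selection", "selected k=", k)
  }

  raw_labels <- ward_cluster(jittered, k)
  profiles <- extract_profiles(features, raw_labels)
  relabel <- attr(profiles, "relabel")
  labels <- unname(relabel[as.character(raw_labels)])
  log <- log_stage(log, "cluster", "k=", k, " sizes=",
                   paste(profiles$size, collapse = "/"))
  utils::write.csv(profiles, file.path(config$out_dir, "profiles.csv"),
                   row.names = FALSE)

  fp <- withCallingHandlers(
    compute_fingerprints(labels, mat$country, k, config$min_country_n),
    warning = function(w) {
      log <<- log_stage(log, "fingerprint", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_fingerprints(fp, file.path(config$out_dir, "fingerprints.csv"))
  utils::write.csv(as.data.frame(fingerprint_distance(fp)),
                   file.path(config$out_dir, "fingerprint_distances.csv"))
  tree <- country_dendrogram(fp)
  write_newick(tree, file.path(config$out_dir, "country_tree.nwk"))
  log <- log_stage(log, "fingerprint", length(fp$countries),
                   " countries fingerprinted")

  assoc <- NULL
  if (!is.null(config$indices)) {
    assoc <- correlate_fingerprints(fp, read_index_table(config$indices))
    write_correlations(assoc, file.path(config$out_dir, "correlations.csv"))
    log <- log_stage(log, "associate", sum(assoc$cells$flagged),
                     " flagged cells over ", length(assoc$countries),
                     " countries")
  }

  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  list(matrix = mat, features = features, gap = gap, k = k,
       labels = labels, profiles = profiles, fingerprints = fp,
       tree = tree, association = assoc, log = log)
}

#' Simulate a study and write its files
#'
#' Generates a synthetic questionnaire population from a
#' [generator_config()], writes the respondent CSV in the pipeline's input
#' dialect, writes a synthetic index table (one index per response type plus
#' padding is not attempted — the five named indices are drawn against the
#' first five fingerprint components with the given target correlations),
#' and writes the ground truth (labels and generating fingerprints) for
#' evaluation.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory.
#' @param index_rhos Named numeric vector of target Spearman correlations
#'   for the synthetic indices `CO2, EPI, GBI, NIS, LPI` against fingerprint
#'   components 1..5; default 0.5 each. Indices are only written when the
#'   population has at least 5 countries.
#' @return Named list of written file paths.
#' @export
simulate_study <- function(config, out_dir,
                           index_rhos = c(CO2 = 0.5, EPI = 0.5, GBI = 0.5,
                                          NIS = 0.5, LPI = 0.5)) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- sample_questionnaires(config)
  paths <- list(responses = file.path(out_dir, "responses.csv"),
                truth_labels = file.path(out_dir, "truth_labels.csv"),
                truth_fingerprints = file.path(out_dir,
                                               "truth_fingerprints.csv"))
  write_responses(pop$matrix, paths$responses)
  utils::write.csv(pop$truth, paths$truth_labels, row.names = FALSE)
  k <- nrow(config$profiles)
  fp_true <- fingerprint_set(
    do.call(rbind, config$country_fingerprints),
    names(config$country_fingerprints))
  write_fingerprints(fp_true, paths$truth_fingerprints)
  if (length(config$country_fingerprints) >= 5L) {
    idx <- data.frame(country = fp_true$countries)
    for (j in seq_along(index_rhos)) {
      comp <- fp_true$matrix[, min(j, k)]
      idx[[names(index_rhos)[j]]] <-
        sample_index(stats::setNames(comp, fp_true$countries),
                     index_rhos[j], seed = config$seed + j)$index
    }
    paths$indices <- file.path(out_dir, "indices.csv")
    utils::write.csv(idx, paths$indices, row.names = FALSE)
  }
  paths
}
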