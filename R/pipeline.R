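# End-to-end driver: abundance series + community model -> abruptness,
# replicate coupling runs, per-day networks, hierarchy reports, centrality
# tables, community scores and transfer tables, with a machine-readable
# manifest. All tabular outputs are TSV; nested reports are JSON.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one validated,
#' serializable object. The configuration round-trips losslessly through
#' JSON, and its MD5 hash identifies a run in the manifest.
#'
#' @param window Abruptness window width in days (default 5).
#' @param tau Edge threshold on the mean coupling score (default 0).
#' @param n_runs Replicate coupling runs (default 10).
#' @param base_seed Seed of the first run (default 1).
#' @param mode Coupling mode: `"auto"`, `"exhaustive"` or `"montecarlo"`.
#' @param n_samples Monte-Carlo sample count per score (default 1000).
#' @param min_abundance Node detection threshold \eqn{\theta} (default 0:
#'   presence).
#' @param damping PageRank damping factor (default 0.85).
#' @param mro_denominator MRO denominator variant (default `"min"`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 5, tau = 0, n_runs = 10, base_seed = 1,
                            mode = c("auto", "exhaustive", "montecarlo"),
                            n_samples = 1000, min_abundance = 0,
                            damping = 0.85,
                            mro_denominator = c("min", "union", "mean")) {
  cfg <- list(
    window = check_count(window, "window"),
    tau = check_fraction(tau, "tau"),
    n_runs = check_count(n_runs, "n_runs"),
    base_seed = as.integer(check_nonneg(base_seed, "base_seed")),
    mode = match.arg(mode),
    n_samples = check_count(n_samples, "n_samples"),
    min_abundance = check_nonneg(min_abundance, "min_abundance"),
    damping = check_fraction(damping, "damping"),
    mro_denominator = match.arg(mro_denominator)
  )
  structure(cfg, class = "pipeline_config")
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path File path.
#' @return `read_config()` returns a validated [pipeline_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' MD5 hash identifying a configuration
#'
#' @param config A [pipeline_config()].
#' @return A hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # canonical serialization: fixed key order from the constructor
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

restrict_community <- function(model, ids) {
  ids <- check_species(model, ids)
  community_model(model$species[model$species$id %in% ids, ],
                  medium = model$medium, metabolites = model$metabolites)
}

#' Run the full facilitative-network pipeline
#'
#' Computes the abruptness series, performs the replicate coupling runs once
#' on the full community model, and then, for each requested day, restricts
#' the analysis to the species detected on that day: builds the directed
#' interaction network, its hierarchy report (treeness, feedforwardness,
#' orderability), centrality tables, community scores (MIP, MRO) and
#' metabolite-transfer tables. Days on which fewer than two species are
#' detected are skipped with a structured log record rather than an error.
#'
#' @param series Abundance series tibble.
#' @param model A [community_model()] covering the series' species (ids must
#'   match).
#' @param config A [pipeline_config()].
#' @param days Days to analyze (default: every day in the series).
#' @param out_dir Optional output directory; when given, all result tables,
#'   per-run coupling files and a `manifest.json` are written there.
#' @return An object of class `pipeline_result`: list with `abruptness`,
#'   `runs` (`coupling_runs`), `networks` (list keyed by day), `hierarchy`,
#'   `centrality`, `scores`, `transfers`, `skipped` (tibbles) and
#'   `manifest`.
#' @export
run_pipeline <- function(series, model, config = pipeline_config(),
                         days = NULL, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must be a pipeline_config")
  }
  validate_series(series)
  days <- as.integer(days %||% sort(unique(series$day)))
  abrupt <- abruptness(series, window = config$window)
  runs <- replicate_runs(model, n_runs = config$n_runs,
                         base_seed = config$base_seed, mode = config$mode,
                         n_samples = config$n_samples)
  networks <- list()
  hierarchy <- list()
  centrality <- list()
  scores <- list()
  transfers <- list()
  skipped <- list()
  for (day in days) {
    detected <- intersect(detect_nodes(series, day, config$min_abundance),
                          species_ids(model))
    if (length(detected) < 2) {
      skipped[[length(skipped) + 1L]] <- tibble(
        day = day, n_detected = length(detected), reason = "insufficient nodes")
      message(sprintf("[facilinet] day %d skipped: %d detected species",
                      day, length(detected)))
      next
    }
    net <- build_network(runs, tau = config$tau, detected = detected, day = day)
    networks[[as.character(day)]] <- net
    hierarchy[[length(hierarchy) + 1L]] <- glance(
      hierarchy_report(net, day = day))
    centrality[[length(centrality) + 1L]] <- centrality_report(
      net, damping = config$damping)
    sub <- restrict_community(model, detected)
    mip <- metabolic_interaction_potential(sub)
    mro <- metabolic_resource_overlap(sub, denominator = config$mro_denominator)
    scores[[length(scores) + 1L]] <- tibble(
      day = day, n_detected = length(detected),
      mip = as.numeric(mip), mip_status = attr(mip, "status"),
      mro = as.numeric(mro))
    tr <- transfer_attribution(model, members = detected)
    freq <- transfer_frequency(tr)
    if (nrow(freq) > 0) {
      freq$frequency <- freq$count / sum(freq$count)
    } else {
      freq$frequency <- numeric(0)
    }
    transfers[[length(transfers) + 1L]] <- mutate(freq, day = day, .before = 1)
  }
  empty_skip <- tibble(day = integer(), n_detected = integer(),
                       reason = character())
  result <- structure(
    list(
      abruptness = abrupt,
      runs = runs,
      networks = networks,
      hierarchy = bind_rows(hierarchy),
      centrality = bind_rows(centrality),
      scores = bind_rows(scores),
      transfers = bind_rows(transfers),
      skipped = if (length(skipped)) bind_rows(skipped) else empty_skip,
      manifest = list(
        package = "facilinet",
        version = as.character(utils::packageVersion("facilinet")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        config = unclass(config),
        config_hash = config_hash(config),
        seeds = runs$seeds,
        days_analyzed = setdiff(days, if (length(skipped)) bind_rows(skipped)$day else integer()),
        days_skipped = if (length(skipped)) bind_rows(skipped)$day else integer()
      )
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d day(s) analyzed, %d skipped; config %s\n",
              length(x$networks), nrow(x$skipped), x$manifest$config_hash))
  invisible(x)
}

#' Write every pipeline result table to a directory
#'
#' Writes `abruptness.tsv`, one `scs_run_<k>.tsv` per replicate run plus the
#' aggregate `scs_aggregate.tsv`, per-day network edge lists under
#' `networks/`, `hierarchy.tsv`, `centrality.tsv`, `community_scores.tsv`,
#' `transfers.tsv` (with standardized per-day frequencies) and
#' `manifest.json` naming the generating config hash. Re-running with the
#' same inputs and configuration reproduces the files identically.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
  readr::write_tsv(as_tibble(result$abruptness),
                   file.path(out_dir, "abruptness.tsv"))
  for (k in seq_along(result$runs$runs)) {
    run <- result$runs$runs[[k]]
    readr::write_tsv(run$scs, file.path(out_dir, sprintf("scs_run_%02d.tsv", k)))
  }
  readr::write_tsv(result$runs$summary, file.path(out_dir, "scs_aggregate.tsv"))
  for (day in names(result$networks)) {
    write_network_tsv(result$networks[[day]],
                      file.path(out_dir, "networks", sprintf("day_%s.tsv", day)))
  }
  readr::write_tsv(result$hierarchy, file.path(out_dir, "hierarchy.tsv"))
  readr::write_tsv(result$centrality, file.path(out_dir, "centrality.tsv"))
  readr::write_tsv(result$scores, file.path(out_dir, "community_scores.tsv"))
  readr::write_tsv(result$transfers, file.path(out_dir, "transfers.tsv"))
  readr::write_tsv(result$skipped, file.path(out_dir, "skipped.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
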