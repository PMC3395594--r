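# End-to-end orchestration: a single YAML config drives conservation
# scoring, site classification, statistics, mutation design, and kinetic
# fitting, with seeded determinism and plain TSV/JSON outputs.

.CONFIG_DEFAULTS <- list(cutoff = 6.0, rsasa_cutoff = 0.50,
                         conservation_threshold = 0.5,
                         frequency_threshold = 0.05, seed = 1L,
                         method = "jsd")

.CONFIG_RANGES <- list(cutoff = c(0, 30), rsasa_cutoff = c(0, 1.2),
                       conservation_threshold = c(0, 1),
                       frequency_threshold = c(0, 1))

#' Validate a pipeline configuration
#'
#' Reads a YAML config, applies defaults (6.0 Angstrom cutoff, 0.50 rSASA,
#' 0.5 conservation threshold, 0.05 frequency threshold, seed 1), and
#' range-checks thresholds. Input paths are checked at [run_pipeline] time.
#'
#' @param path YAML file, or a named list of settings.
#' @return Object of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (file.exists(path)) {
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  } else stop("config file not found: ", path)
  for (nm in names(.CONFIG_DEFAULTS))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- .CONFIG_DEFAULTS[[nm]]
  for (nm in names(.CONFIG_RANGES)) {
    r <- .CONFIG_RANGES[[nm]]
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < r[1] || v > r[2])
      stop(sprintf("range error: %s = %s outside permitted [%g, %g]",
                   nm, format(v), r[1], r[2]))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages for which the config names inputs: conservation
#' scoring of an MSA (`msa`, `query_id`), structural site classification
#' (`structure`, `ligand_roles`, optional `chain`), conservation statistics
#' and composition enrichment (when both are available), mutation design
#' (optionally with `outcomes`), and kinetic fitting of velocity CSVs
#' (`kinetics`, a named list of files). Outputs are written under
#' `out_dir` as TSV/JSON stamped with the seed and a config digest.
#'
#' @param config A `pipeline_config` (or path/list accepted by
#'   [validate_config]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (is.null(config$msa))
    stop("validation error: required field 'msa' (alignment FASTA) missing")
  for (f in c("msa", "structure", "outcomes")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("validation error: ", f, " path does not exist: ", config[[f]])
  }
  for (f in config$kinetics)
    if (!file.exists(f))
      stop("validation error: kinetics path does not exist: ", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  stamp <- list(schema_version = "1",
                seed = config$seed,
                config_md5 = unname(tools::md5sum(cfg_file)))
  unlink(cfg_file)
  results <- list(stamp = stamp)

  aln <- read_msa_fasta(config$msa, query_id = config$query_id)
  profile <- conservation_profile(aln, method = config$method)
  write_conservation_tsv(profile, file.path(out_dir, "conservation.tsv"))
  results$profile <- profile

  annotation <- NULL
  if (!is.null(config$structure)) {
    roles <- unlist(config$ligand_roles)
    model <- read_structure(config$structure, ligand_roles = roles)
    annotation <- classify_sites(model, cutoff = config$cutoff,
                                 rsasa_cutoff = config$rsasa_cutoff,
                                 chain = config$chain)
    write_sites_tsv(annotation, file.path(out_dir, "sites.tsv"))
    results$annotation <- annotation

    mapped <- map_to_structure(profile,
                               structure_chain_sequence(model,
                                                        config$chain))
    mapped$resno <- annotation$resno[mapped$structure_index]
    mapped$wild_type <- mapped$chain_residue
    results$mapped_profile <- mapped

    keep <- !mapped$unmapped
    stats_tbl <- compare_site_conservation(
      mapped$normalized_score[keep],
      annotation$class[mapped$structure_index[keep]])
    comp <- composition_table(annotation)
    enrich <- fisher_enrichment(comp, by = "group")
    results$stats <- list(conservation = stats_tbl, enrichment = enrich)
    jsonlite::write_json(c(stamp, list(conservation = stats_tbl,
                                       enrichment = enrich)),
                         file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    outcomes <- if (!is.null(config$outcomes))
      read_mutation_outcomes(config$outcomes) else NULL
    freqs <- msa_column_frequencies(aln)
    report <- design_report(mapped[keep, ],
                            annotation[mapped$structure_index[keep], ],
                            column_freqs = freqs, outcomes = outcomes,
                            conservation_threshold =
                              config$conservation_threshold,
                            frequency_threshold =
                              config$frequency_threshold)
    results$design <- report
    jsonlite::write_json(c(stamp, list(
      candidates = report$candidates, proposals = report$proposals,
      outcome_analysis = report$outcome_analysis)),
      file.path(out_dir, "design.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (!is.null(config$kinetics)) {
    fits <- lapply(config$kinetics, function(path) {
      dat <- read_kinetic_csv(path)
      h <- fit_hill(dat)
      fit <- if (any(dat$inhibitor_uM > 0)) fit_inhibition(dat, h) else h
      list(estimates = as.list(fit$estimates), se = as.list(fit$se),
           r_squared = fit$r_squared, model = fit$model,
           poor_fit = fit$poor_fit)
    })
    names(fits) <- names(config$kinetics)
    results$kinetics <- fits
    jsonlite::write_json(c(stamp, list(fits = fits)),
                         file.path(out_dir, "kinetics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
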