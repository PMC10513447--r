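default_config <- function() {
  list(
    simulate = list(n_species = 706, points_per_species = 124,
                    status_mode = "clade_biased"),
    inputs = NULL,
    thin_km = 5,
    data_mode = "both",
    replicates = 9999,
    anomaly_sign = "all_minus_subset",
    seed = 1L,
    out_dir = "phyloinvasion_run")
}

#' Read a pipeline configuration file
#'
#' YAML with the fields of the default configuration: either a `simulate`
#' block (passed to [simulate_invasion_dataset()]) or an `inputs` block with
#' paths `tree, occurrences, regions, climate`; plus `thin_km`, `data_mode`,
#' `replicates`, `anomaly_sign`, `seed`, `out_dir`. Missing fields take the
#' defaults.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_config(), cfg)
  if (!is.null(cfg$simulate) && !is.null(cfg$inputs))
    stop("config must supply either 'simulate' or 'inputs', not both",
         call. = FALSE)
  if (!is.null(cfg$inputs)) out$simulate <- NULL
  out
}

#' Generate and write a synthetic dataset from a configuration
#'
#' Runs the generators and writes `tree.nwk`, `occurrences.csv`,
#' `regions.geojson` and `climate.csv` into the output directory (created if
#' absent). Reruns with the same configuration are byte-identical.
#'
#' @param config config list (see [read_run_config()]).
#' @return the simulated dataset list, invisibly; files on disk.
#' @export
run_simulate <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  ds <- do.call(simulate_invasion_dataset, sim_args)
  write_tree_newick(ds$tree, file.path(config$out_dir, "tree.nwk"))
  write_occurrences_csv(ds$occurrences,
                        file.path(config$out_dir, "occurrences.csv"))
  write_regions_geojson(ds$regions, file.path(config$out_dir, "regions.geojson"))
  utils::write.csv(as.data.frame(ds$grid),
                   file.path(config$out_dir, "climate.csv"), row.names = FALSE)
  invisible(ds)
}

load_inputs <- function(paths) {
  grid <- utils::read.csv(paths$climate)
  class(grid) <- c("climate_grid", "data.frame")
  list(tree = read_tree_newick(file = paths$tree),
       occurrences = read_occurrences_csv(paths$occurrences),
       regions = read_regions_geojson(paths$regions),
       grid = grid,
       statuses = NULL)
}

#' Validate pipeline inputs
#'
#' Structural checks run before any analysis: every occurrence species is a
#' tree tip, status values are legal, coordinates are in range, and region
#' units do not overlap. Failures are reported, not thrown.
#'
#' @param tree a `phylo`.
#' @param occurrences occurrence data frame.
#' @param regions named list of `region_lattice`s.
#' @return data frame `check, pass, detail`.
#' @export
validate_inputs <- function(tree, occurrences, regions) {
  checks <- list()
  add <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail)
  missing <- setdiff(unique(occurrences$species), tree$tip.label)
  add("species_on_tree", length(missing) == 0,
      paste(missing, collapse = ", "))
  bad_status <- setdiff(unique(occurrences$status), STATUS_LEVELS)
  add("status_values", length(bad_status) == 0,
      paste(bad_status, collapse = ", "))
  out_of_range <- sum(occurrences$lat < -90 | occurrences$lat > 90 |
                        occurrences$lon < -180 | occurrences$lon > 180)
  add("coordinates_in_range", out_of_range == 0,
      if (out_of_range) paste(out_of_range, "records out of range") else "")
  overlap_ok <- all(vapply(regions, function(rg)
    !inherits(try(check_lattice_disjoint(rg), silent = TRUE), "try-error"),
    logical(1)))
  add("regions_disjoint", overlap_ok, "")
  do.call(rbind, checks)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the inputs, validate, deduplicate, spatially thin,
#' build per-scale community matrices and status assemblages, compute
#' NRI/NTI against the tip-shuffle null, derive anomalies, and run the
#' statistics layer (AICc data-mode selection, two-way ANOVA with Holm post
#' hocs, climate regressions, cross-type Spearman correlations). All outputs
#' are written under `config$out_dir` together with a JSON run manifest;
#' reruns with an identical configuration are byte-identical.
#'
#' @param config config list or path to a YAML config.
#' @return list with `structure` (the `phylostruct`), `anomalies`, `stats`,
#'   and `manifest`, invisibly; files on disk.
#' @export
run_all <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "inputs")],
                   package_version = as.character(
                     utils::packageVersion("phyloinvasion")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      write_manifest(manifest, out_dir)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res
  }

  data <- stage("inputs", {
    if (!is.null(config$inputs)) load_inputs(config$inputs)
    else run_simulate(config)
  })
  statuses <- data$statuses
  if (is.null(statuses)) {
    st <- unique(data$occurrences[c("species", "status")])
    statuses <- stats::setNames(st$status, st$species)
  }

  stage("validate", {
    rep <- validate_inputs(data$tree, data$occurrences, data$regions)
    if (!all(rep$pass))
      stop("validation failed: ",
           paste(rep$check[!rep$pass], collapse = ", "))
    rep
  })

  n_raw <- nrow(data$occurrences)
  occ <- stage("dedupe", dedupe_occurrences(data$occurrences))
  n_dedup <- nrow(occ)
  occ <- stage("thin", thin_occurrences(occ, config$thin_km))
  n_thin <- nrow(occ)
  write_occurrences_csv(occ, file.path(out_dir, "occurrences_thinned.csv"))

  asm <- stage("communities", {
    parts <- lapply(data$regions, function(rg) {
      mat <- assign_to_regions(occ, rg)
      list(assemblages = build_assemblages(mat, statuses),
           dropped = attr(mat, "n_dropped"))
    })
    do.call(rbind, lapply(parts, `[[`, "assemblages"))
  })

  ps <- stage("metrics", phylo_structure(data$tree, asm,
                                         data_mode = config$data_mode,
                                         replicates = config$replicates,
                                         seed = derive_seed(config$seed, 100)))
  write_metrics_csv(ps, file.path(out_dir, "metrics.csv"))

  anom <- stage("anomalies", anomalies(ps, config$anomaly_sign))
  utils::write.csv(anom, file.path(out_dir, "anomalies.csv"),
                   row.names = FALSE, quote = FALSE)

  stats_out <- stage("stats", {
    res <- ps$results
    out <- list()
    mode <- config$data_mode
    if (mode == "both") {
      sel <- select_data_mode(ps)
      out$mode_selection <- data.frame(
        mode = sel$mode, aicc_presence = unname(sel$aicc["presence"]),
        aicc_abundance = unname(sel$aicc["abundance"]),
        delta_aicc = sel$delta, tie = sel$tie)
      mode <- sel$mode
    }
    sel_res <- res[res$data_mode == mode & res$usable & res$ses_defined, ]
    for (metric in c("NRI", "NTI")) {
      out[[paste0("anova_", metric)]] <-
        two_way_anova(sel_res, metric, "community_type", "scale")
      ph <- posthoc_pairwise(sel_res[[metric]], sel_res$community_type)
      ph$metric <- metric
      out[[paste0("posthoc_", metric)]] <- ph
    }
    cov <- aggregate_climate(data$grid, data$regions)
    out$climate <- climate_regressions(sel_res, cov)
    out$correlations <- cross_type_correlations(sel_res)
    out$selected_mode <- mode
    for (nm in setdiff(names(out), "selected_mode"))
      utils::write.csv(out[[nm]],
                       file.path(out_dir, "stats", paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    out
  })

  # recompute per-assemblage usability (rbind drops the summary attribute)
  smry <- stats::aggregate(species ~ scale + unit + community_type, asm,
                           length)
  smry$usable <- smry$species >= 2
  manifest$stages <- list(
    records_read = n_raw, records_deduped = n_dedup, records_thinned = n_thin,
    assemblages_total = nrow(smry), assemblages_usable = sum(smry$usable),
    metrics_rows = nrow(ps$results), anomaly_rows = nrow(anom),
    selected_mode = stats_out$selected_mode)
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_manifest(manifest, out_dir)
  invisible(list(structure = ps, anomalies = anom, stats = stats_out,
                 manifest = manifest))
}

write_manifest <- function(manifest, out_dir) {
  manifest$started <- NULL; manifest$finished <- NULL  # keep outputs byte-stable
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Composition of the analyzed alien flora
#'
#' Published census counts for the alien vascular flora of China that frame
#' the analysis: source checklist sizes, species per invasion stage before
#' and after occurrence-based filtering, occurrence record totals by source,
#' and the species counts of the three largest families with their stage
#' breakdown. Derived totals and family percentage shares are recomputed
#' from the raw counts.
#'
#' @return list with `counts` (the raw table), `n_species_analyzed`,
#'   `n_occurrences`, `n_candidate_species`, and `family_shares` (percent of
#'   analyzed species per family, rounded to 2 decimals).
#' @export
alien_flora_composition <- function() {
  path <- system.file("extdata", "alien_flora_china_counts.csv",
                      package = "phyloinvasion")
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(grp, cat) counts$count[counts$group == grp &
                                            counts$category == cat]
  stages <- c("introduced", "naturalized", "invasive")
  n_analyzed <- sum(vapply(stages, function(s) pick("analyzed", s), numeric(1)))
  n_candidate <- sum(vapply(stages, function(s) pick("consensus", s),
                            numeric(1)))
  n_occ <- sum(counts$count[counts$group == "occurrence_source"])
  fam <- counts[counts$group == "family_total", ]
  shares <- stats::setNames(round(100 * fam$count / n_analyzed, 2),
                            fam$category)
  list(counts = counts, n_species_analyzed = n_analyzed,
       n_occurrences = n_occ, n_candidate_species = n_candidate,
       family_shares = shares)
}
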