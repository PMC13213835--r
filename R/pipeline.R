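#' Run a configured analysis pipeline
#'
#' Executes the selected stages in order and writes every stage's outputs
#' plus a run manifest (`manifest.json`) into the output directory. The
#' configuration is a list (or path to a YAML file) with fields:
#'
#' * `out_dir` — output directory (created).
#' * `seed` — integer seed recorded and used by stochastic stages.
#' * `stages` — list of stage entries, each a list with `stage` and its
#'   parameters.
#'
#' Supported stages and their parameters:
#'
#' * `deltag`: `kd` (molar), optional `temperature`.
#' * `mddg`: `energy_csv`, optional `order_csv`, `window`, `poly_order`,
#'   `merge_threshold` (kcal/mol, coarse-grain before tree building);
#'   writes `tree.json` and `tree.svg` (when the device is available).
#' * `wham`: `manifest` (window manifest CSV), optional `n_bins`, `range`,
#'   `tolerance`, `temperature`, `bias_convention`, `n_plateau`; writes
#'   `pmf.csv` and reports the dissociation free energy.
#' * `rmsf`: `pdb`, optional `selection`; writes `rmsf.csv`.
#' * `rmsd`: `pdb`, optional `selection`; writes `rmsd.csv`.
#' * `pucker`: `pdb`, `residue`, optional `classifier`; writes
#'   `pucker.json`.
#' * `compare_profiles`: `x_csv`, `y_csv` (CSV `resid,value`); writes
#'   `comparison.json` with Pearson/Spearman/paired t/Wilcoxon.
#' * `simulate_energy`: `means`, optional `sds`, `dwell`, `spike`,
#'   `n_frames`; writes `energy.csv` (consumed by `mddg`).
#'
#' Configuration is validated before anything is written; a failing stage
#' is recorded in the manifest with its error and does not abort later
#' stages. Deterministic stages rerun from the same config and seed give
#' byte-identical outputs.
#'
#' @param config list or YAML file path.
#' @return the run manifest (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) .stopf("config needs out_dir")
  if (is.null(config$stages) || !length(config$stages))
    .stopf("config needs a non-empty stages list")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  ## validate everything up front: no outputs on validation failure
  inputs <- character(0)
  for (st in config$stages) {
    if (is.null(st$stage)) .stopf("every stage entry needs a 'stage' field")
    for (fld in c("energy_csv", "order_csv", "manifest", "pdb", "x_csv", "y_csv")) {
      p <- st[[fld]]
      if (!is.null(p)) {
        if (!file.exists(p)) .stopf("stage '%s': input file not found: %s", st$stage, p)
        inputs <- c(inputs, p)
      }
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- as.list(tools::md5sum(unique(inputs)))
  manifest <- list(
    tool = "gagmd",
    version = as.character(utils::packageVersion("gagmd")),
    seed = seed,
    config = config,
    input_checksums = checksums,
    stages = list())
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    rec <- list(stage = st$stage, status = "ok", outputs = list())
    res <- tryCatch(.run_stage(st, config$out_dir, seed, si),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rec$status <- "error"
      rec$error <- conditionMessage(res)
    } else {
      rec$outputs <- res$outputs
      rec$results <- res$results
    }
    manifest$stages[[si]] <- rec
  }
  js <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE, force = TRUE)
  writeLines(js, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

.stage_path <- function(out_dir, si, name) file.path(out_dir, sprintf("stage%02d_%s", si, name))

.run_stage <- function(st, out_dir, seed, si) {
  outputs <- list(); results <- list()
  put <- function(name, path) outputs[[name]] <<- path
  switch(
    st$stage,
    deltag = {
      temp <- if (is.null(st$temperature)) 298.15 else st$temperature
      dg <- delta_g_from_kd(st$kd, temp)
      results$delta_g_kcal_mol <- dg
    },
    simulate_energy = {
      model <- basin_model(means = unlist(st$means),
                           sds = if (is.null(st$sds)) 0.2 else unlist(st$sds),
                           dwell = if (is.null(st$dwell)) 20 else unlist(st$dwell),
                           spike = if (is.null(st$spike)) 8 else st$spike)
      nfr <- if (is.null(st$n_frames)) 1000L else as.integer(st$n_frames)
      gen <- gen_basin_energy_series(model, nfr, seed = seed)
      p <- .stage_path(out_dir, si, "energy.csv")
      write_energy_csv(gen$series, p); put("energy_csv", p)
      results$n_visits <- gen$n_visits
    },
    mddg = {
      es <- read_energy_csv(st$energy_csv)
      spec <- smoothing_spec(
        window_length = if (is.null(st$window)) 5L else st$window,
        poly_order = if (is.null(st$poly_order)) 3L else st$poly_order,
        sampling_interval = attr(es, "dt"))
      ex <- detect_proxy_extrema(smooth_energy(es, spec))
      if (!is.null(st$merge_threshold)) ex <- coarse_grain_minima(ex, st$merge_threshold)
      ov <- if (!is.null(st$order_csv)) read_order_parameter_csv(st$order_csv) else NULL
      tree <- build_disconnectivity(ex, ov)
      p <- .stage_path(out_dir, si, "tree.json")
      tree_to_json(tree, p); put("tree_json", p)
      sv <- .stage_path(out_dir, si, "tree.svg")
      ok <- tryCatch({
        grDevices::svg(sv); plot(tree); grDevices::dev.off(); TRUE
      }, error = function(e) FALSE)
      if (ok) put("tree_svg", sv)
      results$n_minima <- nrow(tree$leaves)
      results$cutoff_timescale_ns <- cutoff_timescale(spec)
    },
    wham = {
      windows <- read_umbrella_windows(st$manifest)
      spec <- wham_spec(
        n_bins = if (is.null(st$n_bins)) 21L else st$n_bins,
        range = if (is.null(st$range)) c(0, 20) else unlist(st$range),
        tolerance = if (is.null(st$tolerance)) 0.01 else st$tolerance,
        temperature = if (is.null(st$temperature)) 298.15 else st$temperature,
        bias_convention = if (is.null(st$bias_convention)) "full-k" else st$bias_convention)
      pmf <- wham_solve(windows, spec)
      p <- .stage_path(out_dir, si, "pmf.csv")
      write_pmf_csv(pmf, p); put("pmf_csv", p)
      npl <- if (is.null(st$n_plateau)) 3L else st$n_plateau
      results$dissociation_free_energy_kcal_mol <- dissociation_free_energy(pmf, npl)
    },
    rmsf = {
      traj <- read_structure(st$pdb)
      prof <- rmsf_profile(traj, selection = st$selection)
      p <- .stage_path(out_dir, si, "rmsf.csv")
      utils::write.csv(data.frame(resid = prof$resid, value = prof$rmsf),
                       p, row.names = FALSE, quote = FALSE)
      put("rmsf_csv", p)
    },
    rmsd = {
      traj <- read_structure(st$pdb)
      rs <- rmsd_series(traj, selection = if (is.null(st$selection)) "heavy" else st$selection)
      p <- .stage_path(out_dir, si, "rmsd.csv")
      utils::write.csv(rs, p, row.names = FALSE, quote = FALSE)
      put("rmsd_csv", p)
    },
    pucker = {
      traj <- annotate_rings(read_structure(st$pdb))
      cls <- if (is.null(st$classifier)) "cp" else st$classifier
      fr <- pucker_populations(traj, st$residue, classifier = cls)
      p <- .stage_path(out_dir, si, "pucker.json")
      writeLines(jsonlite::toJSON(as.list(fr), auto_unbox = TRUE, digits = NA), p)
      put("pucker_json", p)
      results$populations <- as.list(fr)
    },
    compare_profiles = {
      rd <- function(path) {
        df <- utils::read.csv(path)
        flex_profile(df$resid, df$value)
      }
      x <- rd(st$x_csv); y <- rd(st$y_csv)
      tt <- paired_t_test(x, y); wx <- wilcoxon_signed_rank(x, y)
      results <- list(pearson = pearson(x, y), spearman = spearman(x, y),
                      paired_t = list(statistic = tt$statistic, p = tt$p.value),
                      wilcoxon = list(W = wx$statistic, p = wx$p.value,
                                      method = wx$method),
                      n = tt$n)
      p <- .stage_path(out_dir, si, "comparison.json")
      writeLines(jsonlite::toJSON(results, auto_unbox = TRUE, digits = NA), p)
      put("comparison_json", p)
    },
    .stopf("unknown stage '%s'", st$stage)
  )
  list(outputs = outputs, results = results)
}
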