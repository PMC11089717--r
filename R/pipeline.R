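#' Default pipeline configuration
#'
#' One document of every tunable the end-to-end run uses. Any element can be
#' overridden through `...` (nested lists are replaced wholesale).
#'
#' @param outdir output directory.
#' @param base_seed base RNG seed; every per-cell seed derives from it.
#' @param ... overrides, e.g. `n_cells = 3`, `reconstruct = FALSE`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("dipstruct_run_"),
                            base_seed = 1, ...) {
  cfg <- list(
    outdir = outdir,
    base_seed = base_seed,
    genome = list(n_chrom = 20, chrom_length = 15e6, bin_size = 1e6,
                  cpg_mean = 0.02, cpg_sd_log = 0.6, cpg_smooth = 2,
                  seed = 1),
    archetypes = c("naive_like", "primed_like"),
    n_cells = 5,
    impute = imputation_params(),
    reconstruct = TRUE,
    coarse_bin_multiplier = 5,
    schedule = anneal_schedule(),
    compartment_bin = 1e6)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate -> impute -> (reconstruct) -> metrics -> compare, writing every
#' stage artifact under `config$outdir` and returning a run manifest. The
#' whole run is deterministic under `config$base_seed`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list with `manifest` (per-cell seeds and archetypes), `metrics`
#'   (per-cell metric table), `comparison` (cohort contrasts), `pca`
#'   (clustering result) and `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  g <- config$genome
  if (is.null(g$bin_size) || is.null(g$n_chrom))
    stop("config validation failed: genome parameters missing")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("stage simulate")
  toy <- make_toy_genome(g$n_chrom, g$chrom_length, g$bin_size, g$cpg_mean,
                         g$cpg_sd_log, g$cpg_smooth, seed = g$seed)
  write_cpg_bedgraph(toy$cpg, file.path(config$outdir, "cpg.bedgraph"),
                     toy$genome)
  archs <- if (is.character(config$archetypes)) {
    stats::setNames(lapply(config$archetypes, cell_archetype),
                    config$archetypes)
  } else {
    config$archetypes
  }
  if (is.null(names(archs)) || any(names(archs) == ""))
    stop("config validation failed: archetypes must be named")
  cohort <- simulate_cohort(toy$genome, toy$cpg, archs,
                            n_cells = config$n_cells,
                            base_seed = config$base_seed)
  for (cid in names(cohort$cells)) {
    write_contacts(cohort$cells[[cid]]$contacts,
                   file.path(config$outdir, paste0(cid, ".raw.contacts")))
    write_3dg(cohort$cells[[cid]]$structure,
              file.path(config$outdir, paste0(cid, ".truth.3dg")))
  }

  say("stage impute")
  cleaned <- list()
  for (cid in names(cohort$cells)) {
    cleaned[[cid]] <- impute_pipeline(cohort$cells[[cid]]$contacts,
                                      config$impute)
    write_contacts(cleaned[[cid]],
                   file.path(config$outdir, paste0(cid, ".cleaned.contacts")))
  }

  structures <- list()
  if (isTRUE(config$reconstruct)) {
    say("stage reconstruct")
    for (cid in names(cohort$cells)) {
      sched <- config$schedule
      sched$seed <- config$base_seed + match(cid, names(cohort$cells))
      structures[[cid]] <- reconstruct_pipeline(
        cleaned[[cid]], toy$genome,
        coarse_bin = config$coarse_bin_multiplier * toy$genome$bin_size,
        schedule = sched)
      write_3dg(structures[[cid]],
                file.path(config$outdir, paste0(cid, ".recon.3dg")))
    }
  } else {
    # structure metrics fall back to the simulator truth structures
    structures <- lapply(cohort$cells, `[[`, "structure")
  }

  say("stage metrics")
  rows <- list()
  vectors <- list()
  for (cid in names(cohort$cells)) {
    s <- structures[[cid]]
    rows[[cid]] <- data.table(
      cell_id = cid,
      archetype = cohort$cells[[cid]]$archetype,
      intermingling = intermingling_index(s)$mean,
      compartment_score = as.numeric(compartment_score(s, toy$cpg)),
      radial_cpg_cor = as.numeric(
        radial_cpg_correlation(s, toy$cpg, config$compartment_bin)),
      interchrom_fraction = interchrom_stats(
        cohort$cells[[cid]]$contacts)$fraction)
    vectors[[cid]] <- contacting_cpg(cohort$cells[[cid]]$contacts, toy$cpg,
                                     config$compartment_bin,
                                     mode = "celltype")
  }
  metrics <- rbindlist(rows)
  fwrite(metrics, file.path(config$outdir, "metrics.tsv"), sep = "\t")
  pca <- compartment_pca(vectors, seed = config$base_seed)

  say("stage compare")
  comparison <- compare_cohorts(metrics, group = "archetype")
  fwrite(comparison, file.path(config$outdir, "comparison.tsv"), sep = "\t")

  manifest <- list(base_seed = config$base_seed,
                   cells = cohort$manifest,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                   outdir = config$outdir)
  jsonlite::write_json(
    list(base_seed = manifest$base_seed,
         cells = cohort$manifest,
         pca_clusters = as.list(pca$cluster)),
    file.path(config$outdir, "manifest.json"), auto_unbox = TRUE)
  list(manifest = manifest, metrics = metrics, comparison = comparison,
       pca = pca, outdir = config$outdir, genome = toy$genome,
       cpg = toy$cpg, cells = cohort$cells, cleaned = cleaned,
       structures = structures)
}

#' Compare per-cell metrics between two cohorts
#'
#' Rank-based two-sample contrasts (Wilcoxon rank-sum, exact p for small
#' samples) per metric column.
#'
#' @param metrics data.frame with a cohort column and numeric metric
#'   columns.
#' @param group name of the cohort column.
#' @param alternative passed to [stats::wilcox.test()] with the first cohort
#'   level as `x`.
#' @return `data.table(metric, mean_<a>, mean_<b>, difference, p_value)`.
#' @export
compare_cohorts <- function(metrics, group = "archetype",
                            alternative = "two.sided") {
  dt <- as.data.table(metrics)
  lv <- sort(unique(dt[[group]]))
  if (length(lv) != 2) stop("exactly two cohorts required, got ", length(lv))
  if (min(table(dt[[group]])) < 3)
    stop("need at least 3 cells per cohort")
  num <- names(dt)[vapply(dt, is.numeric, logical(1))]
  out <- lapply(num, function(m) {
    a <- dt[[m]][dt[[group]] == lv[1]]
    b <- dt[[m]][dt[[group]] == lv[2]]
    if (all(is.na(a)) || all(is.na(b))) {
      warning("metric ", m, " missing in one cohort; omitted")
      return(NULL)
    }
    wt <- stats::wilcox.test(a, b, alternative = alternative, exact = TRUE)
    data.table(metric = m, mean_a = mean(a, na.rm = TRUE),
               mean_b = mean(b, na.rm = TRUE),
               difference = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
               p_value = wt$p.value)
  })
  res <- rbindlist(out)
  setnames(res, c("mean_a", "mean_b"),
           c(paste0("mean_", lv[1]), paste0("mean_", lv[2])))
  res
}
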