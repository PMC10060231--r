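#' Run the full analysis pipeline on simulated data
#'
#' Chains the package's stages end-to-end: simulate inputs, calibrate the
#' run-on standard curve and deconvolve stage activities, derive and
#' apply normalization factors, compute per-gene pausing/retention
#' summaries, build and cluster fold-change trajectories, and run the
#' overlap and co-occurrence permutation tests. Each stage writes its
#' outputs under `out_dir` and a manifest (parameters, derived seeds,
#' output checksums) is written as JSON. One master seed deterministically
#' derives per-stage seeds, so the run is reproducible byte-for-byte and
#' each stage is independently reproducible.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param steps Character vector of steps, or `"all"`. Steps:
#'   `simulate`, `calibrate`, `normalize`, `pause`, `cluster`, `overlap`.
#'   Later steps recompute what they need from the simulation in memory.
#' @param config A [sim_config()]; its seed is overridden by the derived
#'   simulate seed.
#' @param n_iter Permutation iterations for the overlap stage.
#' @param k Number of trajectory clusters.
#' @param reference Reference stage for normalization.
#' @return Invisibly, a list with each stage's in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1, steps = "all",
                         config = sim_config(), n_iter = 1000, k = 2,
                         reference = "LZ") {
  all_steps <- c("simulate", "calibrate", "normalize", "pause",
                 "cluster", "overlap")
  if (identical(steps, "all")) steps <- all_steps
  if (!all(steps %in% all_steps)) {
    stop_input("unknown step(s): ",
               paste(setdiff(steps, all_steps), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stats::setNames(
    lapply(all_steps, function(s) derive_seed(seed, s)), all_steps)
  config$seed <- seeds$simulate
  res <- list()
  outputs <- character(0)
  emit <- function(sub, file) {
    d <- file.path(out_dir, sub)
    dir.create(d, showWarnings = FALSE)
    p <- file.path(d, file)
    outputs <<- c(outputs, p)
    p
  }

  ## the downstream stages always need the simulated objects in memory
  ann <- simulate_annotation(config)
  tracks <- simulate_stage_tracks(config, ann)
  runon <- simulate_runon_table(config)
  peaks <- simulate_peaks(config, ann)
  res$sim <- list(ann = ann, tracks = tracks, runon = runon, peaks = peaks)

  if ("simulate" %in% steps) {
    write_chrom_sizes(ann$chrom_sizes, emit("sim", "genome.chrom.sizes"))
    write_bed(ann$genes, emit("sim", "genes.bed"))
    for (nm in names(peaks)) {
      write_bed(peaks[[nm]], emit("sim", paste0(nm, ".bed")))
    }
    for (st in names(tracks)) {
      write_bedgraph(tracks[[st]]$plus,
                     emit("sim", paste0(st, ".bedGraph")))
      write_bedgraph(tracks[[st]]$minus,
                     emit("sim", paste0(st, ".minus.bedGraph")))
    }
    utils::write.csv(runon$samples, emit("sim", "runon_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(runon$standards, emit("sim", "runon_standards.csv"),
                     row.names = FALSE)
  }

  curve <- fit_standard_curve(runon$standards)
  acts <- deconvolve_activities(runon$samples, curve)
  res$calibrate <- list(curve = curve, activities = acts)
  if ("calibrate" %in% steps) {
    utils::write.csv(
      data.frame(stage = names(acts$activity),
                 activity = as.numeric(acts$activity)),
      emit("norm", "activities.csv"), row.names = FALSE)
  }

  lib_sizes <- vapply(tracks, function(tp) {
    library_size(tp$plus) + library_size(tp$minus)
  }, numeric(1))
  factors <- normalization_factors(lib_sizes, acts, reference)
  res$normalize <- factors
  if ("normalize" %in% steps) {
    utils::write.csv(factors, emit("norm", "factors.csv"),
                     row.names = FALSE)
    for (st in names(tracks)) {
      f <- factors$factor[factors$stage == st]
      write_bedgraph(rescale_track(tracks[[st]]$plus, f),
                     emit("norm", paste0(st, ".norm.bedGraph")))
      write_bedgraph(rescale_track(tracks[[st]]$minus, f),
                     emit("norm", paste0(st, ".norm.minus.bedGraph")))
    }
  }

  summaries <- lapply(tracks, summarize_genes, genes = ann$genes)
  res$pause <- summaries
  if ("pause" %in% steps) {
    for (st in names(summaries)) {
      utils::write.table(summaries[[st]],
                         emit("pause", paste0(st, "_summary.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pit <- pausing_index_table(summaries, ann$genes)
    utils::write.table(pit, emit("pause", "pausing_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("cluster" %in% steps) {
    M <- build_trajectories(summaries, factors)
    cl <- cluster_trajectories(M, k = k, seed = seeds$cluster)
    res$cluster <- list(matrix = M, clusters = cl)
    utils::write.table(
      data.frame(gene_id = rownames(M), M, check.names = FALSE),
      emit("cluster", "trajectories.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = names(cl$assignments),
                 cluster = cl$assignments),
      emit("cluster", "assignments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("overlap" %in% steps) {
    enr <- overlap_enrichment_test(peaks$accessible, peaks$tre,
                                   ann$chrom_sizes, n_iter = n_iter,
                                   seed = seeds$overlap)
    cooc <- cooccurrence_test(peaks$accessible, peaks$tre, peaks$dsb,
                              n_iter = n_iter, seed = seeds$overlap,
                              chrom_sizes = ann$chrom_sizes)
    res$overlap <- list(enrichment = enr, cooccurrence = cooc)
    jsonlite::write_json(
      list(enrichment = list(observed = enr$observed,
                             p = enr$p_empirical, n_iter = enr$n_iter,
                             direction = enr$direction, seed = enr$seed),
           cooccurrence = list(observed = cooc$observed,
                               p = cooc$p_empirical, n_iter = cooc$n_iter,
                               direction = cooc$direction,
                               seed = cooc$seed)),
      emit("overlap", "results.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(iter = seq_along(enr$null_values),
                 enrichment_null = enr$null_values,
                 cooccurrence_null = cooc$null_values),
      emit("overlap", "null_distributions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    version = as.character(utils::packageVersion("meionascent")),
    master_seed = seed, derived_seeds = seeds, steps = steps,
    parameters = list(n_iter = n_iter, k = k, reference = reference,
                      n_chroms = config$n_chroms,
                      chrom_length = config$chrom_length,
                      n_genes = config$n_genes,
                      activity = as.list(config$activity),
                      segregation = config$segregation),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
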