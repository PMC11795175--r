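#' Run the full overlap-analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: simulate a cohort, call DEGs per dataset,
#' disjointify the three reference signatures, run the four-way directional
#' overlap test of every dataset against every reference, assemble the
#' signed index table, correlate the three index pairs across datasets, and
#' meta-analyze pathway enrichment of the per-dataset overlap gene sets.
#' Everything is written under \code{out_dir} in stable plain-text formats
#' together with a machine-readable manifest (config echo, seed, package
#' version, per-stage status); reruns with the same config and seed are
#' numerically identical. On a stage failure the manifest names the failed
#' stage, partial outputs are retained, and an error is signalled.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving all randomness.
#' @param n_datasets cohort size (default 20).
#' @param config optional named list overriding \code{\link{synthetic_config}}
#'   fields (e.g. \code{universe_size}, \code{noise_sd}).
#' @param fc_threshold,p_threshold DEG criterion (defaults 1.2 and 0.05).
#' @param trend cohort severity schedule (\code{"signature"} or
#'   \code{"null"}), see \code{\link{generate_cohort}}.
#' @param disjoint_references enforce disjoint reference gene sets
#'   (default TRUE; the generator already makes them disjoint, and
#'   \code{\link{disjointify}} is applied regardless as a guarantee).
#' @param correlation \code{"pearson"} (default) or \code{"spearman"}.
#' @param top_k pathways kept per meta-enrichment table (default 15).
#' @param write_fixtures also write the raw synthetic inputs (matrices,
#'   reference tables, GMT, truth.json) under \code{out_dir/fixtures}.
#' @return (invisibly) a list with the cohort, DEG signatures, overlap
#'   results, \code{index_table}, \code{correlations} and per-reference
#'   \code{meta_enrichment} tables.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_datasets = 20, config = list(),
                         fc_threshold = 1.2, p_threshold = 0.05,
                         trend = "signature", disjoint_references = TRUE,
                         correlation = "pearson", top_k = 15,
                         write_fixtures = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  manifest <- list(tool = "sigoverlap",
                   version = as.character(utils::packageVersion("sigoverlap")),
                   seed = seed, n_datasets = n_datasets,
                   config = config,
                   params = list(fc_threshold = fc_threshold,
                                 p_threshold = p_threshold, trend = trend,
                                 disjoint_references = disjoint_references,
                                 correlation = correlation, top_k = top_k),
                   stages = character())
  stage <- "configure"
  res <- tryCatch({
    cfg <- do.call(synthetic_config, c(config, list(seed = seed)))

    stage <- "simulate"; logf("simulate: cohort of", n_datasets, "datasets")
    study <- generate_cohort(cfg, n_datasets = n_datasets, trend = trend,
                             dir = if (write_fixtures)
                               file.path(out_dir, "fixtures") else NULL)
    manifest$stages <- c(manifest$stages, "simulate")

    stage <- "deg_call"; logf("deg_call: FC >", fc_threshold, ", p <", p_threshold)
    degs <- lapply(study$datasets, function(d)
      call_degs(d$matrix, fc_threshold, p_threshold, name = d$name,
                species = "mouse"))
    manifest$stages <- c(manifest$stages, "deg_call")

    stage <- "disjointify"
    refs <- if (disjoint_references)
      disjointify(study$references$maturity, study$references$ph,
                  study$references$hyperexcitation)
    else study$references
    manifest$stages <- c(manifest$stages, "disjointify")

    stage <- "overlap"; logf("overlap: ", length(degs), "datasets x 3 references")
    universe <- study$universe
    overlap_dir <- file.path(out_dir, "overlaps")
    dir.create(overlap_dir, showWarnings = FALSE)
    overlaps <- list()
    for (nm in names(degs)) for (r in names(refs)) {
      ov <- signature_overlap(degs[[nm]], refs[[r]], universe)
      overlaps[[paste(nm, r, sep = "_vs_")]] <- ov
      write_overlap_json(ov, file.path(overlap_dir,
                                       paste0(nm, "_vs_", r, ".json")))
    }
    utils::write.table(overlap_summary(overlaps),
                       file.path(out_dir, "overlap_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages <- c(manifest$stages, "overlap")

    stage <- "indices"; logf("indices: building index table")
    index_table <- build_index_table(degs, refs, universe)
    utils::write.table(index_table, file.path(out_dir, "index_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages <- c(manifest$stages, "indices")

    stage <- "correlate"
    correlations <- correlate_indices(index_table, "all", method = correlation)
    utils::write.table(correlations, file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages <- c(manifest$stages, "correlate")

    stage <- "enrich"; logf("enrich: meta-analysis, top", top_k)
    meta <- list()
    for (r in names(refs)) {
      rows <- do.call(rbind, lapply(names(degs), function(nm)
        enrich(overlap_gene_set(degs[[nm]], refs[[r]]), study$gmt, universe,
               dataset = nm)))
      meta[[r]] <- meta_rank(rows, top_k = top_k)
      utils::write.table(meta[[r]],
                         file.path(out_dir, paste0("meta_enrichment_", r, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages <- c(manifest$stages, "enrich")

    manifest$status <- "ok"
    list(study = study, degs = degs, references = refs,
         overlaps = overlaps, index_table = index_table,
         correlations = correlations, meta_enrichment = meta)
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    logf("FAILED at stage", stage, ":", conditionMessage(e))
    e
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (inherits(res, "error"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(res))
  logf("done")
  invisible(res)
}
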