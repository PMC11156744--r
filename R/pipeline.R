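#' Pipeline configuration
#'
#' Collects every tunable of the screening pipeline in one validated
#' object: the bioefficacy weights, the cluster count and linkage, the
#' PCA variance floor, the bootstrap effort and the seed that makes the
#' whole run reproducible.
#'
#' @param weights a [bi_weights()] configuration.
#' @param k number of clusters for the dendrogram cut (default 6).
#' @param cluster_method `"ward"` (squared Euclidean) or `"upgma"`.
#' @param variance_floor percent of variance PCA components must reach.
#' @param bootstrap_replicates phylogeny bootstrap replicates.
#' @param mg_day,sp_day summary days for growth/sporulation (default:
#'   latest present).
#' @param seed random seed recorded in the manifest and used for every
#'   stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(weights = bi_weights(), k = 6,
                            cluster_method = c("ward", "upgma"),
                            variance_floor = 70,
                            bootstrap_replicates = 100,
                            mg_day = NULL, sp_day = NULL, seed = 42) {
  cluster_method <- match.arg(cluster_method)
  if (!inherits(weights, "bi_weights")) weights <- do.call(bi_weights, weights)
  stopifnot(k >= 1, variance_floor > 0, variance_floor <= 100,
            bootstrap_replicates >= 1)
  structure(list(weights = weights, k = k,
                 cluster_method = cluster_method,
                 variance_floor = variance_floor,
                 bootstrap_replicates = bootstrap_replicates,
                 mg_day = mg_day, sp_day = sp_day, seed = seed),
            class = "pipeline_config")
}

#' Run the full strain-screening pipeline
#'
#' Orchestrates ingest, corrected mortality, bioefficacy indexing and
#' categorization, PCA-based strain selection, BI clustering, and (when
#' an alignment is supplied) the ITS phylogeny, writing one file bundle
#' under `out_dir`:
#'
#' * `inputs/` -- the validated input tables (checksummed in the
#'   manifest);
#' * `summaries.csv` (1-decimal presentation) and
#'   `summaries_full.csv` (full precision);
#' * `pca.json`, `pca_scores.csv` -- eigenvalues, proportions, raw and
#'   varimax-rotated loadings, flagged variable-component pairs,
#'   strain ranking;
#' * `cluster_report.csv`, `cluster_labels.csv`, `dendrogram.nwk`;
#' * `phylo.nwk`, `phylo_distances.csv` (skipped without alignment);
#' * `manifest.json` -- seed, configuration, input checksums, stage
#'   status and collected warnings. No timestamps are written, so
#'   identical inputs, configuration and seed give byte-identical
#'   bundles.
#'
#' A stage failure is recorded in the manifest (stage name and message)
#' and the remaining stages are not run; files written by completed
#' stages are kept.
#'
#' @param panel list with `strains`, `growth`, `spores`, `bioassay`
#'   (from [read_measurements()] or [generate_panel()]).
#' @param out_dir output directory (created if absent).
#' @param alignment optional [epf_alignment()] (or path to an aligned
#'   FASTA) for the phylogeny stage.
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(panel, out_dir, alignment = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  warnings_log <- character(0)
  stages <- list()
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) return(invisible(NULL))
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      failed <<- TRUE
      stages[[name]] <<- list(status = "failed",
                              message = conditionMessage(res))
    } else {
      stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  run_stage("ingest", function() {
    panel$strains <- validate_strains(panel$strains)
    panel$growth <- validate_growth(panel$growth)
    panel$spores <- validate_spores(panel$spores)
    panel$bioassay <- validate_bioassay(panel$bioassay)
    write_measurements(panel, file.path(out_dir, "inputs"))
    if (is.character(alignment) && is.null(dim(alignment))) {
      alignment <<- read_alignment(alignment)
    }
    if (!is.null(alignment)) {
      write_alignment(alignment, file.path(out_dir, "inputs",
                                           "alignment.fasta"))
    }
    state$panel <- panel
    list(n_strains = nrow(panel$strains),
         n_bioassay_rows = nrow(panel$bioassay))
  })

  run_stage("summaries", function() {
    sm <- build_strain_summaries(state$panel, weights = config$weights,
                                 mg_day = config$mg_day,
                                 sp_day = config$sp_day)
    state$summaries <- sm
    write_summaries(sm, file.path(out_dir, "summaries.csv"))
    write.csv(sm, file.path(out_dir, "summaries_full.csv"),
              row.names = FALSE, quote = FALSE)
    list(n = nrow(sm))
  })

  run_stage("pca", function() {
    sm <- state$summaries
    feats <- sm[, c("strain_id", "MG", "SP", "MO3", "MO5", "MO7", "BI")]
    p <- epf_pca(feats)
    retained <- retain_components(p, config$variance_floor)
    vm <- varimax_rotation(p, retained)
    cc <- component_correlations(feats, p, retained)
    sel <- select_strains(p)
    jsonlite::write_json(list(
      eigenvalues = p$eigenvalues,
      proportion = p$proportion,
      cumulative = p$cumulative,
      retained = retained,
      loadings = as.data.frame(p$loadings),
      rotated_loadings = as.data.frame(vm$loadings),
      correlations = cc,
      top_strains = head(sel, 10L)
    ), file.path(out_dir, "pca.json"), digits = 10, auto_unbox = TRUE)
    write.csv(sel, file.path(out_dir, "pca_scores.csv"),
              row.names = FALSE, quote = FALSE)
    state$pca <- p
    list(retained = length(retained),
         cumulative_2 = round(p$cumulative[2L], 2))
  })

  run_stage("cluster", function() {
    sm <- state$summaries
    bi <- setNames(sm$BI, sm$strain_id)
    d <- squared_euclidean(bi)
    linkage <- if (config$cluster_method == "ward") {
      ward_linkage(d)
    } else {
      upgma_linkage(sqrt(d))
    }
    cl <- cut_and_label(linkage, k = config$k, bi = bi)
    state$clusters <- cl
    write.csv(cl$report, file.path(out_dir, "cluster_report.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(data.frame(strain_id = names(cl$labels),
                         cluster_label = unname(cl$labels)),
              file.path(out_dir, "cluster_labels.csv"),
              row.names = FALSE, quote = FALSE)
    writeLines(linkage_to_newick(linkage),
               file.path(out_dir, "dendrogram.nwk"))
    list(k = config$k)
  })

  run_stage("phylo", function() {
    if (is.null(alignment)) {
      return(list(skipped = TRUE,
                  message = "no alignment supplied; stage skipped"))
    }
    d <- tn93_matrix(alignment)
    tree <- bootstrap_support(alignment,
                              replicates = config$bootstrap_replicates,
                              seed = config$seed)
    ape::write.tree(tree, file.path(out_dir, "phylo.nwk"))
    write.csv(as.data.frame(d), file.path(out_dir, "phylo_distances.csv"),
              quote = FALSE)
    ann <- annotate_tree(tree, meta = state$panel$strains,
                         categories = state$clusters$labels)
    writeLines(ann$newick, file.path(out_dir, "phylo_annotated.nwk"))
    list(n_taxa = nrow(alignment),
         total_length = attr(tree, "total_length"))
  })

  input_files <- list.files(file.path(out_dir, "inputs"),
                            full.names = TRUE)
  checksums <- as.list(tools::md5sum(input_files))
  names(checksums) <- basename(input_files)
  manifest <- list(
    package = "epfscreen",
    version = as.character(utils::packageVersion("epfscreen")),
    seed = config$seed,
    config = list(weights = unclass(config$weights), k = config$k,
                  cluster_method = config$cluster_method,
                  variance_floor = config$variance_floor,
                  bootstrap_replicates = config$bootstrap_replicates),
    input_checksums = checksums,
    stages = stages,
    warnings = warnings_log,
    status = if (failed) "failed" else "ok"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (failed) {
    warning("run_pipeline: a stage failed; see manifest.json",
            call. = FALSE)
  }
  invisible(manifest)
}
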