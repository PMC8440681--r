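#' Pipeline configuration
#'
#' Declarative description of a full run: either a simulation spec or
#' paths to an existing 10x directory + annotation table, plus the QC,
#' embedding, shift-statistic and contrast parameters. One seed drives
#' every stochastic stage.
#'
#' @param out_dir output directory (created).
#' @param sim_spec a [synthetic_spec()], or NULL to read from files.
#' @param input_dir 10x-style matrix directory (when `sim_spec` is NULL).
#' @param annotation_path annotation TSV/CSV (when `sim_spec` is NULL).
#' @param gmt_path optional GMT file; gene-set stage is skipped if NULL.
#' @param thresholds a [qc_thresholds()].
#' @param hvg_n,n_pcs,clip,scale_total embedding parameters.
#' @param scheme a [subsample_scheme()].
#' @param lfc_threshold,p_threshold,use_adjusted DEG-count parameters.
#' @param seed root seed; overrides the seeds inside `sim_spec`/`scheme`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim_spec = NULL,
                            input_dir = NULL,
                            annotation_path = NULL,
                            gmt_path = NULL,
                            thresholds = qc_thresholds(),
                            hvg_n = 2000L, n_pcs = 20L, clip = 10,
                            scale_total = 1e4,
                            scheme = subsample_scheme(),
                            lfc_threshold = 0.5, p_threshold = 0.05,
                            use_adjusted = FALSE,
                            seed = 1L) {
  if (is.null(sim_spec)) {
    if (is.null(input_dir) || is.null(annotation_path))
      stop_validation("need either sim_spec or (input_dir + annotation_path)")
    if (!dir.exists(input_dir))
      stop_validation(sprintf("input_dir does not exist: %s", input_dir))
    if (!file.exists(annotation_path))
      stop_validation(sprintf("annotation_path does not exist: %s", annotation_path))
  }
  if (!is.null(gmt_path) && !file.exists(gmt_path))
    stop_validation(sprintf("gmt_path does not exist: %s", gmt_path))
  seed <- as.integer(seed)
  if (!is.null(sim_spec)) sim_spec$seed <- seed
  scheme$seed <- seed
  structure(list(out_dir = out_dir, sim_spec = sim_spec,
                 input_dir = input_dir, annotation_path = annotation_path,
                 gmt_path = gmt_path, thresholds = thresholds,
                 hvg_n = as.integer(hvg_n), n_pcs = as.integer(n_pcs),
                 clip = clip, scale_total = scale_total, scheme = scheme,
                 lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 use_adjusted = use_adjusted, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate/load -> QC -> normalize + HVG + PCA -> per-cell-type shift
#' statistic -> per-cluster DEG counts -> gene-set activity (optional) ->
#' proportion shifts. Writes all tables plus a JSON manifest under
#' `config$out_dir`; rerunning with an identical config reproduces every
#' numeric output exactly (the manifest's timing fields aside). Stage
#' errors propagate with the stage name and are recorded in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_validation("config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "scshift",
    version = as.character(utils::packageVersion("scshift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config_echo(config),
    stages = list())
  state <- new.env(parent = emptyenv())

  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, config$out_dir)
      scshift_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   class(e)[1])
    })
    info <- if (is.list(res) && !is.null(res$info)) res$info else list()
    manifest$stages[[name]] <<- c(list(status = "ok",
                                       seconds = round(proc.time()[["elapsed"]] - t0, 3)),
                                  info)
    res
  }

  stage("load", function() {
    if (!is.null(config$sim_spec)) {
      d <- generate_dataset(config$sim_spec)
      state$m <- d$matrix; state$ann <- d$annotation
      write_tsv(d$truth$cells, file.path(config$out_dir, "truth_cells.tsv"))
      write_tsv(d$truth$genes, file.path(config$out_dir, "truth_genes.tsv"))
    } else {
      state$m <- read_counts_mtx(config$input_dir)
      state$ann <- read_cell_annotation(config$annotation_path)
    }
    list(info = list(genes = nrow(state$m$values), cells = ncol(state$m$values)))
  })

  stage("qc", function() {
    r <- apply_qc_filters(state$m, config$thresholds)
    state$m <- r$matrix
    state$ann <- state$ann[state$ann$barcode %in% state$m$barcodes, , drop = FALSE]
    write_counts_mtx(state$m, file.path(config$out_dir, "filtered_matrix"))
    jsonlite::write_json(unclass(r$report),
                         file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(info = list(genes = nrow(state$m$values), cells = ncol(state$m$values)))
  })

  stage("embed", function() {
    nm <- log_normalize(state$m, config$scale_total)
    hvgs <- select_hvgs(nm, config$hvg_n)
    scaled <- scale_center(nm, hvgs, config$clip)
    K <- min(config$n_pcs, dim(scaled))
    emb <- pca_embed(scaled, K = K, seed = config$seed)
    state$nm <- nm; state$emb <- emb
    write_embedding_tsv(emb, file.path(config$out_dir, "embedding.tsv"))
    list(info = list(n_hvgs = length(hvgs), K = K))
  })

  stage("shift", function() {
    res <- shift_per_celltype(state$emb, state$ann, config$scheme)
    write_tsv(res$table, file.path(config$out_dir, "shift_results.tsv"))
    if (length(res$results))
      write_tsv(shift_replicate_table(res$results),
                file.path(config$out_dir, "shift_replicates.tsv"))
    list(info = list(scored = sum(!res$table$skipped),
                     skipped = sum(res$table$skipped)))
  })

  stage("degs", function() {
    tab <- deg_counts_per_cluster(state$nm, state$ann,
                                  lfc_threshold = config$lfc_threshold,
                                  p_threshold = config$p_threshold,
                                  use_adjusted = config$use_adjusted)
    write_tsv(tab, file.path(config$out_dir, "deg_counts.tsv"))
    list(info = list(clusters_tested = sum(tab$tested)))
  })

  if (!is.null(config$gmt_path)) {
    stage("genesets", function() {
      sets <- read_gmt(config$gmt_path)
      act <- geneset_activity(state$nm, state$ann, sets)
      write_tsv(act$activity, file.path(config$out_dir, "geneset_activity.tsv"))
      write_tsv(act$contrast, file.path(config$out_dir, "geneset_condition_lfc.tsv"))
      list(info = list(sets = length(sets), skipped = length(act$skipped)))
    })
  }

  stage("proportions", function() {
    tab <- proportion_shift(state$ann)
    write_tsv(tab, file.path(config$out_dir, "proportions.tsv"))
    list(info = list(clusters = nrow(tab)))
  })

  write_manifest(manifest, config$out_dir)
  invisible(manifest)
}

# JSON-serializable echo of the config (class attributes stripped).
config_echo <- function(config) {
  echo <- unclass(config)
  for (nm in c("thresholds", "scheme")) echo[[nm]] <- unclass(echo[[nm]])
  if (!is.null(echo$sim_spec)) {
    s <- unclass(echo$sim_spec)
    s$clusters <- as.list(s$clusters)
    echo$sim_spec <- s
  }
  echo
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}
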