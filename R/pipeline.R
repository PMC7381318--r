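#' Run the end-to-end core-selection pipeline
#'
#' Orchestrates the stages simulate/read -> qc -> distance -> select ->
#' evaluate from a single declarative configuration (a named list or the
#' path of a YAML file). Each stage logs its input/output record counts;
#' all artifacts are written under `out_dir`, together with a
#' `manifest.yaml` recording the parameters and seeds used, so a run can be
#' replayed exactly.
#'
#' Configuration keys (defaults in parentheses):
#' \describe{
#'   \item{genotypes}{path of a genotype table to read; if absent, the
#'     `simulate` block is used.}
#'   \item{simulate}{list passed to [sim_genotypes()] (collection_sizes,
#'     n_markers, fst, missing_rate, seed, ...).}
#'   \item{qc}{list: max_missing (0.30), maf_min (0.05), het_max (0.125),
#'     impute_seed (1) or `no_impute: true`.}
#'   \item{select}{list: sizes (required), methods (all nine labels), R
#'     (100), base_seed (0), budget (max_evaluations, patience, restarts),
#'     common_metric ("MRD").}
#'   \item{out_dir}{output directory (required).}
#' }
#'
#' @param config named list or YAML file path.
#' @return invisibly, the [compare_methods()] report; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config field `out_dir` is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[coreselect] ", sprintf(...))

  # --- stage: simulate / read -----------------------------------------
  if (!is.null(config$genotypes)) {
    if (!file.exists(config$genotypes))
      stop("config field `genotypes` names a missing file: ",
           config$genotypes)
    g <- read_genotype_table(config$genotypes)
    log_msg("read %d accessions x %d markers from %s", n_accessions(g),
            n_markers(g), config$genotypes)
  } else if (!is.null(config$simulate)) {
    g <- do.call(sim_genotypes, config$simulate)
    log_msg("simulated %d accessions x %d markers", n_accessions(g),
            n_markers(g))
  } else stop("config must provide either `genotypes` or `simulate`")
  write_genotype_table(g, file.path(out_dir, "genotypes.tsv"))

  # --- stage: qc ------------------------------------------------------
  qc <- config$qc %||% list()
  impute_seed <- if (isTRUE(qc$no_impute)) NULL else qc$impute_seed %||% 1
  qcr <- qc_cascade(g, max_missing = qc$max_missing %||% 0.30,
                    maf_min = qc$maf_min %||% 0.05,
                    het_max = qc$het_max %||% 0.125,
                    impute_seed = impute_seed)
  g <- qcr$genotypes
  log_msg("qc retained %d markers", n_markers(g))
  qc_tab <- do.call(rbind, lapply(qcr$reports, function(r) r$stages))
  write.table(qc_tab, file.path(out_dir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (n_markers(g) == 0) stop("stage qc removed every marker")

  # --- stage: distance ------------------------------------------------
  pairwise <- anyNA(g$calls)
  D <- mrd_dist(g, pairwise_complete = pairwise)
  write_distance_matrix(D, file.path(out_dir, "distance_mrd.tsv"))
  log_msg("MRD distance matrix written (%d x %d)", nrow(D), ncol(D))

  # --- stage: select + evaluate ---------------------------------------
  sel <- config$select %||% list()
  if (is.null(sel$sizes)) stop("config field `select: sizes` is required")
  if (pairwise) stop("selection requires complete data; enable imputation")
  report <- compare_methods(
    g, sizes = as.integer(unlist(sel$sizes)), R = sel$R %||% 100,
    methods = unlist(sel$methods) %||%
      c("ENE-MRD", "ENE-CSE", "ANE-MRD", "ANE-CSE", "SD", "EH", "AC",
        "kmedoids", "random"),
    base_seed = sel$base_seed %||% 0,
    budget = sel$budget %||% list(),
    common_metric = sel$common_metric %||% "MRD")
  log_msg("produced %d cores (%d optimizer cores)", report$n_total_cores,
          report$n_optimizer_cores)

  write.table(report$stability, file.path(out_dir, "stability.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$quality_summary, file.path(out_dir, "quality.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  freq_tab <- do.call(rbind, lapply(names(report$frequencies), function(key)
    data.frame(method_size = key,
               accession = names(report$frequencies[[key]]),
               f = unname(report$frequencies[[key]]),
               stringsAsFactors = FALSE)))
  write.table(freq_tab, file.path(out_dir, "selection_frequencies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "coreselect",
    version = as.character(utils::packageVersion("coreselect")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = config)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_msg("done; artifacts in %s", out_dir)
  invisible(report)
}
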