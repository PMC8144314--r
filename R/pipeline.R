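#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically read from YAML) with:
#' \describe{
#'   \item{summary_stats}{path to the SNP summary-statistics TSV}
#'   \item{genotypes}{list: `path`, `format` ("vcf"/"dosage_tsv")}
#'   \item{genes}{list: `path`, `dialect` ("bed0"/"tsv1")}
#'   \item{expression}{optional list of series, each with `name`, `matrix`,
#'     `groups`, `map` paths}
#'   \item{rule}{boundary rule, default "0kbloc"}
#'   \item{rho_mode}{"r2" (default) or "abs_r"}
#'   \item{vegas}{list: `stages`, `thresholds`}
#'   \item{alpha}{family-wise level, default 0.05}
#'   \item{de_engine}{"moderated" (default) or "ordinary"}
#'   \item{seed}{master seed}
#'   \item{out_dir}{output directory}
#' }
#'
#' @param config A named list or a path to a YAML file.
#' @return The validated config with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    rule = "0kbloc", rho_mode = "r2",
    vegas = list(stages = c(1e3, 1e4, 1e6), thresholds = c(0.1, 0.001)),
    alpha = 0.05, de_engine = "moderated", seed = 1L
  )
  config <- modifyList(defaults, config)
  for (field in c("summary_stats", "genotypes", "genes", "out_dir")) {
    if (is.null(config[[field]])) {
      stop_param(paste0("run config missing required field: ", field))
    }
  }
  if (!config$rule %in% c("0kbloc", "10kbloc", "20kbloc", "50kbloc", "0kbldbin")) {
    stop_param(paste0("unknown boundary rule: ", config$rule))
  }
  if (!config$rho_mode %in% c("abs_r", "r2")) stop_param("rho_mode must be abs_r or r2")
  config
}

#' Run the full gene-based testing pipeline
#'
#' Stages run in order: read inputs, map SNPs to genes, compute per-gene
#' LD, run both gene tests, intersect with a Bonferroni decision, and (when
#' expression series are configured) run the differential-expression screen
#' with probe collapse. All result tables are written as TSV into
#' `out_dir`, together with a `manifest.yaml` recording the config, the
#' seed, and warning counts (dropped rows, ridge repairs, imputed
#' genotypes), which suffices to reproduce the run.
#'
#' @param config A run configuration (list or YAML path); see
#'   [read_run_config()].
#' @return Invisibly, a list with `mapped`, `setscreen`, `vegas`,
#'   `decisions`, `de` (per series) and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "genewise_pipeline_error")
    })
  }

  snps <- stage("read_summary_stats", read_summary_stats(config$summary_stats))
  panel <- stage("read_genotypes",
                 read_genotypes(config$genotypes$path, config$genotypes$format))
  genes <- stage("read_gene_models",
                 read_gene_models(config$genes$path, config$genes$dialect))

  mapped <- stage("map", map_snps(genes, snps, rule = config$rule, panel = panel))
  ss <- stage("setscreen", set_screen_scan(mapped, panel, rho_mode = config$rho_mode))
  vg <- stage("vegas", vegas_scan(
    mapped, panel,
    stages = config$vegas$stages, thresholds = config$vegas$thresholds,
    seed = config$seed
  ))
  dec <- stage("decide", decide(ss, vg, alpha = config$alpha))

  de <- list()
  for (series in config$expression %||% list()) {
    eset <- stage(paste0("read_expression:", series$name),
                  read_expression(series$matrix, series$groups, series$map))
    probes <- stage(paste0("de:", series$name),
                    moderated_t(eset, engine = config$de_engine))
    genes_de <- collapse_probes(probes, eset$probe_map)
    de[[series$name]] <- list(probes = probes, genes = genes_de)
    readr::write_tsv(tidy(probes), file.path(config$out_dir, paste0("de_probes_", series$name, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(genes_de, file.path(config$out_dir, paste0("de_genes_", series$name, ".tsv")),
                     progress = FALSE)
  }

  readr::write_tsv(tidy_scan(ss), file.path(config$out_dir, "setscreen.tsv"), progress = FALSE)
  readr::write_tsv(tidy_scan(vg), file.path(config$out_dir, "vegas.tsv"), progress = FALSE)
  readr::write_tsv(tidy(dec), file.path(config$out_dir, "decisions.tsv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("genewise")),
    seed = config$seed,
    rule = config$rule,
    rho_mode = config$rho_mode,
    alpha = config$alpha,
    n_snps_input = nrow(snps),
    n_snps_underflow = sum(snps$underflow),
    n_rows_rejected = attr(snps, "n_rejected") %||% 0L,
    n_genotypes_imputed = panel$n_imputed %||% 0L,
    n_genes_input = nrow(genes),
    n_genes_dropped = length(attr(mapped, "dropped_genes")),
    n_genes_tested = nrow(dec),
    n_ridge_repairs = sum(vg$ridge > 0),
    n_significant = sum(dec$significant)
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(
    mapped = mapped, setscreen = ss, vegas = vg,
    decisions = dec, de = de, manifest = manifest
  ))
}

tidy_scan <- function(x) as_tibble(unclass_keep(x))
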