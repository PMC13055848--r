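#' Run configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. The
#' defaults are the published analysis choices: proteins need at least two
#' unique peptides to be quantified; compartment calls are made at adjusted
#' p < 0.05; the top-N transmembrane ranking uses N = 200; a transcript
#' counts as robustly expressed in a cell class when more than 30% of its
#' cells express it at log2(CPM+1) of at least 4.
#'
#' @param min_unique_peptides minimum unique peptides per protein (default 2).
#' @param nc_pseudocount intensity pseudocount added to numerator and
#'   denominator of negative-control ratios (default 1).
#' @param significance_alpha significance level for compartment calls,
#'   in (0, 1) (default 0.05).
#' @param adjust multiple-testing adjustment for compartment calls:
#'   `"BH"` (Benjamini-Hochberg, default) or `"none"` (raw p values).
#' @param top_n size of the top transmembrane-protein ranking (default 200).
#' @param ranking_metric metric for the top-N ranking: `"mean_nc_ratio"`
#'   (default) or `"mean_intensity"`.
#' @param inclusive_threshold if `TRUE` (default) the ROC cutoff retains
#'   proteins with ratio >= threshold; `FALSE` retains ratio > threshold.
#' @param expr_fraction_threshold fraction-of-cells threshold, strict `>`
#'   (default 0.30).
#' @param expr_level_threshold expression level threshold in log2(CPM+1)
#'   units, inclusive `>=` (default 4).
#' @param seed integer seed driving all randomness of a run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_unique_peptides = 2L,
                       nc_pseudocount = 1,
                       significance_alpha = 0.05,
                       adjust = c("BH", "none"),
                       top_n = 200L,
                       ranking_metric = c("mean_nc_ratio", "mean_intensity"),
                       inclusive_threshold = TRUE,
                       expr_fraction_threshold = 0.30,
                       expr_level_threshold = 4,
                       seed = 1L) {
  adjust <- match.arg(adjust)
  ranking_metric <- match.arg(ranking_metric)
  cfg <- list(
    schema = "endoprofiler/run_config/1",
    min_unique_peptides = as.integer(min_unique_peptides),
    nc_pseudocount = nc_pseudocount,
    significance_alpha = significance_alpha,
    adjust = adjust,
    top_n = as.integer(top_n),
    ranking_metric = ranking_metric,
    inclusive_threshold = isTRUE(inclusive_threshold),
    expr_fraction_threshold = expr_fraction_threshold,
    expr_level_threshold = expr_level_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$min_unique_peptides < 0L) {
    ep_validation_error("min_unique_peptides must be >= 0")
  }
  if (!is.numeric(cfg$nc_pseudocount) || cfg$nc_pseudocount < 0) {
    ep_validation_error("nc_pseudocount must be a non-negative number")
  }
  if (cfg$significance_alpha <= 0 || cfg$significance_alpha >= 1) {
    ep_validation_error("significance_alpha must lie in (0, 1)")
  }
  if (cfg$top_n < 1L) ep_validation_error("top_n must be >= 1")
  if (cfg$expr_fraction_threshold < 0 || cfg$expr_fraction_threshold > 1) {
    ep_validation_error("expr_fraction_threshold must lie in [0, 1]")
  }
  if (cfg$expr_level_threshold < 0) {
    ep_validation_error("expr_level_threshold must be >= 0")
  }
  invisible(cfg)
}

#' Read and write run configurations
#'
#' Configurations are stored as YAML with a versioned `schema` key so a run
#' can be reproduced from its config file alone.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_config()` returns a `run_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ep_schema_error(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema) || !startsWith(raw$schema, "endoprofiler/run_config/")) {
    ep_schema_error("config file lacks a recognized schema key")
  }
  raw$schema <- NULL
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (", x$schema, ")\n", sep = "")
  for (k in setdiff(names(x), "schema")) {
    cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  }
  invisible(x)
}
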