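#' Analysis configuration
#'
#' Bundles every tunable threshold of the workflow with its default. Defaults
#' follow the published analysis where the study states a value and documented
#' conventions where it does not:
#'
#' * `deg_p`, `deg_fc`: differential-expression significance (raw p) and linear
#'   fold-change gates (p <= 0.05, |FC| >= 2).
#' * `dml_p`, `dml_delta_beta`: differential-methylation Mann-Whitney p and
#'   group-mean beta-difference gates (p <= 0.05, |delta-beta| >= 0.2).
#' * `cn_gain`, `cn_loss`: per-gene copy-number log2 gates used by the
#'   integration filters (>= 0.5 gain, <= -0.8 loss).
#' * `integ_expr_log2`: per-sample expression log2-ratio gate for integration
#'   (|log2| >= 2).
#' * `gistic_q`: FDR q-value cutoff for recurrent regions (q < 0.25).
#' * `adm2_min_probes`, `adm2_min_abs_mean`, `adm2_window_mb`: aberration-call
#'   gates (>= 3 probes, |mean log2| >= 0.58, 5 Mb window context).
#' * `homozygous_del_log2`: log2 at or below which a deletion is treated as
#'   homozygous rather than one-copy (-1.3, roughly a single remaining copy at
#'   50% tumor purity).
#' * `broad_arm_fraction`: a recurrent region is broad when it spans at least
#'   this fraction of its chromosome arm (0.5, the usual GISTIC convention).
#' * `permutations`: permutations for the G-score null (>= 100 enforced).
#' * `cbs_alpha`, `cbs_nperm`: segmentation split-acceptance level and
#'   permutations per split test.
#' * `seed`: integer seed forwarded to every stochastic step.
#'
#' @param ... named overrides of any default listed above.
#' @return An object of class `analysis_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config(permutations = 500)
#' cfg$gistic_q
analysis_config <- function(...) {
  cfg <- list(
    deg_p = 0.05,
    deg_fc = 2.0,
    dml_p = 0.05,
    dml_delta_beta = 0.2,
    cn_gain = 0.5,
    cn_loss = -0.8,
    integ_expr_log2 = 2.0,
    gistic_q = 0.25,
    adm2_min_probes = 3L,
    adm2_min_abs_mean = 0.58,
    adm2_window_mb = 5.0,
    homozygous_del_log2 = -1.3,
    broad_arm_fraction = 0.5,
    permutations = 1000L,
    cbs_alpha = 0.01,
    cbs_nperm = 1000L,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_analysis_config(structure(cfg, class = "analysis_config"))
}

validate_analysis_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  for (f in c("deg_p", "dml_p", "gistic_q")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(f, " must be a probability in (0, 1)")
    }
  }
  if (cfg$deg_fc <= 1) stop("deg_fc must exceed 1 (linear fold-change)")
  if (cfg$dml_delta_beta <= 0 || cfg$dml_delta_beta > 1) {
    stop("dml_delta_beta must lie in (0, 1]")
  }
  if (cfg$cn_gain <= 0) stop("cn_gain must be positive")
  if (cfg$cn_loss >= 0) stop("cn_loss must be negative")
  if (cfg$homozygous_del_log2 >= cfg$cn_loss) {
    stop("homozygous_del_log2 must be below cn_loss")
  }
  if (cfg$adm2_min_probes < 1) stop("adm2_min_probes must be >= 1")
  if (cfg$adm2_min_abs_mean <= 0) stop("adm2_min_abs_mean must be positive")
  if (cfg$broad_arm_fraction <= 0 || cfg$broad_arm_fraction > 1) {
    stop("broad_arm_fraction must lie in (0, 1]")
  }
  if (cfg$permutations < 100) stop("permutations must be >= 100")
  if (cfg$cbs_alpha <= 0 || cfg$cbs_alpha >= 1) stop("cbs_alpha in (0,1)")
  cfg$adm2_min_probes <- as.integer(cfg$adm2_min_probes)
  cfg$permutations <- as.integer(cfg$permutations)
  cfg$cbs_nperm <- as.integer(cfg$cbs_nperm)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Read or write a configuration file
#'
#' Configurations are stored as YAML key-value text mirroring
#' [analysis_config()]; unknown keys are rejected on read.
#'
#' @param path file path.
#' @param cfg an `analysis_config` object.
#' @return `read_config` returns an `analysis_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_analysis_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}
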