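#' Analysis configuration
#'
#' Collects every tunable parameter of the biomarker-discovery pipeline in a
#' single validated object.  Defaults follow the method's standard settings:
#' both significance levels at 0.05, a logarithmic LDA-score reporting
#' threshold of 2.0, and effect sizes stabilised by 30 bootstrap cycles each
#' drawing two-thirds of the samples with replacement, with the influence of
#' the LDA coefficients capped at three orders of magnitude.
#'
#' @param alpha_class significance level for the class-level Kruskal-Wallis
#'   screen (default 0.05).
#' @param alpha_subclass significance level for the pairwise subclass Wilcoxon
#'   tests (default 0.05).
#' @param lda_threshold minimum absolute logarithmic LDA score for a feature
#'   to be reported as a biomarker (default 2.0).
#' @param multiclass_strategy `"strict"` requires a feature to separate every
#'   pair of classes; `"nonstrict"` requires at least one class to separate
#'   from all others.
#' @param pairing_mode `"all_pairs"` compares every subclass of one class with
#'   every subclass of the other; `"same_name"` restricts comparisons to
#'   identically named subclasses (stratified designs).
#' @param min_subclass_size subclass cardinality below which the Wilcoxon test
#'   is replaced by a sign comparison of subclass medians (default 10).
#' @param n_boot number of bootstrap iterations for the LDA effect size
#'   (default 30).
#' @param boot_fraction fraction of samples drawn (with replacement) per
#'   bootstrap iteration (default 2/3).
#' @param coeff_influence_orders cap, in orders of magnitude, on how much the
#'   discriminant-axis component of a feature's effect may exceed its raw
#'   class-mean difference (default 3).
#' @param rng_seed integer seed controlling all stochastic steps.
#' @param hierarchy_separator string separating the segments of hierarchical
#'   feature identifiers (default `"|"`).
#' @param normalization_total per-sample total after normalization
#'   (default 1.0, i.e. relative abundances).
#' @param normalize logical; normalize each sample column before testing
#'   (default `TRUE`; disable for data whose features are independent, such
#'   as the synthetic benchmark).
#' @param stratified_kw logical; if `TRUE` the class-level test is run on
#'   ranks aligned within subclass strata before pooling (off by default).
#' @param kw_fdr logical; if `TRUE`, Benjamini-Hochberg-adjusted
#'   Kruskal-Wallis p-values are gated against `alpha_class` instead of the
#'   raw p-values (off by default; the gate design needs no correction).
#'
#' @return An object of class `lefse_config` (a named list).
#' @examples
#' cfg <- lefse_config(alpha_class = 0.01)
#' cfg$lda_threshold
#' @export
lefse_config <- function(alpha_class = 0.05,
                         alpha_subclass = 0.05,
                         lda_threshold = 2.0,
                         multiclass_strategy = c("strict", "nonstrict"),
                         pairing_mode = c("all_pairs", "same_name"),
                         min_subclass_size = 10L,
                         n_boot = 30L,
                         boot_fraction = 2 / 3,
                         coeff_influence_orders = 3,
                         rng_seed = 1L,
                         hierarchy_separator = "|",
                         normalization_total = 1.0,
                         normalize = TRUE,
                         stratified_kw = FALSE,
                         kw_fdr = FALSE) {
  multiclass_strategy <- match.arg(multiclass_strategy)
  pairing_mode <- match.arg(pairing_mode)
  stopifnot(
    is.numeric(alpha_class), length(alpha_class) == 1L,
    alpha_class > 0, alpha_class < 1,
    is.numeric(alpha_subclass), length(alpha_subclass) == 1L,
    alpha_subclass > 0, alpha_subclass < 1,
    is.numeric(lda_threshold), lda_threshold >= 0,
    is.numeric(min_subclass_size), min_subclass_size >= 0,
    is.numeric(n_boot), n_boot >= 1,
    is.numeric(boot_fraction), boot_fraction > 0, boot_fraction <= 1,
    is.numeric(coeff_influence_orders), coeff_influence_orders >= 0,
    is.character(hierarchy_separator), nchar(hierarchy_separator) > 0,
    is.numeric(normalization_total), normalization_total > 0,
    is.logical(normalize), is.logical(stratified_kw), is.logical(kw_fdr)
  )
  structure(
    list(
      alpha_class = alpha_class,
      alpha_subclass = alpha_subclass,
      lda_threshold = lda_threshold,
      multiclass_strategy = multiclass_strategy,
      pairing_mode = pairing_mode,
      min_subclass_size = as.integer(min_subclass_size),
      n_boot = as.integer(n_boot),
      boot_fraction = boot_fraction,
      coeff_influence_orders = coeff_influence_orders,
      rng_seed = as.integer(rng_seed),
      hierarchy_separator = hierarchy_separator,
      normalization_total = normalization_total,
      normalize = normalize,
      stratified_kw = stratified_kw,
      kw_fdr = kw_fdr
    ),
    class = "lefse_config"
  )
}

#' @export
print.lefse_config <- function(x, ...) {
  cat("lefse_config\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
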