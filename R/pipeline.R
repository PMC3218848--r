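#' Run the full biomarker-discovery pipeline
#'
#' Normalizes the table (unless disabled), screens every feature with the
#' class-level Kruskal-Wallis test, gates the survivors on subclass
#' consistency, and scores the remaining candidates with the bootstrapped
#' LDA effect size.  Features whose logarithmic score reaches
#' `config$lda_threshold` are reported as biomarkers, ranked by descending
#' score.
#'
#' @param table an [abundance_table].
#' @param annotation a [sample_annotation] for the same samples.
#' @param config a [lefse_config()].
#' @return An object of class `lefse_result`: a list with
#'   \describe{
#'     \item{results}{data.frame, one row per feature: `feature`,
#'       `log_max_mean` (log10 of the highest class mean on the
#'       `[1, 10^6]` scale), `enriched_class`, `lda_score` (`NA` unless both
#'       gates passed), `kw_p`, `passed_kw`, `passed_consistency`,
#'       `is_biomarker`.}
#'     \item{biomarkers}{the biomarker rows, sorted by descending score.}
#'     \item{report}{stage counts, configuration echo and warnings.}
#'     \item{table, annotation}{the (normalized) inputs, for plotting.}
#'   }
#' @examples
#' syn <- generate_synthetic(synthetic_spec("a", t = 150, n_features = 20,
#'                                          n_samples = 40, seed = 1))
#' res <- lefse(syn$table, syn$annotation,
#'              lefse_config(normalize = FALSE, rng_seed = 1))
#' res$report$counts
#' @export
lefse <- function(table, annotation, config = lefse_config()) {
  warnings_seen <- character()
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  if (config$normalize && !table$normalized) {
    table <- withCallingHandlers(
      normalize_per_sample(table, config$normalization_total),
      warning = note)
  }
  sig <- run_significance(table, annotation, config)
  class_means <- attr(sig, "class_means")
  gates <- attr(sig, "gates")
  candidates <- sig$feature[sig$passed_consistency]

  scores <- rep(NA_real_, nrow(sig))
  names(scores) <- sig$feature
  if (length(candidates)) {
    pairs <- unique(do.call(c, lapply(gates[match(candidates, sig$feature)],
                                      `[[`, "passing_class_pairs")))
    if (!length(pairs)) {
      pairs <- utils::combn(sort(unique(annotation$class)), 2L,
                            simplify = FALSE)
    }
    design <- build_design(table, annotation, candidates)
    lda <- withCallingHandlers(bootstrap_lda(design, pairs, config),
                               warning = note)
    scores[lda$feature] <- lda$score
    # restrict each feature's max to the class pairs that passed for it
    pair_means <- attr(lda, "pair_means")
    scale <- 1e6 / config$normalization_total
    for (f in intersect(candidates, rownames(pair_means))) {
      own <- attr(sig, "gates")[[match(f, sig$feature)]]$passing_class_pairs
      keys <- intersect(vapply(own, paste, character(1L),
                               collapse = " vs "), colnames(pair_means))
      if (length(keys)) {
        eff <- max(pair_means[f, keys], na.rm = TRUE)
        if (is.finite(eff)) scores[f] <- log10(max(eff * scale, 1))
      }
    }
    dropped <- setdiff(candidates, design$features)
    if (length(dropped)) {  # constant candidates carry no effect
      scores[dropped] <- 0
    }
  }
  scale <- 1e6 / config$normalization_total
  results <- data.frame(
    feature = sig$feature,
    log_max_mean = log10(pmax(apply(class_means, 1L, max) * scale, 1)),
    enriched_class = sig$enriched_class,
    lda_score = unname(scores),
    kw_p = sig$kw_p,
    passed_kw = sig$passed_kw,
    passed_consistency = sig$passed_consistency,
    stringsAsFactors = FALSE
  )
  results$is_biomarker <- !is.na(results$lda_score) &
    results$lda_score >= config$lda_threshold
  biomarkers <- results[results$is_biomarker, , drop = FALSE]
  biomarkers <- biomarkers[order(-biomarkers$lda_score,
                                 biomarkers$feature), , drop = FALSE]
  report <- list(
    config = config,
    counts = c(features = nrow(results),
               kw_passing = sum(results$passed_kw),
               consistency_passing = sum(results$passed_consistency),
               biomarkers = nrow(biomarkers)),
    warnings = warnings_seen
  )
  structure(list(results = results, biomarkers = biomarkers, report = report,
                 table = table, annotation = annotation,
                 class_means = class_means),
            class = "lefse_result")
}

#' @export
print.lefse_result <- function(x, ...) {
  cts <- x$report$counts
  cat(sprintf(paste0("lefse_result: %d features -> %d passed the class test",
                     " -> %d consistent -> %d biomarkers\n"),
              cts["features"], cts["kw_passing"], cts["consistency_passing"],
              cts["biomarkers"]))
  if (nrow(x$biomarkers)) {
    top <- utils::head(x$biomarkers[, c("feature", "enriched_class",
                                        "lda_score", "kw_p")], 10L)
    print(top, row.names = FALSE, digits = 4L)
    if (nrow(x$biomarkers) > 10L) {
      cat("... and", nrow(x$biomarkers) - 10L, "more\n")
    }
  }
  if (length(x$report$warnings)) {
    cat("warnings:", paste(unique(x$report$warnings), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write per-feature results to TSV
#'
#' Columns: `feature`, `log_max_mean`, `enriched_class`, `lda_score` (empty
#' when the feature did not pass both gates) and `kw_p`, one row per input
#' feature in the original order.
#'
#' @param result a [lefse()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lefse_results <- function(result, path) {
  stopifnot(inherits(result, "lefse_result"))
  r <- result$results
  out <- data.frame(
    feature = r$feature,
    log_max_mean = sprintf("%.6f", r$log_max_mean),
    enriched_class = r$enriched_class,
    lda_score = ifelse(is.na(r$lda_score), "", sprintf("%.6f", r$lda_score)),
    kw_p = sprintf("%.6g", r$kw_p),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
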