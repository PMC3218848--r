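#' Class-level Kruskal-Wallis screen
#'
#' Tests whether a feature's abundances are identically distributed across
#' classes, using the midrank-based Kruskal-Wallis statistic with tie
#' correction and the chi-square approximation on `k - 1` degrees of freedom.
#' A feature identical across all samples yields `p = 1` (no rank variation,
#' nothing to reject).
#'
#' With `strata` given (and `stratified = TRUE` in the caller), values are
#' replaced by midranks computed within each stratum, rescaled to a common
#' 0..1 range, before the pooled test; this aligns rank information across
#' strata of unequal size.
#'
#' @param values numeric vector, one abundance per sample.
#' @param classes class label per sample (at least two classes, each with at
#'   least one sample).
#' @param alpha significance level; the gate is `p < alpha`.
#' @param strata optional stratum label per sample for the aligned-rank
#'   variant; `NULL` for the plain class-factor test.
#' @return A list with `statistic` (H), `p`, and `passed`.
#' @examples
#' kw_class_test(c(1, 2, 3, 7, 8, 9), rep(c("A", "B"), each = 3))
#' @export
kw_class_test <- function(values, classes, alpha = 0.05, strata = NULL) {
  classes <- as.character(classes)
  stopifnot(length(values) == length(classes))
  cls <- unique(classes)
  if (length(cls) < 2L) stop("design error: fewer than 2 classes")
  if (any(table(factor(classes, levels = cls)) == 0L)) {
    stop("design error: class with zero samples")
  }
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p = 1, passed = FALSE))
  }
  x <- values
  if (!is.null(strata)) {
    x <- numeric(length(values))
    for (idx in split(seq_along(values), as.character(strata))) {
      r <- rank(values[idx])
      x[idx] <- if (length(idx) > 1L) (r - 1) / (length(idx) - 1) else 0.5
    }
  }
  kt <- stats::kruskal.test(x, factor(classes, levels = cls))
  p <- kt$p.value
  h <- unname(kt$statistic)
  if (!is.finite(p)) {  # complete ties within the correction
    p <- 1
    h <- 0
  }
  list(statistic = h, p = p, passed = p < alpha)
}

#' Pairwise Wilcoxon rank-sum comparison
#'
#' Two-sided unpaired rank-sum test between two groups, with the direction of
#' the difference taken as the sign of `median(a) - median(b)` (0 when the
#' medians are equal).  The exact null distribution is used when both groups
#' have at most `exact_max` observations and no ties are present; otherwise
#' the normal approximation with continuity and tie correction.
#'
#' @param a,b numeric vectors of abundances for the two groups (non-empty).
#' @param alpha significance level; the gate is `p < alpha`.
#' @param exact_max largest group size for which the exact distribution is
#'   used (default 25).
#' @return A list with `p`, `direction` (-1, 0, +1) and `passed`.
#' @examples
#' wilcoxon_pair(c(1, 2, 3, 4), c(10, 11, 12, 13))
#' @export
wilcoxon_pair <- function(a, b, alpha = 0.05, exact_max = 25L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- max(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  d <- sign(stats::median(a) - stats::median(b))
  list(p = wt$p.value, direction = d, passed = wt$p.value < alpha)
}

subclasses_of <- function(annotation, cls) {
  sort(unique(annotation$subclass[annotation$class == cls]))
}

#' Subclass-level biological-consistency gate for one class pair
#'
#' Step 2 of the pipeline for a single pair of classes.  Enumerates subclass
#' pairs -- every subclass of the first class against every subclass of the
#' second under `all_pairs`, or only identically named subclasses under
#' `same_name` -- and applies [wilcoxon_pair()] to each, unless either
#' subclass has fewer than `min_subclass_size` samples, in which case the
#' test is replaced by a comparison of subclass medians (the pair passes when
#' the median difference is non-zero with the common sign).  The verdict
#' passes only if every pair passes with one common non-zero direction; no
#' multiple-testing correction is applied because all comparisons are
#' required to reject.
#'
#' @param values numeric vector, one abundance per sample.
#' @param annotation a [sample_annotation].
#' @param config a [lefse_config()].
#' @param class_pair character vector of two distinct class labels; the
#'   reported direction compares medians of the first class minus the second.
#' @return An object of class `consistency_verdict`: a list with `passed`,
#'   `direction` (the common direction, 0 if none), `pairs` (data.frame with
#'   columns subclass_a, subclass_b, test, p_or_sign, direction) and
#'   `failing_reason` (`NA`, `"p_above_alpha"` or `"sign_conflict"`).
#' @export
subclass_consistency <- function(values, annotation, config = lefse_config(),
                                 class_pair) {
  stopifnot(length(class_pair) == 2L, class_pair[1L] != class_pair[2L])
  sa <- subclasses_of(annotation, class_pair[1L])
  sb <- subclasses_of(annotation, class_pair[2L])
  if (config$pairing_mode == "same_name") {
    if (!identical(sa, sb)) {
      stop("design error: same_name pairing requires identical subclass ",
           "name sets in classes ", class_pair[1L], " and ", class_pair[2L])
    }
    pairs <- data.frame(subclass_a = sa, subclass_b = sb,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- expand.grid(subclass_a = sa, subclass_b = sb,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  n <- nrow(pairs)
  pairs$test <- character(n)
  pairs$p_or_sign <- numeric(n)
  pairs$direction <- numeric(n)
  pair_ok <- logical(n)
  any_p_fail <- FALSE
  for (i in seq_len(n)) {
    va <- values[annotation$subclass == pairs$subclass_a[i] &
                   annotation$class == class_pair[1L]]
    vb <- values[annotation$subclass == pairs$subclass_b[i] &
                   annotation$class == class_pair[2L]]
    if (min(length(va), length(vb)) < config$min_subclass_size) {
      d <- sign(stats::median(va) - stats::median(vb))
      pairs$test[i] <- "median_sign"
      pairs$p_or_sign[i] <- d
      pairs$direction[i] <- d
      pair_ok[i] <- d != 0
    } else {
      w <- wilcoxon_pair(va, vb, alpha = config$alpha_subclass)
      pairs$test[i] <- "wilcoxon"
      pairs$p_or_sign[i] <- w$p
      pairs$direction[i] <- w$direction
      pair_ok[i] <- w$passed && w$direction != 0
      if (!w$passed) any_p_fail <- TRUE
    }
  }
  dirs <- unique(pairs$direction)
  consistent <- length(dirs) == 1L && dirs[1L] != 0
  passed <- all(pair_ok) && consistent
  reason <- if (passed) NA_character_
            else if (any_p_fail) "p_above_alpha" else "sign_conflict"
  structure(
    list(passed = passed,
         direction = if (consistent) dirs[1L] else 0,
         pairs = pairs,
         failing_reason = reason),
    class = "consistency_verdict"
  )
}

#' Multiclass consistency gate
#'
#' Applies [subclass_consistency()] to class pairs under the configured
#' multiclass strategy.  `strict` requires every unordered class pair to
#' pass; `nonstrict` requires at least one class to pass against all the
#' others.  With two classes both strategies reduce to the single pair.
#'
#' @param values numeric vector, one abundance per sample.
#' @param annotation a [sample_annotation].
#' @param config a [lefse_config()].
#' @return A list with `passed`, `passing_class_pairs` (list of length-2
#'   character vectors for every pair that individually passed; consumed by
#'   the LDA step) and `verdicts` (per-pair [subclass_consistency()] results,
#'   named `"A vs B"`).
#' @export
multiclass_gate <- function(values, annotation, config = lefse_config()) {
  classes <- sort(unique(annotation$class))
  pair_mat <- utils::combn(classes, 2L)
  verdicts <- vector("list", ncol(pair_mat))
  names(verdicts) <- apply(pair_mat, 2L, paste, collapse = " vs ")
  for (j in seq_len(ncol(pair_mat))) {
    verdicts[[j]] <- subclass_consistency(values, annotation, config,
                                          pair_mat[, j])
  }
  ok <- vapply(verdicts, `[[`, logical(1L), "passed")
  passed <- if (config$multiclass_strategy == "strict") {
    all(ok)
  } else {
    any(vapply(classes, function(cl) {
      involved <- apply(pair_mat, 2L, function(p) cl %in% p)
      all(ok[involved])
    }, logical(1L)))
  }
  list(passed = passed,
       passing_class_pairs = lapply(which(ok), function(j) pair_mat[, j]),
       verdicts = verdicts)
}

#' Run the two significance gates over every feature
#'
#' Applies the class-level Kruskal-Wallis screen to every feature and the
#' subclass consistency gate to the features that pass it.  Also records,
#' for every feature, the class with the highest within-class mean (ties
#' broken towards the lexicographically smallest class label) and the
#' per-class means.
#'
#' @param table an [abundance_table] (normalized unless `config$normalize`
#'   is `FALSE`).
#' @param annotation a [sample_annotation] for the same samples.
#' @param config a [lefse_config()].
#' @return A data.frame with one row per feature and columns `feature`,
#'   `kw_p`, `passed_kw`, `passed_consistency`, `enriched_class`; per-class
#'   means are attached as attribute `class_means` (features x classes
#'   matrix) and the per-feature gate details as attribute `gates` (list of
#'   [multiclass_gate()] results for KW-passing features).
#' @export
run_significance <- function(table, annotation, config = lefse_config()) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(annotation, "sample_annotation"))
  if (!identical(table$sample_ids, annotation$sample_id)) {
    stop("table and annotation describe different samples")
  }
  design <- validate_design(annotation, config)
  classes <- design$classes
  v <- table$values
  n_feat <- nrow(v)
  strata <- if (config$stratified_kw) annotation$subclass else NULL

  kw <- lapply(seq_len(n_feat), function(i) {
    kw_class_test(v[i, ], annotation$class, alpha = config$alpha_class,
                  strata = strata)
  })
  kw_p <- vapply(kw, `[[`, numeric(1L), "p")
  gate_p <- if (config$kw_fdr) stats::p.adjust(kw_p, method = "BH") else kw_p
  passed_kw <- gate_p < config$alpha_class

  class_means <- t(apply(v, 1L, function(x) {
    vapply(classes, function(cl) mean(x[annotation$class == cl]), numeric(1L))
  }))
  colnames(class_means) <- classes
  rownames(class_means) <- table$feature_ids
  enriched <- classes[apply(class_means, 1L, which.max)]

  gates <- vector("list", n_feat)
  passed_cons <- logical(n_feat)
  for (i in which(passed_kw)) {
    g <- multiclass_gate(v[i, ], annotation, config)
    gates[[i]] <- g
    passed_cons[i] <- g$passed
  }
  res <- data.frame(feature = table$feature_ids,
                    kw_p = kw_p,
                    passed_kw = passed_kw,
                    passed_consistency = passed_cons,
                    enriched_class = enriched,
                    stringsAsFactors = FALSE)
  attr(res, "class_means") <- class_means
  attr(res, "gates") <- gates
  res
}
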