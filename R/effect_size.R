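#' Build the LDA design for candidate features
#'
#' Assembles the independent variables for the effect-size model: the
#' candidate feature columns plus, where informative, integer-coded subclass
#' and subject covariates.  The class is the dependent variable.  Degenerate
#' covariates carry no information beyond the class or the sample identity
#' and are dropped: the subclass covariate is omitted when subclasses
#' coincide with classes, the subject covariate when every sample is its own
#' subject.
#'
#' @param table an [abundance_table].
#' @param annotation a [sample_annotation].
#' @param features character vector of candidate feature ids (at least one).
#' @return A list with `x` (samples x predictors numeric matrix), `y`
#'   (factor of class labels) and `features` (the feature ids among the
#'   predictor columns).
#' @export
build_design <- function(table, annotation, features) {
  stopifnot(length(features) >= 1L, all(features %in% table$feature_ids))
  if (any(table(annotation$class) < 2L)) {
    stop("effect-size error: a class has a single sample; the model cannot ",
         "be fit")
  }
  x <- t(table$values[features, , drop = FALSE])
  colnames(x) <- features
  subclass_informative <- !identical(annotation$subclass, annotation$class)
  subject_informative <- anyDuplicated(annotation$subject) > 0L
  if (subclass_informative) {
    x <- cbind(x, .subclass = as.integer(factor(annotation$subclass)))
  }
  if (subject_informative) {
    x <- cbind(x, .subject = as.integer(factor(annotation$subject)))
  }
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  x <- x[, keep, drop = FALSE]
  list(x = x, y = factor(annotation$class),
       features = intersect(features, colnames(x)))
}

# Fit a two-class linear discriminant, jittering the predictors with a tiny
# seeded perturbation when the within-class scatter is singular.  Returns
# the first-axis scaling vector (named by predictor) or NULL on failure.
fit_lda_axis <- function(x, y, jitter_rel = 1e-10, max_tries = 3L) {
  for (k in seq_len(max_tries)) {
    fit <- tryCatch(
      suppressWarnings(MASS::lda(x, grouping = y, tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      w <- fit$scaling[, 1L]
      names(w) <- colnames(x)
      return(w)
    }
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1
    x <- x + matrix(stats::rnorm(length(x)), nrow(x)) *
      rep(sds * jitter_rel, each = nrow(x))
  }
  NULL
}

#' Per-feature LDA effect size for one class pair
#'
#' Fits a two-class linear discriminant on the samples of the pair and, for
#' every candidate feature, averages two components measured on the
#' abundance scale: the raw absolute difference of class means, and the
#' feature's contribution to the separation of the class means along the
#' first (unit-normalized) discriminant axis.  The axis component is capped
#' at `10^coeff_influence_orders` times the raw component so that
#' near-singular discriminants cannot dominate the average.
#'
#' @param design a [build_design()] result (possibly subset to a bootstrap
#'   draw).
#' @param class_pair character vector of two class labels present in the
#'   design.
#' @param coeff_influence_orders cap (orders of magnitude) on the axis
#'   component relative to the raw component.
#' @return Named numeric vector of effects, one per candidate feature, or
#'   `NULL` when the discriminant cannot be fit.
#' @export
lda_effect_one_pair <- function(design, class_pair,
                                coeff_influence_orders = 3) {
  sel <- design$y %in% class_pair
  x <- design$x[sel, , drop = FALSE]
  y <- droplevels(design$y[sel])
  if (any(table(y) < 2L)) {
    stop("effect-size error: both classes need at least 2 samples")
  }
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  feats <- design$features
  raw <- vapply(feats, function(f) {
    if (!f %in% colnames(x)) return(0)
    abs(mean(x[y == class_pair[1L], f]) - mean(x[y == class_pair[2L], f]))
  }, numeric(1L))
  if (!any(keep)) {          # every predictor constant in this draw
    return(raw / 2)
  }
  xk <- x[, keep, drop = FALSE]
  w <- fit_lda_axis(xk, y)
  if (is.null(w)) return(NULL)
  w_unit <- w / sqrt(sum(w^2))
  proj <- as.vector(xk %*% w_unit)
  dproj <- mean(proj[y == class_pair[1L]]) - mean(proj[y == class_pair[2L]])
  cap <- 10^coeff_influence_orders
  axis <- vapply(feats, function(f) {
    if (!f %in% names(w_unit)) return(0)
    min(abs(w_unit[[f]] * dproj), cap * raw[[f]])
  }, numeric(1L))
  (raw + axis) / 2
}

#' Bootstrapped LDA scores
#'
#' Estimates each candidate feature's effect size by repeated stratified
#' bootstrap: each iteration draws `ceiling(boot_fraction * n_c)` samples
#' with replacement within every class, computes [lda_effect_one_pair()] for
#' every passing class pair, and the per-pair effects are averaged over
#' iterations; each feature then takes the maximum mean effect over its
#' passing pairs.  The logarithmic score maps the effect into the
#' `[1, 10^6]` interval: `score = log10(max(effect * 10^6 / total, 1))`, so
#' relative abundances (total 1) yield scores in `[0, 6]`.
#'
#' @param design a [build_design()] result.
#' @param passing_class_pairs list of length-2 character vectors (the class
#'   pairs that passed the consistency gate for these features, or all pairs).
#' @param config a [lefse_config()]; uses `n_boot`, `boot_fraction`,
#'   `coeff_influence_orders`, `rng_seed` and `normalization_total`.
#' @return A data.frame with columns `feature`, `effect`, `score` and
#'   `class_pair_of_max`, in the input feature order.
#' @export
bootstrap_lda <- function(design, passing_class_pairs,
                          config = lefse_config()) {
  stopifnot(length(passing_class_pairs) >= 1L)
  feats <- design$features
  pair_keys <- vapply(passing_class_pairs, paste, character(1L),
                      collapse = " vs ")
  sums <- matrix(0, nrow = length(feats), ncol = length(pair_keys),
                 dimnames = list(feats, pair_keys))
  counts <- matrix(0L, nrow = length(feats), ncol = length(pair_keys),
                   dimnames = list(feats, pair_keys))
  idx_by_class <- split(seq_along(design$y), design$y)
  n_skipped <- 0L
  with_seed(config$rng_seed, {
    for (it in seq_len(config$n_boot)) {
      draw <- unlist(lapply(idx_by_class, function(idx) {
        sample(idx, size = ceiling(config$boot_fraction * length(idx)),
               replace = TRUE)
      }), use.names = FALSE)
      sub <- list(x = design$x[draw, , drop = FALSE], y = design$y[draw],
                  features = feats)
      for (j in seq_along(pair_keys)) {
        eff <- lda_effect_one_pair(sub, passing_class_pairs[[j]],
                                   config$coeff_influence_orders)
        if (is.null(eff)) {
          n_skipped <- n_skipped + 1L
          next
        }
        sums[, j] <- sums[, j] + eff[feats]
        counts[, j] <- counts[, j] + 1L
      }
    }
  })
  if (n_skipped > 0L) {
    warning(n_skipped, " bootstrap fit(s) skipped (singular discriminant)")
  }
  if (all(counts == 0L)) {
    stop("effect-size error: no bootstrap iteration produced a usable fit")
  }
  means <- sums / pmax(counts, 1L)
  means[counts == 0L] <- NA_real_
  best <- apply(means, 1L, function(m) {
    if (all(is.na(m))) return(c(NA_real_, NA_integer_))
    j <- which.max(m)
    c(m[j], j)
  })
  effect <- best[1L, ]
  pair_of_max <- ifelse(is.na(best[2L, ]), NA_character_,
                        pair_keys[best[2L, ]])
  scale <- 1e6 / config$normalization_total
  score <- log10(pmax(effect * scale, 1))
  out <- data.frame(feature = feats, effect = effect, score = score,
                    class_pair_of_max = pair_of_max,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pair_means") <- means
  out
}
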