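#' Specification of a synthetic benchmark dataset
#'
#' Describes one Gaussian dataset of the three benchmark collections used to
#' measure detector error rates.  Every dataset has `n_features` features
#' (half positive, half negative) over `n_samples` samples split evenly into
#' two classes, each class split evenly into two subclasses.
#'
#' Collections:
#' \describe{
#'   \item{a}{subclass structure meaningless; negatives are
#'     `N(mu, sigma)` everywhere (`sigma` 100), positives have class means
#'     `mu - t` and `mu + t` (`t` from 1 to 150).}
#'   \item{b}{as (a) with `t = 1000` and `sigma` varied (1000 to 10000).}
#'   \item{c}{positives as in (b); negatives have inconsistent subclasses:
#'     the first class's second subclass and the second class's first
#'     subclass share mean `mu`, while the outer subclasses sit at
#'     `mu - t` and `mu + t` (`t = 1000`) -- a class-level difference that
#'     is not consistent between subclasses.}
#' }
#'
#' @param collection `"a"`, `"b"` or `"c"`.
#' @param t separation parameter (defaults: the grid value for (a), 1000
#'   for (b)/(c)).
#' @param sigma within-group standard deviation (defaults: 100 for (a), the
#'   grid value for (b)/(c)).
#' @param n_features total feature count (default 1000, half positive).
#' @param n_samples total sample count (default 100).
#' @param base_mean baseline mean abundance (default 10000).
#' @param seed RNG seed for [generate_synthetic()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(collection = c("a", "b", "c"), t = NULL,
                           sigma = NULL, n_features = 1000L,
                           n_samples = 100L, base_mean = 10000,
                           seed = 1L) {
  collection <- match.arg(collection)
  if (is.null(t)) t <- if (collection == "a") 100 else 1000
  if (is.null(sigma)) sigma <- if (collection == "a") 100 else 1000
  stopifnot(sigma > 0, t >= 0, n_features >= 2L, n_features %% 2L == 0L,
            n_samples >= 8L, n_samples %% 4L == 0L)
  structure(list(collection = collection, t = t, sigma = sigma,
                 n_features = as.integer(n_features),
                 n_samples = as.integer(n_samples),
                 base_mean = base_mean, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic benchmark dataset
#'
#' Draws the Gaussian feature matrix described by a [synthetic_spec()].
#' Values are kept exactly as drawn (no truncation at zero, which would
#' distort the null distribution), so the table is built without the
#' non-negativity check and must be analyzed unnormalized
#' (`normalize = FALSE`), as the features are independent.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `table` ([abundance_table]), `annotation`
#'   ([sample_annotation]) and `truth` (logical vector, `TRUE` for positive
#'   features, named by feature id).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_pos <- spec$n_features %/% 2L
  n_neg <- spec$n_features - n_pos
  quarter <- spec$n_samples %/% 4L
  cls <- rep(c("class1", "class2"), each = 2L * quarter)
  sub <- rep(c("c1_s1", "c1_s2", "c2_s1", "c2_s2"), each = quarter)
  mu <- spec$base_mean
  t <- spec$t
  # per-subclass means, rows: positive / negative feature kinds
  pos_means <- c(c1_s1 = mu - t, c1_s2 = mu - t,
                 c2_s1 = mu + t, c2_s2 = mu + t)
  neg_means <- if (spec$collection == "c") {
    c(c1_s1 = mu - t, c1_s2 = mu, c2_s1 = mu, c2_s2 = mu + t)
  } else {
    c(c1_s1 = mu, c1_s2 = mu, c2_s1 = mu, c2_s2 = mu)
  }
  with_seed(spec$seed, {
    draw <- function(means, n_feat) {
      m <- matrix(stats::rnorm(n_feat * spec$n_samples, sd = spec$sigma),
                  nrow = n_feat)
      sweep(m, 2L, means[sub], "+")
    }
    values <- rbind(draw(pos_means, n_pos), draw(neg_means, n_neg))
  })
  ids <- c(sprintf("pos_%04d", seq_len(n_pos)),
           sprintf("neg_%04d", seq_len(n_neg)))
  tab <- abundance_table(values, feature_ids = ids,
                         sample_ids = paste0("sample_", seq_len(spec$n_samples)),
                         nonnegative = FALSE)
  ann <- sample_annotation(tab$sample_ids, cls, sub)
  truth <- stats::setNames(c(rep(TRUE, n_pos), rep(FALSE, n_neg)), ids)
  list(table = tab, annotation = ann, truth = truth)
}

#' Error rates of a detection
#'
#' False positive and false negative rates with the *total* feature count as
#' denominator: `fpr` is the number of detected negatives over `n_features`,
#' `fnr` the number of missed positives over `n_features`.  With half the
#' features positive, both rates lie in `[0, 0.5]`.
#'
#' @param detected character vector of detected feature ids.
#' @param truth named logical vector as returned by [generate_synthetic()].
#' @return A list with `fpr`, `fnr` and `n_detected`.
#' @export
evaluate_detection <- function(detected, truth) {
  stopifnot(all(detected %in% names(truth)))
  n <- length(truth)
  pos <- names(truth)[truth]
  neg <- names(truth)[!truth]
  list(fpr = length(intersect(detected, neg)) / n,
       fnr = length(setdiff(pos, detected)) / n,
       n_detected = length(detected))
}

#' Detect differential features with a configurable detector
#'
#' `"kw"` reports every feature whose class-level Kruskal-Wallis p-value is
#' below `config$alpha_class`; `"lefse"` additionally requires the subclass
#' consistency gate (the LDA scoring step plays no role in detection).
#'
#' @param table an [abundance_table].
#' @param annotation a [sample_annotation].
#' @param detector `"kw"` or `"lefse"`.
#' @param config a [lefse_config()].
#' @return Character vector of detected feature ids.
#' @export
detect_features <- function(table, annotation,
                            detector = c("kw", "lefse"),
                            config = lefse_config(normalize = FALSE)) {
  detector <- match.arg(detector)
  if (config$normalize && !table$normalized) {
    table <- normalize_per_sample(table, config$normalization_total)
  }
  v <- table$values
  kw_pass <- vapply(seq_len(nrow(v)), function(i) {
    kw_class_test(v[i, ], annotation$class, alpha = config$alpha_class)$passed
  }, logical(1L))
  if (detector == "kw") {
    return(table$feature_ids[kw_pass])
  }
  pass <- kw_pass
  for (i in which(kw_pass)) {
    pass[i] <- multiclass_gate(v[i, ], annotation, config)$passed
  }
  table$feature_ids[pass]
}

#' Benchmark a detector over a parameter grid
#'
#' Generates replicate synthetic datasets at every grid point, runs the
#' detector at `alpha = 0.05` (class and subclass) with per-sample
#' normalization disabled, and records the error rates.  Default grids:
#' collection (a) varies the separation `t` over
#' `{1, 10, 25, 50, 75, 100, 125, 150}`; collections (b) and (c) vary the
#' standard deviation over `{1000, 2500, 5000, 7500, 10000}`.
#'
#' @param detector `"kw"` or `"lefse"`.
#' @param collection `"a"`, `"b"` or `"c"`.
#' @param grid numeric vector of `t` values (collection a) or `sigma` values
#'   (b, c); `NULL` for the defaults above.
#' @param replicates datasets per grid point (default 10).
#' @param seed master seed; per-dataset seeds are derived from it.
#' @param config detector configuration (default alphas 0.05, no
#'   normalization).
#' @param n_features,n_samples dataset dimensions (defaults 1000 and 100).
#' @return A data.frame with one row per generated dataset: `detector`,
#'   `collection`, `param`, `replicate`, `seed`, `fpr`, `fnr`, `n_detected`.
#' @export
run_benchmark <- function(detector = c("kw", "lefse"),
                          collection = c("a", "b", "c"), grid = NULL,
                          replicates = 10L, seed = 1L,
                          config = lefse_config(normalize = FALSE),
                          n_features = 1000L, n_samples = 100L) {
  detector <- match.arg(detector)
  collection <- match.arg(collection)
  if (is.null(grid)) {
    grid <- if (collection == "a") c(1, 10, 25, 50, 75, 100, 125, 150)
            else c(1000, 2500, 5000, 7500, 10000)
  }
  n_runs <- length(grid) * replicates
  run_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_runs))
  out <- vector("list", n_runs)
  k <- 0L
  for (g in grid) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      spec <- if (collection == "a") {
        synthetic_spec("a", t = g, n_features = n_features,
                       n_samples = n_samples, seed = run_seeds[k])
      } else {
        synthetic_spec(collection, sigma = g, n_features = n_features,
                       n_samples = n_samples, seed = run_seeds[k])
      }
      syn <- generate_synthetic(spec)
      det <- detect_features(syn$table, syn$annotation, detector, config)
      ev <- evaluate_detection(det, syn$truth)
      out[[k]] <- data.frame(detector = detector, collection = collection,
                             param = g, replicate = r, seed = run_seeds[k],
                             fpr = ev$fpr, fnr = ev$fnr,
                             n_detected = ev$n_detected,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Synthetic murine-colitis-style demonstration table
#'
#' Builds a small synthetic 16S-style dataset emulating the design of a
#' murine ulcerative-colitis comparison: 20 case and 10 control fecal
#' samples, clade-path feature rows spanning an RDP-like taxonomy from
#' domain to genus, and exactly 19 truly differential clades whose
#' directions mirror the biology of that model (Bifidobacteriaceae and
#' *Bifidobacterium* depleted in the case class, Lachnospiraceae and
#' Ruminococcaceae enriched with the exceptions *Roseburia* and
#' *Papillibacter*, Staphylococcaceae and Porphyromonadaceae
#' control-enriched).  This is a synthetic stand-in, not the original study
#' data; it is intended for examples and for end-to-end pipeline checks
#' against a known ground truth.
#'
#' Genus-level abundances are log-normal around class-specific means;
#' ancestor clades are sums of their descendant genera, so the hierarchy is
#' internally consistent and differential genera propagate upward exactly
#' as designed.
#'
#' @param seed RNG seed for the log-normal draws.
#' @param n_case,n_control samples per class (defaults 20 and 10).
#' @return A list with `table` (unnormalized [abundance_table]),
#'   `annotation` (class `case`/`control`, subject per mouse) and `truth`
#'   (character vector of the 19 differential clade ids).
#' @export
synthetic_colitis_table <- function(seed = 7L, n_case = 20L,
                                    n_control = 10L) {
  genera <- data.frame(
    path = c(
      "Bacteria|Actinobacteria|Actinobacteria|Bifidobacteriales|Bifidobacteriaceae|Bifidobacterium",
      "Bacteria|Actinobacteria|Actinobacteria|Bifidobacteriales|Bifidobacteriaceae|Metascardovia",
      "Bacteria|Actinobacteria|Actinobacteria|Bifidobacteriales|Bifidobacteriaceae|Scardovia",
      "Bacteria|Actinobacteria|Actinobacteria|Coriobacteriales|Coriobacteriaceae|Olsenella",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Butyrivibrio",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Roseburia",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Dorea",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Lachnospira",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Faecalibacterium",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Papillibacter",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Ruminococcus",
      "Bacteria|Firmicutes|Clostridia|Clostridiales|Clostridiaceae|Clostridium",
      "Bacteria|Firmicutes|Bacilli|Lactobacillales|Lactobacillaceae|Lactobacillus",
      "Bacteria|Firmicutes|Bacilli|Bacillales|Staphylococcaceae|Staphylococcus",
      "Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Bacteroidaceae|Bacteroides",
      "Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Porphyromonadaceae|Parabacteroides",
      "Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotella",
      "Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Rikenellaceae|Alistipes",
      "Bacteria|Proteobacteria|Gammaproteobacteria|Enterobacteriales|Enterobacteriaceae|Escherichia",
      "Bacteria|Verrucomicrobia|Verrucomicrobiae|Verrucomicrobiales|Verrucomicrobiaceae|Akkermansia"),
    base = c(0.06, 0.008, 0.001, 0.004,
             0.02, 0.015, 0.015, 0.01, 0.03, 0.008, 0.03, 0.05,
             0.05, 0.004,
             0.15, 0.03, 0.08, 0.04,
             0.02, 0.03),
    case_mult = c(0.12, 1, 1, 1,
                  3.5, 0.15, 1, 1, 3, 0.15, 1, 1,
                  1, 0.15,
                  1, 0.2, 1, 1,
                  1, 1),
    sdlog = c(0.30, 0.30, 0.30, 0.30,
              0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30,
              0.30, 0.30,
              0.30, 0.30, 0.50, 0.30,
              0.35, 0.35),
    stringsAsFactors = FALSE
  )
  truth <- c(
    "Bacteria|Actinobacteria",
    "Bacteria|Actinobacteria|Actinobacteria",
    "Bacteria|Actinobacteria|Actinobacteria|Bifidobacteriales",
    "Bacteria|Actinobacteria|Actinobacteria|Bifidobacteriales|Bifidobacteriaceae",
    "Bacteria|Actinobacteria|Actinobacteria|Bifidobacteriales|Bifidobacteriaceae|Bifidobacterium",
    "Bacteria|Firmicutes",
    "Bacteria|Firmicutes|Clostridia",
    "Bacteria|Firmicutes|Clostridia|Clostridiales",
    "Bacteria|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae",
    "Bacteria|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Butyrivibrio",
    "Bacteria|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Roseburia",
    "Bacteria|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae",
    "Bacteria|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Faecalibacterium",
    "Bacteria|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Papillibacter",
    "Bacteria|Firmicutes|Bacilli|Bacillales",
    "Bacteria|Firmicutes|Bacilli|Bacillales|Staphylococcaceae",
    "Bacteria|Firmicutes|Bacilli|Bacillales|Staphylococcaceae|Staphylococcus",
    "Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Porphyromonadaceae",
    "Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Porphyromonadaceae|Parabacteroides")

  n <- n_case + n_control
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))
  leaf <- with_seed(seed, {
    m <- matrix(0, nrow = nrow(genera), ncol = n)
    for (i in seq_len(nrow(genera))) {
      mu <- genera$base[i] * ifelse(is_case, genera$case_mult[i], 1)
      m[i, ] <- stats::rlnorm(n, meanlog = log(mu) - genera$sdlog[i]^2 / 2,
                              sdlog = genera$sdlog[i])
    }
    m
  })
  # ancestor rows as sums of descendant genera
  all_paths <- unique(unlist(lapply(strsplit(genera$path, "|", fixed = TRUE),
                                    function(s) {
    vapply(seq_along(s), function(k) paste(s[1:k], collapse = "|"),
           character(1L))
  })))
  values <- t(vapply(all_paths, function(p) {
    under <- startsWith(genera$path, paste0(p, "|")) | genera$path == p
    colSums(leaf[under, , drop = FALSE])
  }, numeric(n)))
  sample_ids <- c(paste0("case_", seq_len(n_case)),
                  paste0("control_", seq_len(n_control)))
  tab <- abundance_table(values, feature_ids = all_paths,
                         sample_ids = sample_ids)
  ann <- sample_annotation(sample_ids,
                           class = ifelse(is_case, "case", "control"),
                           subject = paste0("mouse_", seq_len(n)))
  list(table = tab, annotation = ann, truth = truth)
}
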