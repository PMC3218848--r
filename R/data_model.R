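#' Feature-abundance table
#'
#' Container for a features-by-samples matrix of non-negative abundances.
#' Feature identifiers may encode a taxonomic or functional hierarchy as
#' separator-delimited clade paths (e.g.
#' `Bacteria|Actinobacteria|Actinomycetales`).
#'
#' @param values numeric matrix, one row per feature, one column per sample;
#'   all entries finite and non-negative.
#' @param feature_ids unique feature identifiers (defaults to rownames).
#' @param sample_ids unique sample identifiers (defaults to colnames).
#' @param normalized logical; `TRUE` when every sample column has already
#'   been rescaled to sum to `total`.
#' @param separator hierarchy separator used inside `feature_ids`.
#' @param total the per-sample sum that `normalized` refers to.
#' @param nonnegative enforce the non-negativity invariant (default `TRUE`).
#'   Synthetic Gaussian benchmark tables are built with `FALSE`, keeping
#'   negative draws untruncated so the null distribution is not distorted.
#'
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, feature_ids = rownames(values),
                            sample_ids = colnames(values),
                            normalized = FALSE, separator = "|",
                            total = 1.0, nonnegative = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) {
    feature_ids <- paste0("feature_", seq_len(nrow(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("feature_ids length does not match the number of rows")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length does not match the number of columns")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("abundance values must be finite and non-missing")
  }
  if (nonnegative && any(values < 0)) {
    stop("abundance values must be non-negative")
  }
  segs <- strsplit(feature_ids, separator, fixed = TRUE)
  if (any(vapply(segs, function(s) any(!nzchar(s)), logical(1L)))) {
    stop("feature ids must not contain empty hierarchy segments")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  if (normalized) {
    sums <- colSums(values)
    bad <- abs(sums - total) > 1e-9 & sums > 0
    if (any(bad)) {
      stop("normalized table has sample columns not summing to ", total, ": ",
           paste(sample_ids[bad], collapse = ", "))
    }
  }
  structure(
    list(values = values, feature_ids = feature_ids, sample_ids = sample_ids,
         normalized = normalized, separator = separator, total = total),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples (%s)\n",
              length(x$feature_ids), length(x$sample_ids),
              if (x$normalized) {
                sprintf("normalized, per-sample total %g", x$total)
              } else "unnormalized"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Per-sample annotation
#'
#' One class label per sample (required), with optional subclass and subject
#' labels.  When the subclass is absent it defaults to the class (a single
#' subclass per class); when the subject is absent it defaults to the sample
#' id.  Subclasses must be nested within classes: the same subclass name may
#' not appear under two different classes.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param class character vector of class labels, one per sample; at least
#'   two distinct values across samples.
#' @param subclass optional character vector of subclass labels.
#' @param subject optional character vector of subject labels.
#'
#' @return An object of class `sample_annotation`: a data.frame with columns
#'   `sample_id`, `class`, `subclass`, `subject`.
#' @export
sample_annotation <- function(sample_ids, class, subclass = NULL,
                              subject = NULL) {
  sample_ids <- as.character(sample_ids)
  class <- as.character(class)
  n <- length(sample_ids)
  if (length(class) != n || anyNA(class) || any(!nzchar(class))) {
    stop("a class label is required for every sample")
  }
  if (length(unique(class)) < 2L) {
    stop("design error: fewer than 2 classes")
  }
  if (is.null(subclass)) subclass <- class
  if (is.null(subject)) subject <- sample_ids
  subclass <- as.character(subclass)
  subject <- as.character(subject)
  if (length(subclass) != n || length(subject) != n) {
    stop("subclass/subject must have one value per sample")
  }
  ann <- data.frame(sample_id = sample_ids, class = class,
                    subclass = subclass, subject = subject,
                    stringsAsFactors = FALSE)
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

parse_numeric_row <- function(fields, row_label, row_num) {
  x <- suppressWarnings(as.numeric(fields))
  bad <- which(is.na(x) & !(fields %in% c("NA")))
  if (length(bad)) {
    stop(sprintf(
      "parse error: non-numeric abundance '%s' in row '%s' (line %d), column %d",
      fields[bad[1L]], row_label, row_num, bad[1L] + 1L))
  }
  if (anyNA(x)) {
    stop(sprintf("parse error: missing value in row '%s' (line %d)",
                 row_label, row_num))
  }
  x
}

#' Read an annotated feature-abundance table
#'
#' Parses a tab-delimited text file whose first column holds row names and
#' whose remaining columns are samples.  Metadata rows (class, optionally
#' subclass and subject) are addressed by row index among the file's rows;
#' all other rows are parsed as numeric feature abundances.  Row order is
#' preserved.
#'
#' @param path path to a tab-delimited UTF-8 text file (no quoting), or a
#'   character vector of already-read lines.
#' @param config a [lefse_config()]; supplies the hierarchy separator.
#' @param class_row 1-based index (among file rows) of the class row.
#' @param subclass_row optional index of the subclass row (`NA` to omit).
#' @param subject_row optional index of the subject row (`NA` to omit).
#' @param transpose logical; set `TRUE` for column-major files with features
#'   in columns and samples in rows.
#'
#' @return A list with elements `table` ([abundance_table]) and `annotation`
#'   ([sample_annotation]).
#' @examples
#' lines <- c("class\tA\tA\tB\tB",
#'            "Bacteria|Firmicutes\t1\t2\t3\t4",
#'            "Bacteria|Bacteroidetes\t4\t3\t2\t1")
#' x <- read_lefse_table(lines)
#' dim(x$table)
#' @export
read_lefse_table <- function(path, config = lefse_config(), class_row = 1L,
                             subclass_row = NA, subject_row = NA,
                             transpose = FALSE) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, encoding = "UTF-8")
  } else {
    as.character(path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty input")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (transpose) {
    ncols <- lengths(fields)
    if (length(unique(ncols)) != 1L) {
      stop("format error: ragged rows (widths ",
           paste(sort(unique(ncols)), collapse = ", "), ")")
    }
    m <- do.call(rbind, fields)
    fields <- lapply(seq_len(ncol(m)), function(j) m[, j])
  }
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("format error: ragged rows (row %d has %d fields, row 1 has %d)",
                 which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L],
                 widths[1L]))
  }
  if (widths[1L] < 2L) stop("format error: no sample columns")
  n_rows <- length(fields)
  row_names <- vapply(fields, `[[`, character(1L), 1L)
  body <- lapply(fields, function(f) f[-1L])
  n_samples <- widths[1L] - 1L

  meta_idx <- c(class = class_row,
                subclass = if (is.na(subclass_row)) NA_integer_ else subclass_row,
                subject = if (is.na(subject_row)) NA_integer_ else subject_row)
  if (is.na(meta_idx["class"]) || meta_idx["class"] < 1L ||
      meta_idx["class"] > n_rows) {
    stop("configuration error: missing or out-of-range class row")
  }
  used <- meta_idx[!is.na(meta_idx)]
  if (any(used < 1L) || any(used > n_rows) || anyDuplicated(used)) {
    stop("configuration error: metadata row indices out of range or duplicated")
  }

  class_lab <- body[[meta_idx[["class"]]]]
  subclass_lab <- if (!is.na(meta_idx["subclass"])) body[[meta_idx[["subclass"]]]] else NULL
  subject_lab <- if (!is.na(meta_idx["subject"])) body[[meta_idx[["subject"]]]] else NULL

  feat_rows <- setdiff(seq_len(n_rows), used)
  if (!length(feat_rows)) stop("format error: no feature rows")
  values <- matrix(0, nrow = length(feat_rows), ncol = n_samples)
  for (i in seq_along(feat_rows)) {
    r <- feat_rows[i]
    values[i, ] <- parse_numeric_row(body[[r]], row_names[r], r)
  }
  sample_ids <- paste0("sample_", seq_len(n_samples))
  tab <- abundance_table(values, feature_ids = row_names[feat_rows],
                         sample_ids = sample_ids,
                         separator = config$hierarchy_separator,
                         total = config$normalization_total)
  ann <- sample_annotation(sample_ids, class_lab, subclass_lab, subject_lab)
  list(table = tab, annotation = ann)
}

#' Write an annotated feature-abundance table
#'
#' Inverse of [read_lefse_table()]: writes the class, subclass and subject
#' metadata rows followed by the feature rows, tab-delimited, with full
#' double precision so that a write/read round trip reproduces the values
#' bit-exactly.
#'
#' @param table an [abundance_table].
#' @param annotation a [sample_annotation] for the same samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lefse_table <- function(table, annotation, path) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(annotation, "sample_annotation"))
  if (!identical(table$sample_ids, annotation$sample_id)) {
    stop("table and annotation describe different samples")
  }
  meta <- c(paste(c("class", annotation$class), collapse = "\t"),
            paste(c("subclass", annotation$subclass), collapse = "\t"),
            paste(c("subject", annotation$subject), collapse = "\t"))
  feat <- vapply(seq_along(table$feature_ids), function(i) {
    paste(c(table$feature_ids[i], sprintf("%.17g", table$values[i, ])),
          collapse = "\t")
  }, character(1L))
  writeLines(c(meta, feat), path, useBytes = TRUE)
  invisible(path)
}

#' Normalize each sample column to a fixed total
#'
#' Rescales every sample column of the table so that it sums to `total`
#' (default 1, i.e. relative abundances).  All-zero columns are left at zero
#' with a warning; the operation is idempotent and preserves each column's
#' zero pattern.
#'
#' @param table an [abundance_table].
#' @param total positive per-sample target sum.
#' @return A normalized [abundance_table].
#' @examples
#' tab <- abundance_table(matrix(c(2, 3, 5), ncol = 1))
#' normalize_per_sample(tab)$values
#' @export
normalize_per_sample <- function(table, total = table$total) {
  stopifnot(inherits(table, "abundance_table"), total > 0)
  v <- table$values
  sums <- colSums(v)
  zero <- sums == 0
  if (any(zero)) {
    warning("all-zero sample column(s) left unnormalized: ",
            paste(table$sample_ids[zero], collapse = ", "))
  }
  nz <- !zero
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2L, sums[nz] / total, "/")
  abundance_table(v, feature_ids = table$feature_ids,
                  sample_ids = table$sample_ids, normalized = TRUE,
                  separator = table$separator, total = total)
}

#' Summarize the class/subclass design
#'
#' Reports the classes, the subclasses nested within each class with their
#' cardinalities, which subclasses fall below the small-subclass threshold
#' (triggering the median-sign fallback in the consistency gate), and whether
#' same-name subclass pairing is applicable (identical subclass name sets
#' across all classes).
#'
#' Subclasses are nested within classes: under `all_pairs` pairing a
#' subclass name appearing in two classes is a design error, while under
#' `same_name` pairing that repetition is exactly the expected stratified
#' structure (the same stratum observed in each class).
#'
#' @param annotation a [sample_annotation].
#' @param config a [lefse_config()].
#' @return An object of class `lefse_design`: a list with elements `classes`,
#'   `subclasses` (data.frame class/subclass/n/small), `small_subclasses`,
#'   `same_name_applicable` and `n_pairs_all_pairs` (cross-class subclass
#'   comparisons per feature and class pair, summed over class pairs).
#' @export
validate_design <- function(annotation, config = lefse_config()) {
  stopifnot(inherits(annotation, "sample_annotation"))
  classes <- sort(unique(annotation$class))
  if (length(classes) < 2L) stop("design error: fewer than 2 classes")
  tab <- as.data.frame(table(class = annotation$class,
                             subclass = annotation$subclass),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  span <- tapply(tab$class, tab$subclass, function(x) length(unique(x)))
  if (config$pairing_mode == "all_pairs" && any(span > 1L)) {
    stop("design error: subclass spans multiple classes: ",
         paste(names(span)[span > 1L], collapse = ", "))
  }
  tab <- tab[order(tab$class, tab$subclass), ]
  names(tab)[3L] <- "n"
  tab$small <- tab$n < config$min_subclass_size
  per_class <- split(tab$subclass, tab$class)
  name_sets <- lapply(per_class, sort)
  same_name <- length(unique(vapply(name_sets, paste, character(1L),
                                    collapse = "\r"))) == 1L
  pair_counts <- utils::combn(classes, 2L, function(p) {
    length(per_class[[p[1L]]]) * length(per_class[[p[2L]]])
  })
  structure(
    list(classes = classes,
         subclasses = tab,
         small_subclasses = tab$subclass[tab$small],
         same_name_applicable = same_name,
         n_pairs_all_pairs = sum(pair_counts)),
    class = "lefse_design"
  )
}

#' @export
print.lefse_design <- function(x, ...) {
  cat(sprintf("lefse_design: %d classes (%s)\n", length(x$classes),
              paste(x$classes, collapse = ", ")))
  print(as.data.frame(x$subclasses), row.names = FALSE)
  cat(sprintf("same-name pairing applicable: %s; all-pairs comparisons: %d\n",
              x$same_name_applicable, x$n_pairs_all_pairs))
  if (length(x$small_subclasses)) {
    cat("small subclasses (median-sign fallback):",
        paste(x$small_subclasses, collapse = ", "), "\n")
  }
  invisible(x)
}
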