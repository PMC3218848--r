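#' Build a clade tree from hierarchical feature identifiers
#'
#' Turns separator-delimited clade paths into a rooted tree, synthesizing
#' implicit ancestors that have no feature row of their own.  Each node
#' carries its mean abundance across all samples (when a feature row exists
#' for it) and, if results are supplied, its significance record (enriched
#' class and LDA score for biomarkers).
#'
#' @param feature_ids character vector of clade paths.
#' @param results optional [lefse()] result (or its `results` data.frame)
#'   used to attach significance records.
#' @param table optional [abundance_table] used to attach mean abundances.
#' @param separator hierarchy separator (default `"|"`).
#' @return An object of class `clade_tree`: a data.frame of nodes with
#'   columns `id` (path), `parent` (path or `NA` for roots), `label` (last
#'   segment), `depth`, `is_leaf`, `abundance` (`NA` when the node has no
#'   feature row), `enriched_class`, `score`.
#' @export
build_clade_tree <- function(feature_ids, results = NULL, table = NULL,
                             separator = "|") {
  if (anyDuplicated(feature_ids)) {
    stop("validation error: duplicate clade paths")
  }
  segs <- strsplit(feature_ids, separator, fixed = TRUE)
  all_paths <- unique(unlist(lapply(segs, function(s) {
    vapply(seq_along(s), function(k) paste(s[1:k], collapse = separator),
           character(1L))
  })))
  depth <- lengths(strsplit(all_paths, separator, fixed = TRUE))
  parent <- vapply(seq_along(all_paths), function(i) {
    if (depth[i] == 1L) return(NA_character_)
    s <- strsplit(all_paths[i], separator, fixed = TRUE)[[1L]]
    paste(s[-length(s)], collapse = separator)
  }, character(1L))
  nodes <- data.frame(id = all_paths, parent = parent,
                      label = vapply(strsplit(all_paths, separator,
                                              fixed = TRUE),
                                     function(s) s[length(s)], character(1L)),
                      depth = depth, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), ]
  nodes$is_leaf <- !(nodes$id %in% nodes$parent)
  nodes$abundance <- NA_real_
  if (!is.null(table)) {
    hit <- match(nodes$id, table$feature_ids)
    nodes$abundance[!is.na(hit)] <-
      rowMeans(table$values)[hit[!is.na(hit)]]
  }
  nodes$enriched_class <- NA_character_
  nodes$score <- NA_real_
  if (!is.null(results)) {
    r <- if (inherits(results, "lefse_result")) results$results else results
    sig <- r[!is.na(r$lda_score) &
               (if ("is_biomarker" %in% names(r)) r$is_biomarker
                else TRUE), , drop = FALSE]
    hit <- match(nodes$id, sig$feature)
    nodes$enriched_class[!is.na(hit)] <- sig$enriched_class[hit[!is.na(hit)]]
    nodes$score[!is.na(hit)] <- sig$lda_score[hit[!is.na(hit)]]
  }
  rownames(nodes) <- NULL
  attr(nodes, "separator") <- separator
  class(nodes) <- c("clade_tree", "data.frame")
  nodes
}

#' @export
print.clade_tree <- function(x, ...) {
  cat(sprintf("clade_tree: %d nodes, depth %d, %d significant\n",
              nrow(x), max(x$depth), sum(!is.na(x$score))))
  invisible(x)
}

# Deterministic radial layout: leaves at evenly spaced angles in input
# order, internal nodes at the mean angle of their children, radius
# proportional to depth.
layout_radial <- function(tree) {
  leaves <- tree$id[tree$is_leaf]
  angle <- stats::setNames(rep(NA_real_, nrow(tree)), tree$id)
  angle[leaves] <- 2 * pi * (seq_along(leaves) - 1L) / length(leaves)
  for (d in sort(unique(tree$depth), decreasing = TRUE)) {
    for (i in which(tree$depth == d & !tree$is_leaf)) {
      kids <- tree$id[!is.na(tree$parent) & tree$parent == tree$id[i]]
      angle[tree$id[i]] <- mean(angle[kids])
    }
  }
  maxd <- max(tree$depth)
  radius <- (tree$depth - 1L) / max(maxd - 1L, 1L)
  data.frame(id = tree$id, angle = unname(angle[tree$id]), radius = radius,
             x = radius * cos(unname(angle[tree$id])),
             y = radius * sin(unname(angle[tree$id])),
             stringsAsFactors = FALSE)
}

class_palette <- function(classes) {
  pal <- c("#d7191c", "#2c7bb6", "#1a9641", "#fdae61", "#984ea3", "#a6611a")
  stats::setNames(pal[seq_along(classes) %% length(pal) + 1L], classes)
}

#' Draw a radial cladogram
#'
#' Renders the clade tree with node circles whose diameter grows with the
#' square root of mean abundance, significant nodes colored by their
#' enriched class (with a shaded sector over the clade), non-significant
#' nodes in a neutral color, and a legend mapping classes to colors.
#' Significant nodes up to `label_depth` are labelled in place; deeper ones
#' through a lettered key in the legend.  Drawing is deterministic given
#' the input order.
#'
#' @param tree a [build_clade_tree()] result (non-empty).
#' @param label_depth deepest level labelled directly on the plot.
#' @param radius_range circle radii (inches) mapped to the abundance range.
#' @param neutral_col color for non-significant nodes.
#' @param main plot title.
#' @return Invisibly, the node layout data.frame.
#' @export
plot_cladogram <- function(tree, label_depth = 3L,
                           radius_range = c(0.4, 2.5),
                           neutral_col = "#f2d21f", main = "") {
  stopifnot(inherits(tree, "clade_tree"))
  if (!nrow(tree)) stop("empty tree")
  lay <- layout_radial(tree)
  classes <- sort(unique(tree$enriched_class[!is.na(tree$enriched_class)]))
  pal <- class_palette(classes)
  ab <- tree$abundance
  size <- rep(radius_range[1L], nrow(tree))
  if (any(!is.na(ab)) && diff(range(sqrt(ab), na.rm = TRUE)) > 0) {
    s <- sqrt(ab)
    size[!is.na(ab)] <- radius_range[1L] +
      (s[!is.na(ab)] - min(s, na.rm = TRUE)) /
      diff(range(s, na.rm = TRUE)) * diff(radius_range)
  }
  op <- graphics::par(mar = c(1, 1, if (nzchar(main)) 3 else 1, 1), xpd = NA)
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(-1.45, 1.45), c(-1.45, 1.45), asp = 1)
  if (nzchar(main)) graphics::title(main = main)
  # shaded sector over each significant clade's angular span
  sig <- which(!is.na(tree$enriched_class))
  sep <- attr(tree, "separator")
  if (is.null(sep)) sep <- "|"
  for (i in sig) {
    desc_leaves <- tree$is_leaf &
      (startsWith(tree$id, paste0(tree$id[i], sep)) | tree$id == tree$id[i])
    angs <- lay$angle[desc_leaves]
    if (!length(angs)) next
    a0 <- min(angs) - 0.05
    a1 <- max(angs) + 0.05
    aa <- seq(a0, a1, length.out = 32L)
    r0 <- max(lay$radius[lay$id == tree$id[i]], 0.02)
    graphics::polygon(c(r0 * cos(aa), rev(1.08 * cos(aa))),
                      c(r0 * sin(aa), rev(1.08 * sin(aa))),
                      col = grDevices::adjustcolor(pal[tree$enriched_class[i]],
                                                   alpha.f = 0.15),
                      border = NA)
  }
  pid <- match(tree$parent, lay$id)
  ok <- !is.na(pid)
  graphics::segments(lay$x[ok], lay$y[ok], lay$x[pid[ok]], lay$y[pid[ok]],
                     col = "grey55")
  col <- ifelse(is.na(tree$enriched_class), neutral_col,
                pal[tree$enriched_class])
  graphics::points(lay$x, lay$y, pch = 21L, bg = col, col = "grey25",
                   cex = size)
  lab_direct <- which(!is.na(tree$score) & tree$depth <= label_depth)
  lab_keyed <- which(!is.na(tree$score) & tree$depth > label_depth)
  if (length(lab_direct)) {
    graphics::text(lay$x[lab_direct] * 1.14, lay$y[lab_direct] * 1.14,
                   tree$label[lab_direct], cex = 0.7)
  }
  keys <- character(0L)
  if (length(lab_keyed)) {
    keys <- make.unique(letters[(seq_along(lab_keyed) - 1L) %% 26L + 1L])
    graphics::text(lay$x[lab_keyed] * 1.12, lay$y[lab_keyed] * 1.12, keys,
                   cex = 0.65)
  }
  leg <- c(sprintf("%s", classes),
           if (length(lab_keyed)) sprintf("%s: %s", keys,
                                          tree$label[lab_keyed]))
  leg_fill <- c(pal[classes], rep(NA, length(lab_keyed)))
  if (length(leg)) {
    graphics::legend("bottomleft", legend = leg, fill = leg_fill,
                     border = NA, bty = "n", cex = 0.65,
                     x.intersp = c(rep(1, length(classes)),
                                   rep(0.2, length(lab_keyed))))
  }
  invisible(lay)
}

#' Horizontal barplot of LDA scores
#'
#' One bar per biomarker (absolute score at or above `threshold`), grouped
#' and colored by enriched class; with two classes the second class's bars
#' extend to the negative side.  Bars are sorted by score within class,
#' matching the ranked biomarker list.
#'
#' @param results a [lefse()] result or its `results` data.frame.
#' @param threshold minimum absolute score shown (default 2).
#' @return A ggplot object (an annotated empty plot when nothing reaches
#'   the threshold).
#' @export
plot_score_histogram <- function(results, threshold = 2.0) {
  r <- if (inherits(results, "lefse_result")) results$results else results
  r <- r[!is.na(r$lda_score) & abs(r$lda_score) >= threshold, , drop = FALSE]
  if (!nrow(r)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no biomarkers above threshold") +
             ggplot2::theme_void())
  }
  classes <- sort(unique(r$enriched_class))
  sign_of <- if (length(classes) == 2L) {
    stats::setNames(c(1, -1), classes)
  } else {
    stats::setNames(rep(1, length(classes)), classes)
  }
  r$signed <- r$lda_score * sign_of[r$enriched_class]
  r <- r[order(r$signed), , drop = FALSE]
  r$feature <- factor(r$feature, levels = r$feature)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$signed, y = .data$feature,
                                  fill = .data$enriched_class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = class_palette(classes),
                               name = "enriched class") +
    ggplot2::labs(x = "LDA score (log10)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-sample abundance histogram for one feature
#'
#' Bars show the feature's abundance in every sample, grouped by class and
#' subclass (one fill color per subclass); solid and dashed horizontal lines
#' mark each class's mean and median.  When the table is normalized the
#' abundance axis is bounded by the normalization interval.
#'
#' @param feature_id the feature to plot (must exist in the table).
#' @param table an [abundance_table].
#' @param annotation a [sample_annotation].
#' @return A ggplot object.
#' @export
plot_feature_histogram <- function(feature_id, table, annotation) {
  i <- match(feature_id, table$feature_ids)
  if (is.na(i)) stop("unknown feature: ", feature_id)
  df <- data.frame(sample = table$sample_ids,
                   value = table$values[i, ],
                   class = annotation$class,
                   subclass = annotation$subclass,
                   stringsAsFactors = FALSE)
  df <- df[order(df$class, df$subclass, df$sample), ]
  df$sample <- factor(df$sample, levels = df$sample)
  stats_df <- do.call(rbind, lapply(split(df, df$class), function(d) {
    data.frame(class = d$class[1L], mean = mean(d$value),
               median = stats::median(d$value), stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                        fill = .data$subclass)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = stats_df,
                        ggplot2::aes(yintercept = .data$mean),
                        linetype = "solid") +
    ggplot2::geom_hline(data = stats_df,
                        ggplot2::aes(yintercept = .data$median),
                        linetype = "dashed") +
    ggplot2::facet_grid(~class, scales = "free_x", space = "free_x") +
    ggplot2::labs(title = feature_id, x = NULL,
                  y = if (table$normalized) "relative abundance"
                      else "abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6))
  if (table$normalized) {
    p <- p + ggplot2::coord_cartesian(ylim = c(0, table$total))
  }
  p
}

newick_quote <- function(x) {
  gsub("[ ,;:()\\[\\]']", "_", x)
}

#' Export the clade tree as Newick
#'
#' Writes the taxonomy as a rooted Newick tree with unit branch lengths.
#' With `scores = TRUE`, significant nodes carry a bracketed comment
#' `[&score=...,class=...]` after their label (readers that follow the
#' strict grammar should use `scores = FALSE`).
#'
#' @param tree a [build_clade_tree()] result.
#' @param path output file; `NULL` returns the Newick string.
#' @param scores include score comments (default `FALSE`).
#' @return The Newick string, invisibly when written to a file.
#' @export
write_clade_newick <- function(tree, path = NULL, scores = FALSE) {
  stopifnot(inherits(tree, "clade_tree"))
  rec <- function(id) {
    kids <- tree$id[!is.na(tree$parent) & tree$parent == id]
    i <- match(id, tree$id)
    lab <- newick_quote(tree$label[i])
    if (scores && !is.na(tree$score[i])) {
      lab <- sprintf("%s[&score=%.4f,class=%s]", lab, tree$score[i],
                     newick_quote(tree$enriched_class[i]))
    }
    if (!length(kids)) return(paste0(lab, ":1"))
    paste0("(", paste(vapply(sort(kids), rec, character(1L)),
                      collapse = ","), ")", lab, ":1")
  }
  roots <- tree$id[is.na(tree$parent)]
  nwk <- if (length(roots) == 1L) {
    paste0(rec(roots), ";")
  } else {
    paste0("(", paste(vapply(sort(roots), rec, character(1L)),
                      collapse = ","), ");")
  }
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
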