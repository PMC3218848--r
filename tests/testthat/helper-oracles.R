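# Independent oracles for the rank tests and the discriminant, coded from
# the textbook formulas (not via stats:: or MASS::), for use on tiny inputs.

# Kruskal-Wallis H with midranks and tie correction.
oracle_kw_h <- function(values, classes) {
  r <- rank(values)  # midranks
  n <- length(values)
  groups <- split(r, classes)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) sum(g)^2 / length(g), numeric(1))) -
    3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(NA_real_)
  h / corr
}

# Exhaustive permutation p-value of H: fraction of all distinct label
# assignments with H at least as large as observed.
oracle_kw_perm_p <- function(values, classes) {
  h_obs <- oracle_kw_h(values, classes)
  perms <- all_label_assignments(classes)
  hs <- apply(perms, 1L, function(cl) oracle_kw_h(values, cl))
  mean(hs >= h_obs - 1e-12)
}

# All distinct assignments of the multiset of labels to positions.
all_label_assignments <- function(classes) {
  n <- length(classes)
  labs <- sort(unique(classes))
  counts <- table(factor(classes, levels = labs))
  out <- list()
  recurse <- function(assigned, remaining) {
    if (length(assigned) == n) {
      out[[length(out) + 1L]] <<- assigned
      return(invisible())
    }
    pos <- length(assigned) + 1L
    for (l in labs) {
      if (remaining[l] > 0L) {
        rem <- remaining
        rem[l] <- rem[l] - 1L
        recurse(c(assigned, l), rem)
      }
    }
  }
  recurse(character(0L), counts)
  do.call(rbind, out)
}

# Exact two-sided rank-sum p-value by enumeration of all C(n, na) splits
# (matches the exact Wilcoxon two-sided rule: twice the smaller tail,
# capped at 1).  Valid for tie-free data.
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  splits <- utils::combn(n, na)
  ws <- apply(splits, 2L, function(idx) sum(r[idx]))
  lo <- mean(ws <= w_obs + 1e-12)
  hi <- mean(ws >= w_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# Closed-form two-class linear discriminant direction: pooled within-class
# scatter inverse times the mean difference.
oracle_lda_direction <- function(x, y) {
  cls <- sort(unique(as.character(y)))
  x1 <- x[y == cls[1L], , drop = FALSE]
  x2 <- x[y == cls[2L], , drop = FALSE]
  s1 <- crossprod(scale(x1, center = TRUE, scale = FALSE))
  s2 <- crossprod(scale(x2, center = TRUE, scale = FALSE))
  sw <- (s1 + s2) / (nrow(x) - 2L)
  w <- solve(sw, colMeans(x1) - colMeans(x2))
  w / sqrt(sum(w^2))
}
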