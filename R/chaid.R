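# Ordinal CHAID classification tree on the integer score against the
# binary death indicator: adjacent score categories are merged while their
# 2x2 Pearson chi-square is non-significant, and nodes split on the merged
# categories when the Bonferroni-adjusted chi-square is significant.
# Used to discover the risk-class boundaries.

#' CHAID tree parameters
#'
#' Defaults follow the published analysis: maximum depth 3, at least 1000
#' cases in a parent node and 500 in a child, significance level 0.05 for
#' both splitting and merging.
#'
#' @param max_depth maximum tree depth.
#' @param min_parent minimum node size for a node to be considered for
#'   splitting.
#' @param min_child minimum size of every child a split would create.
#' @param alpha_split significance level for the Bonferroni-adjusted split
#'   test.
#' @param alpha_merge significance level below which adjacent categories
#'   stay separate.
#' @return a list of class `chaid_params`.
#' @export
chaid_params <- function(max_depth = 3L, min_parent = 1000L,
                         min_child = 500L, alpha_split = 0.05,
                         alpha_merge = 0.05) {
  stopifnot(max_depth >= 1, min_parent >= 1, min_child >= 1,
            alpha_split > 0, alpha_split < 1,
            alpha_merge > 0, alpha_merge < 1)
  structure(list(max_depth = as.integer(max_depth),
                 min_parent = as.integer(min_parent),
                 min_child = as.integer(min_child),
                 alpha_split = alpha_split, alpha_merge = alpha_merge),
            class = "chaid_params")
}

# Pearson chi-square on a k x 2 count table, without continuity
# correction. Zero-margin columns/rows contribute nothing; a table with a
# degenerate outcome margin has statistic 0 and p 1.
.chisq2 <- function(tab, warn_expected = FALSE) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  if (n == 0 || any(cs == 0) || sum(rs > 0) < 2L) {
    return(list(stat = 0, df = (nrow(tab) - 1L), p = 1))
  }
  keep <- rs > 0
  tab <- tab[keep, , drop = FALSE]
  rs <- rs[keep]
  E <- outer(rs, cs) / n
  if (warn_expected && min(E) < 5) {
    warning("chi-square test with expected cell count < 5", call. = FALSE)
  }
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Merge step on a k x 2 count matrix of ordinal categories: repeatedly
# merge the adjacent pair with the largest chi-square p-value while that
# p-value exceeds alpha_merge. Only adjacent pairs merge (ordinal
# predictor); ties go to the lower score interval. Afterwards, categories
# smaller than min_child are force-merged with their most similar adjacent
# neighbour (largest pairwise p), the classic CHAID treatment of sparse
# categories, so that a near-empty score tail cannot veto a split. Returns
# a list of contiguous index vectors.
.merge_step <- function(counts, alpha_merge, min_child = 1L) {
  groups <- as.list(seq_len(nrow(counts)))
  pair_p <- function(groups, r) {
    tab <- rbind(colSums(counts[groups[[r]], , drop = FALSE]),
                 colSums(counts[groups[[r + 1L]], , drop = FALSE]))
    .chisq2(tab)$p
  }
  repeat {
    if (length(groups) < 2L) break
    p <- vapply(seq_len(length(groups) - 1L), pair_p, numeric(1),
                groups = groups)
    best <- which.max(p)
    if (p[best] <= alpha_merge) break
    groups[[best]] <- c(groups[[best]], groups[[best + 1L]])
    groups[[best + 1L]] <- NULL
  }
  repeat {
    if (length(groups) < 2L) break
    size <- vapply(groups, function(g) sum(counts[g, ]), numeric(1))
    small <- which(size < min_child)
    if (!length(small)) break
    i <- small[1L]
    cand <- c(if (i > 1L) i - 1L, if (i < length(groups)) i)
    p <- vapply(cand, pair_p, numeric(1), groups = groups)
    at <- cand[which.max(p)]
    groups[[at]] <- c(groups[[at]], groups[[at + 1L]])
    groups[[at + 1L]] <- NULL
  }
  groups
}

#' Merge adjacent score categories by chi-square similarity
#'
#' The CHAID merge step, exposed on raw data: treats the distinct score
#' values as ordinal categories and merges adjacent ones whose outcome
#' distributions do not differ significantly.
#'
#' @param score integer score vector.
#' @param event binary outcome vector.
#' @param alpha_merge merge significance level (default 0.05).
#' @return a `data.frame` with one row per merged category: `lo`, `hi`
#'   (score interval, inclusive), `n`, `n_events`.
#' @export
merge_score_categories <- function(score, event, alpha_merge = 0.05) {
  stopifnot(length(score) == length(event))
  counts <- .score_counts(score, event)
  groups <- .merge_step(counts$m, alpha_merge)
  data.frame(
    lo = vapply(groups, function(g) counts$values[min(g)], numeric(1)),
    hi = vapply(groups, function(g) counts$values[max(g)], numeric(1)),
    n = vapply(groups, function(g) sum(counts$m[g, ]), numeric(1)),
    n_events = vapply(groups, function(g) sum(counts$m[g, 2L]), numeric(1))
  )
}

.score_counts <- function(score, event) {
  values <- sort(unique(score))
  f <- factor(score, levels = values)
  m <- cbind(`0` = tabulate(f[event == 0], nbins = length(values)),
             `1` = tabulate(f[event == 1], nbins = length(values)))
  list(values = values, m = m)
}

# Recursive grower over a contiguous index range of the score-value count
# matrix. Split acceptance: after merging to g categories out of c0, the
# overall chi-square p-value is Bonferroni-multiplied by the number of
# contiguous partitions choose(c0 - 1, g - 1), capped at 1; the split is
# accepted iff the adjusted p is below alpha_split and every child reaches
# min_child.
.chaid_grow <- function(m, values, idx, depth, params) {
  sub <- m[idx, , drop = FALSE]
  node <- list(
    interval = c(values[idx[1L]], values[idx[length(idx)]]),
    n = sum(sub), n_events = sum(sub[, 2L]),
    depth = depth, split_p = NULL, children = NULL
  )
  if (length(idx) < 2L || node$n < params$min_parent ||
      depth >= params$max_depth || node$n_events %in% c(0L, node$n)) {
    return(node)
  }
  groups <- .merge_step(sub, params$alpha_merge, params$min_child)
  g <- length(groups)
  if (g < 2L) return(node)
  tab <- t(vapply(groups, function(gr) colSums(sub[gr, , drop = FALSE]),
                  numeric(2)))
  test <- .chisq2(tab, warn_expected = TRUE)
  adj_p <- min(1, test$p * choose(length(idx) - 1L, g - 1L))
  child_n <- rowSums(tab)
  if (adj_p >= params$alpha_split || any(child_n < params$min_child)) {
    return(node)
  }
  node$split_p <- adj_p
  node$children <- lapply(groups, function(gr) {
    .chaid_grow(m, values, idx[gr], depth + 1L, params)
  })
  node
}

#' Grow a CHAID tree on the score against a binary outcome
#'
#' Single-predictor ordinal CHAID: the integer score is the only split
#' variable, so deeper levels re-split score intervals. See
#' [chaid_params()] for the stopping rules.
#'
#' @param score integer score vector.
#' @param event binary outcome vector (1 = death within follow-up).
#' @param params a [chaid_params()] object.
#' @return a nested tree of class `mcds_chaid`; each node carries its score
#'   `interval`, `n`, `n_events`, the adjusted `split_p` (when split) and
#'   `children`.
#' @export
mcds_chaid <- function(score, event, params = chaid_params()) {
  stopifnot(length(score) == length(event), all(score >= 0),
            all(event %in% c(0, 1)))
  counts <- .score_counts(score, event)
  root <- .chaid_grow(counts$m, counts$values,
                      seq_along(counts$values), 0L, params)
  structure(c(root, list(params = params)), class = "mcds_chaid")
}

.chaid_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  do.call(c, lapply(node$children, .chaid_leaves))
}

#' Extract a stratification scheme from a CHAID tree
#'
#' Orders the leaves by score interval and converts them into an
#' exhaustive, non-overlapping partition of the nonnegative integers: each
#' class starts at its leaf's smallest observed score, and the first class
#' is extended down to 0.
#'
#' @param tree an `mcds_chaid` tree.
#' @return an [mcds_scheme()].
#' @export
extract_boundaries <- function(tree) {
  stopifnot(inherits(tree, "mcds_chaid"))
  leaves <- .chaid_leaves(tree)
  lowers <- sort(vapply(leaves, function(l) l$interval[1L], numeric(1)))
  lowers[1L] <- 0
  mcds_scheme(as.integer(lowers))
}

#' @export
print.mcds_chaid <- function(x, ...) {
  rec <- function(node, indent) {
    iv <- node$interval
    lab <- if (iv[1] == iv[2]) as.character(iv[1]) else
      paste0(iv[1], "-", iv[2])
    cat(strrep("  ", indent),
        sprintf("[%s] n=%d events=%d (%.2f%%)", lab, node$n, node$n_events,
                100 * node$n_events / max(node$n, 1)),
        if (!is.null(node$split_p)) {
          sprintf("  split adj.p=%.3g", node$split_p)
        } else "",
        "\n", sep = "")
    for (ch in node$children %||% list()) rec(ch, indent + 1L)
  }
  cat("CHAID tree on M-CDS score\n")
  rec(x, 0L)
  invisible(x)
}
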