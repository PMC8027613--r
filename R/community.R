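## Distance-based community comparison: contaminant filtering, Bray-Curtis
## distances and permutation tests (ANOSIM, PERMANOVA, Mantel).

#' Remove contaminant genera from an ASV table
#'
#' Drops ASVs whose genus-level classification matches a blocklist of
#' commonly identified reagent/laboratory contaminants.  Matching is
#' case-insensitive exact equality on the genus string; unassigned genera
#' are never treated as contaminants.
#'
#' @param counts ASV-by-sample numeric matrix.
#' @param taxonomy Named character vector of genus assignments (names are
#'   ASV ids, matching `rownames(counts)`); `NA` or `""` means unassigned.
#' @param blocklist Character vector of contaminant genus names.  The
#'   package ships a starter list at
#'   `system.file("extdata", "contaminant_genera.tsv", package = "ventredox")`.
#' @return The filtered matrix, with attribute `removed`: a data.frame of
#'   removed ASV ids, their genus and their per-sample counts.
#' @export
filter_contaminants <- function(counts, taxonomy, blocklist) {
  counts <- check_count_matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs rownames (ASV ids)",
                                      call. = FALSE)
  genus <- taxonomy[rownames(counts)]
  genus[is.na(genus)] <- ""
  hit <- tolower(genus) %in% tolower(blocklist[nzchar(blocklist)])
  removed <- data.frame(asv_id = rownames(counts)[hit],
                        genus = unname(genus[hit]),
                        stringsAsFactors = FALSE)
  if (any(hit)) removed <- cbind(removed, counts[hit, , drop = FALSE])
  out <- counts[!hit, , drop = FALSE]
  if (nrow(out) == 0) stop("no ASVs left after contaminant filtering",
                           call. = FALSE)
  attr(out, "removed") <- removed
  out
}

#' Bray-Curtis distance matrix between samples
#'
#' `d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))` over features,
#' computed for every pair of samples (columns).  Normalized counts are
#' recommended; a warning is issued when the table does not look scaled.
#'
#' @param counts Feature-by-sample numeric matrix, or a
#'   `normalized_counts` object (its normalized table is used).
#' @param warn_raw Warn when given a plain table of what looks like raw
#'   integer counts.
#' @return A symmetric sample-by-sample matrix with zero diagonal and
#'   entries in `[0, 1]`.
#' @export
bray_curtis <- function(counts, warn_raw = TRUE) {
  if (inherits(counts, "normalized_counts")) {
    counts <- counts$normalized
  } else if (warn_raw && all(counts == round(counts))) {
    warning("table looks like raw counts; normalization is recommended",
            call. = FALSE)
  }
  counts <- check_count_matrix(counts)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop(sprintf("all-zero sample(s): %s",
                 paste(colnames(counts)[zero], collapse = ", ")),
         call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  dimnames(d) <- list(colnames(counts), colnames(counts))
  d
}

check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) ||
      any(diag(d) != 0) || any(d < 0))
    stop("not a valid distance matrix (symmetric, zero diagonal, >= 0)",
         call. = FALSE)
  d
}

# All permutations of 1..n as an n! x n matrix (n <= 8 guard).
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Permutation machinery shared by anosim/permanova: statistic under label
# permutations, add-one p-value, or exhaustive enumeration (identity is
# part of the enumeration, so the add-one convention holds automatically).
permutation_p <- function(stat_fun, n, n_perm, seed, exhaustive) {
  observed <- stat_fun(seq_len(n))
  if (exhaustive) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1, stat_fun)
    p <- sum(stats >= observed - 1e-12) / length(stats)
    list(observed = observed, p = p, n_perm = length(stats))
  } else {
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_fun(sample.int(n)), numeric(1))
    })
    p <- (1 + sum(perm_stats >= observed - 1e-12)) / (n_perm + 1)
    list(observed = observed, p = p, n_perm = n_perm)
  }
}

#' ANOSIM on a distance matrix
#'
#' Analysis of similarities: on the rank-transformed pairwise distances
#' (average ranks for ties), `R = (mean between-group rank - mean
#' within-group rank) / (N(N-1)/4)`, in `[-1, 1]`.  Significance by
#' permuting group labels; the p-value uses the add-one convention, so it
#' is never below `1/(n_perm + 1)`.
#'
#' @param d Symmetric distance matrix (e.g. from [bray_curtis()]).
#' @param groups Group labels, one per sample, at least two groups.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all permutations instead of sampling
#'   (exact p; feasible up to 8 samples).
#' @return A `grouping_test` list: `statistic_name` ("anosim_R"),
#'   `statistic`, `p`, `n_perm`, `seed`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL,
                        exhaustive = FALSE) {
  d <- check_distance_matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (!exhaustive && is.null(seed))
    stop("an explicit seed is required", call. = FALSE)

  lower <- lower.tri(d)
  r <- rank(d[lower])
  denom <- n * (n - 1) / 4
  gi <- as.integer(groups)
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]

  stat_fun <- function(ord) {
    g <- gi[ord]
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  res <- permutation_p(stat_fun, n, n_perm, seed, exhaustive)
  structure(list(statistic_name = "anosim_R", statistic = res$observed,
                 p = res$p, n_perm = res$n_perm, seed = seed),
            class = "grouping_test")
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the sum of
#' squared distances into between- and within-group components,
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` from within-group pairs
#' each divided by its group size, `pseudo-F = (SS_between/(g-1)) /
#' (SS_within/(N-g))`, `r2 = SS_between / SS_total`.  On univariate
#' Euclidean distances the pseudo-F equals the classical one-way ANOVA F.
#' Significance by permutation of group labels (add-one p-value).
#'
#' @inheritParams anosim_test
#' @return A `grouping_test` list: `statistic_name`
#'   ("permanova_pseudoF"), `statistic`, `r2`, `p`, `n_perm`, `seed`.
#' @export
permanova_test <- function(d, groups, n_perm = 999, seed = NULL,
                           exhaustive = FALSE) {
  d <- check_distance_matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (!exhaustive && is.null(seed))
    stop("an explicit seed is required", call. = FALSE)

  d2 <- d^2
  lower <- lower.tri(d2)
  ss_total <- sum(d2[lower]) / n
  gi <- as.integer(groups)
  sizes <- tabulate(gi, g)
  pair_i <- row(d2)[lower]
  pair_j <- col(d2)[lower]
  d2v <- d2[lower]

  decomposition <- function(ord) {
    lab <- gi[ord]
    li <- lab[pair_i]
    within <- li == lab[pair_j]
    ss_within <- sum(tapply(d2v[within], li[within], sum) /
                       sizes[sort(unique(li[within]))])
    ss_between <- ss_total - ss_within
    if (ss_total == 0) return(0)  # degenerate: all samples identical
    (ss_between / (g - 1)) / (ss_within / (n - g))
  }
  res <- permutation_p(decomposition, n, n_perm, seed, exhaustive)

  # r2 for the observed labelling
  within <- gi[pair_i] == gi[pair_j]
  ss_within <- sum(tapply(d2v[within], gi[pair_i][within], sum) /
                     sizes[sort(unique(gi[pair_i][within]))])
  r2 <- if (ss_total > 0) (ss_total - ss_within) / ss_total else 0

  structure(list(statistic_name = "permanova_pseudoF",
                 statistic = res$observed, r2 = r2, p = res$p,
                 n_perm = res$n_perm, seed = seed),
            class = "grouping_test")
}

#' @export
print.grouping_test <- function(x, ...) {
  cat(sprintf("<grouping_test> %s = %.4f%s, p = %.4g (%d permutations)\n",
              x$statistic_name, x$statistic,
              if (!is.null(x$r2)) sprintf(", r2 = %.3f", x$r2) else "",
              x$p, x$n_perm))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Correlates the strictly-lower-triangle entries of two distance matrices
#' (Pearson or Spearman) and assesses significance by jointly permuting the
#' rows and columns of the second matrix.  One-sided (positive association)
#' by default.
#'
#' @param d1,d2 Distance matrices over the same samples in the same order
#'   (n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` permutations (n <= 8).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `mantel_result` list: `r`, `p`, `method`, `n_perm`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL, exhaustive = FALSE,
                        alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  d1 <- check_distance_matrix(d1)
  d2 <- check_distance_matrix(d2)
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  if (nrow(d2) != n) stop("distance matrices differ in size", call. = FALSE)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices must cover the same ids in the same order",
         call. = FALSE)
  if (!exhaustive && is.null(seed))
    stop("an explicit seed is required", call. = FALSE)

  lower <- lower.tri(d1)
  x <- d1[lower]
  if (stats::var(x) == 0 || stats::var(d2[lower]) == 0)
    stop("constant distance vector: correlation undefined", call. = FALSE)

  stat_fun <- function(ord) {
    y <- d2[ord, ord][lower]
    stats::cor(x, y, method = method)
  }
  score <- if (alternative == "greater") stat_fun else function(ord) abs(stat_fun(ord))
  res <- permutation_p(score, n, n_perm, seed, exhaustive)
  r_obs <- stat_fun(seq_len(n))
  structure(list(r = r_obs, p = res$p, method = method,
                 alternative = alternative, n_perm = res$n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r (%s) = %.4f, p = %.4g (%d permutations, %s)\n",
              x$method, x$r, x$p, x$n_perm, x$alternative))
  invisible(x)
}

#' Euclidean distance matrix from environmental metadata
#'
#' Builds a sample-by-sample Euclidean distance matrix from selected numeric
#' metadata columns (e.g. mineralogy or element concentrations), for use in
#' Mantel tests against a community distance matrix.  Columns are
#' standardized to unit variance by default so that variables on different
#' scales contribute comparably.
#'
#' @param metadata Data.frame with a `sample_id` column and numeric
#'   variables.
#' @param columns Character vector of column names to use.
#' @param standardize Scale each column to zero mean, unit variance.
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
env_distance <- function(metadata, columns, standardize = TRUE) {
  stopifnot("sample_id" %in% names(metadata),
            all(columns %in% names(metadata)))
  x <- as.matrix(metadata[, columns, drop = FALSE])
  if (!is.numeric(x)) stop("selected columns must be numeric", call. = FALSE)
  if (standardize) x <- scale(x)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  d
}
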