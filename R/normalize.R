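## Between-sample normalization of count tables: trimmed mean of M-values
## (TMM) for gene x sample metagenomic counts and cumulative sum scaling
## (CSS) for marker-gene (ASV) tables.

check_count_matrix <- function(counts, min_samples = 1L) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (any(!is.finite(counts))) stop("counts must be finite", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(counts) < min_samples)
    stop(sprintf("need at least %d samples", min_samples), call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  counts
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalization for compositional bias in count
#' data.  Unless a reference is given, the reference sample is the one whose
#' upper-quartile/library-size ratio is closest to the mean of those ratios.
#' For each sample, gene-wise log2 abundance ratios M (library-size-scaled,
#' versus the reference) and average log2 abundances A are computed over
#' genes positive in both samples, doubly trimmed (30% on M, 5% on A by
#' default, each side), and the factor is 2 to the precision-weighted mean
#' of the surviving M values, with weights from the binomial delta-method
#' variance.  Factors are rescaled to have geometric mean 1, so they are
#' invariant to pure sequencing-depth differences.
#'
#' @param counts Gene-by-sample numeric matrix of non-negative counts
#'   (at least 2 samples, each with positive library size).
#' @param logratio_trim Two-sided trim fraction on M (default 0.30).
#' @param abs_trim Two-sided trim fraction on A (default 0.05).
#' @param reference Optional reference sample name or index.
#' @param weighted Use the precision weights (default).  The weights depend
#'   on absolute library sizes, so the weighted estimator is only
#'   asymptotically invariant to depth rescaling of a single sample; the
#'   unweighted trimmed mean (`weighted = FALSE`) is exactly invariant.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05,
                        reference = NULL, weighted = TRUE) {
  counts <- check_count_matrix(counts, min_samples = 2L)
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
      abs_trim < 0 || abs_trim >= 0.5)
    stop("trim fractions must lie in [0, 0.5)", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop(sprintf("sample(s) with zero library size: %s",
                 paste(colnames(counts)[lib <= 0], collapse = ", ")),
         call. = FALSE)

  if (is.null(reference)) {
    uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    ref <- match(reference, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample", call. = FALSE)
  } else ref <- as.integer(reference)

  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    logratio_trim, abs_trim, weighted)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# One sample against the reference.  Doubly-trimmed, precision-weighted
# mean of M values; trimming keeps ranks in [floor(n*trim)+1, n-floor(n*trim)]
# on both the M and A orderings.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            logratio_trim, abs_trim, weighted = TRUE) {
  pos <- obs > 0 & ref > 0
  if (!any(pos))
    stop("sample shares no positive genes with the reference", call. = FALSE)
  obs <- obs[pos]; ref <- ref[pos]
  p_obs <- obs / lib_obs
  p_ref <- ref / lib_ref
  M <- log2(p_obs / p_ref)
  A <- (log2(p_obs) + log2(p_ref)) / 2
  # delta-method variance of M under binomial sampling
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)

  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  # guard against numerically identical columns
  if (max(abs(M[keep])) < 1e-10) return(1)
  if (weighted) 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  else 2^mean(M[keep])
}

#' CSS scaling factors
#'
#' Cumulative-sum-scaling normalization for sparse marker-gene count
#' tables: each sample's factor is the sum of its counts up to (and
#' including) the chosen quantile of its positive counts.  The quantile is
#' taken over positive counts only, with the nearest-rank (type 1)
#' convention, so factors are positively homogeneous of degree one in each
#' column.
#'
#' @param counts Feature-by-sample numeric matrix of non-negative counts;
#'   every sample needs at least one positive count.
#' @param css_quantile Quantile in (0, 1); default 0.5.
#' @return Named numeric vector of per-sample factors.
#' @export
css_factors <- function(counts, css_quantile = 0.5) {
  counts <- check_count_matrix(counts)
  if (css_quantile <= 0 || css_quantile >= 1)
    stop("css_quantile must lie in (0, 1)", call. = FALSE)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    x <- x[x > 0]
    if (length(x) == 0)
      stop(sprintf("sample '%s' has no positive counts", colnames(counts)[j]),
           call. = FALSE)
    q <- stats::quantile(x, css_quantile, type = 1, names = FALSE)
    sum(x[x <= q])
  }, numeric(1))
  if (any(f <= 0))
    stop("css_quantile too low: a sample's scaling factor is zero",
         call. = FALSE)
  setNames(f, colnames(counts))
}

#' Normalize a count table
#'
#' Applies TMM or CSS scaling and returns the normalized table together
#' with the factors; the input table is left untouched.  For TMM the
#' normalized values are counts per million of effective library size
#' (library size times factor); for CSS they are counts divided by the
#' sample factor and rescaled by the median factor, the convention of the
#' originating method.
#'
#' @param counts Feature-by-sample numeric matrix (raw counts).
#' @param method `"tmm"` or `"css"`.
#' @param ... Passed to [tmm_factors()] or [css_factors()].
#' @return A `normalized_counts` object: list with `normalized` (matrix),
#'   `factors`, `method` and `counts` (the raw input).
#' @export
normalize_counts <- function(counts, method = c("tmm", "css"), ...) {
  method <- match.arg(method)
  if (inherits(counts, "normalized_counts"))
    stop("table is already normalized", call. = FALSE)
  counts <- check_count_matrix(counts, min_samples = 1L)
  if (method == "tmm") {
    f <- tmm_factors(counts, ...)
    eff <- colSums(counts) * f
    normalized <- sweep(counts, 2, eff, "/") * 1e6
  } else {
    f <- css_factors(counts, ...)
    normalized <- sweep(counts, 2, f, "/") * stats::median(f)
  }
  structure(list(normalized = normalized, factors = f, method = method,
                 counts = counts),
            class = "normalized_counts")
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat(sprintf("<normalized_counts> %s; %d features x %d samples\nfactors: %s\n",
              toupper(x$method), nrow(x$normalized), ncol(x$normalized),
              paste(sprintf("%s=%.4g", names(x$factors), x$factors),
                    collapse = ", ")))
  invisible(x)
}
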