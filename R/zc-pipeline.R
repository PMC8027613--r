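## Abundance-weighted proteome Z_C: weighting, pooling, subsampling and
## pairwise statistical comparison.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Build an abundance-weighted proteome
#'
#' Attaches per-protein elemental chemistry and an abundance-derived weight
#' to each predicted protein of one sample.  Weights are proportional to the
#' (normalized) abundance of the encoding gene and sum to one, so multiplying
#' a sample's abundances by any positive constant leaves the weighted
#' proteome unchanged.
#'
#' @param proteins A data.frame with columns `protein_id`, `gene_id`,
#'   `sequence` (e.g. from [read_protein_fasta()]).
#' @param abundances Named numeric vector of per-gene abundances (names are
#'   gene ids), or a gene-by-sample matrix/data.frame together with
#'   `sample_id`.
#' @param sample_id Sample identifier; required when `abundances` is a
#'   matrix, otherwise used only as a label.
#' @param missing_gene Policy when a protein's gene has no abundance:
#'   `"drop"` excludes the protein with a warning; `"fail"` errors.
#' @param max_nonstandard_frac Proteins with more than this fraction of
#'   non-standard residues are excluded (with a warning); the remaining
#'   non-standard residues are dropped from the formulas.
#' @return A `weighted_proteome`: data.frame with columns `protein_id`,
#'   `gene_id`, `weight`, `length`, `c` (carbon count) and `zc`, plus
#'   attribute `sample_id`.
#' @export
weight_proteome <- function(proteins, abundances, sample_id = NULL,
                            missing_gene = c("drop", "fail"),
                            max_nonstandard_frac = 0.1) {
  missing_gene <- match.arg(missing_gene)
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "gene_id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id in proteome", call. = FALSE)

  if (is.matrix(abundances) || is.data.frame(abundances)) {
    if (is.null(sample_id))
      stop("sample_id is required with a gene-by-sample abundance table",
           call. = FALSE)
    if (!sample_id %in% colnames(abundances))
      stop(sprintf("sample '%s' not found in abundance table", sample_id),
           call. = FALSE)
    abundances <- setNames(as.numeric(abundances[, sample_id]),
                           rownames(abundances))
  }
  if (is.null(sample_id)) sample_id <- "sample"

  chem <- proteome_chemistry(proteins$sequence)
  frac_bad <- chem$n_nonstandard / (chem$length + chem$n_nonstandard)
  keep <- chem$length >= 1 & frac_bad <= max_nonstandard_frac
  if (any(!keep))
    warning(sprintf("excluding %d protein(s) with > %.0f%% non-standard residues",
                    sum(!keep), 100 * max_nonstandard_frac), call. = FALSE)
  dropped_res <- sum(chem$n_nonstandard[keep])
  if (dropped_res > 0)
    warning(sprintf("dropped %d non-standard residue(s) from retained proteins",
                    dropped_res), call. = FALSE)

  ab <- abundances[proteins$gene_id]
  no_gene <- is.na(ab)
  if (any(no_gene)) {
    if (missing_gene == "fail")
      stop(sprintf("no abundance for gene(s): %s",
                   paste(unique(proteins$gene_id[no_gene]), collapse = ", ")),
           call. = FALSE)
    warning(sprintf("dropping %d protein(s) whose gene has no abundance",
                    sum(no_gene)), call. = FALSE)
  }
  keep <- keep & !no_gene
  if (!any(keep)) stop("no proteins left after filtering", call. = FALSE)

  w <- as.numeric(ab[keep])
  if (any(w < 0)) stop("negative abundances", call. = FALSE)
  if (sum(w) <= 0)
    stop(sprintf("sample '%s': all gene abundances are zero", sample_id),
         call. = FALSE)
  out <- data.frame(protein_id = proteins$protein_id[keep],
                    gene_id = proteins$gene_id[keep],
                    weight = w / sum(w),
                    length = chem$length[keep],
                    c = chem$c[keep],
                    zc = chem$zc[keep],
                    stringsAsFactors = FALSE)
  structure(out, sample_id = sample_id,
            class = c("weighted_proteome", "data.frame"))
}

#' Analytic pool Z_C of a weighted proteome
#'
#' The Z_C of the abundance-weighted composite proteome: the carbon- and
#' weight-weighted mean of per-protein Z_C, identical to the Z_C of the
#' weighted sum of all elemental formulas.  This is the analytic target the
#' subsampling estimator converges to as the subsample size grows.
#'
#' @param wp A `weighted_proteome` from [weight_proteome()].
#' @return A single numeric Z_C value.
#' @export
pool_zc <- function(wp) {
  if (NROW(wp) == 0) stop("empty proteome", call. = FALSE)
  sum(wp$weight * wp$c * wp$zc) / sum(wp$weight * wp$c)
}

#' Replicate subsampled Z_C distribution of one sample
#'
#' Emulates intra-sample variability by repeatedly drawing a composite
#' proteome of about `target_aa` amino acids: proteins are drawn whole, with
#' replacement, with probability proportional to their abundance weight,
#' until the cumulative residue count first reaches `target_aa` (the last
#' protein is kept whole, so replicates have `target_aa` residues on
#' average).  Each replicate's Z_C is the Z_C of the pooled elemental
#' formula of the drawn proteins, i.e. the carbon-weighted mean of their
#' Z_C values, so per-draw contributions are normalized by protein length.
#'
#' @param wp A `weighted_proteome`.
#' @param target_aa Residues per replicate (default 200000).
#' @param n_reps Number of replicates (default 100; at least 2).
#' @param seed Integer seed; required, so every run is reproducible.
#' @param per_protein_mean If `TRUE`, a replicate's Z_C is instead the
#'   unweighted mean of the drawn proteins' Z_C values (each protein counts
#'   once regardless of length); default `FALSE`.
#' @return A `zc_distribution`: list with `sample_id`, `replicate_values`,
#'   `mean`, `sd`, and `params` (target_aa, n_reps, seed).
#' @export
subsample_zc <- function(wp, target_aa = 200000, n_reps = 100, seed,
                         per_protein_mean = FALSE) {
  if (NROW(wp) == 0) stop("empty proteome", call. = FALSE)
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required", call. = FALSE)
  if (target_aa < 1) stop("target_aa must be positive", call. = FALSE)

  w <- wp$weight
  len <- wp$length
  cc <- wp$c
  czc <- wp$c * wp$zc
  mean_len <- sum(w * len)
  n_prot <- length(w)

  vals <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      need <- target_aa
      tot_c <- 0
      tot_czc <- 0
      tot_n <- 0L
      tot_zc <- 0
      repeat {
        n_draw <- max(16L, ceiling(need / mean_len * 1.2) + 8L)
        idx <- sample.int(n_prot, n_draw, replace = TRUE, prob = w)
        cl <- cumsum(len[idx])
        stop_at <- which(cl >= need)
        if (length(stop_at)) {
          idx <- idx[seq_len(stop_at[1L])]
          tot_c <- tot_c + sum(cc[idx])
          tot_czc <- tot_czc + sum(czc[idx])
          tot_n <- tot_n + length(idx)
          tot_zc <- tot_zc + sum(wp$zc[idx])
          break
        }
        tot_c <- tot_c + sum(cc[idx])
        tot_czc <- tot_czc + sum(czc[idx])
        tot_n <- tot_n + length(idx)
        tot_zc <- tot_zc + sum(wp$zc[idx])
        need <- need - cl[length(cl)]
      }
      if (per_protein_mean) tot_zc / tot_n else tot_czc / tot_c
    }, numeric(1))
  })

  structure(list(sample_id = attr(wp, "sample_id"),
                 replicate_values = vals,
                 mean = mean(vals),
                 sd = stats::sd(vals),
                 params = list(target_aa = target_aa, n_reps = n_reps,
                               seed = seed,
                               per_protein_mean = per_protein_mean)),
            class = "zc_distribution")
}

#' @export
print.zc_distribution <- function(x, ...) {
  cat(sprintf("<zc_distribution> %s: mean Z_C = %.4f, sd = %.4f (%d replicates of ~%d aa)\n",
              x$sample_id, x$mean, x$sd, length(x$replicate_values),
              x$params$target_aa))
  invisible(x)
}

#' Compare two replicate Z_C distributions
#'
#' Means are compared with Welch's unequal-variance t-test on the replicate
#' values.  Dispersions are compared with a Wilcoxon rank-sum test on the
#' absolute deviations of replicate values from their sample mean (a
#' Levene-type comparison; a rank-sum test on the raw values tests location,
#' not spread).  Set `wilcoxon_on = "values"` for a rank-sum test of
#' location instead.
#'
#' @param a,b `zc_distribution` objects with at least 2 replicates each.
#' @param wilcoxon_on `"dispersion"` (default) or `"values"`.
#' @return A one-row data.frame: `sample_a`, `sample_b`, `welch_t`,
#'   `welch_p`, `wilcoxon_w`, `wilcoxon_p`, `degenerate`.
#' @export
compare_zc <- function(a, b, wilcoxon_on = c("dispersion", "values")) {
  wilcoxon_on <- match.arg(wilcoxon_on)
  stopifnot(inherits(a, "zc_distribution"), inherits(b, "zc_distribution"))
  x <- a$replicate_values
  y <- b$replicate_values
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 replicates per sample", call. = FALSE)

  degenerate <- stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate && mean(x) == mean(y)) {
    tt <- list(statistic = 0, p.value = 1)
  } else if (degenerate) {
    tt <- list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0)
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }

  wx <- switch(wilcoxon_on,
               dispersion = abs(x - mean(x)),
               values = x)
  wy <- switch(wilcoxon_on,
               dispersion = abs(y - mean(y)),
               values = y)
  wt <- suppressWarnings(stats::wilcox.test(wx, wy, exact = FALSE))

  data.frame(sample_a = a$sample_id, sample_b = b$sample_id,
             welch_t = tt$statistic, welch_p = tt$p.value,
             wilcoxon_w = unname(wt$statistic), wilcoxon_p = wt$p.value,
             degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' All pairwise Z_C comparisons with multiplicity adjustment
#'
#' Runs [compare_zc()] on every pair of samples and adjusts both families of
#' p-values (Holm by default) across all pairs in the run.
#'
#' @param dists List of `zc_distribution` objects.
#' @param adjust Adjustment method passed to [stats::p.adjust()].
#' @inheritParams compare_zc
#' @return Data.frame with one row per unordered pair, including
#'   `welch_p_adj` and `wilcoxon_p_adj`.
#' @export
compare_zc_pairs <- function(dists, adjust = "holm",
                             wilcoxon_on = c("dispersion", "values")) {
  wilcoxon_on <- match.arg(wilcoxon_on)
  if (length(dists) < 2) stop("need >= 2 samples", call. = FALSE)
  pairs <- utils::combn(length(dists), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    compare_zc(dists[[pairs[1, k]]], dists[[pairs[2, k]]],
               wilcoxon_on = wilcoxon_on)
  })
  out <- do.call(rbind, rows)
  out$welch_p_adj <- stats::p.adjust(out$welch_p, method = adjust)
  out$wilcoxon_p_adj <- stats::p.adjust(out$wilcoxon_p, method = adjust)
  out
}

#' Summarize replicate Z_C distributions
#'
#' @param dists List of `zc_distribution` objects.
#' @return Data.frame: `sample_id`, `mean`, `sd`, `n_reps`, `target_aa`,
#'   `seed`.
#' @export
zc_summary <- function(dists) {
  do.call(rbind, lapply(dists, function(d) {
    data.frame(sample_id = d$sample_id, mean = d$mean, sd = d$sd,
               n_reps = length(d$replicate_values),
               target_aa = d$params$target_aa, seed = d$params$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Strip plot of replicate Z_C distributions
#'
#' Draws one jittered column of replicate Z_C values per sample with the
#' per-sample mean overplotted, and a dashed line at the across-sample
#' grand mean — the standard way to display subsampled proteome Z_C.
#'
#' @param dists List of `zc_distribution` objects.
#' @return A ggplot object.
#' @export
plot_zc_distributions <- function(dists) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- do.call(rbind, lapply(dists, function(d) {
    data.frame(sample_id = d$sample_id, zc = d$replicate_values)
  }))
  means <- zc_summary(dists)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$zc)) +
    ggplot2::geom_jitter(width = 0.18, alpha = 0.45, size = 0.8) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(x = .data$sample_id, y = .data$mean),
                        size = 2.4) +
    ggplot2::geom_hline(yintercept = mean(df$zc), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = expression(italic(Z)[C]))
}
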