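# Independent oracles used to check the package implementations.  These are
# written from first principles (free amino-acid formulas, explicit
# per-atom oxidation-state accounting, naive permutation enumeration,
# literal normalization formulas) and never call the code paths they check.

# Free amino acid formulas: C, H, N, O, S of the free molecule.
FREE_AA <- rbind(
  A = c(3, 7, 1, 2, 0),  R = c(6, 14, 4, 2, 0), N = c(4, 8, 2, 3, 0),
  D = c(4, 7, 1, 4, 0),  C = c(3, 7, 1, 2, 1),  E = c(5, 9, 1, 4, 0),
  Q = c(5, 10, 2, 3, 0), G = c(2, 5, 1, 2, 0),  H = c(6, 9, 3, 2, 0),
  I = c(6, 13, 1, 2, 0), L = c(6, 13, 1, 2, 0), K = c(6, 14, 2, 2, 0),
  M = c(5, 11, 1, 2, 1), F = c(9, 11, 1, 2, 0), P = c(5, 9, 1, 2, 0),
  S = c(3, 7, 1, 3, 0),  T = c(4, 9, 1, 3, 0),  W = c(11, 12, 2, 2, 0),
  Y = c(9, 11, 1, 3, 0), V = c(5, 11, 1, 2, 0))
colnames(FREE_AA) <- c("C", "H", "N", "O", "S")

# Mean carbon oxidation state by explicit per-atom accounting: the sum of
# all atomic oxidation states must equal the net charge, with nominal
# states H = +1, N = -3, O = -2, S = -2; solve for the carbon mean.
oracle_zc_atoms <- function(C, H, N, O, S, charge = 0) {
  others <- H * (+1) + N * (-3) + O * (-2) + S * (-2)
  unname((charge - others) / C)
}

# Z_C of a peptide built from free amino acids joined by peptide bonds:
# each bond releases one water, so a chain of n residues keeps n - 1 fewer
# waters than the free molecules; without the terminal water it loses n.
oracle_peptide_zc <- function(seq, terminal_water = TRUE) {
  aa <- strsplit(seq, "")[[1]]
  atoms <- colSums(FREE_AA[aa, , drop = FALSE])
  n_water <- if (terminal_water) length(aa) - 1 else length(aa)
  atoms["H"] <- atoms["H"] - 2 * n_water
  atoms["O"] <- atoms["O"] - n_water
  oracle_zc_atoms(atoms["C"], atoms["H"], atoms["N"], atoms["O"], atoms["S"])
}

random_peptide <- function(max_len = 50) {
  len <- sample(1:max_len, 1)
  paste(sample(rownames(FREE_AA), len, replace = TRUE), collapse = "")
}

# Step-by-step TMM per the published formula: quantile-ratio reference
# selection, M/A over doubly positive genes, double trim by rank, weighted
# mean of M with binomial delta-method precision weights, geometric-mean-1
# rescaling.  Written independently of the package function.
oracle_tmm <- function(counts, trimM = 0.3, trimA = 0.05) {
  lib <- colSums(counts)
  ratios <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(ratios - mean(ratios)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]; r <- counts[, ref]
    use <- x > 0 & r > 0
    x <- x[use]; r <- r[use]
    M <- log2((x / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((x / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - x) / (lib[j] * x) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    keepM <- rank(M) >= floor(n * trimM) + 1 & rank(M) <= n - floor(n * trimM)
    keepA <- rank(A) >= floor(n * trimA) + 1 & rank(A) <= n - floor(n * trimA)
    keep <- keepM & keepA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  })
  f / exp(mean(log(f)))
}

# All permutations of a vector, recursively (small n only).
perms_of <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms_of(v[-i])))
  out
}

# Naive ANOSIM R: literal definition on average-ranked distances.
oracle_anosim_R <- function(d, groups) {
  n <- nrow(d)
  rd <- matrix(0, n, n)
  rd[lower.tri(rd)] <- rank(d[lower.tri(d)])
  between <- c(); within <- c()
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (groups[i] == groups[j]) within <- c(within, rd[i, j])
    else between <- c(between, rd[i, j])
  }
  (mean(between) - mean(within)) / (n * (n - 1) / 4)
}

# Naive one-way PERMANOVA pseudo-F from the squared-distance partition.
oracle_permanova_F <- function(d, groups) {
  n <- nrow(d)
  g <- length(unique(groups))
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(d[idx, idx][lower.tri(d[idx, idx])]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

# Random KEGG-style module definition over a disjoint KO id pool.
random_module_definition <- function(ko_pool) {
  n_steps <- sample(2:6, 1)
  used <- 0
  steps <- character(n_steps)
  for (s in seq_len(n_steps)) {
    kind <- sample(c("ko", "or", "and"), 1, prob = c(0.5, 0.3, 0.2))
    take <- switch(kind, ko = 1, or = sample(2:3, 1), and = 2)
    kos <- ko_pool[(used + 1):(used + take)]
    used <- used + take
    steps[s] <- switch(kind,
      ko = kos,
      or = paste0("(", paste(kos, collapse = ","), ")"),
      and = paste(kos, collapse = "+"))
  }
  paste(steps, collapse = " ")
}
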