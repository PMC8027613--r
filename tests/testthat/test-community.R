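toy_asv <- function() {
  counts <- matrix(c(10, 5, 0,
                     8, 6, 1,
                     0, 2, 12), 3, 3, byrow = TRUE,
                   dimnames = list(c("ASV_1", "ASV_2", "ASV_3"),
                                   c("s1", "s2", "s3")))
  taxonomy <- c(ASV_1 = "Ralstonia", ASV_2 = "Thiomicrospira", ASV_3 = "")
  list(counts = counts, taxonomy = taxonomy)
}

test_that("contaminant filtering is exact, case-insensitive genus matching", {
  t <- toy_asv()
  out <- filter_contaminants(t$counts, t$taxonomy, c("ralstonia"))
  expect_equal(rownames(out), c("ASV_2", "ASV_3"))
  rep <- attr(out, "removed")
  expect_equal(rep$asv_id, "ASV_1")
  expect_equal(unname(unlist(rep[1, c("s1", "s2", "s3")])), c(10, 5, 0))
  # no prefix matching, empty blocklist is a no-op, unassigned kept
  t2 <- toy_asv()
  t2$taxonomy["ASV_2"] <- "Ralstonia2"
  out2 <- filter_contaminants(t2$counts, t2$taxonomy, "Ralstonia")
  expect_equal(rownames(out2), c("ASV_2", "ASV_3"))
  out3 <- filter_contaminants(t$counts, t$taxonomy, character(0))
  expect_equal(nrow(out3), 3)
  expect_error(
    filter_contaminants(t$counts, t$taxonomy,
                        c("Ralstonia", "Thiomicrospira", "")),
    NA)  # unassigned ASV_3 survives even with "" in the blocklist
})

test_that("Bray-Curtis follows the shared-abundance definition", {
  m <- cbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0), d = c(2, 0, 0))
  d <- suppressWarnings(bray_curtis(m))
  expect_equal(unname(d["a", "b"]), 0.5)
  expect_equal(unname(d["a", "c"]), 0)   # identical samples
  expect_equal(unname(d["b", "d"]), 1)   # disjoint supports
  expect_true(all(d >= 0 & d <= 1) && all(diag(d) == 0))
  expect_equal(d, t(d))
  bad <- cbind(a = c(1, 0), b = c(0, 0))
  expect_error(suppressWarnings(bray_curtis(bad)), "all-zero")
  expect_warning(bray_curtis(m), "raw counts")
})

test_that("ANOSIM reaches R = 1 under complete separation", {
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_true(res$p >= 1 / 100)
})

test_that("ANOSIM statistic and exhaustive p match naive enumeration", {
  set.seed(11)
  x <- matrix(rnorm(6 * 4), 6, 4)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, g, exhaustive = TRUE)
  expect_equal(res$statistic, oracle_anosim_R(d, g), tolerance = 1e-12)
  # enumeration over all 20 distinct assignments of labels to samples
  combos <- t(combn(6, 3))
  stats <- apply(combos, 1, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    oracle_anosim_R(d, gg)
  })
  p_exact <- mean(stats >= res$statistic - 1e-12)
  expect_equal(res$p, p_exact)
  # and the vegan implementation agrees on the statistic
  expect_equal(res$statistic,
               unname(suppressWarnings(
                 vegan::anosim(as.dist(d), g, permutations = 2))$statistic),
               tolerance = 1e-12)
})

test_that("PERMANOVA matches the enumeration oracle and adonis2", {
  set.seed(12)
  x <- matrix(rnorm(6 * 4), 6, 4)
  d <- as.matrix(dist(x))
  g <- c("a", "a", "b", "b", "b", "a")
  res <- permanova_test(d, g, exhaustive = TRUE)
  expect_equal(res$statistic, oracle_permanova_F(d, g), tolerance = 1e-12)
  combos <- t(combn(6, 3))
  stats <- apply(combos, 1, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    oracle_permanova_F(d, gg)
  })
  expect_equal(res$p, mean(stats >= res$statistic - 1e-12))
  ad <- suppressWarnings(vegan::adonis2(as.dist(d) ~ g, permutations = 5))
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ad$R2[1], tolerance = 1e-10)
})

test_that("univariate PERMANOVA pseudo-F equals the classical ANOVA F", {
  set.seed(13)
  y <- rnorm(12)
  g <- rep(c("a", "b", "c"), times = c(5, 4, 3))  # unbalanced
  d <- as.matrix(dist(y))
  res <- permanova_test(d, g, n_perm = 19, seed = 2)
  f_anova <- summary(aov(y ~ factor(g)))[[1]][["F value"]][1]
  expect_equal(res$statistic, f_anova, tolerance = 1e-10)
})

test_that("identical groups of identical samples give r2 = 0", {
  m <- cbind(s1 = c(3, 1), s2 = c(3, 1), s3 = c(3, 1), s4 = c(3, 1))
  d <- suppressWarnings(bray_curtis(m))
  res <- permanova_test(d, c("a", "a", "b", "b"), n_perm = 9, seed = 1)
  expect_equal(res$r2, 0)
})

test_that("ANOSIM is rank-based, PERMANOVA is not, under monotone transforms", {
  set.seed(14)
  x <- matrix(rnorm(8 * 3), 8, 3)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 4)
  d_sq <- d^2  # monotone transform, still a valid dissimilarity
  expect_equal(anosim_test(d, g, n_perm = 9, seed = 1)$statistic,
               anosim_test(d_sq, g, n_perm = 9, seed = 1)$statistic)
  expect_false(isTRUE(all.equal(
    permanova_test(d, g, n_perm = 9, seed = 1)$statistic,
    permanova_test(d_sq, g, n_perm = 9, seed = 1)$statistic)))
})

test_that("grouping statistics ignore label names and sample order", {
  set.seed(15)
  x <- matrix(rnorm(8 * 3), 8, 3)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 4)
  perm <- sample(8)
  r1 <- anosim_test(d, g, n_perm = 49, seed = 3)
  r2 <- anosim_test(d[perm, perm], g[perm], n_perm = 49, seed = 3)
  expect_equal(r1$statistic, r2$statistic)
  g_renamed <- ifelse(g == "a", "chimney", "seawater")
  expect_equal(permanova_test(d, g, n_perm = 9, seed = 1)$r2,
               permanova_test(d, g_renamed, n_perm = 9, seed = 1)$r2)
})

test_that("Mantel r matches vegan; perfect and affine correlation give r = 1", {
  set.seed(16)
  x <- matrix(rnorm(6 * 3), 6, 3)
  d1 <- as.matrix(dist(x))
  # self-correlation: r = 1 and p at the attainable floor (identity is the
  # only distance-preserving permutation of generic points)
  res_self <- mantel_test(d1[1:5, 1:5], d1[1:5, 1:5], exhaustive = TRUE)
  expect_equal(res_self$r, 1)
  expect_equal(res_self$p, 1 / 120)
  d_aff <- 2.5 * d1 + 0.3
  diag(d_aff) <- 0
  expect_equal(mantel_test(d1, d_aff, n_perm = 9, seed = 1)$r, 1)
  d2 <- as.matrix(dist(matrix(rnorm(6 * 3), 6, 3)))
  res <- mantel_test(d1, d2, n_perm = 99, seed = 4)
  vm <- suppressWarnings(vegan::mantel(as.dist(d1), as.dist(d2), permutations = 5))
  expect_equal(res$r, unname(vm$statistic), tolerance = 1e-12)
  res_sp <- mantel_test(d1, d2, method = "spearman", n_perm = 99, seed = 4)
  vs <- suppressWarnings(vegan::mantel(as.dist(d1), as.dist(d2),
                                       method = "spearman",
                                       permutations = 5))
  expect_equal(res_sp$r, unname(vs$statistic), tolerance = 1e-12)
})

test_that("Mantel exhaustive p matches enumeration over all permutations", {
  set.seed(17)
  y <- matrix(rnorm(5 * 3), 5, 3)
  d1 <- as.matrix(dist(y))
  d2 <- as.matrix(dist(y + rnorm(15, 0, 0.4)))
  res <- mantel_test(d1, d2, exhaustive = TRUE)
  perms <- perms_of(1:5)
  lower <- lower.tri(d1)
  r_all <- apply(perms, 1, function(p) cor(d1[lower], d2[p, p][lower]))
  r_obs <- cor(d1[lower], d2[lower])
  expect_equal(res$r, r_obs)
  expect_equal(res$p, mean(r_all >= r_obs - 1e-12))
  expect_equal(res$n_perm, 120)
})

test_that("Mantel rejects degenerate input", {
  d_const <- matrix(1, 4, 4); diag(d_const) <- 0
  d_ok <- as.matrix(dist(rnorm(4)))
  expect_error(mantel_test(d_const, d_ok, n_perm = 9, seed = 1), "constant")
  expect_error(mantel_test(d_ok[1:3, 1:3], d_ok[1:3, 1:3],
                           n_perm = 9, seed = 1), "at least 4")
})

test_that("permutation p-values respect the add-one floor and the seed", {
  set.seed(18)
  x <- matrix(rnorm(8 * 3), 8, 3)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 4)
  for (fun in list(anosim_test, permanova_test)) {
    r1 <- fun(d, g, n_perm = 99, seed = 7)
    r2 <- fun(d, g, n_perm = 99, seed = 7)
    expect_identical(r1$p, r2$p)
    expect_gte(r1$p, 1 / 100)
    expect_error(fun(d, g, n_perm = 99), "seed")
    expect_error(fun(d, rep("a", 8), n_perm = 9, seed = 1), "2 groups")
  }
})

test_that("environmental distances standardize columns by default", {
  md <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                   brucite = c(80, 75, 10, 5),
                   Sr_ppm = c(1000, 900, 5000, 5200))
  d <- env_distance(md, c("brucite", "Sr_ppm"))
  expect_equal(rownames(d), md$sample_id)
  # standardization makes the two variables contribute comparably
  d_raw <- env_distance(md, c("brucite", "Sr_ppm"), standardize = FALSE)
  expect_gt(cor(as.dist(d), as.dist(d_raw)), 0.9)
  expect_false(isTRUE(all.equal(as.dist(d), as.dist(d_raw))))
})
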