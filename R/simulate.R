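## Synthetic-data generators with analytically known ground truth.  Every
## generator is a pure function of its parameters and seed, and returns the
## ground truth needed to predict downstream results without rerunning it.

# Fixed background residue composition (roughly natural protein frequencies
# over the 20 standard residues), used by the proteome generator.
background_composition <- function() {
  freq <- c(A = 8.3, R = 5.5, N = 4.0, D = 5.5, C = 1.4, E = 6.8, Q = 3.9,
            G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
            P = 4.7, S = 6.6, T = 5.3, W = 1.1, Y = 2.9, V = 6.9)
  freq / sum(freq)
}

#' Generate a synthetic predicted proteome with a programmed pool Z_C
#'
#' Emits one sample's predicted proteins plus per-gene abundances such that
#' the abundance-weighted pool Z_C of the proteome equals `target_zc`.
#' Residues are drawn from a mixture of a fixed background composition
#' (weight `background_fraction`) and a glycine/leucine tuning pair whose
#' mixing fraction is solved analytically from the carbon-weighted Z_C
#' balance; glycine (+1) and leucine (-1) span the residue Z_C range, so
#' with `background_fraction = 0` any target in `(-1, 1)` is achievable.
#' After the random draw, a small number of glycine/leucine swaps pins the
#' realized abundance-weighted pool Z_C to the target (within `tol`), so the
#' ground truth is exact rather than approximate.
#'
#' @param n_proteins Number of proteins (default 5000).
#' @param target_zc Programmed abundance-weighted pool Z_C.
#' @param sample_id Sample label.
#' @param length_mean,length_sd Protein length distribution (residues);
#'   lengths are truncated below at 30.
#' @param background_fraction Share of residues drawn from the fixed
#'   background composition (default 0.5; narrows the achievable Z_C hull,
#'   reported in the error message when the target is outside it).
#' @param abundance_sdlog Log-SD of the log-normal per-gene abundances.
#' @param seed Integer seed (required).
#' @param tol Absolute tolerance for the realized pool Z_C.
#' @return List with `proteins` (data.frame `protein_id`, `gene_id`,
#'   `sequence`), `abundances` (named vector), and `truth` (list:
#'   `sample_id`, `target_zc`, `pool_zc` as realized, `phi` the glycine
#'   fraction of the tuning component, `n_proteins`, `seed`).
#' @export
simulate_proteome <- function(n_proteins = 5000, target_zc = -0.168,
                              sample_id = "S1",
                              length_mean = 300, length_sd = 80,
                              background_fraction = 0.5,
                              abundance_sdlog = 1, seed, tol = 1e-6) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(n_proteins >= 1, background_fraction >= 0, background_fraction < 1)

  bg <- background_composition()
  rmat <- residue_matrix()
  rz <- residue_zc()
  cb <- sum(bg * rmat[names(bg), "c"])                  # carbon per bg residue
  nb <- sum(bg * rmat[names(bg), "c"] * rz[names(bg)])  # carbon-weighted Z_C
  m <- background_fraction
  t <- target_zc

  # carbon-weighted Z_C balance: solve the glycine fraction phi of the
  # G/L tuning component from  t = N(phi) / C(phi)
  phi <- (m * (t * cb - nb) + 6 * (1 - m) * (t + 1)) /
    (4 * (1 - m) * (t + 2))
  if (phi < 0 || phi > 1) {
    lo <- (m * nb - 6 * (1 - m)) / (m * cb + 6 * (1 - m))
    hi <- (m * nb + 2 * (1 - m)) / (m * cb + 2 * (1 - m))
    stop(sprintf(
      "target_zc = %.4f outside the achievable interval [%.4f, %.4f] at background_fraction = %.2f",
      t, lo, hi, m), call. = FALSE)
  }

  with_seed(seed, {
    len <- pmax(30L, as.integer(round(rnorm(n_proteins, length_mean,
                                            length_sd))))
    n_bg <- rbinom(n_proteins, len, m)
    n_tune <- len - n_bg
    n_gly <- rbinom(n_proteins, n_tune, phi)
    w <- rlnorm(n_proteins, meanlog = 0, sdlog = abundance_sdlog)
    w <- w / sum(w)

    # background residue counts per protein (20 columns)
    bg_counts <- matrix(0L, n_proteins, length(bg),
                        dimnames = list(NULL, names(bg)))
    for (i in which(n_bg > 0)) {
      draw <- sample.int(length(bg), n_bg[i], replace = TRUE, prob = bg)
      tab <- tabulate(draw, length(bg))
      bg_counts[i, ] <- tab
    }

    # per-protein carbon and carbon-weighted Z_C numerator
    ccol <- rmat[colnames(bg_counts), "c"]
    ncol_ <- ccol * rz[colnames(bg_counts)]
    c_i <- as.numeric(bg_counts %*% ccol) + 2 * n_gly + 6 * (n_tune - n_gly)
    num_i <- as.numeric(bg_counts %*% ncol_) + 2 * n_gly - 6 * (n_tune - n_gly)

    # pin the realized weighted pool Z_C to the target by G<->L swaps
    N <- sum(w * num_i)
    C <- sum(w * c_i)
    ord <- order(w)  # ascending weight: fine-grained steps last
    for (round_k in 1:80) {
      err <- N / C - t
      if (abs(err) < tol) break
      if (err > 0) {
        cand <- ord[n_gly[ord] > 0]       # G -> L lowers Z_C
        dN <- -8 * w[cand]; dC <- 4 * w[cand]; dir <- -1L
      } else {
        cand <- ord[(n_tune - n_gly)[ord] > 0]  # L -> G raises Z_C
        dN <- 8 * w[cand]; dC <- -4 * w[cand]; dir <- 1L
      }
      if (length(cand) == 0) break
      # first-order effect of each candidate swap on the pooled value;
      # take as many (ascending weight) as fit inside the current error
      eff <- (dN - t * dC) / C
      k <- max(1L, sum(abs(cumsum(eff)) <= abs(err)))
      take <- cand[seq_len(min(k, length(cand)))]
      n_gly[take] <- n_gly[take] + dir
      num_i[take] <- num_i[take] + 8 * dir
      c_i[take] <- c_i[take] - 4 * dir
      N <- sum(w * num_i)
      C <- sum(w * c_i)
    }
    if (abs(N / C - t) > tol)
      warning(sprintf(
        "realized pool Z_C %.6f differs from target %.6f by more than tol (proteome too small to pin exactly)",
        N / C, t), call. = FALSE)

    # realize sequences: shuffle of background + glycine + leucine residues
    codes <- colnames(bg_counts)
    sequences <- vapply(seq_len(n_proteins), function(i) {
      res <- c(rep(codes, bg_counts[i, ]),
               rep("G", n_gly[i]), rep("L", n_tune[i] - n_gly[i]))
      paste(res[sample.int(length(res))], collapse = "")
    }, character(1))

    ids <- sprintf("%s_gene_%05d", sample_id, seq_len(n_proteins))
    proteins <- data.frame(protein_id = ids, gene_id = ids,
                           sequence = sequences, stringsAsFactors = FALSE)
    abundances <- setNames(w, ids)
    truth <- list(sample_id = sample_id, target_zc = target_zc,
                  pool_zc = N / C, phi = phi, n_proteins = n_proteins,
                  background_fraction = m, seed = seed)
    list(proteins = proteins, abundances = abundances, truth = truth)
  })
}

#' Generate negative-binomial gene counts with group effects
#'
#' Gene-by-sample counts with a log-normal gene-level baseline and
#' negative-binomial sampling noise, plus optional multiplicative
#' fold-changes applied to a subset of genes in the non-reference groups —
#' the structure TMM normalization assumes (most genes unchanged).
#'
#' @param n_genes Number of genes.
#' @param samples Data.frame with `sample_id` and `group`.
#' @param mean_count Mean of the gene baseline (counts).
#' @param baseline_sdlog Log-SD of the gene baselines.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param fold_change Fold-change applied to affected genes in each
#'   non-reference group.
#' @param frac_affected Fraction of genes affected per non-reference group.
#' @param depth_range Per-sample library-depth multipliers are drawn
#'   uniformly from this range.
#' @param seed Integer seed (required).
#' @return List with `counts` (matrix) and `truth` (baselines, affected
#'   gene ids per group, depth factors).
#' @export
simulate_gene_counts <- function(n_genes = 2000, samples,
                                 mean_count = 50, baseline_sdlog = 1,
                                 dispersion = 0.2, fold_change = 4,
                                 frac_affected = 0.1,
                                 depth_range = c(0.5, 2), seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  groups <- factor(samples$group)
  with_seed(seed, {
    base <- rlnorm(n_genes, log(mean_count), baseline_sdlog)
    gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
    depth <- runif(nrow(samples), depth_range[1], depth_range[2])
    affected <- list()
    mu <- matrix(base, n_genes, nrow(samples))
    for (lev in levels(groups)[-1]) {
      idx <- sample.int(n_genes, round(frac_affected * n_genes))
      affected[[lev]] <- gene_ids[idx]
      mu[idx, groups == lev] <- mu[idx, groups == lev] * fold_change
    }
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n_genes, nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    list(counts = counts,
         truth = list(baseline = setNames(base, gene_ids),
                      affected = affected,
                      depth = setNames(depth, samples$sample_id),
                      dispersion = dispersion, fold_change = fold_change,
                      seed = seed))
  })
}

#' Default synthetic KEGG-style module set
#'
#' Four small modules over disjoint synthetic KO pools covering the grammar
#' features (linear steps, alternatives, complexes, optional components and
#' gap steps); the default module set of [simulate_annotations()].
#'
#' @return Data.frame with `module_id`, `name`, `definition`.
#' @export
synthetic_modules <- function() {
  data.frame(
    module_id = c("MS0001", "MS0002", "MS0003", "MS0004"),
    name = c("four-step linear", "alternatives", "complex subunits",
             "optional and gap"),
    definition = c(
      "K10001 K10002 K10003 K10004",
      "(K10011,K10012) K10013 (K10014,K10015) K10016",
      "K10021+K10022 K10023 K10024+K10025+K10026 K10027",
      "K10031 -K10039 K10032 -- K10033 K10034"),
    stringsAsFactors = FALSE)
}

#' Generate gene annotations realizing a programmed completion matrix
#'
#' Builds an annotation table whose per-lineage KO content realizes a
#' programmed per-lineage, per-module fraction of required steps exactly,
#' plus single-copy-gene panel genes (`scg12`, `scg40`, `rrna16s`) whose
#' lineage proportions are programmed through deterministic per-gene
#' abundances, and optional marker genes.
#'
#' @param completion_program Data.frame with `lineage`, `module_id`,
#'   `fraction`: the fraction of required steps of that module to realize
#'   for that lineage.  Each fraction must be an integer number of steps;
#'   otherwise an error suggests the nearest realizable fraction.
#' @param modules Module definitions: data.frame with `module_id`,
#'   `definition` (default [synthetic_modules()]).
#' @param lineage_proportions Named numeric vector (lineage -> relative
#'   abundance) used to assign deterministic abundances to panel genes;
#'   defaults to equal proportions over the programmed lineages.
#' @param sample_ids Samples for the emitted abundance matrix.
#' @param marker_program Optional data.frame with `lineage`, `ko`,
#'   `symbol`, `abundance` rows adding marker genes.
#' @return List with `annotations` (data.frame: `gene_id`, `ko`, `symbol`,
#'   `lineage`, `panels`), `abundance` (gene-by-sample matrix, deterministic),
#'   `modules`, and `truth` (the realized detection matrix and panel
#'   proportions).
#' @export
simulate_annotations <- function(completion_program,
                                 modules = synthetic_modules(),
                                 lineage_proportions = NULL,
                                 sample_ids = "S1",
                                 marker_program = NULL) {
  stopifnot(all(c("lineage", "module_id", "fraction")
                %in% names(completion_program)))
  parsed <- lapply(seq_len(nrow(modules)), function(i)
    parse_module(modules$definition[i], modules$module_id[i]))
  names(parsed) <- modules$module_id

  lineages <- unique(completion_program$lineage)
  if (is.null(lineage_proportions))
    lineage_proportions <- setNames(rep(1 / length(lineages),
                                        length(lineages)), lineages)
  # program names are phylum-level labels; emit full ranked lineage strings
  full_lineage <- function(lin)
    ifelse(grepl(";", lin, fixed = TRUE), lin, paste0("Bacteria;", lin))

  rows <- list()
  add_row <- function(gene_id, ko, symbol, lineage, panels, abundance)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene_id, ko = ko, symbol = symbol, lineage = lineage,
      panels = panels, abundance = abundance, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(completion_program))) {
    lin <- completion_program$lineage[i]
    mid <- completion_program$module_id[i]
    frac <- completion_program$fraction[i]
    m <- parsed[[mid]]
    if (is.null(m)) stop(sprintf("unknown module '%s'", mid), call. = FALSE)
    k_exact <- frac * m$step_count
    k <- round(k_exact)
    if (abs(k_exact - k) > 1e-9)
      stop(sprintf(
        "fraction %.4f not realizable for %s (%d steps); nearest realizable: %.4f or %.4f",
        frac, mid, m$step_count, floor(k_exact) / m$step_count,
        ceiling(k_exact) / m$step_count), call. = FALSE)
    steps <- m$expression$children
    required <- steps[!vapply(steps, function(s)
      s$kind == "gap" || isTRUE(s$optional), logical(1))]
    if (k > 0) {
      kos <- unique(unlist(lapply(required[seq_len(k)], node_minimal_kos)))
      for (j in seq_along(kos))
        add_row(sprintf("%s_%s_step%02d", gsub("\\W", "", lin), mid, j),
                kos[j], NA_character_, full_lineage(lin), "", 1)
    }
  }

  # panel genes with deterministic per-gene abundance equal to the lineage
  # proportion, so panel-restricted relative abundances recover the
  # programmed proportions exactly
  for (lin in lineages) {
    prop <- lineage_proportions[[lin]]
    slug <- gsub("\\W", "", lin)
    for (j in 1:40) {
      panels <- if (j <= 12) "scg12,scg40" else "scg40"
      add_row(sprintf("%s_scg_%02d", slug, j), "", NA_character_,
              full_lineage(lin), panels, prop)
    }
    add_row(sprintf("%s_16s", slug), "", NA_character_, full_lineage(lin),
            "rrna16s", prop)
  }

  if (!is.null(marker_program)) {
    for (i in seq_len(nrow(marker_program)))
      add_row(sprintf("marker_%s_%03d",
                      gsub("\\W", "", marker_program$lineage[i]), i),
              marker_program$ko[i], marker_program$symbol[i],
              full_lineage(marker_program$lineage[i]), "",
              marker_program$abundance[i])
  }

  ann <- do.call(rbind, rows)
  abundance <- matrix(ann$abundance, nrow(ann), length(sample_ids),
                      dimnames = list(ann$gene_id, sample_ids))
  ann$abundance <- NULL

  expected <- completion_program
  expected$detected <- vapply(seq_len(nrow(expected)), function(i) {
    expected$fraction[i] > 0.5
  }, logical(1))

  list(annotations = ann, abundance = abundance, modules = modules,
       truth = list(detection = expected,
                    lineage_proportions = 100 * lineage_proportions /
                      sum(lineage_proportions)))
}

#' Generate an ASV table with programmed between-group separation
#'
#' Dirichlet-multinomial community counts: a log-normal base composition,
#' a multiplicative effect of programmed magnitude on a subset of ASVs in
#' each non-reference group, per-sample Dirichlet draws (overdispersion
#' controlled by `concentration`) and multinomial sampling at the given
#' depth.  Optionally spikes contaminant ASVs at fixed counts for testing
#' the contaminant filter.
#'
#' @param n_asv Number of community ASVs.
#' @param samples Data.frame with `sample_id` and `group` (>= 2 samples per
#'   group when an effect is programmed).
#' @param depth Reads per sample.
#' @param concentration Dirichlet concentration (larger = less
#'   sample-to-sample overdispersion).
#' @param effect_size Multiplicative effect on affected ASVs
#'   (1 = no group structure).
#' @param frac_affected Fraction of ASVs affected per non-reference group.
#' @param contaminants Optional data.frame with `genus` and `count`:
#'   one spiked ASV per row, at that exact count in every sample.
#' @param seed Integer seed (required).
#' @return List with `counts` (ASV-by-sample matrix), `taxonomy` (named
#'   genus vector), `metadata` (sample_id, group, two numeric environment
#'   covariates separated along the group structure), and `truth`.
#' @export
simulate_asv_table <- function(n_asv = 150, samples, depth = 20000,
                               concentration = 200, effect_size = 1,
                               frac_affected = 0.2, contaminants = NULL,
                               seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  groups <- factor(samples$group)
  if (effect_size != 1 && any(table(groups) < 2))
    stop("need >= 2 samples per group when a group effect is programmed",
         call. = FALSE)
  with_seed(seed, {
    base <- rlnorm(n_asv, 0, 1)
    base <- base / sum(base)
    asv_ids <- sprintf("ASV_%04d", seq_len(n_asv))
    comp <- matrix(base, n_asv, nlevels(groups),
                   dimnames = list(asv_ids, levels(groups)))
    affected <- list()
    free <- seq_len(n_asv)
    for (lev in levels(groups)[-1]) {
      idx <- sample(free, min(length(free), round(frac_affected * n_asv)))
      free <- setdiff(free, idx)
      affected[[lev]] <- asv_ids[idx]
      comp[idx, lev] <- comp[idx, lev] * effect_size
      comp[, lev] <- comp[, lev] / sum(comp[, lev])
    }
    counts <- sapply(seq_len(nrow(samples)), function(j) {
      alpha <- concentration * comp[, as.character(groups[j])]
      p <- rgamma(n_asv, shape = alpha, rate = 1)
      p <- p / sum(p)
      rmultinom(1, depth, p)[, 1]
    })
    dimnames(counts) <- list(asv_ids, samples$sample_id)

    genera <- sprintf("Genus%03d", seq_len(n_asv))
    taxonomy <- setNames(genera, asv_ids)
    if (!is.null(contaminants) && nrow(contaminants) > 0) {
      spike_ids <- sprintf("ASV_C%03d", seq_len(nrow(contaminants)))
      spike <- matrix(rep(contaminants$count, ncol(counts)),
                      nrow(contaminants), ncol(counts),
                      dimnames = list(spike_ids, colnames(counts)))
      counts <- rbind(counts, spike)
      taxonomy <- c(taxonomy, setNames(contaminants$genus, spike_ids))
    }

    gi <- as.integer(groups)
    metadata <- data.frame(sample_id = samples$sample_id,
                           group = samples$group,
                           env1 = gi + rnorm(nrow(samples), 0, 0.2),
                           env2 = rnorm(nrow(samples)),
                           stringsAsFactors = FALSE)
    list(counts = counts, taxonomy = taxonomy, metadata = metadata,
         truth = list(base = setNames(base, asv_ids), affected = affected,
                      effect_size = effect_size,
                      concentration = concentration, depth = depth,
                      contaminants = contaminants, seed = seed))
  })
}
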