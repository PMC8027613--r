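## Marker-gene and hydrogenase abundance profiles, lineage-level KEGG-module
## completion matrices, and lineage relative abundance from gene panels.

split_csv_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

# normalized gene x sample abundance matrix from either a matrix or a
# normalized_counts object
as_abundance_matrix <- function(counts) {
  if (inherits(counts, "normalized_counts")) counts$normalized
  else check_count_matrix(counts)
}

STANDARD_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                    "species")

#' Extract one taxonomic rank from lineage strings
#'
#' Lineages are semicolon-separated, ordered coarse to fine
#' (`domain;phylum;class;order;family;genus[;species]`).  Empty or missing
#' ranks map to `"unclassified"`.
#'
#' @param lineage Character vector of lineage strings.
#' @param rank One of `"domain"`, `"phylum"`, ..., `"species"`.
#' @return Character vector of rank names.
#' @export
lineage_at_rank <- function(lineage, rank = "phylum") {
  rank <- match.arg(rank, STANDARD_RANKS)
  idx <- match(rank, STANDARD_RANKS)
  parts <- strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE)
  out <- vapply(parts, function(p) {
    if (length(p) >= idx) trimws(p[idx]) else ""
  }, character(1))
  out[!nzchar(out)] <- "unclassified"
  out
}

# matcher: genes hitting any of the row's KO ids, or failing that any of its
# gene symbols; each gene counted once.
match_genes <- function(annotations, kos, symbols) {
  gene_kos <- split_csv_field(annotations$ko)
  hit_ko <- if (length(kos))
    vapply(gene_kos, function(k) any(k %in% kos), logical(1))
  else rep(FALSE, nrow(annotations))
  hit_sym <- if (length(symbols))
    !is.na(annotations$symbol) & annotations$symbol %in% symbols
  else rep(FALSE, nrow(annotations))
  annotations$gene_id[hit_ko | hit_sym]
}

profile_matrix <- function(annotations, counts, map, name_col) {
  counts <- as_abundance_matrix(counts)
  stopifnot(is.data.frame(annotations),
            all(c("gene_id", "ko") %in% names(annotations)))
  if (anyDuplicated(map[[name_col]]))
    stop(sprintf("duplicate %s in map", name_col), call. = FALSE)
  out <- matrix(0, nrow = nrow(map), ncol = ncol(counts),
                dimnames = list(map[[name_col]], colnames(counts)))
  kos_list <- split_csv_field(map$ko_ids)
  sym_list <- split_csv_field(map$gene_symbols)
  for (i in seq_len(nrow(map))) {
    if (length(kos_list[[i]]) == 0 && length(sym_list[[i]]) == 0)
      stop(sprintf("map row '%s' has no matcher", map[[name_col]][i]),
           call. = FALSE)
    genes <- match_genes(annotations, kos_list[[i]], sym_list[[i]])
    genes <- intersect(genes, rownames(counts))
    if (length(genes))
      out[i, ] <- colSums(counts[genes, , drop = FALSE])
  }
  out
}

#' Marker-gene abundance matrix
#'
#' Sums normalized gene abundances over a map of metabolic marker genes
#' (methanogenesis, methanotrophy, CO and formate metabolism, sulfur,
#' nitrogen and oxygen respiration, carbon fixation ...).  Genes are matched
#' by KO id first, with gene symbol as fallback, and counted once even when
#' both match.  Markers without any matching gene are kept as explicit
#' all-zero rows: the absence of e.g. a methanogenesis marker from every
#' sample is itself a result.
#'
#' @param annotations Annotation data.frame with columns `gene_id`, `ko`
#'   (comma-separated KO ids), `symbol`.
#' @param counts Normalized gene-by-sample matrix or a
#'   `normalized_counts` object.
#' @param map Marker map: data.frame with `marker_name`, `ko_ids`,
#'   `gene_symbols`, `category` (each marker in exactly one category).
#'   Defaults to the map shipped with the package, which is a reconstruction
#'   from published results and is meant to be user-edited.
#' @return Numeric marker-by-sample matrix.
#' @export
marker_abundance <- function(annotations, counts, map = default_marker_map()) {
  stopifnot(all(c("marker_name", "ko_ids", "gene_symbols", "category")
                %in% names(map)))
  if (anyDuplicated(map$marker_name))
    stop("a marker maps to more than one category", call. = FALSE)
  profile_matrix(annotations, counts, map, "marker_name")
}

#' Hydrogenase group abundance matrix
#'
#' Like [marker_abundance()], for [FeFe]- and [NiFe]-hydrogenase groups and
#' subgroups (A, A3, B, C; 1, 2, 3a, 3b, 3d, 4).
#'
#' @inheritParams marker_abundance
#' @param map Data.frame with `group_label`, `ko_ids`, `gene_symbols`.
#' @return Numeric group-by-sample matrix with the full group index, all-zero
#'   rows included.
#' @export
hydrogenase_profile <- function(annotations, counts,
                                map = default_hydrogenase_map()) {
  stopifnot(all(c("group_label", "ko_ids", "gene_symbols") %in% names(map)))
  profile_matrix(annotations, counts, map, "group_label")
}

#' @rdname marker_abundance
#' @export
default_marker_map <- function() {
  utils::read.delim(system.file("extdata", "marker_genes.tsv",
                                package = "ventredox", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname hydrogenase_profile
#' @export
default_hydrogenase_map <- function() {
  utils::read.delim(system.file("extdata", "hydrogenase_groups.tsv",
                                package = "ventredox", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Per-lineage module completion matrix
#'
#' Pools the KO annotations of each lineage's genes at the chosen rank and
#' scores every KEGG module with [module_completeness()], producing the
#' pathway-completion detection matrix (fraction of required steps present,
#' and the detected flag under the more-than-half rule).
#'
#' @param annotations Annotation data.frame with `gene_id`, `ko`, `lineage`.
#' @param modules List of `module_definition` objects, or a data.frame with
#'   columns `module_id` and `definition`.
#' @param rank Taxonomic rank at which to pool genes.
#' @return Data.frame: `lineage`, `module_id`, `fraction_present`,
#'   `detected`.
#' @export
lineage_completion_matrix <- function(annotations, modules, rank = "phylum") {
  if (is.data.frame(modules))
    modules <- lapply(seq_len(nrow(modules)), function(i)
      parse_module(modules$definition[i], modules$module_id[i]))
  lin <- lineage_at_rank(annotations$lineage, rank)
  kos_by_lin <- tapply(annotations$ko, lin, function(k)
    unique(unlist(split_csv_field(k))), simplify = FALSE)
  rows <- lapply(names(kos_by_lin), function(l) {
    kos <- kos_by_lin[[l]]
    if (is.null(kos)) kos <- character(0)
    do.call(rbind, lapply(modules, function(m) {
      res <- module_completeness(m, kos)
      data.frame(lineage = l, module_id = res$module_id,
                 fraction_present = res$fraction_present,
                 detected = res$detected, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Lineage relative abundance per sample
#'
#' Sums normalized gene abundance by lineage within each sample and reports
#' percentages.  The gene set can be all genes, one of the single-copy gene
#' panels (12- or 40-gene, supplied as panel flags in the annotation table),
#' or reconstructed 16S rRNA genes; single-copy panels turn gene-level
#' abundance into organism-level relative abundance.  Genes without a
#' lineage at the chosen rank are bucketed as `"unclassified"`.
#'
#' @param annotations Annotation data.frame with `gene_id`, `lineage` and,
#'   for panel modes, a `panels` column of comma-separated flags
#'   (`scg12`, `scg40`, `rrna16s`).
#' @param counts Normalized gene-by-sample matrix or `normalized_counts`.
#' @param mode `"all_genes"`, `"scg12"`, `"scg40"` or `"rrna16s"`.
#' @param rank Taxonomic rank.
#' @return Lineage-by-sample matrix of percentages; every column sums
#'   to 100.
#' @export
lineage_abundance <- function(annotations, counts,
                              mode = c("all_genes", "scg12", "scg40",
                                       "rrna16s"),
                              rank = "phylum") {
  mode <- match.arg(mode)
  counts <- as_abundance_matrix(counts)
  ann <- annotations
  if (mode != "all_genes") {
    if (!"panels" %in% names(ann))
      stop("annotation table has no 'panels' column", call. = FALSE)
    flags <- split_csv_field(ann$panels)
    ann <- ann[vapply(flags, function(f) mode %in% f, logical(1)), ,
               drop = FALSE]
  }
  ann <- ann[ann$gene_id %in% rownames(counts), , drop = FALSE]
  if (nrow(ann) == 0)
    stop(sprintf("no genes in panel '%s'", mode), call. = FALSE)
  lin <- lineage_at_rank(ann$lineage, rank)
  sub <- counts[ann$gene_id, , drop = FALSE]
  agg <- rowsum(sub, group = lin)
  totals <- colSums(agg)
  if (any(totals <= 0))
    stop(sprintf("sample(s) with zero abundance in panel '%s': %s", mode,
                 paste(colnames(agg)[totals <= 0], collapse = ", ")),
         call. = FALSE)
  sweep(agg, 2, totals, "/") * 100
}
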