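## Shared readers and writers.  Everything tabular is TSV: UTF-8, header
## row mandatory, '.' decimal separator, first column = feature id — the
## dialect of the upstream counting and annotation tools this package
## consumes.

#' Read predicted protein sequences from FASTA
#'
#' The header token up to the first whitespace is the protein id (and the
#' default gene id).  Wrapped and unwrapped FASTA are both accepted,
#' sequences are upper-cased, and a trailing stop codon `*` is stripped.
#' Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @param gene_map Optional named character vector mapping protein ids to
#'   gene ids.
#' @return Data.frame with `protein_id`, `gene_id`, `sequence`, in input
#'   order.
#' @export
read_protein_fasta <- function(path, gene_map = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop(sprintf("empty FASTA file: %s", path),
                              call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  sequence <- sub("\\*+$", "", toupper(as.character(seqs)))
  gene_id <- if (is.null(gene_map)) ids else {
    mapped <- gene_map[ids]
    ifelse(is.na(mapped), ids, mapped)
  }
  data.frame(protein_id = ids, gene_id = unname(gene_id),
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Data.frame with `protein_id` and `sequence`.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @export
write_protein_fasta <- function(proteins, path, width = 60) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i]), con)
    seq <- proteins$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1, nchar(seq))),
               con)
  }
  invisible(path)
}

#' Read a feature-by-sample count table from TSV
#'
#' First column feature ids, header row of sample ids.  Negative or
#' non-numeric cells are rejected with their line number.
#'
#' @param path TSV file (Windows line endings tolerated).
#' @param check_nonnegative Reject negative cells.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_count_table <- function(path, check_nonnegative = TRUE) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs an id column and >= 1 sample",
                          call. = FALSE)
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at line %d, column '%s' of %s",
                   bad[1] + 1L, names(vals)[j], path), call. = FALSE)
    if (check_nonnegative && any(v < 0, na.rm = TRUE))
      stop(sprintf("negative count at line %d, column '%s' of %s",
                   which(v < 0)[1] + 1L, names(vals)[j], path), call. = FALSE)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample table to TSV
#'
#' Values are serialized with full double precision so a write/read
#' round-trip is an identity on values.
#'
#' @param x Numeric matrix with rownames.
#' @param path Output file.
#' @param id_column Name of the id column (default "feature_id").
#' @export
write_count_table <- function(x, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(x),
                   apply(x, 2, function(col) sprintf("%.15g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table from TSV
#'
#' Expected columns: `gene_id`, `ko` (comma-separated KO ids), `symbol`,
#' `lineage` (semicolon-separated ranks, coarse to fine), `panels`
#' (comma-separated flags among `scg12`, `scg40`, `rrna16s`).  Missing
#' optional columns are filled with empty values.
#'
#' @param path TSV file.
#' @return Data.frame with the five columns above.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  if (!"gene_id" %in% names(ann))
    stop("annotation table needs a 'gene_id' column", call. = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation table", call. = FALSE)
  for (col in c("ko", "symbol", "lineage", "panels"))
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  ann$ko[is.na(ann$ko)] <- ""
  ann$panels[is.na(ann$panels)] <- ""
  ann[, c("gene_id", "ko", "symbol", "lineage", "panels")]
}

#' Read sample metadata from TSV
#'
#' @param path TSV with at least `sample_id` and `group` columns; free
#'   numeric columns (mineralogy, element concentrations ...) are kept for
#'   [env_distance()].
#' @return Data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"sample_id" %in% names(md))
    stop("metadata needs a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  md
}

#' Read KEGG module definitions from TSV
#'
#' @param path TSV with columns `module_id`, `name` (optional),
#'   `definition`.
#' @return Data.frame.
#' @export
read_module_definitions <- function(path) {
  mods <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("module_id", "definition") %in% names(mods)))
    stop("module table needs 'module_id' and 'definition' columns",
         call. = FALSE)
  mods
}

#' Write a run manifest
#'
#' Records the package version, R version, configuration (including every
#' seed), and md5 checksums of the input files, as YAML.  Two runs with the
#' same configuration and inputs produce identical manifests except for the
#' timestamp.
#'
#' @param config Named list of run parameters; every stochastic step's seed
#'   must appear here.
#' @param inputs Character vector of input file paths (must exist).
#' @param path Output YAML file.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(config, inputs, path) {
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop(sprintf("missing input file(s): %s",
                 paste(missing_in, collapse = ", ")), call. = FALSE)
  manifest <- list(
    tool = "ventredox",
    version = as.character(utils::packageVersion("ventredox")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = unname(tools::md5sum(
      local({
        tmp <- tempfile()
        yaml::write_yaml(config, tmp)
        tmp
      }))),
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
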