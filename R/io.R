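#' Write / read the canonical TSV dialect
#'
#' Tab-separated, header row, `.` decimal, no quoting, no row names —
#' chosen so outputs diff bit-exactly between runs.
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a matrix as TSV with an id column
#'
#' @param m matrix with row names.
#' @param path file path.
#' @param id_col name for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read gene sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read a plain-text gene list (one id per line)
#'
#' @param genes character vector.
#' @param path file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Write / read a label grid as a plain-text integer matrix
#'
#' Space-separated rows of integer labels, no header.
#'
#' @param grid integer matrix.
#' @param path file path.
#' @export
write_label_grid <- function(grid, path) {
  utils::write.table(grid, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_label_grid
#' @export
read_label_grid <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write an hclust merge tree as Newick
#'
#' @param hc an [stats::hclust] object.
#' @param path file path.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}

#' Read transcript regions from three per-region FASTA files
#'
#' @param utr5_path,cds_path,utr3_path FASTA paths; headers are gene ids
#'   and must agree across files.
#' @return data.frame with columns `gene_id`, `utr5`, `cds`, `utr3`.
#' @export
read_transcript_regions <- function(utr5_path, cds_path, utr3_path) {
  u5 <- read_fasta(utr5_path)
  cds <- read_fasta(cds_path)
  u3 <- read_fasta(utr3_path)
  genes <- names(cds)
  if (!setequal(genes, names(u5)) || !setequal(genes, names(u3)))
    stop("region FASTA files do not cover the same genes")
  data.frame(gene_id = genes, utr5 = unname(u5[genes]),
             cds = unname(cds[genes]), utr3 = unname(u3[genes]),
             stringsAsFactors = FALSE)
}

#' Read a two-colour intensity table and array metadata into an experiment
#'
#' The intensity TSV has a `probe` column then `<array>_red_fg` /
#' `<array>_green_fg` column pairs; the metadata TSV has columns
#' `array_id`, `sample_id`, `group`, `replicate`, `dye_swap`.
#'
#' @param intensity_path,metadata_path TSV paths.
#' @return an [array_experiment()].
#' @export
read_array_experiment <- function(intensity_path, metadata_path) {
  tab <- read_tsv(intensity_path)
  md <- read_tsv(metadata_path)
  md$dye_swap <- as.logical(md$dye_swap)
  red <- as.matrix(tab[, paste0(md$array_id, "_red_fg"), drop = FALSE])
  green <- as.matrix(tab[, paste0(md$array_id, "_green_fg"), drop = FALSE])
  array_experiment(tab$probe, red, green, md)
}

#' Write an array experiment as intensity + metadata TSVs
#'
#' @param exp an [array_experiment()].
#' @param intensity_path,metadata_path output TSV paths.
#' @export
write_array_experiment <- function(exp, intensity_path, metadata_path) {
  md <- exp$metadata
  tab <- data.frame(probe = exp$probe_id, stringsAsFactors = FALSE)
  for (a in seq_len(nrow(md))) {
    tab[[paste0(md$array_id[a], "_red_fg")]] <- exp$red_fg[, a]
    tab[[paste0(md$array_id[a], "_green_fg")]] <- exp$green_fg[, a]
  }
  write_tsv(tab, intensity_path)
  write_tsv(md, metadata_path)
  invisible(intensity_path)
}
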