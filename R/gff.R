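#' Read gene coordinates from a GFF3 file
#'
#' Extracts features of one type (default `"gene"`) from a GFF3 file and
#' returns them as an ordered gene table for one species. Genes are grouped
#' by contig and sorted by `(start, end, gene_id)`; 0-based ranks within each
#' contig record the gene order used to call adjacencies. GFF3 coordinates
#' are 1-based inclusive and kept as such. Overlapping genes are retained.
#'
#' @param path path to a GFF3 file (uncompressed or gzip), or a character
#'   string containing GFF3 text (detected by embedded newlines).
#' @param species species (leaf) label the file belongs to.
#' @param feature_type GFF3 `type` column value to select (default "gene").
#' @param id_attr attribute holding the gene identifier (default "ID").
#' @return data.frame with columns `gene_id`, `species`, `contig`, `start`,
#'   `end`, `strand`, `rank`.
#' @export
read_gff <- function(path, species, feature_type = "gene", id_attr = "ID") {
  if (length(path) == 1L && grepl("\n", path)) {
    tf <- tempfile(fileext = ".gff3")
    writeLines(path, tf)
    on.exit(unlink(tf), add = TRUE)
    path <- tf
  }
  g <- rtracklayer::readGFF(path, filter = list(type = feature_type))
  g <- as.data.frame(g)
  if (nrow(g) == 0L) {
    stop_input(sprintf("%s: no '%s' features in GFF3", species, feature_type))
  }
  if (!id_attr %in% names(g)) {
    stop_input(sprintf("%s: attribute '%s' absent from all '%s' features",
                       species, id_attr, feature_type))
  }
  ids <- as.character(g[[id_attr]])
  bad <- is.na(ids) | ids == ""
  if (any(bad)) {
    warning(sprintf("%s: dropping %d '%s' feature(s) without '%s' attribute",
                    species, sum(bad), feature_type, id_attr))
    g <- g[!bad, , drop = FALSE]; ids <- ids[!bad]
  }
  if (nrow(g) == 0L) {
    stop_input(sprintf("%s: no usable '%s' features in GFF3", species, feature_type))
  }
  if (anyDuplicated(ids)) {
    stop_input(sprintf("%s: duplicated gene ids in GFF3: %s", species,
                       paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", ")))
  }
  out <- data.frame(
    gene_id = ids, species = species,
    contig = as.character(g$seqid),
    start = as.integer(g$start), end = as.integer(g$end),
    strand = as.character(g$strand), stringsAsFactors = FALSE
  )
  out$strand[!out$strand %in% c("+", "-")] <- "."
  o <- order(out$contig, out$start, out$end, out$gene_id, method = "radix")
  out <- out[o, , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$contig, FUN = seq_along) - 1L
  rownames(out) <- NULL
  out
}

#' Write a gene table as GFF3
#'
#' Inverse of [read_gff()] for simulator output and round-trip tests. Gene
#' coordinates are synthesized from ranks when absent:
#' gene at rank i sits at `[1000*i + 1, 1000*i + 500]`.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `strand`, `rank`
#'   (and optionally `start`/`end`).
#' @param path output file path.
#' @param source value for the GFF3 source column.
#' @export
write_gff <- function(genes, path, source = "ancora") {
  if (is.null(genes$start)) {
    genes$start <- 1000L * genes$rank + 1L
    genes$end <- 1000L * genes$rank + 500L
  }
  o <- order(genes$contig, genes$rank, method = "radix")
  genes <- genes[o, , drop = FALSE]
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$contig, source, genes$start, genes$end,
                   ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
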