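# Readers and writers for the package's external formats. GFF3 and BED go
# through rtracklayer when available; TSVs through data.table.

#' Write a simulated genome bundle to disk
#'
#' Emits `genome.fasta`, `genes.gff3`, `tes.gff3`, `syntelogs.tsv` and
#' `manifest.json` into `dir`. GFF3 is 1-based closed with `ID=` attributes.
#'
#' @param sim a `subdom_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "subdom_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$sequences, file.path(dir, "genome.fasta"))
  write_gff3(data.frame(chrom = sim$genes$chrom, source = "subdom",
                        type = "gene", start = sim$genes$start,
                        end = sim$genes$end, strand = sim$genes$strand,
                        id = sim$genes$gene_id, stringsAsFactors = FALSE),
             file.path(dir, "genes.gff3"))
  write_gff3(data.frame(chrom = sim$tes$chrom, source = "subdom",
                        type = "transposable_element", start = sim$tes$start,
                        end = sim$tes$end, strand = sim$tes$strand,
                        id = sim$tes$te_id, family = sim$tes$family,
                        stringsAsFactors = FALSE),
             file.path(dir, "tes.gff3"))
  data.table::fwrite(syntelog_table(sim), file.path(dir, "syntelogs.tsv"),
                     sep = "\t", na = "NA")
  write_manifest(sim$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

## minimal deterministic GFF3 writer (attributes: ID plus optional family)
write_gff3 <- function(df, path) {
  attrs <- paste0("ID=", df$id)
  if (!is.null(df$family)) attrs <- paste0(attrs, ";family=", df$family)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   df$chrom, df$source, df$type, as.integer(df$start),
                   as.integer(df$end), df$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a gene or TE annotation from GFF3
#'
#' Uses rtracklayer when installed, otherwise a plain-text fallback limited
#' to the columns this package needs.
#'
#' @param path GFF3 file.
#' @return data.frame `chrom`, `start`, `end`, `strand`, `id`, `family`
#'   (NA when absent).
#' @export
read_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               id = as.character(md$ID),
               family = if ("family" %in% names(md)) as.character(md$family)
                        else NA_character_,
               stringsAsFactors = FALSE)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = FALSE, skip = "##",
                            col.names = c("chrom", "source", "type", "start",
                                          "end", "score", "strand", "phase",
                                          "attr"))
    id <- sub("ID=", "", regmatches(dt$attr, regexpr("ID=[^;]+", dt$attr)))
    fam <- rep(NA_character_, nrow(dt))
    hasfam <- grepl("family=", dt$attr)
    fam[hasfam] <- sub(".*family=([^;]+).*", "\\1", dt$attr[hasfam])
    data.frame(chrom = dt$chrom, start = dt$start, end = dt$end,
               strand = dt$strand, id = id, family = fam,
               stringsAsFactors = FALSE)
  }
}

#' Read / write a dense whitespace-delimited contact matrix
#'
#' @param path text file of whitespace-separated numbers, one matrix row per
#'   line.
#' @return numeric matrix.
#' @export
read_contact_matrix <- function(path) {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stopf("contact matrix is not square: %dx%d", nrow(m), ncol(m))
  m
}

#' @rdname read_contact_matrix
#' @param m matrix to write.
#' @export
write_contact_matrix <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path, sep = " ",
                     col.names = FALSE)
  invisible(path)
}

#' Write methylation calls as an allc-style TSV
#'
#' Columns: `chrom`, `pos0` (0-based), `strand`, `context`, `mc_reads`,
#' `total_reads`.
#'
#' @param calls calls data.frame with 1-based `pos` (internal convention).
#' @param path output TSV.
#' @export
write_methylation_tsv <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, pos0 = calls$pos - 1L,
                    strand = calls$strand, context = calls$context,
                    mc_reads = calls$mc_reads, total_reads = calls$total_reads)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  data.frame(chrom = dt$chrom, pos = dt$pos0 + 1L, strand = dt$strand,
             context = dt$context, mc_reads = dt$mc_reads,
             total_reads = dt$total_reads, stringsAsFactors = FALSE)
}

#' Write TAD intervals as BED (0-based half-open)
#'
#' @param tads data.frame `tad_id`, `chrom`, `start`, `end` (1-based closed).
#' @param path output BED file.
#' @export
write_tads_bed <- function(tads, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", tads$chrom, as.integer(tads$start) - 1L,
                     as.integer(tads$end), tads$tad_id), path)
  invisible(path)
}

#' @rdname write_tads_bed
#' @export
read_tads_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start0", "end", "tad_id"))
  data.frame(tad_id = dt$tad_id, chrom = dt$chrom, start = dt$start0 + 1L,
             end = dt$end, stringsAsFactors = FALSE)
}
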