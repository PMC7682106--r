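#' Read a GFF3 annotation into a feature table
#'
#' Coordinates stay 1-based inclusive (the internal convention); a feature
#' with `end < start` or missing strand is rejected.
#'
#' @param path GFF3 file.
#' @return data.frame (`id`, `type`, `start`, `end`, `strand`).
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("malformed GFF3 '%s': %s",
                                           path, conditionMessage(e)))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stopf("feature without strand in '%s'", path)
  id <- S4Vectors::mcols(gr)$ID
  if (is.null(id)) id <- S4Vectors::mcols(gr)$Name
  if (is.null(id) || anyNA(id)) stopf("features need an ID attribute")
  ann <- data.frame(id = as.character(id),
                    type = as.character(S4Vectors::mcols(gr)$type),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = strand)
  if (any(ann$end < ann$start)) stopf("feature with end < start")
  ann
}

#' Write a feature table as GFF3
#'
#' @param annotation data.frame (`id`, `type`, `start`, `end`, `strand`).
#' @param path output file.
#' @param seqname contig name.
#' @export
write_annotation <- function(annotation, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$type,
    ID = annotation$id,
    phase = ifelse(annotation$type == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a bedGraph track into a dense per-position vector
#'
#' bedGraph intervals are 0-based half-open; the returned vector is 1-based
#' per-position. Overlapping intervals are summed.
#'
#' @param path bedGraph file.
#' @param genome_length length of the returned vector.
#' @param allow_negative permit negative values (off for count tracks).
#' @return numeric vector of length `genome_length`.
#' @export
read_bedgraph <- function(path, genome_length, allow_negative = FALSE) {
  vec <- numeric(genome_length)
  if (file.size(path) == 0) return(vec)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stopf("malformed bedGraph '%s': %s",
                                           path, conditionMessage(e)))
  score <- S4Vectors::mcols(gr)$score
  if (!allow_negative && any(score < 0)) {
    stopf("negative values in count track '%s'", path)
  }
  s <- GenomicRanges::start(gr)  # already 1-based after import
  e <- pmin(GenomicRanges::end(gr), genome_length)
  for (i in seq_along(gr)) {
    if (s[i] <= genome_length) {
      vec[s[i]:e[i]] <- vec[s[i]:e[i]] + score[i]
    }
  }
  vec
}

#' Write a per-position vector as bedGraph
#'
#' Zero runs are omitted; output intervals are 0-based half-open.
#'
#' @param track numeric per-position vector (1-based).
#' @param path output file.
#' @param seqname contig name.
#' @export
write_bedgraph <- function(track, path, seqname = "chr") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  df <- data.frame(chrom = seqname, start = starts[keep] - 1L,
                   end = ends[keep], value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read the universal TSV exchange format
#'
#' UTF-8, tab-separated, `.` decimal separator, `NA` for missing.
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write a genome sequence as FASTA
#'
#' @param genome [Biostrings::DNAString].
#' @param path file path.
#' @param name sequence name.
#' @export
write_genome <- function(genome, path, name = "chr") {
  set <- Biostrings::DNAStringSet(genome)
  names(set) <- name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  set[[1]]
}
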