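#' Read a strand-specific signal track
#'
#' Reads a per-base 3'-end signal track (bedGraph or bigWig) and returns
#' per-chromosome run-length-encoded coverage. Scores on minus-strand
#' tracks are often stored negative by convention; absolute values are
#' taken so downstream arithmetic always sees non-negative signal.
#'
#' @param path Path to a bedGraph (.bedGraph/.bg) or bigWig (.bw/.bigWig)
#'   file.
#' @return An \code{RleList} of per-base signal, one element per
#'   chromosome.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) stop("no such track: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    "BigWig"
  } else {
    "bedGraph"
  }
  gr <- rtracklayer::import(path, format = fmt)
  track_coverage(gr)
}

#' Per-base coverage from a scored GRanges
#'
#' @param gr A \code{GRanges} with a numeric \code{score} column.
#' @return An \code{RleList} of per-base signal.
#' @export
track_coverage <- function(gr) {
  if (length(gr) == 0) return(GenomicRanges::coverage(gr))
  if (is.null(S4Vectors::mcols(gr)$score)) {
    stop("signal track needs a numeric score column", call. = FALSE)
  }
  S4Vectors::mcols(gr)$score <- abs(S4Vectors::mcols(gr)$score)
  GenomicRanges::coverage(gr, weight = "score")
}

#' Read gene models from a BED6 annotation
#'
#' Columns: chrom, start, end, name, score, strand (0-based half-open).
#' The TSS is the 5' end of the annotated interval (start on +, end on -)
#' and the TTS its 3' end.
#'
#' @param path Path to a BED6 file.
#' @return A data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (0-based half-open).
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("no such annotation: ", path, call. = FALSE)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("annotation must be BED6", call. = FALSE)
  genes <- data.frame(
    gene_id = as.character(bed[[4]]),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    strand = as.character(bed[[6]]),
    stringsAsFactors = FALSE
  )
  validate_genes(genes)
}

validate_genes <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_id must be unique in the annotation", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(genes$end <= genes$start)) {
    stop("gene end must exceed start (0-based half-open)", call. = FALSE)
  }
  genes
}

#' Read a differential-expression gene list
#'
#' One gene id per line; blank lines and lines starting with '#' ignored.
#'
#' @param path Path to the list.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such gene list: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a table as TSV
#'
#' Plain tab-separated output with a header row, no quoting, no row
#' names; used for densities, calibration, rate and summary tables.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by \code{write_tsv}
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# Signal over [start0, end0) (0-based half-open) on one chromosome,
# padding with zeros beyond the track and for absent chromosomes.
region_signal <- function(cov, chrom, start0, end0) {
  len <- end0 - start0
  if (len <= 0) return(numeric(0))
  out <- numeric(len)
  if (!chrom %in% names(cov)) return(out)
  rle <- cov[[chrom]]
  n <- length(rle)
  lo <- max(start0 + 1L, 1L)      # 1-based inclusive
  hi <- min(end0, n)
  if (hi >= lo) {
    out[(lo - start0):(hi - start0)] <-
      as.numeric(S4Vectors::window(rle, lo, hi))
  }
  out
}

# Sense-strand signal at offsets 0..len-1 downstream of the TSS.
# tss0 is the 0-based TSS coordinate. On the minus strand, downstream
# means decreasing genome coordinates, so the extracted window is
# reversed; a single increasing-offset code path serves both strands.
oriented_signal <- function(cov, chrom, strand, tss0, len) {
  if (strand == "+") {
    region_signal(cov, chrom, tss0, tss0 + len)
  } else {
    rev(region_signal(cov, chrom, tss0 - len + 1L, tss0 + 1L))
  }
}

# Map a half-open offset interval [off_start, off_end) downstream of the
# TSS back to 0-based genome coordinates.
offsets_to_genome <- function(strand, tss0, off_start, off_end) {
  if (strand == "+") {
    c(tss0 + off_start, tss0 + off_end)
  } else {
    c(tss0 - off_end + 1L, tss0 - off_start + 1L)
  }
}
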