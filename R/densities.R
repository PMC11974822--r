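#' Locate the pause window downstream of a TSS
#'
#' Scans a sense-strand signal vector (offset 0 at the TSS) for the
#' window of length \code{window} with the maximum summed signal among
#' all start offsets \code{0 .. search_len - window}. Ties are broken in
#' favour of the most TSS-proximal window. Equivalent to brute-force
#' enumeration of every candidate window.
#'
#' @param signal Numeric vector of per-base sense-strand signal starting
#'   at the TSS; shorter vectors are zero-padded to \code{search_len}.
#' @param search_len Length of the search region, bp (200 for PRO-seq,
#'   300 for GRO-seq).
#' @param window Window width, bp (default 50).
#' @return List with \code{start}, \code{end} (0-based half-open offsets
#'   from the TSS), \code{width}, \code{sum} (summed signal) and
#'   \code{zero_signal} (TRUE when the whole search region is zero; such
#'   genes are excluded downstream).
#' @export
find_pause_window <- function(signal, search_len = 200, window = 50) {
  if (window <= 0 || search_len < window) {
    stop("need search_len >= window > 0", call. = FALSE)
  }
  s <- numeric(search_len)
  k <- min(length(signal), search_len)
  if (k > 0) s[seq_len(k)] <- signal[seq_len(k)]
  if (any(s < 0) || any(!is.finite(s))) {
    stop("signal must be finite and >= 0", call. = FALSE)
  }
  cs <- c(0, cumsum(s))
  sums <- cs[(window + 1):(search_len + 1)] - cs[1:(search_len - window + 1)]
  off <- which.max(sums) - 1L   # which.max takes the first maximum
  list(start = off, end = off + as.integer(window),
       width = as.integer(window), sum = sums[off + 1L],
       zero_signal = all(s == 0))
}

#' Gene-body interval downstream of the pause window
#'
#' The body starts \code{offset} bp past the end of the pause window and
#' runs to the annotated gene end, or to the distance an initiated
#' polymerase can travel during the treatment at \code{cap_rate}
#' (whichever is shorter). Offsets are measured from the TSS along the
#' sense strand.
#'
#' @param pause_end Offset of the pause-window end (half-open).
#' @param gene_length TSS-to-TTS length, bp.
#' @param treatment_minutes Treatment duration in minutes, or NULL for an
#'   uncapped body.
#' @param cap_rate Elongation rate used for the travel cap, bp/min
#'   (default 2000).
#' @param offset Gap between pause window and body start, bp (default
#'   500).
#' @return List with \code{start}, \code{end} offsets; \code{end <=
#'   start} marks a gene too short to have a body (dropped downstream).
#' @export
define_gene_body <- function(pause_end, gene_length,
                             treatment_minutes = NULL, cap_rate = 2000,
                             offset = 500) {
  body_start <- pause_end + offset
  body_end <- gene_length
  if (!is.null(treatment_minutes) && is.finite(treatment_minutes)) {
    body_end <- min(body_end,
                    body_start + round(treatment_minutes * cap_rate))
  }
  list(start = as.integer(body_start), end = as.integer(body_end))
}

#' Summed signal over the pause window
#'
#' @param signal Sense-strand signal vector from the TSS.
#' @param pause Window from \code{\link{find_pause_window}}.
#' @return Summed counts.
#' @export
pause_sum <- function(signal, pause) {
  interval_sum(signal, pause$start, pause$end)
}

#' Mean per-bp signal over the gene body
#'
#' Bases without signal (gaps in a sparse track) contribute 0 to the sum
#' but full length to the denominator.
#'
#' @param signal Sense-strand signal vector from the TSS.
#' @param body_start,body_end Half-open offsets from the TSS.
#' @return Mean counts per bp.
#' @export
body_mean <- function(signal, body_start, body_end) {
  if (body_end <= body_start) {
    stop("empty body interval", call. = FALSE)
  }
  interval_sum(signal, body_start, body_end) / (body_end - body_start)
}

# Sum over half-open offset interval, reading past-the-end bases as 0.
interval_sum <- function(signal, start, end) {
  if (end <= start) return(0)
  lo <- start + 1L
  hi <- min(end, length(signal))
  if (hi < lo) return(0)
  sum(signal[lo:hi])
}

#' Per-gene pause and body densities from signal tracks
#'
#' For each gene, extracts sense-strand signal downstream of the TSS,
#' finds the pause window (or reuses supplied windows, e.g. windows
#' defined on control data and held fixed for the treatment), defines the
#' body region, and records the pause sum and body mean.
#'
#' @param cov_plus,cov_minus \code{RleList} per-base signal for each
#'   strand (from \code{\link{read_signal_track}} or
#'   \code{\link{track_coverage}}).
#' @param genes Gene annotation data.frame (see
#'   \code{\link{read_gene_bed}}).
#' @param search_len,window Pause-window search parameters, bp.
#' @param body_offset Gap between pause window and body, bp.
#' @param treatment_minutes,cap_rate Body-length cap (see
#'   \code{\link{define_gene_body}}).
#' @param condition,replicate Labels stored on each record.
#' @param pause_windows Optional data.frame with columns \code{gene_id},
#'   \code{pause_off_start}, \code{pause_off_end} fixing the windows
#'   instead of searching.
#' @return A data.frame of density records: one row per gene with genomic
#'   pause/body coordinates, \code{pause_sum}, \code{body_mean}, label
#'   columns, and flags \code{zero_signal} and \code{no_body}.
#' @export
gene_densities <- function(cov_plus, cov_minus, genes,
                           search_len = 200, window = 50,
                           body_offset = 500,
                           treatment_minutes = NULL, cap_rate = 2000,
                           condition = "control", replicate = 1L,
                           pause_windows = NULL) {
  genes <- validate_genes(genes)
  n <- nrow(genes)
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    pause_start = NA_integer_, pause_end = NA_integer_,
    pause_sum = NA_real_,
    body_start = NA_integer_, body_end = NA_integer_,
    body_mean = NA_real_,
    pause_off_start = NA_integer_, pause_off_end = NA_integer_,
    zero_signal = FALSE, no_body = FALSE,
    condition = condition, replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  fixed <- NULL
  if (!is.null(pause_windows)) {
    fixed <- pause_windows[match(genes$gene_id, pause_windows$gene_id), ]
  }
  for (i in seq_len(n)) {
    g <- genes[i, ]
    tss0 <- if (g$strand == "+") g$start else g$end - 1L
    glen <- g$end - g$start
    cov <- if (g$strand == "+") cov_plus else cov_minus
    read_len <- max(search_len,
                    glen)  # body never extends past the gene end
    sig <- oriented_signal(cov, g$chrom, g$strand, tss0, read_len)

    if (is.null(fixed) || is.na(fixed$pause_off_start[i])) {
      pw <- find_pause_window(sig[seq_len(search_len)], search_len, window)
    } else {
      pw <- list(start = fixed$pause_off_start[i],
                 end = fixed$pause_off_end[i])
      pw$sum <- interval_sum(sig, pw$start, pw$end)
      pw$zero_signal <- all(sig[seq_len(search_len)] == 0)
    }
    body <- define_gene_body(pw$end, glen, treatment_minutes, cap_rate,
                             body_offset)
    pg <- offsets_to_genome(g$strand, tss0, pw$start, pw$end)
    out$pause_start[i] <- pg[1]; out$pause_end[i] <- pg[2]
    out$pause_off_start[i] <- pw$start; out$pause_off_end[i] <- pw$end
    out$pause_sum[i] <- pw$sum
    out$zero_signal[i] <- isTRUE(pw$zero_signal)
    if (body$end > body$start) {
      bg <- offsets_to_genome(g$strand, tss0, body$start, body$end)
      out$body_start[i] <- bg[1]; out$body_end[i] <- bg[2]
      out$body_mean[i] <- body_mean(sig, body$start, body$end)
    } else {
      out$no_body[i] <- TRUE
    }
  }
  out
}

#' Filter to expressed genes
#'
#' A gene is retained when its raw pause sum, summed over all replicates
#' of the reference condition, reaches \code{min_pause_sum} and its body
#' mean is positive in every sample. Genes flagged zero-signal or without
#' a usable body are dropped.
#'
#' @param records Density records (all samples, unnormalized).
#' @param min_pause_sum Minimum summed raw pause counts (default 10).
#' @return Character vector of retained gene ids.
#' @export
expressed_genes <- function(records, min_pause_sum = 10) {
  bad <- unique(records$gene_id[records$zero_signal | records$no_body |
                                  records$body_mean <= 0])
  tot <- tapply(records$pause_sum, records$gene_id, sum)
  keep <- names(tot)[tot >= min_pause_sum]
  setdiff(keep, bad)
}
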