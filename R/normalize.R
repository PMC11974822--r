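#' Median-of-ratios size factors
#'
#' For each control gene the reference is the geometric mean of its
#' counts across samples; a sample's size factor is the median over
#' control genes of count/reference. Genes with a zero count in any
#' sample are excluded from the median (their geometric mean would be
#' zero). For globally repressive treatments, restrict
#' \code{control_genes} to genes whose distal bodies are unaffected
#' within the treatment time (e.g. gene regions longer than the distance
#' polymerase can clear).
#'
#' @param count_table Numeric matrix, genes x samples, rownames = gene
#'   ids.
#' @param control_genes Gene ids used for the median, or \code{"all"}.
#' @return Named numeric vector of per-sample size factors (> 0).
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' rownames(m) <- paste0("g", 1:3)
#' size_factors(m)   # c(0.7071, 1.4142): geometric mean 1
size_factors <- function(count_table, control_genes = "all") {
  m <- as.matrix(count_table)
  if (any(m < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!identical(control_genes, "all")) {
    m <- m[rownames(m) %in% control_genes, , drop = FALSE]
  }
  m <- m[apply(m, 1, function(x) all(x > 0)), , drop = FALSE]
  if (nrow(m) == 0) {
    stop("no usable control genes (all have a zero count)", call. = FALSE)
  }
  log_geo <- rowMeans(log(m))
  sf <- apply(m, 2, function(cnt) exp(stats::median(log(cnt) - log_geo)))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size factors must be finite and > 0", call. = FALSE)
  }
  sf
}

#' Per-gene count table for size-factor estimation
#'
#' Total signal per gene and sample: pause sum plus the summed body
#' signal (body mean times body length). Column order is
#' condition.replicate.
#'
#' @param records Density records from \code{\link{gene_densities}}, all
#'   samples stacked.
#' @param body_only Use only the body signal (the long-gene controlGenes
#'   strategy counts distal body reads).
#' @return Numeric matrix, genes x samples.
#' @export
density_count_table <- function(records, body_only = FALSE) {
  records$sample <- paste(records$condition, records$replicate, sep = ".")
  body_sum <- ifelse(is.na(records$body_mean), 0,
                     records$body_mean * (records$body_end - records$body_start))
  tot <- if (body_only) body_sum else records$pause_sum + body_sum
  tab <- tapply(tot, list(records$gene_id, records$sample), sum,
                default = 0)
  as.matrix(tab)
}

#' Apply size factors to density records
#'
#' Divides each sample's pause sum and body mean by its size factor.
#' Fold changes across conditions are unchanged when both conditions are
#' rescaled by a common constant, but correct per-sample factors are
#' required for replicate averaging and for comparing library depths.
#'
#' @param records Density records.
#' @param factors Named vector from \code{\link{size_factors}}, names
#'   \code{condition.replicate}.
#' @return Records with normalized \code{pause_sum} and \code{body_mean}.
#' @export
normalize_densities <- function(records, factors) {
  key <- paste(records$condition, records$replicate, sep = ".")
  if (!all(key %in% names(factors))) {
    stop("missing size factor for sample(s): ",
         paste(unique(key[!key %in% names(factors)]), collapse = ", "),
         call. = FALSE)
  }
  f <- factors[key]
  records$pause_sum <- records$pause_sum / f
  records$body_mean <- records$body_mean / f
  records
}

#' Average replicate records per gene and condition
#'
#' Arithmetic mean of (already normalized) pause sums and body means
#' across replicates; coordinate columns must agree across replicates
#' (the pause window is defined once per gene).
#'
#' @param records Normalized density records.
#' @return One record per gene and condition, \code{replicate = NA}.
#' @export
average_replicates <- function(records) {
  key <- interaction(records$gene_id, records$condition, drop = TRUE)
  first <- records[!duplicated(key), ]
  first <- first[order(key[!duplicated(key)]), ]
  agg_p <- tapply(records$pause_sum, key, mean)
  agg_b <- tapply(records$body_mean, key, mean)
  zero <- tapply(records$zero_signal, key, any)
  nob <- tapply(records$no_body, key, any)
  first$pause_sum <- as.numeric(agg_p[levels(key)])
  first$body_mean <- as.numeric(agg_b[levels(key)])
  first$zero_signal <- as.logical(zero[levels(key)])
  first$no_body <- as.logical(nob[levels(key)])
  first$replicate <- NA_integer_
  rownames(first) <- NULL
  first
}

#' Per-gene fold changes between two conditions
#'
#' Joins averaged density records for a control and a treatment
#' condition and computes the fold changes in pause density, body
#' density, pause release (fc_b / fc_p) and the bounds on the fold
#' change in initiation. Genes with a zero pause or body density in
#' either condition are excluded (ratios are undefined at zero; no
#' pseudocounts) and reported in the \code{dropped} attribute.
#'
#' @param control,treatment Averaged density records (one row per gene).
#' @param genes Optional gene ids to restrict to (e.g. the expressed
#'   set).
#' @return Data.frame with columns \code{gene_id}, \code{p_control},
#'   \code{b_control}, \code{p_treatment}, \code{b_treatment},
#'   \code{fc_p}, \code{fc_b}, \code{fc_krel}, \code{fc_kinit_lower},
#'   \code{fc_kinit_upper}; attribute \code{dropped} lists excluded
#'   genes with reasons.
#' @export
density_fold_changes <- function(control, treatment, genes = NULL) {
  if (!is.null(genes)) {
    control <- control[control$gene_id %in% genes, ]
    treatment <- treatment[treatment$gene_id %in% genes, ]
  }
  m <- merge(control[, c("gene_id", "pause_sum", "body_mean")],
             treatment[, c("gene_id", "pause_sum", "body_mean")],
             by = "gene_id", suffixes = c("_control", "_treatment"))
  ok <- m$pause_sum_control > 0 & m$body_mean_control > 0 &
    m$pause_sum_treatment > 0 & m$body_mean_treatment > 0
  dropped <- data.frame(
    gene_id = m$gene_id[!ok],
    reason = rep("zero pause or body density in one condition",
                 sum(!ok)),
    stringsAsFactors = FALSE
  )
  m <- m[ok, ]
  fc_p <- m$pause_sum_treatment / m$pause_sum_control
  fc_b <- m$body_mean_treatment / m$body_mean_control
  bounds <- fold_change_initiation_bounds(fc_p, fc_b)
  out <- data.frame(
    gene_id = m$gene_id,
    p_control = m$pause_sum_control, b_control = m$body_mean_control,
    p_treatment = m$pause_sum_treatment,
    b_treatment = m$body_mean_treatment,
    fc_p = fc_p, fc_b = fc_b,
    fc_krel = fold_change_pause_release(fc_b, fc_p),
    fc_kinit_lower = bounds$lower, fc_kinit_upper = bounds$upper,
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- dropped
  out
}
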