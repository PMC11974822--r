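#' Clamp a target initiation fold change into its admissible bounds
#'
#' The fold change in initiation for a gene must lie between the fold
#' changes of its pause and body densities. When an externally assumed
#' value (e.g. 0.25 after triptolide) falls inside the bounds it is used
#' as-is; otherwise it is replaced by the bound closest to the target,
#' moved into the interior of the interval by \code{offset} (5% by
#' default): \code{(1 - offset) * upper} when clamping down,
#' \code{(1 + offset) * lower} when clamping up. The interior placement
#' keeps the assigned value strictly between the bounds, which prevents
#' the termination/release ratio from degenerating to 0 or undefined.
#'
#' @param lower,upper Bounds on the initiation fold change (0 < lower <=
#'   upper). Vectorized.
#' @param target Assumed fold change in initiation.
#' @param offset Interior offset fraction, in (0, 1).
#' @return List with vectors \code{assigned} and \code{clamped}.
#' @export
#' @examples
#' clamp_initiation_fold_change(0.18, 0.40, 0.25)  # inside: unchanged
#' clamp_initiation_fold_change(0.10, 0.20, 0.25)  # above: 0.95 * 0.20
clamp_initiation_fold_change <- function(lower, upper, target = 0.25,
                                         offset = 0.05) {
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(upper < lower)) {
    stop("need 0 < lower <= upper", call. = FALSE)
  }
  if (!is.finite(target) || target <= 0) {
    stop("target must be > 0", call. = FALSE)
  }
  if (offset <= 0 || offset >= 1) {
    stop("offset must lie in (0, 1)", call. = FALSE)
  }
  n <- max(length(lower), length(upper))
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  assigned <- rep(target, n)
  above <- target > upper
  below <- target < lower
  assigned[above] <- (1 - offset) * upper[above]
  assigned[below] <- (1 + offset) * lower[below]
  clamped <- above | below
  # collapsed bounds leave no interior: assign the bound itself and let
  # the termination/release ratio report it as a boundary sentinel
  deg <- clamped & upper <= lower * (1 + 1e-12)
  assigned[deg] <- lower[deg]
  bad <- !deg & clamped & (assigned <= lower | assigned >= upper)
  if (any(bad)) {
    stop("offset so large the adjusted value crosses the opposite bound ",
         "for ", sum(bad), " gene(s)", call. = FALSE)
  }
  list(assigned = assigned, clamped = clamped)
}

#' Genome-wide termination/release ratio from an initiation anchor
#'
#' For genes repressed by an initiation inhibitor with known efficacy
#' (triptolide: ~75% inhibition, target fold change 0.25), each gene's
#' initiation fold change is set to the target clamped into its
#' admissible bounds, and the control-condition ratio k_pre/k_rel is
#' solved per gene. The summary reports the median, the 10th-90th
#' percentile (interdecile) range and the fraction of genes with ratio
#' greater than 1 (termination faster than release), over finite
#' non-negative ratios; boundary and negative cases are counted
#' separately.
#'
#' @param fc Fold-change table from \code{\link{density_fold_changes}},
#'   restricted to the repressed gene set.
#' @param target_fc_kinit Assumed initiation fold change (default 0.25).
#' @param offset Clamp offset (default 0.05).
#' @param tol Boundary-detection tolerance passed to
#'   \code{\link{termination_release_ratio}}.
#' @return List with \code{per_gene} (gene_id, fc_kinit_assigned,
#'   clamped, ratio, status) and \code{summary} (median, q10, q90,
#'   fraction_ratio_gt1, n_used, n_zero_boundary, n_undefined_boundary,
#'   n_negative).
#' @export
infer_termination_ratio_genomewide <- function(fc, target_fc_kinit = 0.25,
                                               offset = 0.05,
                                               tol = 1e-9) {
  if (nrow(fc) == 0) stop("empty gene set", call. = FALSE)
  lo <- fc$fc_kinit_lower
  hi <- fc$fc_kinit_upper
  # genes whose bounds are narrower than the clamp offset would cross the
  # opposite bound; give them the interior geometric midpoint instead
  narrow <- (target_fc_kinit > hi & (1 - offset) * hi <= lo) |
    (target_fc_kinit < lo & (1 + offset) * lo >= hi)
  narrow <- narrow & hi > lo
  cl <- clamp_initiation_fold_change(
    ifelse(narrow, sqrt(lo * hi) / (1 + offset), lo),
    ifelse(narrow, sqrt(lo * hi) * (1 + offset), hi),
    target_fc_kinit, offset)
  cl$assigned[narrow] <- sqrt(lo * hi)[narrow]
  cl$clamped <- cl$clamped | narrow
  cl <- list(assigned = cl$assigned, clamped = cl$clamped)
  tr <- termination_release_ratio(fc$fc_krel, cl$assigned, fc$fc_p,
                                  tol = tol)
  per_gene <- data.frame(
    gene_id = fc$gene_id, fc_kinit_assigned = cl$assigned,
    clamped = cl$clamped, ratio = tr$ratio, status = tr$status,
    stringsAsFactors = FALSE
  )
  use <- tr$status == "ok"
  r <- tr$ratio[use]
  q <- if (length(r)) stats::quantile(r, c(0.1, 0.5, 0.9), names = FALSE)
       else rep(NA_real_, 3)
  summary <- data.frame(
    median = q[2], q10 = q[1], q90 = q[3],
    fraction_ratio_gt1 = if (length(r)) mean(r > 1) else NA_real_,
    n_used = sum(use),
    n_zero_boundary = sum(tr$status == "zero_boundary"),
    n_undefined_boundary = sum(tr$status == "undefined_boundary"),
    n_negative = sum(tr$status == "negative")
  )
  list(per_gene = per_gene, summary = summary)
}

#' Per-gene absolute rates, spacings and half-lives
#'
#' Combines occupancy-scaled density records from two conditions into a
#' per-gene rate report: absolute pause release (k_elong * b / p) per
#' condition, premature termination k_pre = r * k_rel(control) held
#' constant between conditions, absolute initiation (p * k_pre +
#' k_elong * b), effective pause release (k_rel * p), polymerase spacing
#' (1/b) and the paused-polymerase half-life, plus fold changes and the
#' bounds on the initiation fold change.
#'
#' @param control,treatment Occupancy-scaled density records
#'   (\code{\link{scale_to_occupancy}}), one row per gene.
#' @param k_elong Elongation rate, bp/min (default 2000).
#' @param r Assumed k_pre / k_rel(control) (default 6.7, the
#'   triptolide-anchored genome-wide median).
#' @param genes Optional gene ids to restrict to.
#' @return Data.frame, one row per retained gene, with rate columns per
#'   condition, fold changes, bounds, flags; attribute \code{dropped}
#'   lists genes excluded for zero densities.
#' @export
absolute_rate_report <- function(control, treatment, k_elong = 2000,
                                 r = 6.7, genes = NULL) {
  for (d in list(control, treatment)) {
    if (!isTRUE(attr(d, "scaled")) || is.null(d$p_occ)) {
      stop("records must be occupancy-scaled (scale_to_occupancy)",
           call. = FALSE)
    }
  }
  check_positive(k_elong, "k_elong")
  if (!is.finite(r) || r < 0) stop("r must be >= 0", call. = FALSE)
  if (!is.null(genes)) {
    control <- control[control$gene_id %in% genes, ]
    treatment <- treatment[treatment$gene_id %in% genes, ]
  }
  cols <- c("gene_id", "p_occ", "b_occ", "clipped_occupancy")
  m <- merge(control[, cols], treatment[, cols], by = "gene_id",
             suffixes = c("_control", "_treatment"))
  ok <- m$p_occ_control > 0 & m$b_occ_control > 0 &
    m$p_occ_treatment > 0 & m$b_occ_treatment > 0
  dropped <- data.frame(gene_id = m$gene_id[!ok],
                        reason = rep("zero density in one condition",
                                     sum(!ok)),
                        stringsAsFactors = FALSE)
  m <- m[ok, , drop = FALSE]

  krel_c <- pause_release_rate(k_elong, m$p_occ_control, m$b_occ_control)
  krel_t <- pause_release_rate(k_elong, m$p_occ_treatment,
                               m$b_occ_treatment)
  kpre <- r * krel_c
  fc_p <- m$p_occ_treatment / m$p_occ_control
  fc_b <- m$b_occ_treatment / m$b_occ_control
  bounds <- fold_change_initiation_bounds(fc_p, fc_b)
  out <- data.frame(
    gene_id = m$gene_id,
    fc_p = fc_p, fc_b = fc_b, fc_krel = fc_b / fc_p,
    fc_kinit_lower = bounds$lower, fc_kinit_upper = bounds$upper,
    fc_kinit_assigned = fold_change_initiation_given_ratio(
      fc_p, fc_b / fc_p, r),
    kpre_over_krel = r,
    krel_control = krel_c, krel_treatment = krel_t,
    kpre = kpre,
    kinit_control = initiation_rate(m$p_occ_control, m$b_occ_control,
                                    kpre, k_elong),
    kinit_treatment = initiation_rate(m$p_occ_treatment,
                                      m$b_occ_treatment, kpre, k_elong),
    effective_release_control =
      effective_pause_release(krel_c, m$p_occ_control),
    effective_release_treatment =
      effective_pause_release(krel_t, m$p_occ_treatment),
    spacing_control = polymerase_spacing(m$b_occ_control),
    spacing_treatment = polymerase_spacing(m$b_occ_treatment),
    half_life_control = pause_half_life(kpre, krel_c),
    half_life_treatment = pause_half_life(kpre, krel_t),
    clipped_occupancy = m$clipped_occupancy_control |
      m$clipped_occupancy_treatment,
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- dropped
  out
}

#' Classify the kinetic mechanism of a perturbed factor
#'
#' Summarizes, over a differentially expressed gene set, the direction
#' of change in pause release and in the bounds of the initiation fold
#' change. A factor whose dominant coherent change sits in the
#' initiation bounds (both bounds on the same side of 1) is reported as
#' an initiation regulator; one whose coherent change is in fc_krel as a
#' pause-release regulator. Both fractions are always reported with
#' their ECDF tables; no hidden thresholds.
#'
#' @param reports Rate or fold-change table with columns \code{gene_id},
#'   \code{fc_krel}, \code{fc_kinit_lower}, \code{fc_kinit_upper}.
#' @param gene_set Differentially expressed gene ids (nonempty).
#' @param direction \code{"activated"} or \code{"repressed"}; fixes the
#'   expected direction of change (> 1 for activated, < 1 for
#'   repressed).
#' @return List with \code{n_genes}, \code{fraction_krel_in_direction},
#'   \code{fraction_kinit_bounds_lt1}, \code{fraction_kinit_bounds_gt1},
#'   \code{fraction_kinit_bounds_straddle},
#'   \code{fraction_kinit_in_direction}, \code{call} ("initiation",
#'   "pause_release" or "ambiguous") and \code{ecdf_tables} (sorted
#'   values with cumulative fractions for fc_krel and both bounds).
#' @export
classify_factor_mechanism <- function(reports, gene_set,
                                      direction = c("activated",
                                                    "repressed")) {
  direction <- match.arg(direction)
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  x <- reports[reports$gene_id %in% gene_set, ]
  if (nrow(x) == 0) stop("no reported genes in the gene set", call. = FALSE)
  dir_test <- if (direction == "activated") {
    function(v) v > 1
  } else {
    function(v) v < 1
  }
  lt1 <- x$fc_kinit_upper < 1
  gt1 <- x$fc_kinit_lower > 1
  straddle <- !lt1 & !gt1
  frac_kinit_dir <- if (direction == "activated") mean(gt1) else mean(lt1)
  frac_krel_dir <- mean(dir_test(x$fc_krel))
  call <- if (frac_kinit_dir >= frac_krel_dir &&
              frac_kinit_dir > mean(straddle)) {
    "initiation"
  } else if (frac_krel_dir > frac_kinit_dir) {
    "pause_release"
  } else {
    "ambiguous"
  }
  ecdf_tab <- function(v) {
    v <- sort(v)
    data.frame(value = v, cum_fraction = seq_along(v) / length(v))
  }
  list(
    n_genes = nrow(x),
    fraction_krel_in_direction = frac_krel_dir,
    fraction_kinit_bounds_lt1 = mean(lt1),
    fraction_kinit_bounds_gt1 = mean(gt1),
    fraction_kinit_bounds_straddle = mean(straddle),
    fraction_kinit_in_direction = frac_kinit_dir,
    call = call,
    ecdf_tables = list(fc_krel = ecdf_tab(x$fc_krel),
                       fc_kinit_lower = ecdf_tab(x$fc_kinit_lower),
                       fc_kinit_upper = ecdf_tab(x$fc_kinit_upper))
  )
}

#' Median and interdecile summary of rate columns
#'
#' @param reports Rate report from \code{\link{absolute_rate_report}}.
#' @param columns Columns to summarize.
#' @return Data.frame with one row per column: median, q10, q90
#'   (linear-interpolation quantiles over finite values).
#' @export
rate_summary <- function(reports,
                         columns = c("krel_control", "krel_treatment",
                                     "kinit_control", "kinit_treatment",
                                     "effective_release_control",
                                     "effective_release_treatment",
                                     "spacing_control",
                                     "spacing_treatment",
                                     "half_life_control",
                                     "half_life_treatment")) {
  columns <- intersect(columns, names(reports))
  do.call(rbind, lapply(columns, function(cn) {
    v <- reports[[cn]]
    v <- v[is.finite(v)]
    q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
    data.frame(quantity = cn, median = q[2], q10 = q[1], q90 = q[3],
               n = length(v), stringsAsFactors = FALSE)
  }))
}
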