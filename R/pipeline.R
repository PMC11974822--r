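#' Build a validated run configuration
#'
#' Collects every tunable of the workflow with the defaults used
#' throughout: a 50 bp pause window searched over 200 bp downstream of
#' the TSS (300 bp for GRO-seq), the body starting 500 bp past the pause
#' window and capped at the distance polymerase travels during the
#' treatment at 2000 bp/min, an assumed elongation rate of 2000 bp/min,
#' a premature-termination to pause-release ratio of 6.7, a target
#' initiation fold change of 0.25 with a 5% clamp offset for
#' triptolide-anchored inference, and the 90th-percentile occupancy
#' fallback for libraries without UMIs.
#'
#' @param assay \code{"proseq"} or \code{"groseq"} (sets the default
#'   search length).
#' @param has_umis Does the library have UMIs (PCR duplicates removed)?
#' @param treatment_minutes Treatment duration, minutes, or NULL (no
#'   body cap).
#' @param k_elong Elongation rate, bp/min.
#' @param r Assumed k_pre / k_rel(control).
#' @param target_fc_kinit Anchor initiation fold change for
#'   inhibitor-calibrated inference.
#' @param clamp_offset Interior clamp offset fraction.
#' @param search_len Pause search length, bp (default by assay).
#' @param window Pause window width, bp.
#' @param body_offset Pause-to-body gap, bp.
#' @param cap_rate Elongation rate used for the body cap, bp/min.
#' @param occupancy_percentile Percentile for the non-UMI occupancy
#'   estimator.
#' @param min_pause_sum Expressed-gene threshold on summed raw pause
#'   counts.
#' @param control_gene_min_length Restrict size-factor control genes to
#'   genes at least this long (bp), or NULL for all genes.
#' @param size_factor_body_only Use only body signal in the size-factor
#'   count table.
#' @param control_condition,treatment_condition Condition labels.
#' @param pause_windows_from \code{"control"} (windows defined on the
#'   pooled control replicates and reused for treatment) or
#'   \code{"each"} (recomputed per sample).
#' @param seed Seed recorded with the run.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(assay = c("proseq", "groseq"), has_umis = FALSE,
                       treatment_minutes = NULL, k_elong = 2000,
                       r = 6.7, target_fc_kinit = 0.25,
                       clamp_offset = 0.05, search_len = NULL,
                       window = 50, body_offset = 500, cap_rate = 2000,
                       occupancy_percentile = 90, min_pause_sum = 10,
                       control_gene_min_length = NULL,
                       size_factor_body_only = FALSE,
                       control_condition = "control",
                       treatment_condition = "treatment",
                       pause_windows_from = c("control", "each"),
                       seed = 1L) {
  assay <- match.arg(assay)
  pause_windows_from <- match.arg(pause_windows_from)
  if (is.null(search_len)) {
    search_len <- if (assay == "groseq") 300 else 200
  }
  cfg <- list(assay = assay, has_umis = isTRUE(has_umis),
              treatment_minutes = treatment_minutes, k_elong = k_elong,
              r = r, target_fc_kinit = target_fc_kinit,
              clamp_offset = clamp_offset, search_len = search_len,
              window = window, body_offset = body_offset,
              cap_rate = cap_rate,
              occupancy_percentile = occupancy_percentile,
              min_pause_sum = min_pause_sum,
              control_gene_min_length = control_gene_min_length,
              size_factor_body_only = isTRUE(size_factor_body_only),
              control_condition = control_condition,
              treatment_condition = treatment_condition,
              pause_windows_from = pause_windows_from,
              seed = as.integer(seed))
  stopifnot(cfg$k_elong > 0, cfg$r >= 0, cfg$target_fc_kinit > 0,
            cfg$clamp_offset > 0, cfg$clamp_offset < 1,
            cfg$search_len >= cfg$window, cfg$window > 0,
            cfg$body_offset >= 0, cfg$cap_rate > 0,
            cfg$occupancy_percentile > 0, cfg$occupancy_percentile <= 100)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Fields absent from the file keep their \code{\link{run_config}}
#' defaults; unknown fields are rejected.
#'
#' @param path YAML config path.
#' @param ... Overrides applied on top of the file (CLI flags).
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Persist a resolved configuration
#'
#' @param config A \code{run_config}.
#' @param path Output YAML path.
#' @return Invisibly, \code{path}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Element-wise sum of coverage RleLists with possibly different
# chromosome sets/lengths.
sum_coverages <- function(covs) {
  chroms <- unique(unlist(lapply(covs, names)))
  out <- lapply(chroms, function(ch) {
    lens <- vapply(covs, function(cv) {
      if (ch %in% names(cv)) length(cv[[ch]]) else 0L
    }, integer(1))
    n <- max(lens)
    total <- S4Vectors::Rle(0, n)
    for (cv in covs) {
      if (!ch %in% names(cv)) next
      x <- cv[[ch]]
      if (length(x) < n) x <- c(x, S4Vectors::Rle(0, n - length(x)))
      total <- total + x
    }
    total
  })
  names(out) <- chroms
  do.call(IRanges::RleList, out)
}

resolve_track <- function(x) {
  if (is.character(x)) read_signal_track(x) else x
}

#' Run the full workflow on a two-condition dataset
#'
#' Stages, in order: per-sample density extraction (pause windows
#' defined on the pooled control replicates by default), size-factor
#' normalization, replicate averaging, expressed-gene filtering,
#' fold-change computation, occupancy calibration from the control
#' condition, absolute-rate reporting, optional inhibitor-anchored
#' termination/release inference, and factor classification per DE
#' list. All tables are written as TSV under \code{out_dir} together
#' with the resolved configuration and a log of dropped genes.
#'
#' @param config A \code{\link{run_config}}.
#' @param samples A data.frame (or list of lists) with one row per
#'   sample: \code{condition}, \code{replicate}, \code{plus},
#'   \code{minus}. Track entries may be file paths (bedGraph/bigWig) or
#'   in-memory \code{RleList}s.
#' @param genes Gene annotation: a BED6 path or a data.frame as from
#'   \code{\link{read_gene_bed}}.
#' @param de_lists Named list of DE gene sets (paths or character
#'   vectors); names containing "repress" are treated as repressed,
#'   others as activated, for classification.
#' @param out_dir Output directory, or NULL to skip writing.
#' @param trp_anchor Run the triptolide-style termination/release
#'   inference on the repressed gene list.
#' @return List with \code{densities}, \code{size_factors},
#'   \code{averaged}, \code{expressed}, \code{fold_changes},
#'   \code{calibration}, \code{rates}, \code{summary},
#'   \code{trp_ratio} (or NULL), \code{classification}, \code{dropped}.
#' @export
run_end_to_end <- function(config, samples, genes, de_lists = NULL,
                           out_dir = NULL, trp_anchor = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(genes)) genes <- read_gene_bed(genes)
  genes <- validate_genes(genes)
  if (is.data.frame(samples)) {
    samples <- lapply(seq_len(nrow(samples)), function(i)
      as.list(samples[i, , drop = FALSE]))
  }
  de_lists <- lapply(de_lists, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      read_gene_list(x)
    } else {
      as.character(x)
    }
  })

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  covs <- stage("tracks", lapply(samples, function(s) {
    list(condition = s$condition, replicate = as.integer(s$replicate),
         plus = resolve_track(s$plus), minus = resolve_track(s$minus))
  }))

  # pause windows fixed from the pooled control replicates
  windows <- NULL
  if (config$pause_windows_from == "control") {
    ctl <- covs[vapply(covs, function(s)
      s$condition == config$control_condition, logical(1))]
    if (length(ctl) == 0) stop("[densities] no control samples",
                               call. = FALSE)
    pooled_p <- sum_coverages(lapply(ctl, `[[`, "plus"))
    pooled_m <- sum_coverages(lapply(ctl, `[[`, "minus"))
    wrec <- stage("densities", gene_densities(
      pooled_p, pooled_m, genes, search_len = config$search_len,
      window = config$window, body_offset = config$body_offset,
      treatment_minutes = config$treatment_minutes,
      cap_rate = config$cap_rate, condition = "pooled_control"))
    windows <- wrec[, c("gene_id", "pause_off_start", "pause_off_end")]
  }

  densities <- stage("densities", do.call(rbind, lapply(covs, function(s)
    gene_densities(s$plus, s$minus, genes,
                   search_len = config$search_len,
                   window = config$window,
                   body_offset = config$body_offset,
                   treatment_minutes = config$treatment_minutes,
                   cap_rate = config$cap_rate,
                   condition = s$condition, replicate = s$replicate,
                   pause_windows = windows))))

  control_set <- "all"
  if (!is.null(config$control_gene_min_length)) {
    control_set <- genes$gene_id[
      genes$end - genes$start >= config$control_gene_min_length]
  }
  counts <- stage("normalization", density_count_table(
    densities, body_only = config$size_factor_body_only))
  sf <- stage("normalization", size_factors(counts, control_set))
  normed <- stage("normalization", normalize_densities(densities, sf))
  averaged <- stage("normalization", average_replicates(normed))

  expressed <- stage("filter", expressed_genes(
    densities, min_pause_sum = config$min_pause_sum))

  ctl_avg <- averaged[averaged$condition == config$control_condition, ]
  trt_avg <- averaged[averaged$condition == config$treatment_condition, ]
  fc <- stage("fold_changes",
              density_fold_changes(ctl_avg, trt_avg, genes = expressed))

  calib <- stage("calibration", max_occupancy(
    ctl_avg$pause_sum[ctl_avg$gene_id %in% expressed &
                        ctl_avg$pause_sum > 0],
    has_umis = config$has_umis,
    percentile = config$occupancy_percentile))
  ctl_occ <- stage("calibration", scale_to_occupancy(ctl_avg, calib))
  trt_occ <- stage("calibration", scale_to_occupancy(trt_avg, calib))

  rates <- stage("rates", absolute_rate_report(
    ctl_occ, trt_occ, k_elong = config$k_elong, r = config$r,
    genes = expressed))
  summ <- stage("rates", rate_summary(rates))

  trp <- NULL
  if (isTRUE(trp_anchor)) {
    rep_idx <- grep("repress", names(de_lists))
    if (length(rep_idx) == 0) {
      stop("[trp_ratio] trp_anchor requires a repressed DE list",
           call. = FALSE)
    }
    rep_set <- unique(unlist(de_lists[rep_idx]))
    trp <- stage("trp_ratio", infer_termination_ratio_genomewide(
      fc[fc$gene_id %in% rep_set, ],
      target_fc_kinit = config$target_fc_kinit,
      offset = config$clamp_offset))
  }

  classification <- NULL
  if (length(de_lists)) {
    classification <- lapply(names(de_lists), function(nm) {
      dir <- if (grepl("repress", nm)) "repressed" else "activated"
      stage("classify",
            classify_factor_mechanism(fc, de_lists[[nm]], dir))
    })
    names(classification) <- names(de_lists)
  }

  unexpressed <- setdiff(genes$gene_id, expressed)
  dropped <- rbind(
    data.frame(gene_id = unexpressed,
               reason = rep("below expressed-gene thresholds",
                            length(unexpressed)),
               stringsAsFactors = FALSE),
    attr(fc, "dropped"), attr(rates, "dropped"))

  result <- list(densities = densities, size_factors = sf,
                 averaged = averaged, expressed = expressed,
                 fold_changes = fc, calibration = calib, rates = rates,
                 summary = summ, trp_ratio = trp,
                 classification = classification, dropped = dropped)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(densities, file.path(out_dir, "densities.tsv"))
    write_tsv(data.frame(sample = names(sf), size_factor = sf),
              file.path(out_dir, "size_factors.tsv"))
    write_tsv(fc, file.path(out_dir, "fold_changes.tsv"))
    write_calibration(calib, file.path(out_dir, "calibration.tsv"))
    write_tsv(rates, file.path(out_dir, "rates.tsv"))
    write_tsv(summ, file.path(out_dir, "summary.tsv"))
    write_tsv(dropped, file.path(out_dir, "dropped_genes.tsv"))
    if (!is.null(trp)) {
      write_tsv(trp$per_gene, file.path(out_dir, "trp_ratio_genes.tsv"))
      write_tsv(trp$summary, file.path(out_dir, "trp_ratio_summary.tsv"))
    }
    if (!is.null(classification)) {
      cls <- do.call(rbind, lapply(names(classification), function(nm) {
        cl <- classification[[nm]]
        data.frame(gene_set = nm, n_genes = cl$n_genes,
                   fraction_krel_in_direction =
                     cl$fraction_krel_in_direction,
                   fraction_kinit_bounds_lt1 =
                     cl$fraction_kinit_bounds_lt1,
                   fraction_kinit_bounds_gt1 =
                     cl$fraction_kinit_bounds_gt1,
                   fraction_kinit_bounds_straddle =
                     cl$fraction_kinit_bounds_straddle,
                   call = cl$call, stringsAsFactors = FALSE)
      }))
      write_tsv(cls, file.path(out_dir, "classification.tsv"))
      for (nm in names(classification)) {
        for (tab in names(classification[[nm]]$ecdf_tables)) {
          write_tsv(classification[[nm]]$ecdf_tables[[tab]],
                    file.path(out_dir,
                              sprintf("ecdf_%s_%s.tsv", nm, tab)))
        }
      }
    }
    write_run_config(config, file.path(out_dir, "resolved_config.yaml"))
  }
  result
}
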