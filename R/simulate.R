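#' Draw a set of simulated genes with known kinetic rates
#'
#' Genes are laid out head-to-tail on one synthetic chromosome with at
#' least \code{gap} bp between them, alternating strands. Control-state
#' rates are drawn log-normally: pause release around a median of 0.86
#' events/min (the scale of measured PRO-seq medians) and initiation
#' around 0.5 RNAP/min, with premature termination tied to pause release
#' through the fixed ratio \code{r}. The true pause position is uniform
#' within the proximal search region and carries a narrow Gaussian
#' footprint.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed RNG seed (mandatory; no hidden global randomness).
#' @param krel_meanlog,krel_sdlog Log-normal parameters for k_rel
#'   (defaults: median 0.86/min, sdlog 1.05 giving an interdecile span
#'   of roughly 0.2-3.3).
#' @param kinit_meanlog,kinit_sdlog Log-normal parameters for k_init
#'   (defaults: median 0.5 RNAP/min, sdlog 1).
#' @param r Ratio k_pre / k_rel applied to every gene (default 6.7).
#' @param k_elong Elongation rate, bp/min (default 2000).
#' @param body_len_range Range of body lengths, bp.
#' @param pause_center_range Range of true pause positions (offsets from
#'   the TSS), kept inside the default 200 bp search region.
#' @param pause_sd Footprint standard deviation, bp; 0 gives a single
#'   spike.
#' @param gap Minimum intergenic distance, bp.
#' @return A data.frame of simulated genes: annotation columns
#'   (\code{gene_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}), true rates (\code{k_init}, \code{k_pre},
#'   \code{k_rel}, \code{k_elong}), \code{pause_center},
#'   \code{pause_sd}, \code{body_len}; attribute \code{chrom_len}.
#' @export
sample_gene_rates <- function(n_genes, seed,
                              krel_meanlog = log(0.86), krel_sdlog = 1.05,
                              kinit_meanlog = log(0.5), kinit_sdlog = 1,
                              r = 6.7, k_elong = 2000,
                              body_len_range = c(1500, 3500),
                              pause_center_range = c(40, 120),
                              pause_sd = 4, gap = 1000) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!is.finite(krel_sdlog) || krel_sdlog < 0 ||
      !is.finite(kinit_sdlog) || kinit_sdlog < 0 ||
      !is.finite(r) || r < 0) {
    stop("invalid rate distribution parameters", call. = FALSE)
  }
  set.seed(seed)
  k_rel <- stats::rlnorm(n_genes, krel_meanlog, krel_sdlog)
  k_init <- stats::rlnorm(n_genes, kinit_meanlog, kinit_sdlog)
  body_len <- round(stats::runif(n_genes, body_len_range[1],
                                 body_len_range[2]))
  center <- round(stats::runif(n_genes, pause_center_range[1],
                               pause_center_range[2]))
  # TSS .. pause search region (200) .. 500 gap .. body
  glen <- 200L + 500L + as.integer(body_len)
  starts <- cumsum(c(gap, glen[-n_genes] + gap))
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "chrSim",
    start = as.integer(starts),
    end = as.integer(starts + glen),
    strand = rep_len(c("+", "-"), n_genes),
    k_init = k_init, k_pre = r * k_rel, k_rel = k_rel,
    k_elong = k_elong,
    pause_center = center, pause_sd = pause_sd,
    body_len = as.integer(body_len),
    stringsAsFactors = FALSE
  )
  attr(genes, "chrom_len") <- as.integer(starts[n_genes] + glen[n_genes] + gap)
  attr(genes, "seed") <- seed
  genes
}

# Expected per-base sense-strand signal for one gene (offsets 0..L-1),
# in occupancy units: the pause footprint integrates to p and every base
# past the footprint carries b (elongating polymerases transit the whole
# distal gene at density b).
gene_mean_profile <- function(p, b, glen, center, sd) {
  mu <- numeric(glen)
  if (sd > 0) {
    off <- max(0, center - 4 * sd):min(glen - 1, center + 4 * sd)
    w <- stats::dnorm(off, center, sd)
    mu[off + 1] <- p * w / sum(w)
  } else {
    mu[center + 1] <- p
  }
  body_from <- min(center + max(1, 4 * sd) + 1, glen - 1)
  mu[(body_from + 1):glen] <- mu[(body_from + 1):glen] + b
  mu
}

#' Generate paired-condition signal tracks with known ground truth
#'
#' Steady-state pause and body densities are computed per gene from the
#' control rates and from the rates after applying per-gene fold changes
#' in initiation and/or pause release (premature termination and
#' elongation stay fixed). Expected counts are the densities times a
#' common signal scale chosen so a unit-library sample carries
#' \code{depth} expected reads; counts are Poisson per base, with an
#' optional library-size multiplier per sample to exercise size-factor
#' estimation.
#'
#' @param genes Simulated genes from \code{\link{sample_gene_rates}}.
#' @param fc_kinit,fc_krel Per-gene fold changes applied in the
#'   treatment condition (length 1 or \code{nrow(genes)}).
#' @param depth Expected reads per unit-library sample (> 0).
#' @param seed RNG seed (mandatory).
#' @param replicates Replicates per condition.
#' @param lib_factors Library-size multipliers, one per sample in the
#'   order control reps then treatment reps (default all 1).
#' @return List with \code{samples} (per sample: condition, replicate,
#'   lib, and \code{plus}/\code{minus} RleList tracks), \code{genes},
#'   \code{truth} (per-gene generating rates, densities and fold
#'   changes), \code{scale} (signal units per occupancy unit) and
#'   \code{seed}.
#' @export
generate_condition_pair <- function(genes, fc_kinit = 1, fc_krel = 1,
                                    depth = 1e6, seed, replicates = 2,
                                    lib_factors = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  n <- nrow(genes)
  fc_kinit <- rep_len(fc_kinit, n)
  fc_krel <- rep_len(fc_krel, n)
  n_samples <- 2 * replicates
  if (is.null(lib_factors)) lib_factors <- rep(1, n_samples)
  stopifnot(length(lib_factors) == n_samples, all(lib_factors > 0))

  p_c <- genes$k_init / (genes$k_pre + genes$k_rel)
  b_c <- genes$k_rel / genes$k_elong * p_c
  krel_t <- genes$k_rel * fc_krel
  p_t <- genes$k_init * fc_kinit / (genes$k_pre + krel_t)
  b_t <- krel_t / genes$k_elong * p_t
  glen <- genes$end - genes$start
  # one scale for both conditions, anchored to the control library
  scale <- depth / sum(p_c + b_c * glen)

  chrom_len <- attr(genes, "chrom_len")
  if (is.null(chrom_len)) chrom_len <- max(genes$end) + 1000L
  conditions <- rep(c("control", "treatment"), each = replicates)
  reps <- rep(seq_len(replicates), 2)

  set.seed(seed)
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    plus <- numeric(chrom_len)
    minus <- numeric(chrom_len)
    trt <- conditions[s] == "treatment"
    for (i in seq_len(n)) {
      p <- if (trt) p_t[i] else p_c[i]
      b <- if (trt) b_t[i] else b_c[i]
      mu <- gene_mean_profile(p, b, glen[i], genes$pause_center[i],
                              genes$pause_sd[i]) * scale * lib_factors[s]
      cnt <- stats::rpois(glen[i], mu)
      if (genes$strand[i] == "+") {
        idx <- (genes$start[i] + 1):genes$end[i]
        plus[idx] <- plus[idx] + cnt
      } else {
        idx <- genes$end[i]:(genes$start[i] + 1)   # decreasing genome pos
        minus[idx] <- minus[idx] + cnt
      }
    }
    samples[[s]] <- list(
      condition = conditions[s], replicate = reps[s], lib = lib_factors[s],
      plus = IRanges::RleList(chrSim = S4Vectors::Rle(plus)),
      minus = IRanges::RleList(chrSim = S4Vectors::Rle(minus))
    )
  }
  truth <- data.frame(
    gene_id = genes$gene_id,
    k_init = genes$k_init, k_pre = genes$k_pre, k_rel = genes$k_rel,
    k_elong = genes$k_elong,
    p_control = p_c, b_control = b_c,
    p_treatment = p_t, b_treatment = b_t,
    fc_kinit = fc_kinit, fc_krel = fc_krel,
    fc_p = p_t / p_c, fc_b = b_t / b_c,
    stringsAsFactors = FALSE
  )
  list(samples = samples, genes = genes, truth = truth, scale = scale,
       seed = seed, chrom_len = chrom_len)
}

#' Write a simulated dataset as standard files
#'
#' Emits one bedGraph per strand per sample, a BED6 annotation,
#' differential-expression gene lists derived from the generating fold
#' changes, the truth table as TSV, and a manifest (YAML) listing every
#' path and the seeds used. Files round-trip bit-identically through the
#' package's readers.
#'
#' @param sim Output of \code{\link{generate_condition_pair}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_tracks <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(p) { paths[[length(paths) + 1]] <<- p; p }

  rle_to_granges <- function(rlelist) {
    grs <- lapply(names(rlelist), function(ch) {
      x <- rlelist[[ch]]
      ends <- cumsum(S4Vectors::runLength(x))
      vals <- S4Vectors::runValue(x)
      keep <- vals > 0
      GenomicRanges::GRanges(
        ch,
        IRanges::IRanges(end = ends[keep],
                         width = S4Vectors::runLength(x)[keep]),
        score = vals[keep])
    })
    do.call(c, grs)
  }

  for (s in sim$samples) {
    base <- sprintf("%s_rep%d", s$condition, s$replicate)
    for (strand in c("plus", "minus")) {
      gr <- rle_to_granges(s[[strand]])
      p <- file.path(out_dir, sprintf("%s_%s.bedGraph", base, strand))
      rtracklayer::export(gr, add(p), format = "bedGraph")
    }
  }
  bed <- data.frame(sim$genes$chrom, sim$genes$start, sim$genes$end,
                    sim$genes$gene_id, rep(0L, nrow(sim$genes)),
                    sim$genes$strand)
  bed_path <- add(file.path(out_dir, "genes.bed"))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  repressed <- sim$truth$gene_id[sim$truth$fc_b < 1]
  activated <- sim$truth$gene_id[sim$truth$fc_b > 1 &
                                   (sim$truth$fc_kinit != 1 |
                                      sim$truth$fc_krel != 1)]
  writeLines(repressed, add(file.path(out_dir, "repressed_genes.txt")))
  writeLines(activated, add(file.path(out_dir, "activated_genes.txt")))
  write_tsv(sim$truth, add(file.path(out_dir, "truth.tsv")))

  manifest <- list(seed = sim$seed, scale = sim$scale,
                   chrom_len = sim$chrom_len, files = unlist(paths))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
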