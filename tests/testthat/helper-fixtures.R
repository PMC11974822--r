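# Shared fixtures and independent oracles, built in code.

# Brute-force pause-window oracle: enumerate every candidate window.
brute_force_window <- function(signal, search_len, window) {
  s <- numeric(search_len)
  k <- min(length(signal), search_len)
  if (k > 0) s[seq_len(k)] <- signal[seq_len(k)]
  best_off <- 0L
  best_sum <- -Inf
  for (off in 0:(search_len - window)) {
    w <- sum(s[(off + 1):(off + window)])
    if (w > best_sum) {           # strict: keeps the first (most proximal)
      best_sum <- w
      best_off <- off
    }
  }
  list(start = best_off, end = best_off + window, sum = best_sum)
}

# Occupancy-scaled density records built directly from p and b vectors.
make_scaled_records <- function(gene_id, p, b, condition = "control") {
  d <- data.frame(gene_id = gene_id, pause_sum = p, body_mean = b,
                  p_occ = p, b_occ = b, clipped_occupancy = FALSE,
                  condition = condition, stringsAsFactors = FALSE)
  attr(d, "scaled") <- TRUE
  d
}

# Exact forward model: densities in two conditions from control rates
# and fold changes in k_init / k_rel (k_pre, k_elong fixed).
forward_densities <- function(k_init, k_pre, k_rel, k_elong,
                              fc_kinit = 1, fc_krel = 1) {
  p_c <- k_init / (k_pre + k_rel)
  b_c <- k_rel / k_elong * p_c
  krel_t <- k_rel * fc_krel
  p_t <- k_init * fc_kinit / (k_pre + krel_t)
  b_t <- krel_t / k_elong * p_t
  list(p_c = p_c, b_c = b_c, p_t = p_t, b_t = b_t,
       fc_p = p_t / p_c, fc_b = b_t / b_c)
}

# Tiny deterministic two-gene annotation on one chromosome.
tiny_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chrT",
    start = c(100L, 4000L),
    end = c(3000L, 7000L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
}
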