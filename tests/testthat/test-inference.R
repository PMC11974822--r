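test_that("initiation targets are clamped into the interior of the bounds", {
  cl <- clamp_initiation_fold_change(0.18, 0.40, 0.25)
  expect_equal(cl$assigned, 0.25)
  expect_false(cl$clamped)

  cl <- clamp_initiation_fold_change(0.10, 0.20, 0.25)
  expect_equal(cl$assigned, 0.19)   # 0.95 * upper bound
  expect_true(cl$clamped)

  cl <- clamp_initiation_fold_change(0.30, 0.50, 0.25)
  expect_equal(cl$assigned, 0.315)  # 1.05 * lower bound
  expect_true(cl$clamped)

  # vectorized, and never exactly at a bound after clamping
  cl <- clamp_initiation_fold_change(c(0.1, 0.3), c(0.2, 0.5), 0.25)
  expect_equal(cl$assigned, c(0.19, 0.315))
  expect_true(all(cl$assigned > c(0.1, 0.3) & cl$assigned < c(0.2, 0.5)))

  # an offset wide enough to cross the other bound is an error
  expect_error(clamp_initiation_fold_change(0.19, 0.20, 0.25, offset = 0.2),
               "crosses")
  expect_error(clamp_initiation_fold_change(0.2, 0.1, 0.25), "lower <= upper")
})

test_that("anchored inference recovers the termination/release ratio", {
  # worked single-gene case: bounds (0.15, 0.3) contain the 0.25 target
  fc <- data.frame(gene_id = "g1", fc_p = 0.3, fc_b = 0.15,
                   fc_krel = 0.5, fc_kinit_lower = 0.15,
                   fc_kinit_upper = 0.3, stringsAsFactors = FALSE)
  res <- infer_termination_ratio_genomewide(fc, target_fc_kinit = 0.25)
  expect_equal(res$per_gene$ratio, 2)
  expect_equal(res$summary$median, 2)

  # noise-free forward model at r = 6.7 with the matching anchor:
  # every gene returns exactly the generating ratio
  set.seed(71)
  n <- 200
  k_rel <- rlnorm(n, log(0.86), 1)
  k_init <- rlnorm(n, log(0.5), 1)
  # pause release must itself change per gene: with fc_krel = 1 the
  # pause and body fold changes coincide and the ratio is undefined
  fc_krel <- rlnorm(n, 0, 0.4)
  fw <- forward_densities(k_init, 6.7 * k_rel, k_rel, 2000,
                          fc_kinit = 0.25, fc_krel = fc_krel)
  bounds <- fold_change_initiation_bounds(fw$fc_p, fw$fc_b)
  expect_equal(fw$fc_b / fw$fc_p, fc_krel, tolerance = 1e-12)
  fc <- data.frame(gene_id = paste0("g", 1:n), fc_p = fw$fc_p,
                   fc_b = fw$fc_b, fc_krel = fw$fc_b / fw$fc_p,
                   fc_kinit_lower = bounds$lower,
                   fc_kinit_upper = bounds$upper,
                   stringsAsFactors = FALSE)
  res <- infer_termination_ratio_genomewide(fc, target_fc_kinit = 0.25)
  expect_equal(res$per_gene$ratio, rep(6.7, n), tolerance = 1e-9)
  expect_equal(res$summary$median, 6.7, tolerance = 1e-9)
  expect_equal(res$summary$fraction_ratio_gt1, 1)
  expect_equal(res$summary$n_used, n)

  # genes whose assigned fc_kinit sits at a bound are sentinels,
  # excluded from the summary
  fc2 <- fc[1:2, ]
  fc2$fc_kinit_lower <- fc2$fc_kinit_upper <- fc2$fc_p  # collapsed bounds
  res2 <- infer_termination_ratio_genomewide(fc2, target_fc_kinit = 0.25)
  expect_equal(res2$summary$n_used, 0)
  expect_equal(res2$summary$n_undefined_boundary, 2)
  expect_error(infer_termination_ratio_genomewide(fc[0, ]), "empty")
})

test_that("absolute rate report inverts known occupancies", {
  ctl <- make_scaled_records("g1", 0.5 / 1.95, 0.25 / 2000 * 0.5 / 1.95)
  trt <- make_scaled_records("g1", 0.5 / 1.95, 0.25 / 2000 * 0.5 / 1.95,
                             condition = "treatment")
  rr <- absolute_rate_report(ctl, trt, k_elong = 2000, r = 6.8)
  expect_equal(rr$krel_control, 0.25, tolerance = 1e-12)
  expect_equal(rr$kpre, 1.7, tolerance = 1e-12)
  expect_equal(rr$kinit_control, 0.5, tolerance = 1e-12)
  expect_equal(rr$spacing_control, 31200, tolerance = 1e-3)
  expect_equal(rr$half_life_control, 60 * log(2) / 1.95, tolerance = 1e-9)
  expect_equal(rr$fc_krel, 1)

  # r = 0: initiation reduces to the body flux
  rr0 <- absolute_rate_report(ctl, trt, k_elong = 2000, r = 0)
  expect_equal(rr0$kinit_control, 2000 * ctl$b_occ)

  # unscaled records are rejected
  bad <- ctl; attr(bad, "scaled") <- NULL
  expect_error(absolute_rate_report(bad, trt), "occupancy-scaled")
})

test_that("doubling the elongation rate doubles rates, halves half-lives", {
  set.seed(72)
  n <- 50
  ctl <- make_scaled_records(paste0("g", 1:n), runif(n, 0.01, 0.9),
                             runif(n, 1e-6, 1e-4))
  trt <- make_scaled_records(paste0("g", 1:n), runif(n, 0.01, 0.9),
                             runif(n, 1e-6, 1e-4), "treatment")
  r1 <- absolute_rate_report(ctl, trt, k_elong = 2000, r = 6.7)
  r2 <- absolute_rate_report(ctl, trt, k_elong = 4000, r = 6.7)
  expect_equal(r2$krel_control, 2 * r1$krel_control)
  expect_equal(r2$kpre, 2 * r1$kpre)
  expect_equal(r2$kinit_control, 2 * r1$kinit_control)
  expect_equal(r2$half_life_control, r1$half_life_control / 2)
  # fold changes and bounds are untouched
  expect_equal(r2$fc_krel, r1$fc_krel)
  expect_equal(r2$fc_kinit_lower, r1$fc_kinit_lower)
})

test_that("factor classification separates initiation from release", {
  set.seed(73)
  n <- 100
  k_rel <- rlnorm(n, log(0.86), 0.8)
  k_init <- rlnorm(n, log(0.5), 0.8)

  mk_fc <- function(fc_kinit, fc_krel) {
    fw <- forward_densities(k_init, 6.7 * k_rel, k_rel, 2000,
                            fc_kinit, fc_krel)
    bounds <- fold_change_initiation_bounds(fw$fc_p, fw$fc_b)
    data.frame(gene_id = paste0("g", 1:n), fc_p = fw$fc_p,
               fc_b = fw$fc_b, fc_krel = fw$fc_b / fw$fc_p,
               fc_kinit_lower = bounds$lower,
               fc_kinit_upper = bounds$upper, stringsAsFactors = FALSE)
  }

  # initiation factor: k_init halved, k_rel untouched
  cl <- classify_factor_mechanism(mk_fc(0.5, 1), paste0("g", 1:n),
                                  "repressed")
  expect_equal(cl$fraction_kinit_bounds_lt1, 1)
  expect_equal(cl$call, "initiation")
  expect_equal(median(cl$ecdf_tables$fc_krel$value), 1, tolerance = 1e-9)

  # pause-release factor: k_rel doubled
  cl <- classify_factor_mechanism(mk_fc(1, 2), paste0("g", 1:n),
                                  "activated")
  expect_equal(cl$fraction_krel_in_direction, 1)
  expect_equal(cl$call, "pause_release")

  # no change: every ECDF degenerate at 1
  cl <- classify_factor_mechanism(mk_fc(1, 1), paste0("g", 1:n),
                                  "activated")
  expect_true(all(cl$ecdf_tables$fc_krel$value == 1))
  expect_equal(cl$fraction_kinit_bounds_straddle, 1)
  expect_error(classify_factor_mechanism(mk_fc(1, 1), character(0),
                                         "activated"), "empty")
})

test_that("summaries are invariant to gene order and global scaling", {
  set.seed(74)
  n <- 80
  p <- runif(n, 0.01, 0.8); b <- runif(n, 1e-6, 1e-4)
  p2 <- pmin(p * runif(n, 0.5, 2), 0.99); b2 <- b * runif(n, 0.5, 2)
  ids <- paste0("g", 1:n)
  r1 <- absolute_rate_report(make_scaled_records(ids, p, b),
                             make_scaled_records(ids, p2, b2, "treatment"))
  perm <- sample(n)
  r2 <- absolute_rate_report(make_scaled_records(ids[perm], p[perm], b[perm]),
                             make_scaled_records(ids, p2, b2, "treatment"))
  expect_equal(rate_summary(r1), rate_summary(r2))

  # a common density scale in both conditions leaves all fold changes
  # and the termination/release ratio untouched
  s <- 3.7
  fc1 <- density_fold_changes(
    data.frame(gene_id = ids, pause_sum = p, body_mean = b),
    data.frame(gene_id = ids, pause_sum = p2, body_mean = b2))
  fc2 <- density_fold_changes(
    data.frame(gene_id = ids, pause_sum = s * p, body_mean = s * b),
    data.frame(gene_id = ids, pause_sum = s * p2, body_mean = s * b2))
  expect_equal(fc1$fc_krel, fc2$fc_krel)
  expect_equal(fc1$fc_kinit_lower, fc2$fc_kinit_lower)
})
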