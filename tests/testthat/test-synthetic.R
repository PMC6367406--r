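null_spec <- function(rho, n = 200L, genes = 20L, seed = 3L)
  cohort_spec(n_per_subtype = c("LAR" = n / 2, "basal" = n / 2,
                                "CLDN-low" = 0, "CLDN-high" = 0),
              modules = list(module_spec("m1", "other",
                                         sprintf("G%02d", seq_len(genes)),
                                         rho = rho)),
              n_noise_genes = 0L, batch_count = 1L, batch_shift = 0,
              noise_sd = 1.0, seed = seed)

test_that("null model genes have mean ~0 within Monte-Carlo error", {
  sim <- generate_expression(null_spec(rho = 0, n = 400L), emit = "log2")
  mu <- rowMeans(sim$expression$values)
  se <- apply(sim$expression$values, 1L, sd) / sqrt(400)
  expect_true(all(abs(mu) <= 4 * se))
})

test_that("latent-factor construction hits the target correlation", {
  sim <- generate_expression(null_spec(rho = 0.8), emit = "log2")
  r <- cor(t(sim$expression$values))
  med <- median(r[upper.tri(r)])
  expect_gt(med, 0.7)
  expect_lt(med, 0.9)
})

test_that("generation is deterministic given the seed", {
  a <- generate_expression(cohort_spec(seed = 5L))
  b <- generate_expression(cohort_spec(seed = 5L))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth, b$truth)
  c <- generate_expression(cohort_spec(seed = 6L))
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("module gene lists must be disjoint", {
  mods <- list(module_spec("m1", "other", c("A", "B")),
               module_spec("m2", "other", c("B", "C")))
  expect_error(cohort_spec(modules = mods), "B")
})

test_that("default cohort carries the planted two-layer structure", {
  sim <- generate_expression(cohort_spec(seed = 9L))
  expect_identical(sort(unique(sim$truth$cellular)),
                   sort(c("LAR", "basal", "CLDN-low", "CLDN-high")))
  expect_equal(table(sim$truth$cellular)[["basal"]], 252L)
  # immune layer roughly at the configured 52% and independent of subtype
  expect_equal(mean(sim$truth$immune == "IM+"), 0.52, tolerance = 0.15)
  expect_true(all(c("CLDN3", "CLDN4", "CLDN7") %in%
                    sim$expression$gene_ids))
  expect_identical(sim$expression$scale_flag, "raw")
  expect_true(all(sim$expression$values > 0))
})

test_that("survival generator respects its boundary contracts", {
  truth <- data.frame(sample_id = sprintf("S%d", 1:50),
                      cellular = rep(c("A", "B"), 25),
                      immune = "IM-", batch = "b1")
  heavy <- generate_survival(truth, c(A = 0.01, B = 0.01),
                             censor_rate = 1e6, horizon_months = 120,
                             seed = 1, label = "cellular")
  expect_true(all(heavy$event == 0L))

  zero <- generate_survival(truth, c(A = 0.01, B = 0.01),
                            censor_rate = 0.01, horizon_months = 0,
                            seed = 1, label = "cellular")
  expect_true(all(zero$rfs_time == 0) && all(zero$event == 0L))

  expect_error(generate_survival(truth, c(A = 0.01), seed = 1,
                                 label = "cellular"), "B")
})

test_that("exponential survival recovers a known hazard ratio", {
  truth <- data.frame(sample_id = sprintf("S%d", 1:1000),
                      cellular = rep(c("fast", "slow"), each = 500),
                      immune = "IM-", batch = "b1")
  clin <- generate_survival(truth, c(fast = 0.02, slow = 0.01),
                            censor_rate = 0, horizon_months = Inf,
                            seed = 21, label = "cellular")
  fit <- cox_binary_hr(clin$rfs_time, clin$event,
                       ifelse(truth$cellular == "fast", 1, 0))
  expect_gt(fit$hr, 1.6)
  expect_lt(fit$hr, 2.5)
})
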