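test_that("specific binding is replicate-averaged total minus nonspecific", {
  d <- data.frame(conc_nM = c(1, 1, 2, 2),
                  total = c(98, 102, 110, 110),
                  nonspecific = c(9, 11, 10, 10))
  sb <- specific_binding(d)
  expect_equal(sb$specific[sb$conc_nM == 1], 90)
  expect_equal(sb$specific[sb$conc_nM == 2], 100)

  flat <- data.frame(conc_nM = 1:3, total = 5, nonspecific = 5)
  expect_equal(specific_binding(flat)$specific, rep(0, 3))

  neg <- data.frame(conc_nM = 1, total = 4, nonspecific = 5)
  sb <- specific_binding(neg)
  expect_equal(sb$specific, -1)
  expect_equal(sb$specific_floored, 0)
  expect_true(sb$negative_flag)

  miss <- data.frame(conc_nM = c(1, 2), total = c(10, 20),
                     nonspecific = c(1, NA))
  expect_error(specific_binding(miss), "2 nM")
})

test_that("noise-free one-site curves are recovered to numerical tolerance", {
  L <- c(0.1, 0.25, 0.5, 1, 2, 5)
  fit <- fit_one_site(L, 100 * L / (1 + L))
  expect_equal(fit$bmax, 100, tolerance = 1e-6)
  expect_equal(fit$kd, 1, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-12)
  expect_false(fit$poorly_constrained)

  # half-saturation model identity through predict()
  expect_equal(predict(fit, data.frame(L = fit$kd)), fit$bmax / 2,
               tolerance = 1e-6)
})

test_that("published-scale parameter sets round-trip through generator and fit", {
  params <- list(cortex_control = c(578.6, 1.01),
                 hippocampus_control = c(701.6, 0.86),
                 hippocampus_caffmtf = c(971.5, 1.16))
  for (p in params) {
    d <- generate_saturation_dataset(p[1], p[2], noise_sd = 0, seed = 1)
    fit <- fit_one_site(specific_binding(d))
    expect_equal(fit$bmax, p[1], tolerance = 1e-3)
    expect_equal(fit$kd, p[2], tolerance = 1e-3)
  }
})

test_that("fit is scale-equivariant and bounded by the data", {
  L <- exp(seq(log(0.09), log(4.95), length.out = 12))
  B <- 350 * L / (0.9 + L)
  f1 <- fit_one_site(L, B)
  f2 <- fit_one_site(L, 10 * B)
  expect_equal(f2$bmax, 10 * f1$bmax, tolerance = 1e-6)
  expect_equal(f2$kd, f1$kd, tolerance = 1e-6)
  expect_gte(f1$bmax, max(B))
  expect_true(all(diff(predict(f1, data.frame(L = seq(0.1, 100, 1)))) > 0))
})

test_that("fitted parameters are unbiased as noise shrinks", {
  est <- function(noise) {
    fits <- sapply(1:30, function(i) {
      d <- generate_saturation_dataset(500, 1, noise_sd = noise,
                                       seed = 700 + i)
      coef(fit_one_site(specific_binding(d)))
    })
    rowMeans(fits)
  }
  hi <- est(20); lo <- est(2)
  expect_lt(abs(lo[["bmax"]] - 500), abs(hi[["bmax"]] - 500) + 2)
  expect_lt(abs(lo[["bmax"]] - 500), 2)
  expect_lt(abs(lo[["kd"]] - 1), 0.02)
})

test_that("degenerate fit inputs are rejected or flagged", {
  expect_error(fit_one_site(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_one_site(c(1, 2, 3), c(-1, -2, -3)), "positive")
  # Kd far above the design span: flagged as poorly constrained
  L <- c(0.1, 0.2, 0.4)
  f <- fit_one_site(L, 1000 * L / (50 + L))
  expect_true(f$poorly_constrained)
})

test_that("dpm conversion follows the specific-activity identity", {
  expect_equal(dpm_to_fmol(2.22 * 80.2, 80.2, 1, 1), 1)
  expect_equal(dpm_to_fmol(1000, 80.2, 1, 2), dpm_to_fmol(1000, 80.2, 1, 1) / 2)
  expect_equal(dpm_to_fmol(1000, 80.2, 0.5, 1),
               2 * dpm_to_fmol(1000, 80.2, 1, 1))
  expect_error(dpm_to_fmol(1, protein_mg = 0), "protein")
  expect_error(dpm_to_fmol(1, efficiency = 1.5), "efficiency")
})

test_that("group comparison of fits uses assay repeats as units", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                  bmax = c(500, 510, 505, 800, 805, 810, 501, 503, 502),
                  kd = rep(c(1, 1.1, 0.9), 3))
  cmp <- compare_binding(d)
  expect_equal(nrow(cmp), 6)  # 3 pairs x 2 parameters
  ab <- cmp[cmp$group1 == "a" & cmp$group2 == "b" & cmp$parameter == "bmax", ]
  expect_lt(ab$p, 0.001)
  ac <- cmp[cmp$group1 == "a" & cmp$group2 == "c" & cmp$parameter == "bmax", ]
  expect_gt(ac$p, 0.1)
  expect_error(compare_binding(data.frame(group = c("a", "b"), bmax = 1:2,
                                          kd = 1:2)), "two replicate")

  ident <- compare_binding(data.frame(group = rep(c("a", "b"), each = 3),
                                      bmax = rep(c(1, 2, 3), 2),
                                      kd = rep(c(1, 2, 3), 2)))
  expect_true(all(ident$p == 1))
})

test_that("replicate-level fits detect a designed group difference", {
  set.seed(61)
  hits <- 0
  for (r in 1:15) {
    fits <- lapply(c(a = 788, b = 898), function(bm) {
      lapply(1:3, function(i)
        fit_one_site(specific_binding(generate_saturation_dataset(
          bm, 0.95, noise_sd = 15, seed = r * 100 + i +
            round(bm)))))
    })
    cmp <- compare_binding(fits)
    p <- cmp$p[cmp$parameter == "bmax"]
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 15, 0.7)
})

test_that("the fitted-model object supports the standard S3 interface", {
  d <- generate_saturation_dataset(600, 1.1, noise_sd = 5, seed = 8)
  fit <- fit_one_site(specific_binding(d))
  expect_s3_class(fit, "one_site_fit")
  expect_named(coef(fit), c("bmax", "kd"))
  expect_length(fitted(fit), 12)
  expect_equal(fitted(fit) + residuals(fit), fit$data$B)
  expect_output(print(fit), "Bmax")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
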