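test_that("IMR chart matches hand arithmetic on a small series", {
  ch <- imr_chart(c(200, 210, 190, 220))
  expect_equal(ch$xbar, 205)
  expect_equal(ch$mrbar, 20)
  expect_equal(ch$ucl_x, 258.2)
  expect_equal(ch$lcl_x, 151.8)
  expect_equal(ch$ucl_mr, 65.34)
  expect_length(ch$out_of_control_indices, 0L)
})

test_that("IMR limits collapse for a constant series", {
  ch <- imr_chart(rep(98, 10))
  expect_equal(ch$mrbar, 0)
  expect_equal(ch$ucl_x, 98)
  expect_equal(ch$lcl_x, 98)
  expect_length(ch$out_of_control_indices, 0L)
  expect_error(imr_chart(98), "at least 2")
})

test_that("the 2.66 constant agrees with 3-sigma limits via d2 = 1.128", {
  # sigma_hat = mrbar/1.128; 3*sigma_hat = (3/1.128)*mrbar = 2.6596*mrbar
  expect_equal(3 / 1.128, 2.66, tolerance = 0.004)
  set.seed(8)
  x <- rnorm(100, 200, 20)
  ch <- imr_chart(x)
  expect_equal(ch$ucl_x, ch$xbar + 3 * ch$mrbar / 1.128,
               tolerance = 0.004 * 3 * ch$mrbar)
})

test_that("out-of-control shadowing points come from the complex population", {
  # a clearly separated two-population mixture, as in the shadowing data
  cfg <- shadowing_config(n_patients = 100L, graph = NULL,
                          needs = need_probabilities(0.4, 0.2, 0, 0),
                          population_params = list(
                            standard = c(mean = 185, sd = 40),
                            complex = c(mean = 330, sd = 70)),
                          seed = 14)
  rec <- generate_shadowing(cfg)
  ch <- imr_chart(rec$total_minutes)
  ooc_x <- which(rec$total_minutes > ch$ucl_x |
                   rec$total_minutes < ch$lcl_x)
  expect_gt(length(ooc_x), 0L)
  expect_true(all(rec$population[ooc_x] == "complex"))
  expect_true(all(ooc_x %in% ch$out_of_control_indices))
})

test_that("capability reproduces the normal-model quantities", {
  cap <- capability(215.7, usl = 150, sigma = 67)
  expect_equal(cap$z_bench, (150 - 215.7) / 67)
  expect_equal(round(cap$z_bench, 2), -0.98)
  expect_equal(cap$p_above_usl, pnorm(0.980597, lower.tail = TRUE),
               tolerance = 1e-5)
  expect_equal(cap$p_above_usl, 0.8366, tolerance = 1e-4)
  expect_equal(cap$sql, cap$z_bench + 1.5)
})

test_that("capability is scale equivariant", {
  a <- capability(215.7, usl = 150, sigma = 67)
  b <- capability(2157, usl = 1500, sigma = 670)
  expect_equal(a$z_bench, b$z_bench)
  expect_equal(a$sql, b$sql)
  expect_equal(a$p_above_usl, b$p_above_usl)
})

test_that("capability from data uses overall or within sigma", {
  set.seed(2)
  x <- rnorm(300, 200, 30)
  co <- capability(x, usl = 150)
  expect_equal(co$mu_hat, mean(x))
  expect_equal(co$sigma_hat, sd(x))
  cw <- capability(x, usl = 150, sigma = "within")
  expect_equal(cw$sigma_hat, mean(abs(diff(x))) / 1.128)
  expect_error(capability(100, usl = 150, sigma = -1), "> 0")
})

test_that("sigma quality level is the exact 1.5-shift affine map", {
  expect_identical(sql_from_zbench(-0.78), 0.72)
  expect_identical(sql_from_zbench(0), 1.5)
  expect_identical(sql_from_zbench(1.17), 2.67)
})

test_that("required sample size follows the ceiling formula", {
  expect_identical(required_sample_size(1.96, 67, 30), 20L)
  expect_identical(required_sample_size(1.96, 0, 30), 1L)
  expect_identical(required_sample_size(1.96, 5.47, 2), 29L)
  expect_error(required_sample_size(1.96, 67, 0), "> 0")
  expect_error(required_sample_size(1.96, -1, 30), ">= 0")
})

test_that("flagged records classify by definition", {
  rec <- data.frame(needs_narcotics = c(TRUE, FALSE, FALSE),
                    needs_equipment = c(FALSE, TRUE, FALSE),
                    needs_supplies = FALSE,
                    gets_addon = c(FALSE, FALSE, FALSE),
                    total_minutes = c(100, 300, 120))
  cl <- classify_populations(rec)
  expect_equal(cl$method, "flags")
  expect_equal(as.character(cl$labels),
               c("standard", "complex", "standard"))
})

test_that("the mixture split recovers a planted 80/20 mixture", {
  set.seed(31)
  n <- 500L
  z <- runif(n) < 0.2
  x <- ifelse(z, rnorm(n, 350, 60), rnorm(n, 180, 30))
  cl <- classify_populations(x)
  expect_equal(cl$method, "mixture")
  m <- cl$mixture$means
  expect_lt(abs(m[1] - 180) / 180, 0.10)
  expect_lt(abs(m[2] - 350) / 350, 0.10)
  expect_gt(mean(cl$labels[z] == "complex"), 0.9)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(5)
  x <- c(rnorm(400, 180, 30), rnorm(100, 350, 60))
  ours <- classify_populations(x)$mixture
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
})

test_that("degenerate duration data is reported, not mislabelled", {
  expect_warning(cl <- classify_populations(rep(120, 10)), "degenerate")
  expect_true(cl$mixture$degenerate)
  expect_true(all(cl$labels == "standard"))
  expect_error(classify_populations(c(1, 2, 3)), "at least 4")
})
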