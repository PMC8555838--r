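test_that("variance table mirrors the decomposition exactly", {
  set.seed(1)
  u <- rnorm(9); u <- u / sqrt(sum(u^2))
  w <- rnorm(120); w <- w - mean(w)
  fit1 <- pma(outer(w, u), cutoff = NULL)
  vt1 <- variance_table(fit1, n_show = 5)
  expect_equal(vt1$ev_pct[1], 100, tolerance = 1e-8)
  expect_lt(max(vt1$ev_pct[-1]), 1e-8)

  sim <- simulate_cohort(tiny_config())
  fit <- pma(sim$cohort)
  vt <- variance_table(fit, n_show = ncol(fit$rotation))
  expect_equal(vt$ev_pct, 100 * fit$ev_fraction, ignore_attr = TRUE)
  expect_true(all(diff(vt$cum_ev_pct) >= -1e-12))
  expect_equal(vt$cum_ev_pct[nrow(vt)], 100, tolerance = 1e-8)
  expect_true(all(vt$description == ""))
})

test_that("point-light exports project the declared plane and round-trip", {
  sim <- simulate_cohort(tiny_config())
  fit <- pma(sim$cohort)
  pmi <- pm_trajectory(fit, 1, signer_id = "s1")
  keys <- extreme_frames(fit, 1)
  keys <- pmin(keys, nrow(pmi$trajectory))  # keys within this signer's rows
  json <- withr::local_tempfile(fileext = ".json")
  export_pld(pmi, json, plane = "frontal", key_frames = keys)
  back <- read_pld(json)
  expect_equal(back$axes, c("x", "y"))     # frontal drops anteroposterior z
  expect_equal(length(back$markers), length(unique(
    sub("_[xyz]$", "", colnames(pmi$trajectory)))))
  expect_equal(back$h[, "m02_h"],
               unname(pmi$trajectory[, "m02_x"]), tolerance = 1e-12)
  expect_equal(back$v[, "m02_v"],
               unname(pmi$trajectory[, "m02_y"]), tolerance = 1e-12)
  expect_equal(unlist(back$key_frames), keys[c("min", "max")])
  # csv flavour and the sagittal plane (z horizontal, y vertical)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_pld(pmi, csv, plane = "sagittal")
  df <- read.csv(csv)
  expect_equal(df$m02_h, unname(pmi$trajectory[, "m02_z"]),
               tolerance = 1e-6)
})

test_that("pipeline configuration round-trips through yaml", {
  cfg <- pipeline_config(cohort = tiny_config(), cutoff = 5.5,
                         n_pms = 4, sim_mode = "signed")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, path)
  back <- read_pipeline_config(path)
  expect_equal(back, cfg)
})

test_that("the full pipeline runs, reports, and is deterministic", {
  cfg <- pipeline_config(cohort = tiny_config(seed = 31))
  out1 <- run_pipeline(cfg)
  expect_s3_class(out1$fit_common, "pma")
  expect_length(out1$fits_individual, 3)
  expect_equal(dim(out1$loo$angles), c(3, out1$n_pms))
  expect_length(out1$similarity, 3)
  expect_equal(length(out1$cross_projection$curve$mean), out1$n_pms)
  expect_true(all(out1$psd$psd >= 0))

  out2 <- run_pipeline(cfg)
  expect_identical(out1$fit_common$rotation, out2$fit_common$rotation)
  expect_identical(out1$fit_common$weights_filtered,
                   out2$fit_common$weights_filtered)
  expect_identical(out1$loo$angles, out2$loo$angles)
  expect_identical(lapply(out1$similarity, `[[`, "sim"),
                   lapply(out2$similarity, `[[`, "sim"))
  expect_identical(out1$cross_projection, out2$cross_projection)
})

test_that("identical-structure cohorts yield unit cross-projection", {
  cfg <- pipeline_config(cohort = tiny_config(snr_db = Inf,
                                              share_mode = "identical",
                                              seed = 32),
                         n_pms = 3)
  out <- run_pipeline(cfg)
  expect_equal(out$cross_projection$at_n_pms, 1, tolerance = 1e-8)
})

test_that("report files and the checksum manifest are written", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(cohort = tiny_config(seed = 33))
  out <- run_pipeline(cfg, output_dir = dir)
  expect_true(file.exists(file.path(dir, "variance_table.csv")))
  expect_true(file.exists(file.path(dir, "loo_angles.csv")))
  expect_true(file.exists(file.path(dir, "cross_projection.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_true(all(nchar(man$md5) == 32))
  vt <- read.csv(file.path(dir, "variance_table.csv"))
  expect_equal(vt$ev_pct, out$variance_table$ev_pct, tolerance = 1e-6)
})
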