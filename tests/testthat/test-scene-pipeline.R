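test_that("scene rendering is bitwise reproducible at a fixed seed", {
  fwd <- test_forward()
  sp <- scene_spec(shape = c(16, 24), noise_sigma = 5, poisson = TRUE,
                   seed = 12)
  s1 <- render_scene(sp, fwd)
  s2 <- render_scene(sp, fwd)
  expect_identical(s1$stack_fn$images, s2$stack_fn$images)
  sp2 <- sp; sp2$seed <- 13L
  s3 <- render_scene(sp2, fwd)
  expect_false(identical(s1$stack_fn$images, s3$stack_fn$images))
})

test_that("scene specification validates regions and domain", {
  expect_error(scene_spec(background = list(mu_a = 3, mu_s_prime = 1)),
               "domain")
  expect_error(scene_spec(regions = list(list(shape = "rect",
                                              rows = c(1, 2), cols = c(1, 2),
                                              mu_a = 0.1, mu_s_prime = 20))),
               "domain")
})

test_that("noise-free pipeline closure recovers each phantom patch to under 0.5%", {
  fwd <- test_forward()
  lut <- build_forward_lut(fwd, 1000L, 1000L)  # dense table for closure
  sp <- six_phantom_scene(patch_px = 40L, margin_px = 10L)
  scene <- render_scene(sp, fwd)
  ref <- render_scene(scene_spec(shape = sp$shape), fwd)  # calibration phantom
  regions <- lapply(sp$regions, function(r) list(rows = r$rows, cols = r$cols))
  names(regions) <- vapply(sp$regions, `[[`, "", "name")
  out <- run_pipeline(list(sample = scene$stack_fn, reference = ref$stack_fn,
                           model = lut, forward = fwd, regions = regions))
  truth <- attr(sp, "patch_props")
  expect_equal(out$report$region, truth$name)
  expect_true(all(abs(out$report$mean_mu_a - truth$mu_a) / truth$mu_a
                  < 0.005))
  expect_true(all(abs(out$report$mean_mu_s_prime - truth$mu_s_prime) /
                    truth$mu_s_prime < 0.005))
})

test_that("forest and lookup-table inversions agree on a shared synthetic scene", {
  fwd <- test_forward()
  lut <- test_lut()
  m <- fit_rfr(generate_training_set(fwd, 5e4, seed = 91), seed = 92)
  sp <- six_phantom_scene(patch_px = 30L, margin_px = 8L)
  scene <- render_scene(sp, fwd)
  ref <- render_scene(scene_spec(shape = sp$shape), fwd)
  regions <- lapply(sp$regions, function(r) list(rows = r$rows,
                                                 cols = r$cols))
  names(regions) <- vapply(sp$regions, `[[`, "", "name")
  base <- list(sample = scene$stack_fn, reference = ref$stack_fn,
               forward = fwd, regions = regions)
  out_lut <- run_pipeline(c(base, list(model = lut)))
  out_rfr <- run_pipeline(c(base, list(model = m)))
  # per-patch means of the two methods agree within the forest's
  # resolution at this reduced training scale (5e4 pairs); agreement
  # tightens with training size
  rel_a <- abs(out_rfr$report$mean_mu_a / out_lut$report$mean_mu_a - 1)
  rel_s <- abs(out_rfr$report$mean_mu_s_prime /
                 out_lut$report$mean_mu_s_prime - 1)
  expect_lt(max(rel_a), 0.25)
  expect_lt(max(rel_s), 0.1)
  # percentage-difference map between the two methods
  pd <- percentage_difference_map(out_rfr$maps$mu_a, out_lut$maps$mu_a)
  expect_equal(dim(pd), dim(out_lut$maps$mu_a))
  expect_true(all(is.finite(pd)))
})

test_that("flagged-pixel fraction grows with the noise level", {
  fwd <- test_forward()
  lut <- test_lut()
  fractions <- vapply(c(0, 20, 120), function(sig) {
    sp <- scene_spec(shape = c(40, 60),
                     background = list(mu_a = 0.3, mu_s_prime = 0.8),
                     noise_sigma = sig, seed = 3)
    scene <- render_scene(sp, fwd)
    ref <- render_scene(scene_spec(shape = c(40, 60), noise_sigma = sig,
                                   seed = 4), fwd)
    out <- run_pipeline(list(sample = scene$stack_fn,
                             reference = ref$stack_fn,
                             model = lut, forward = fwd))
    mean(out$maps$status != 0)
  }, numeric(1))
  expect_true(all(diff(fractions) >= 0))
  expect_equal(fractions[1], 0)
})

test_that("noisy acquisitions still recover patch means to a few percent", {
  fwd <- test_forward()
  lut <- test_lut()
  # Gaussian read noise at 1% of the planar signal level
  sp <- six_phantom_scene(patch_px = 40L, margin_px = 10L, noise_sigma = 6,
                          seed = 5)
  scene <- render_scene(sp, fwd)
  ref <- render_scene(scene_spec(shape = sp$shape, noise_sigma = 6,
                                 seed = 6), fwd)
  regions <- lapply(sp$regions, function(r) list(rows = r$rows, cols = r$cols))
  names(regions) <- vapply(sp$regions, `[[`, "", "name")
  out <- run_pipeline(list(sample = scene$stack_fn, reference = ref$stack_fn,
                           model = lut, forward = fwd, regions = regions))
  truth <- attr(sp, "patch_props")
  expect_true(all(abs(out$report$mean_mu_a - truth$mu_a) / truth$mu_a < 0.1))
  expect_true(all(abs(out$report$mean_mu_s_prime - truth$mu_s_prime) /
                    truth$mu_s_prime < 0.03))
})

test_that("the pipeline accepts file-based configs and writes its outputs", {
  fwd <- test_forward()
  lut <- test_lut()
  dir <- withr::local_tempdir()
  sp <- scene_spec(shape = c(20, 30),
                   background = list(mu_a = 0.05, mu_s_prime = 1.5))
  scene <- render_scene(sp, fwd)
  ref <- render_scene(scene_spec(shape = c(20, 30)), fwd)
  spath <- file.path(dir, "sample.tif")
  rpath <- file.path(dir, "ref.tif")
  write_phase_stack(scene$stack_fn, spath)
  write_phase_stack(ref$stack_fn, rpath)
  mpath <- file.path(dir, "lut.rds")
  fpath <- file.path(dir, "fwd.rds")
  save_artifact(lut, mpath)
  save_artifact(fwd, fpath)
  out_dir <- file.path(dir, "maps")
  cfg <- list(sample = spath, reference = rpath, model = mpath,
              forward = fpath, out_dir = out_dir,
              regions = list(all = list(rows = c(1, 20), cols = c(1, 30))))
  out <- run_pipeline(cfg)
  expect_lt(abs(out$report$mean_mu_a - 0.05) / 0.05, 0.02)
  expect_true(file.exists(file.path(out_dir, "mu_a.tif")))
  expect_true(file.exists(file.path(out_dir, "report.csv")))
  expect_true(file.exists(file.path(out_dir, "report.json")))
  # written maps round-trip through the scale sidecar
  m <- read_map_tiff(file.path(out_dir, "mu_s_prime.tif"))
  expect_equal(as.numeric(m), as.numeric(out$maps$mu_s_prime),
               tolerance = 1e-6)
  expect_error(run_pipeline(list(sample = spath)), "missing")
  expect_error(run_pipeline(list(sample = spath, reference = rpath,
                                 model = file.path(dir, "nope.rds"),
                                 forward = fpath)), "artifact")
})

test_that("artifacts and stacks survive a save/load round trip", {
  dir <- withr::local_tempdir()
  lut <- test_lut()
  p <- file.path(dir, "lut.rds")
  save_artifact(lut, p)
  back <- load_artifact(p)
  expect_identical(back$R0, lut$R0)
  expect_s3_class(back, "sfdi_lut")
  # version guard refuses foreign or stale archives
  saveRDS(list(format = "sfdiops-artifact", version = 99L, object = 1), p)
  expect_error(load_artifact(p), "version")
  saveRDS(42, p)
  expect_error(load_artifact(p), "artifact")
  # phase stacks via multi-page float TIFF with sidecar
  st <- phase_stack(replicate(3, matrix(runif(12, 0, 4000), 3, 4),
                              simplify = FALSE),
                    spatial_frequency = 0.2, pixel_pitch = 0.05)
  sp <- file.path(dir, "stack.tif")
  write_phase_stack(st, sp)
  st2 <- read_phase_stack(sp)
  expect_equal(st2$images, st$images, tolerance = 1e-6)
  expect_equal(st2$spatial_frequency, 0.2)
  expect_equal(st2$pixel_pitch, 0.05)
  # float maps with values far above 1 keep their physical units
  mp <- file.path(dir, "map.tif")
  mm <- matrix(c(0.2, 7.3, 14.9, NA), 2, 2)
  write_map_tiff(mm, mp)
  back <- read_map_tiff(mp)
  expect_equal(as.numeric(back), as.numeric(mm), tolerance = 1e-6)
})
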