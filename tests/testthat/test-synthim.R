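test_that("von Mises sampler hits its distributional endpoints", {
  withr::with_seed(42, {
    u <- rvonmises(2000, 1, 0)
    expect_true(all(u >= 0 & u < 2 * pi))
    # uniform: circular resultant near zero
    expect_lt(sqrt(mean(cos(u))^2 + mean(sin(u))^2), 0.06)
    v <- rvonmises(100, 1.3, Inf)
    expect_equal(v, rep(1.3, 100))
    w <- rvonmises(3000, pi / 3, 8)
    # circular mean close to mu at high concentration
    expect_lt(abs(atan2(mean(sin(w)), mean(cos(w))) - pi / 3), 0.05)
  })
})

test_that("axial orientations live on [0, pi) and concentrate around mu", {
  withr::with_seed(7, {
    th <- raxial(2000, 2.5, 50)
    expect_true(all(th >= 0 & th < pi))
    # axial mean via doubled angles
    m <- atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2
    expect_lt(abs((m - 2.5 + pi / 2) %% pi - pi / 2), 0.02)
  })
})

test_that("rendering is deterministic and respects the canvas bound", {
  p <- cell_phantom(semi_major = 30, semi_minor = 20, n_fibres = 25,
                    orientation_kappa = 2, fibre_width = 2)
  r1 <- render_cell(p, seed = 5, canvas = c(80, 80))
  r2 <- render_cell(p, seed = 5, canvas = c(80, 80))
  expect_identical(r1$image, r2$image)
  expect_identical(r1$mask, r2$mask)
  r3 <- render_cell(p, seed = 6, canvas = c(80, 80))
  expect_false(identical(r1$image, r3$image))
  expect_error(render_cell(p, 1, canvas = c(50, 50)), "larger than canvas")
  np <- nucleus_phantom(semi_major = 20, semi_minor = 15, n_foci = 5,
                        focus_radius = 2)
  n1 <- render_nucleus(np, seed = 3, canvas = c(64, 64))
  n2 <- render_nucleus(np, seed = 3, canvas = c(64, 64))
  expect_identical(n1$image, n2$image)
  expect_error(render_nucleus(np, 1, canvas = c(30, 30)),
               "larger than canvas")
})

test_that("isotropic and parallel fibre textures bracket the anisotropy scale", {
  iso <- render_cell(cell_phantom(semi_major = 45, semi_minor = 32,
                                  n_fibres = 200, orientation_kappa = 0,
                                  fibre_width = 2, noise_sd = 0.02),
                     seed = 11, canvas = c(128, 128))
  a_iso <- fibre_anisotropy(iso$image, iso$mask)
  expect_lt(a_iso$value, 0.15)
  par <- render_cell(cell_phantom(semi_major = 45, semi_minor = 32,
                                  n_fibres = 60, orientation_kappa = Inf,
                                  mean_orientation = 0.7,
                                  fibre_width = 2, noise_sd = 0.02),
                     seed = 11, canvas = c(128, 128))
  a_par <- fibre_anisotropy(par$image, par$mask)
  expect_gt(a_par$value, 0.85)
  # recovered orientation close to the generator's (axial distance)
  d <- abs(a_par$mean_orientation - 0.7) %% pi
  expect_lt(min(d, pi - d), 0.1)
})

test_that("uniform nucleus yields CCP 0 and more foci raise CCP", {
  flat <- render_nucleus(nucleus_phantom(semi_major = 20, semi_minor = 16,
                                         n_foci = 0, noise_sd = 0),
                         seed = 1, canvas = c(64, 64))
  expect_equal(ccp(flat$image, flat$mask)$value, 0)
  few <- render_nucleus(nucleus_phantom(semi_major = 26, semi_minor = 19,
                                        n_foci = 6, focus_radius = 3,
                                        noise_sd = 0.02),
                        seed = 2, canvas = c(96, 96))
  many <- render_nucleus(nucleus_phantom(semi_major = 26, semi_minor = 19,
                                         n_foci = 12, focus_radius = 3,
                                         noise_sd = 0.02),
                         seed = 2, canvas = c(96, 96))
  expect_gt(ccp(many$image, many$mask)$value,
            ccp(few$image, few$mask)$value)
})

test_that("generate_study produces the full design with ground truth", {
  cfg <- test_config(n_cells = 2, n_nuclei = 3)
  st <- generate_study(cfg, seed = 9)
  expect_equal(nrow(st$design), 9 * (2 + 3))
  expect_equal(nrow(st$truth), nrow(st$design))
  expect_setequal(unique(st$design$group),
                  c("unloaded", "physiological", "pathological"))
  expect_setequal(unique(st$design$timepoint), c("1h", "6h", "24h"))
  expect_equal(length(st$images), nrow(st$design))
  # ground truth matches the configured effect template
  tr <- st$truth[st$truth$channel == "nucleus" &
                   st$truth$group == "pathological" &
                   st$truth$timepoint == "1h", ]
  expect_true(all(tr$n_foci == cfg$foci_table["pathological", "1h"]))
  # determinism: identical (config, seed) reproduce identical pixels
  st2 <- generate_study(cfg, seed = 9)
  expect_identical(st$images, st2$images)
  expect_identical(st$design, st2$design)
})

test_that("written studies round-trip through TIFF and CSV", {
  dir <- withr::local_tempdir()
  cfg <- test_config(n_cells = 2, n_nuclei = 2, bit_depth = 16)
  st <- generate_study(cfg, seed = 4, out_dir = dir)
  expect_true(file.exists(file.path(dir, "design.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  loaded <- load_study(dir)
  expect_equal(nrow(loaded$design), nrow(st$design))
  id <- st$design$image_id[1]
  expect_identical(loaded$images[[id]]$mask, st$images[[id]]$mask)
  # 16-bit quantisation error only
  expect_lt(max(abs(loaded$images[[id]]$image - st$images[[id]]$image)),
            1 / 65535)
})

test_that("z-stack mode projects back to the single-plane render", {
  dir <- withr::local_tempdir()
  cfg <- test_config(n_cells = 2, n_nuclei = 2, z_slices = 8)
  st <- generate_study(cfg, seed = 4, out_dir = dir)
  id <- st$design$image_id[1]
  stack <- read_micrograph(file.path(dir, paste0(id, ".tif")))
  expect_equal(length(dim(stack)), 3L)
  expect_equal(dim(stack)[3], 8L)
  expect_lt(max(abs(project_max(stack) - st$images[[id]]$image)), 1 / 65535)
})
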