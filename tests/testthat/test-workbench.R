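test_that("fixture scenarios reproduce the published parameter grid", {
  dir <- withr::local_tempdir()
  paths <- make_fixtures(dir)
  expect_true(all(file.exists(paths)))
  scs <- lapply(paths, read_scenario)
  names(scs) <- vapply(scs, `[[`, character(1), "name")
  # scattering-coefficient series: four slabs
  musgrid <- scs[grepl("^musgrid", names(scs))]
  expect_length(musgrid, 4)
  expect_setequal(vapply(musgrid, function(s) s$medium$mus, numeric(1)),
                  c(2, 4, 6, 10))
  expect_true(all(vapply(musgrid, function(s) s$medium$mua, numeric(1)) ==
                    0.01))
  expect_true(all(vapply(musgrid, function(s) s$medium$g, numeric(1)) == 0.8))
  expect_true(all(vapply(musgrid, function(s) s$medium$d, numeric(1)) == 1))
  expect_true(all(vapply(musgrid, function(s) s$beam$l, integer(1)) == 3L))
  # phantom pair optical depths
  expect_equal(optical_depth(scs[["phantom-lg03-low"]]$medium), 2.0)
  expect_equal(optical_depth(scs[["phantom-lg03-multi"]]$medium), 9.6)
  # shared beam: 633 nm, 1.6 mm waist diameter
  for (s in scs) {
    expect_equal(s$beam$wavelength, 633e-6)
    expect_equal(s$beam$w0, 0.8)
  }
  # simulation-vs-experiment slab
  expect_equal(scs[["validation-lg03"]]$medium$mus, 4)
  expect_equal(scs[["validation-lg03"]]$medium$mua, 0.05)
  # every scenario carries a seed
  expect_true(all(vapply(scs, function(s) is.finite(s$config$seed),
                         logical(1))))
})

test_that("scenario YAML round-trips and rejects invalid configurations", {
  dir <- withr::local_tempdir()
  sc <- scenario("round-trip", hene_beam(3),
                 medium_optics(mus = 5, mua = 0.02, g = 0.7, n = 1.35,
                               d = 2.5),
                 run_config(n_photons = 1e4, n_detect = 1e3, seed = 77,
                            r_d = 4, na = 0.3),
                 pixel_grid(64, 64, 0.1))
  p <- file.path(dir, "rt.yaml")
  write_scenario(sc, p)
  sc2 <- read_scenario(p)
  expect_equal(sc2$medium$mus, 5)
  expect_equal(sc2$beam$l, 3L)
  expect_equal(sc2$config$seed, 77L)
  expect_equal(sc2$config$na, 0.3)
  expect_equal(sc2$grid$pitch, 0.1)

  # validation failures are actionable errors, not silent runs
  y <- yaml::read_yaml(p)
  y$medium$mus_per_mm <- -3
  yaml::write_yaml(y, p); expect_error(read_scenario(p), "mus")
  y$medium$mus_per_mm <- 5; y$medium$g <- 1
  yaml::write_yaml(y, p); expect_error(read_scenario(p), "'g'")
  y$medium$g <- 0.7; y$detector$na_rad <- 2
  yaml::write_yaml(y, p); expect_error(read_scenario(p), "na")
  y$detector$na_rad <- 0.3; y$run$seed <- NULL
  yaml::write_yaml(y, p); expect_error(read_scenario(p), "seed")
})

test_that("float TIFF images round-trip with their sidecar", {
  dir <- withr::local_tempdir()
  grid <- pixel_grid(32, 32, 0.05)
  img <- matrix(stats::rnorm(32 * 32), 32, 32)
  img[3, 5] <- NA
  p <- file.path(dir, "map.tif")
  write_field_tiff(img, p, grid, meta = list(kind = "test"))
  back <- read_field_tiff(p)
  expect_equal(back[!is.na(img)], img[!is.na(img)], tolerance = 1e-6)
  expect_true(is.na(back[3, 5]))
  side <- readLines(paste0(p, ".meta.txt"))
  expect_true(any(grepl("pitch_mm_per_px: 0.05", side)))
  expect_true(any(grepl("kind: test", side)))
})

test_that("the pipeline runs end to end and reproduces bit-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sc <- scenario("mini", hene_beam(3),
                 medium_optics(mus = 6, mua = 0.01, g = 0.8, n = 1.4, d = 1),
                 run_config(n_photons = 5e4, n_detect = 5e3, seed = 404),
                 pixel_grid(64, 64, 0.2))
  out1 <- run_pipeline(sc, dir1, sorter = FALSE, interfere = TRUE,
                       memory = TRUE)
  expect_s3_class(out1$image, "image_pair")
  expect_true(out1$memory$R >= 0 && out1$memory$R <= 1)
  produced <- list.files(dir1)
  expect_true(all(c("mini-intensity.tif", "mini-phase.tif",
                    "mini-occupancy.tif", "mini-interferogram.tif",
                    "mini-summary.csv", "mini-manifest.yaml") %in% produced))
  # manifest round-trip: identical binary outputs on re-run
  run_pipeline(sc, dir2, sorter = FALSE, interfere = TRUE, memory = TRUE)
  for (f in c("mini-intensity.tif", "mini-phase.tif", "mini-occupancy.tif",
              "mini-interferogram.tif")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
})

test_that("free-space scenarios produce the analytic mode image", {
  dir <- withr::local_tempdir()
  paths <- make_fixtures(dir)
  sc <- read_scenario(paths[grepl("depth0", paths)])
  out <- run_pipeline(sc, dir)
  expect_equal(max(out$image$intensity),
               max(Mod(field_map(sc$beam, sc$grid, z = sc$medium$d)$field)^2),
               tolerance = 1e-3)
})

test_that("the command-line front end drives the pipeline", {
  cli <- system.file("scripts", "vortexmc", package = "vortexmc")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  # fixture generation
  out <- system2(rscript, c(cli, "make-fixtures", "--out",
                            file.path(dir, "fx")), stdout = TRUE)
  expect_true(any(grepl("scenario files", out)))
  # analytic free-space maps
  out2 <- system2(rscript, c(cli, "freespace", "--l", "3", "--w0", "0.8",
                             "--n", "64", "--pitch", "0.05",
                             "--out", file.path(dir, "fs")), stdout = TRUE)
  expect_true(file.exists(file.path(dir, "fs", "freespace-phase.tif")))
  # a small simulate run driven from a scenario file
  sc <- scenario("cli-mini", hene_beam(3),
                 medium_optics(mus = 4, mua = 0.01, g = 0.8, n = 1.4, d = 1),
                 run_config(n_photons = 2e4, n_detect = 2e3, seed = 9),
                 pixel_grid(32, 32, 0.4))
  write_scenario(sc, file.path(dir, "mini.yaml"))
  out3 <- system2(rscript, c(cli, "simulate", "--scenario",
                             file.path(dir, "mini.yaml"),
                             "--out", file.path(dir, "run")), stdout = TRUE)
  expect_true(any(grepl("cli-mini complete", out3)))
  expect_true(file.exists(file.path(dir, "run", "cli-mini-intensity.tif")))
  # interferogram and phase-memory analyses through their subcommands
  out4 <- system2(rscript, c(cli, "interfere", "--scenario",
                             file.path(dir, "mini.yaml"),
                             "--out", file.path(dir, "run2")), stdout = TRUE)
  expect_true(file.exists(file.path(dir, "run2",
                                    "cli-mini-interferogram.tif")))
  out5 <- system2(rscript, c(cli, "analyze-phase-memory", "--scenario",
                             file.path(dir, "mini.yaml"),
                             "--out", file.path(dir, "run3")), stdout = TRUE)
  expect_true(any(grepl("phase-memory R", out5)))
  # a broken scenario exits with the validation status
  y <- yaml::read_yaml(file.path(dir, "mini.yaml"))
  y$run$seed <- NULL
  yaml::write_yaml(y, file.path(dir, "bad.yaml"))
  st <- suppressWarnings(
    system2(rscript, c(cli, "simulate", "--scenario",
                       file.path(dir, "bad.yaml"),
                       "--out", file.path(dir, "bad")),
            stdout = FALSE, stderr = FALSE))
  expect_equal(st, 1)
})
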