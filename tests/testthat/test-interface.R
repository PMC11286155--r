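# Configuration loading, schema validation, manifests, seed fan-out and
# the export formats.

test_that("an empty config yields the packaged defaults; round-trip is exact", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(unclass(cfg), unclass(default_config()))
  g <- withr::local_tempfile(fileext = ".yaml")
  dump_config(cfg, g)
  expect_equal(unclass(load_config(g)), unclass(cfg))
  # partial override keeps everything else at default
  writeLines("anatomy:\n  skull:\n    pitch: 3.5\n", f)
  cfg2 <- load_config(f)
  expect_identical(cfg2$anatomy$skull$pitch, 3.5)
  expect_identical(cfg2$loading$stress_factor, 37)
})

test_that("schema violations name the offending key", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("loading:\n  vectors_per_side: 0\n", f)
  expect_error(load_config(f), "vectors_per_side")
  writeLines("loading:\n  muscle_gain: 2\n", f)
  expect_error(load_config(f), "unknown key 'loading.muscle_gain'")
  writeLines("anatomy:\n  cohort:\n    cv: -1\n", f)
  expect_error(load_config(f), "cv")
  expect_error(load_config("no/such/file.yaml"), "not found")
})

test_that("manifests are hashed, recorded and schema-valid", {
  cfg <- default_config()
  expect_identical(config_hash(cfg), config_hash(default_config()))
  cfg2 <- cfg; cfg2$seed <- 99L
  expect_false(identical(config_hash(cfg), config_hash(cfg2)))
  d <- withr::local_tempdir()
  p <- file.path(d, "manifest.json")
  write_manifest(p, cfg,
                 stages = list(solve = list(status = "error",
                                            error = "singularity error",
                                            seconds = 0.2)))
  man <- jsonlite::fromJSON(p)
  expect_identical(man$stages$solve$status, "error")
  expect_match(man$stages$solve$error, "singularity")
  expect_true(validate_manifest(p))
  expect_error(write_manifest(file.path(d, "missing", "m.json"), cfg),
               "output directory")
})

test_that("stage seeds are deterministic, distinct and 32-bit safe", {
  s1 <- stage_seed(1L, "cohort")
  expect_identical(s1, stage_seed(1L, "cohort"))
  expect_false(s1 == stage_seed(1L, "anatomy"))
  expect_false(s1 == stage_seed(2L, "cohort"))
  big <- stage_seed(2147483000L, "cohort")
  expect_true(big >= 0 && big < 2^31)
})

test_that("identical config and seed reproduce the sweep bit-for-bit", {
  gm <- fit_growth(generate_csa_cohort(cohort_params(cv = 0.05, seed = 3)),
                   n_boot = 5)
  mf <- function(a) coarse_mesh(a)
  s1 <- run_series(gm, ages = 48, modes = 1:2, fascia = FALSE,
                   mesh_fun = mf)
  s2 <- run_series(gm, ages = 48, modes = 1:2, fascia = FALSE,
                   mesh_fun = mf)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("VTU, node-set JSON and CSV exports are written and well-formed", {
  d <- withr::local_tempdir()
  mesh <- coarse_mesh(48)
  fm <- coarse_fm(48)
  b <- run_bite(fm, forces_48, mode = 1)
  vt <- file.path(d, "skull.vtu")
  write_mesh_vtu(mesh, vt,
                 cell_data = list(
                   von_mises_stress_MPa = b$field$von_mises_stress,
                   von_mises_strain_microstrain = b$field$von_mises_strain),
                 point_data = list(
                   displacement_mm = matrix(b$solution$u, ncol = 3,
                                            byrow = TRUE)))
  txt <- readLines(vt)
  expect_match(txt[2], "UnstructuredGrid")
  expect_true(any(grepl(sprintf('NumberOfCells="%d"', nrow(mesh$tets)),
                        txt)))
  expect_true(any(grepl("von_mises_stress_MPa", txt)))
  js <- file.path(d, "sets.json")
  write_node_sets_json(mesh, js)
  sets <- jsonlite::fromJSON(js)
  expect_identical(sort(unlist(sets$node_sets$tmj_L)),
                   sort(mesh$node_sets$tmj_L))
  expect_identical(nrow(sets$landmarks), 42L)
  cs <- file.path(d, "cohort.csv")
  write_cohort_csv(generate_csa_cohort(cohort_params(seed = 2)), cs)
  back <- read.csv(cs)
  expect_named(back, c("individual_id", "age_months", "muscle", "csa_cm2"))
  gm <- fit_growth(generate_csa_cohort(cohort_params(cv = 0)), n_boot = 5)
  gcsv <- file.path(d, "growth.csv")
  write_growth_csv(gm, gcsv)
  expect_named(read.csv(gcsv),
               c("muscle", "age_months", "force_N", "ci_lo", "ci_hi"))
})
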