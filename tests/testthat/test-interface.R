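test_that("progress-curve CSV round-trips at full precision", {
  sc <- gen_progress_curve(assay_design(s_total = 100),
                           rate_constants(0.5, 0.01),
                           noise_model(0.05, 0.05, seed = 5))
  sc$curve$condition <- list(guide = "pi9", gtsf1_nM = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_progress_csv(sc$curve, path)
  back <- read_progress_csv(path)
  expect_equal(back$times, sc$curve$times, tolerance = 1e-12)
  expect_equal(back$product, sc$curve$product, tolerance = 1e-12)
  expect_equal(unname(back$replicates), unname(sc$curve$replicates),
               tolerance = 1e-12)
  expect_equal(back$e_nominal, 5)
  expect_equal(back$s_total, 100)
  expect_false(is.null(back$sd))  # 3 replicates -> per-time SDs
})

test_that("progress CSV parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# e_nominal_nM: 5",
               "time_min,product_nM",
               "0,0", "2,1", "1,2", "3,2.5"), path)
  expect_error(read_progress_csv(path), "out of order.*line")
  writeLines(c("time_min,product_nM", "0,0", "1,-0.5", "2,1", "3,2"), path)
  expect_error(read_progress_csv(path), "negative.*line")
  writeLines(c("t,p", "0,0"), path)
  expect_error(read_progress_csv(path), "missing header")
  expect_error(read_progress_csv("nope.csv"), "not found")
})

test_that("titration CSV round-trips", {
  st <- gen_titration(truth = hyperbola_params(1.1, 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(st$series, path)
  back <- read_titration_csv(path)
  expect_equal(back$concs, st$series$concs, tolerance = 1e-12)
  expect_equal(back$k_burst_obs, st$series$k_burst_obs, tolerance = 1e-12)
})

test_that("FASTA round-trip normalises to RNA", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_rna_fasta(c(g1 = "UAGCUUCCGA", g2 = "ACGUACGUAC"), path)
  back <- read_rna_fasta(path)
  expect_equal(unname(back), c("UAGCUUCCGA", "ACGUACGUAC"))
  writeLines(c(">dna", "tagcttccga"), path)
  expect_equal(unname(read_rna_fasta(path)), "UAGCUUCCGA")
})

test_that("cli fit-progress and fit-titration write complete JSON records", {
  dir <- withr::local_tempdir()
  curve_csv <- file.path(dir, "curve.csv")
  sc <- gen_progress_curve(assay_design(s_total = 100),
                           rate_constants(0.3, 0.01))
  write_progress_csv(sc$curve, curve_csv)
  out <- file.path(dir, "fit.json")
  expect_equal(cli(c("fit-progress", curve_csv, "--out", out,
                     "--boot", "100", "--seed", "1")), 0L)
  rec <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(rec$k_burst_per_min, 0.31, tolerance = 1e-4)
  expect_true(all(c("e_apparent_nM", "k_ss_per_min", "ci", "ci_method") %in%
                  names(rec)))
  expect_equal(rec$ci_method, "bootstrap_percentile_100")
  expect_match(rec$meta$config_md5, "^[0-9a-f]{32}$")

  tit_csv <- file.path(dir, "tit.csv")
  write_titration_csv(gen_titration(truth = hyperbola_params(1.1, 8))$series,
                      tit_csv)
  out2 <- file.path(dir, "fit2.json")
  expect_equal(cli(c("fit-titration", tit_csv, "--out", out2)), 0L)
  rec2 <- jsonlite::read_json(out2, simplifyVector = TRUE)
  expect_equal(rec2$kd_nM, 8, tolerance = 1e-6)

  # report summarises the directory
  out3 <- file.path(dir, "summary.csv")
  expect_equal(cli(c("report", dir, "--out", out3)), 0L)
  summ <- read.csv(out3)
  expect_equal(nrow(summ), 2L)
})

test_that("cli dg computes span and free energy from FASTA", {
  dir <- withr::local_tempdir()
  seqs <- panel_sequences(30)
  gfa <- file.path(dir, "guide.fa"); tfa <- file.path(dir, "target.fa")
  write_rna_fasta(seqs$guides, gfa)
  write_rna_fasta(c(target = seqs$target), tfa)
  out <- file.path(dir, "dg.json")
  expect_equal(cli(c("dg", "--guide", gfa, "--target", tfa, "--out", out)), 0L)
  rec <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(rec$span$g_end, 30L)
  expect_lt(rec$dg37_kcal_mol, -40)  # 29-bp helix is very stable
  expect_equal(rec$nn_table, "rna_wc_1998")
})

test_that("cli synth is deterministic under a fixed seed", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  st <- c("synth", "titration", "--kd", "8", "--kpot", "1.1",
          "--cv", "0.05", "--seed", "7")
  expect_equal(cli(c(st, "--out", f1)), 0L)
  expect_equal(cli(c(st, "--out", f2)), 0L)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cli simulate runs from a JSON config and rejects unknown keys", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(
    scheme = "basic",
    rates = list(k1 = 10, k_minus1 = 1, k2 = 1, k3 = 0.004),
    init = list(e = 2, s = 100),
    times = c(0, 1, 2, 5, 10, 30, 60)),
    cfg, auto_unbox = TRUE, digits = NA)
  out <- file.path(dir, "traj.csv")
  expect_equal(cli(c("simulate", "--config", cfg, "--out", out)), 0L)
  traj <- read.csv(out)
  expect_true(all(c("time_min", "E", "S", "ES", "EP", "P", "cleaved_nM") %in%
                  names(traj)))
  expect_true(all(diff(traj$cleaved_nM) >= -1e-9))
  jsonlite::write_json(list(scheme = "basic", rates = list(), init = list(),
                            bogus = 1), cfg, auto_unbox = TRUE)
  expect_equal(cli(c("simulate", "--config", cfg, "--out", out)), 1L)
})

test_that("cli usage errors exit with status 2", {
  expect_equal(suppressMessages(cli(character())), 2L)
  expect_equal(suppressMessages(cli("frobnicate")), 2L)
})
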