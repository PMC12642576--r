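# File formats, run configuration and the command-line interface.

test_that("count matrices round-trip through Matrix Market", {
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 3), j = c(1, 2, 3), x = c(4, 5, 6), dims = c(3, 4),
    dimnames = list(c("cA", "cB", "cC"), c("g1", "g2", "g3", "g4"))
  )
  dir <- withr::local_tempdir()
  write_count_matrix(m, dir)
  back <- read_count_matrix(file.path(dir, "counts.mtx"))
  expect_equal(as.matrix(back), as.matrix(m))
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))

  # genes-as-rows on disk with the orientation flag
  dir2 <- withr::local_tempdir()
  Matrix::writeMM(Matrix::t(m), file.path(dir2, "counts.mtx"))
  readr::write_tsv(tibble::tibble(gene = colnames(m)), file.path(dir2, "genes.tsv"))
  readr::write_tsv(tibble::tibble(cell_id = rownames(m)), file.path(dir2, "cells.tsv"))
  back2 <- read_count_matrix(file.path(dir2, "counts.mtx"),
                             orientation = "genes_by_cells")
  expect_equal(as.matrix(back2), as.matrix(m))
  expect_equal(back2["cB", "g2"], 5)

  # real values rejected without the flag, accepted with it
  dir3 <- withr::local_tempdir()
  mr <- m
  mr[1, 1] <- 4.5
  write_count_matrix(mr, dir3)
  expect_error(read_count_matrix(file.path(dir3, "counts.mtx")),
               "non-integer", class = "istclean_validation_error")
  expect_equal(as.matrix(read_count_matrix(file.path(dir3, "counts.mtx"),
                                           allow_real = TRUE)),
               as.matrix(mr))

  # dimension mismatch names the offending files
  dir4 <- withr::local_tempdir()
  write_count_matrix(m, dir4)
  readr::write_tsv(tibble::tibble(gene = c("g1", "g2")), file.path(dir4, "genes.tsv"))
  expect_error(read_count_matrix(file.path(dir4, "counts.mtx")), "genes.tsv",
               class = "istclean_validation_error")
})

test_that("transcript reader maps the Xenium dialect and optional quality filter", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "transcripts.csv")
  readr::write_csv(tibble::tibble(
    x_location = c(1, 2, 3), y_location = c(4, 5, 6),
    feature_name = c("a", "b", "a"), qv = c(40, 10, 40)
  ), f)
  tx <- read_transcripts(f)
  expect_equal(names(tx), c("x", "y", "gene"))
  expect_equal(nrow(tx), 3)
  tx_q <- read_transcripts(f, col_quality = "qv", min_quality = 20)
  expect_equal(nrow(tx_q), 2)
  expect_error(read_transcripts(f, col_x = "nope"), "col_x",
               class = "istclean_validation_error")
})

test_that("run configuration applies defaults and rejects unknown keys", {
  cfg <- run_config()
  expect_equal(cfg$radius_um, 50)
  expect_equal(cfg$n_hexbins, 200)
  expect_equal(cfg$alpha_cutoff, 0.75)
  expect_equal(cfg$n_restarts, 10L)
  expect_equal(cfg$offset_mode, "additive")
  expect_equal(cfg$min_nonzero_genes, 3L)
  expect_error(run_config(radius = 10), class = "istclean_validation_error")
  expect_equal(run_config(alpha_cutoff = 0.5)$alpha_cutoff, 0.5)
})

test_that("the CLI runs simulate then run end to end", {
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "sim")
  out_dir <- file.path(dir, "out")
  cfg_file <- file.path(dir, "sim.json")
  jsonlite::write_json(
    list(n_cells = 40, extent = 1200, genes_per_type = 6, n_noise_genes = 2),
    cfg_file, auto_unbox = TRUE
  )
  code <- suppressMessages(run_cli(c(
    "simulate", "--config", cfg_file, "--out", sim_dir, "--seed", "4"
  )))
  expect_equal(code, 0L)
  expect_true(all(file.exists(file.path(
    sim_dir, c("counts.mtx", "genes.tsv", "cells.tsv", "transcripts.csv",
               "truth.tsv", "labels.tsv", "report.json")
  ))))

  code <- suppressWarnings(suppressMessages(run_cli(c(
    "run", "--counts", file.path(sim_dir, "counts.mtx"),
    "--cells", file.path(sim_dir, "cells.tsv"),
    "--transcripts", file.path(sim_dir, "transcripts.csv"),
    "--out", out_dir, "--seed", "4"
  ))))
  expect_equal(code, 0L)
  expect_true(all(file.exists(file.path(
    out_dir, c("adjusted.mtx", "fits.tsv", "report.json")
  ))))
  report <- jsonlite::read_json(file.path(out_dir, "report.json"))
  expect_equal(report$config$seed, 4L)
  adj <- read_count_matrix(file.path(out_dir, "adjusted.mtx"))
  raw <- read_count_matrix(file.path(sim_dir, "counts.mtx"))
  expect_true(all(as.matrix(adj) <= as.matrix(raw)))

  # explicit defaults reproduce the default run bit for bit
  out_expl <- file.path(dir, "out_explicit")
  code <- suppressWarnings(suppressMessages(run_cli(c(
    "run", "--counts", file.path(sim_dir, "counts.mtx"),
    "--cells", file.path(sim_dir, "cells.tsv"),
    "--transcripts", file.path(sim_dir, "transcripts.csv"),
    "--out", out_expl, "--seed", "4",
    "--radius", "50", "--alpha-cutoff", "0.75", "--n-restarts", "10"
  ))))
  expect_equal(code, 0L)
  expect_identical(
    readLines(file.path(out_dir, "adjusted.mtx")),
    readLines(file.path(out_expl, "adjusted.mtx"))
  )
  expect_identical(
    readLines(file.path(out_dir, "report.json")),
    readLines(file.path(out_expl, "report.json"))
  )
})

test_that("CLI argument validation exits with code 2", {
  expect_equal(suppressMessages(run_cli(character(0))), 2L)
  expect_equal(suppressMessages(run_cli(c("run", "--cells", "x.tsv"))), 2L)
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(run_cli(c("metrics", "nope"))), 2L)
})

test_that("metrics and markers subcommands work on written datasets", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_cells = 80, extent = 1500,
                                     genes_per_type = 8, n_noise_genes = 2,
                                     seed = 6))
  sim_dir <- file.path(dir, "sim")
  write_dataset(sim, sim_dir)

  # markers come from a contamination-free reference of the same panel,
  # mirroring the clean single-cell references used in practice
  ref <- simulate_dataset(sim_config(n_cells = 80, extent = 1500,
                                     genes_per_type = 8, n_noise_genes = 2,
                                     spill_rate = 0, ambient_rate = 0,
                                     seed = 60))
  ref_dir <- file.path(dir, "ref")
  write_dataset(ref, ref_dir)

  mk_dir <- file.path(dir, "markers")
  code <- suppressMessages(run_cli(c(
    "markers", "derive", "--ref", file.path(ref_dir, "counts.mtx"),
    "--labels", file.path(ref_dir, "labels.tsv"), "--out", mk_dir
  )))
  expect_equal(code, 0L)
  pairs <- readr::read_tsv(file.path(mk_dir, "pairs.tsv"), show_col_types = FALSE)
  expect_gt(nrow(pairs), 0)

  mecr_out <- file.path(dir, "mecr.tsv")
  code <- suppressMessages(run_cli(c(
    "metrics", "mecr", "--counts", file.path(sim_dir, "counts.mtx"),
    "--pairs", file.path(mk_dir, "pairs.tsv"), "--out", mecr_out
  )))
  expect_equal(code, 0L)
  got <- readr::read_tsv(mecr_out, show_col_types = FALSE)
  expect_true(all(got$mecr >= 0 & got$mecr <= 1, na.rm = TRUE))

  pmp_dir <- file.path(dir, "pmp")
  readr::write_tsv(planted_markers(sim)[, c("cell_type", "gene")],
                   file.path(dir, "markers.tsv"))
  code <- suppressMessages(run_cli(c(
    "metrics", "pmp", "--counts", file.path(sim_dir, "counts.mtx"),
    "--markers", file.path(dir, "markers.tsv"),
    "--labels", file.path(sim_dir, "labels.tsv"), "--out", pmp_dir
  )))
  expect_equal(code, 0L)
  summ <- jsonlite::read_json(file.path(pmp_dir, "pmp_summary.json"))
  expect_true(summ$mean_pmp > 0 && summ$mean_pmp <= 1)
})
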