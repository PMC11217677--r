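make_fixture_sheet <- function(dir, n_lines = 2, reps = 2, N = 150,
                               depth = 2e5) {
  rows <- list()
  for (li in seq_len(n_lines)) {
    spec <- random_synthetic_spec(N = N, depth = depth, seed = 100 * li,
                                  sample_id = sprintf("L%d", li))
    gt <- expected_intensity(spec)
    for (r in seq_len(reps)) {
      id <- sprintf("L%d_r%d", li, r)
      m <- sample_counts(gt, seed = 10 * li + r, sample_id = id)
      path <- file.path(dir, paste0(id, ".cool"))
      write_cool(m, path)
      rows[[id]] <- tibble::tibble(sample_id = id,
                                   cell_line = sprintf("L%d", li),
                                   replicate = r, path = path)
    }
  }
  sheet <- dplyr::bind_rows(rows)
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sheet = sheet, path = sheet_path, chrom = "chrS")
}

test_that("run_config validates fields and reads JSON", {
  cfg <- run_config(list(chroms = "chrS", c = 4, out_dir = tempdir()))
  expect_s3_class(cfg$params, "ent3c_params")
  expect_identical(cfg$params$c, 4L)
  expect_error(run_config(list(c = 4, n = 100)), "exactly one")
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(chroms = "chrS", n = 80, phi = 2, seed = 5),
                       jf, auto_unbox = TRUE)
  cfg2 <- run_config(jf)
  expect_identical(cfg2$params$n, 80L)
  expect_identical(cfg2$params$phi, 2L)
  expect_identical(cfg2$seed, 5L)
})

test_that("entropy runs write one TSV per sample and a resolved manifest", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_sheet(dir, n_lines = 1, reps = 2)
  out <- file.path(dir, "out")
  cfg <- run_config(list(samples = fx$path, chroms = fx$chrom,
                         c = 2, out_dir = out))
  res <- run_entropy(cfg)
  expect_length(res$failures, 0)
  tsvs <- list.files(out, pattern = "^signal_.*\\.tsv$")
  expect_length(tsvs, 2L)
  man <- jsonlite::read_json(file.path(out, "entropy_manifest.json"),
                             simplifyVector = TRUE)
  first <- man[[1]]
  expect_identical(first$n, choose_submatrix_dim(first$N_eff, 2))
  sig <- utils::read.delim(file.path(out, paste0("signal_", names(man)[1], ".tsv")))
  expect_identical(nrow(sig), as.integer(first$Phi))
  # rerun is byte-identical
  f1 <- file.path(out, tsvs[1])
  before <- readLines(f1)
  run_entropy(cfg)
  expect_identical(readLines(f1), before)
})

test_that("a missing chromosome fails per sample without killing the run", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_sheet(dir, n_lines = 1, reps = 2)
  cfg <- run_config(list(samples = fx$path, chroms = c("chrS", "chrMissing"),
                         c = 2, out_dir = file.path(dir, "out2")))
  res <- suppressMessages(run_entropy(cfg))
  expect_length(res$signals, 2L)              # present chromosome written
  expect_length(res$failures, 2L)             # absent one reported per sample
  expect_match(res$failures[1], "chrMissing")
})

test_that("comparison runs produce Q tables and benchmark summaries", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_sheet(dir, n_lines = 2, reps = 2)
  out <- file.path(dir, "cmp")
  cfg <- run_config(list(samples = fx$path, chroms = fx$chrom,
                         c = 2, out_dir = out))
  res <- run_compare(cfg)
  expect_identical(nrow(res$qtable), 6L)      # choose(4, 2)
  expect_true(file.exists(file.path(out, "similarity.tsv")))
  expect_true(file.exists(file.path(out, "benchmark_summary.tsv")))
  gl <- glance(res$benchmark)
  expect_true(gl$q_br_bar > gl$q_nr_bar)      # replicates beat non-replicates
  # brute-force check of the summary from the written Q table
  qt <- utils::read.delim(file.path(out, "similarity.tsv"))
  line_of <- function(s) substr(s, 1, 2)
  br <- qt$q[line_of(qt$sample_a) == line_of(qt$sample_b)]
  nr <- qt$q[line_of(qt$sample_a) != line_of(qt$sample_b)]
  expect_equal(gl$q_br_bar, mean(br))
  expect_equal(gl$q_nr_bar, mean(nr))
})

test_that("self-comparison of one file listed twice gives Q = 1", {
  dir <- withr::local_tempdir()
  spec <- random_synthetic_spec(N = 120, depth = 1e5, seed = 8)
  m <- sample_counts(expected_intensity(spec))
  path <- file.path(dir, "one.cool")
  write_cool(m, path)
  sheet <- tibble::tibble(sample_id = c("s1", "s2"), path = path)
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- run_config(list(samples = sp, chroms = "chrS", c = 2,
                         out_dir = file.path(dir, "self")))
  res <- run_compare(cfg)
  expect_equal(res$qtable$q, 1)
  expect_error(run_compare(run_config(list(samples = sheet[1, ], chroms = "chrS",
                                           out_dir = dir))),
               "at least 2")
})

test_that("simulation writes a cooler round-trippable fixture and manifest", {
  dir <- withr::local_tempdir()
  res <- run_simulate(list(N = 200, depth = 1e5, seed = 1,
                           empty_fraction = 0.1, sample_id = "sim"),
                      out_dir = dir)
  m <- load_cooler(res$cool, chrom = "chrS")
  expect_identical(nrow(m$values), 200L)
  expect_equal(m$values, res$matrix$values)
  # 10% of 200 bins forced empty
  expect_identical(sum(empty_bin_rows <- apply(m$values, 1, function(r) all(r == 0))),
                   20L)
  man <- jsonlite::read_json(file.path(dir, "sim_manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(man$spec$seed, 1L)
  expect_length(man$spec$empty_bins, 20L)
  # identical spec twice: identical matrices
  res2 <- run_simulate(list(N = 200, depth = 1e5, seed = 1,
                            empty_fraction = 0.1, sample_id = "sim2"),
                       out_dir = dir)
  expect_identical(res2$matrix$values, res$matrix$values)
  expect_error(run_simulate(list(N = 100, bogus_field = 1), out_dir = dir),
               "bogus_field")
})

test_that("region and PCA runs write BED and coordinate tables", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_sheet(dir, n_lines = 2, reps = 1, N = 150)
  out <- file.path(dir, "reg")
  cfg <- run_config(list(samples = fx$path, chroms = fx$chrom, c = 2,
                         out_dir = out, quantile = 0.05))
  res <- run_regions(cfg, k = 2)
  expect_true(file.exists(file.path(out, "extremes_chrS.bed")))
  expect_true(file.exists(file.path(out, "similar_chrS.bed")))
  expect_identical(nrow(res$chrS$extremes), 4L)
  expect_gte(nrow(res$chrS$similar), 1L)

  dir2 <- withr::local_tempdir()
  fx2 <- make_fixture_sheet(dir2, n_lines = 1, reps = 3, N = 150)
  outp <- file.path(dir, "pca")
  cfgp <- run_config(list(samples = fx2$path, chroms = "chrS", c = 2,
                          out_dir = outp))
  pres <- run_pca(cfgp)
  tab <- utils::read.delim(file.path(outp, "pca_chrS.tsv"))
  expect_identical(nrow(tab), 3L)
  expect_true(all(c("sample_id", "PC1", "PC2") %in% names(tab)))
})
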