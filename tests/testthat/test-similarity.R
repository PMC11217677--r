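fake_signal <- function(values, n = 100L, phi_eff = 1L, id = "s") {
  structure(list(values = values,
                 windows = tibble::tibble(window_index = seq_along(values) - 1L,
                                          chrom = "chrS",
                                          start = (seq_along(values) - 1) * 1e3,
                                          end = (seq_along(values) - 1) * 1e3 + n * 1e3),
                 params = list(n = n, phi = phi_eff, phi_eff = phi_eff,
                               Phi = length(values), c = 7L),
                 sample_id = id, chrom = "chrS", resolution = 1e3),
            class = "entropy_signal")
}

test_that("Q is the Pearson correlation of the two entropy signals", {
  sa <- fake_signal(c(1, 2, 3, 4))
  expect_equal(similarity_q(sa, sa), 1)
  sb <- fake_signal(-c(1, 2, 3, 4) + 10)
  expect_equal(similarity_q(sa, sb), -1)
  sc <- fake_signal(c(1, 2, 3, 5))
  expect_equal(similarity_q(sa, sc), pearson_oracle(c(1, 2, 3, 4), c(1, 2, 3, 5)))
  expect_equal(similarity_q(sa, sc), 0.9827076, tolerance = 1e-6)
})

test_that("incomparable or degenerate signals are rejected", {
  sa <- fake_signal(c(1, 2, 3, 4))
  expect_error(similarity_q(sa, fake_signal(c(1, 2, 3))), "not comparable")
  expect_error(similarity_q(sa, fake_signal(c(1, 2, 3, 4), n = 50L)),
               "window geometry")
  expect_error(similarity_q(sa, fake_signal(c(2, 2, 2, 2))), "degenerate")
})

test_that("matrix-level comparison shares one window geometry", {
  spec <- random_synthetic_spec(N = 300, depth = 3e5, seed = 2,
                                empty_fraction = 0.05)
  pr <- make_pair(spec, "BR", seed_a = 5, seed_b = 6)
  cs <- contact_similarity(pr$a, pr$b, ent3c_params(c = 4))
  expect_identical(cs$signal_a$params$n, cs$signal_b$params$n)
  expect_identical(cs$signal_a$params$Phi, cs$signal_b$params$Phi)
  # n derives from the intersected dimension, not each matrix's own
  common <- intersect_nonempty(list(pr$a, pr$b))
  expect_identical(cs$n_eff, nrow(common[[1]]$values))
  expect_identical(cs$signal_a$params$n,
                   choose_submatrix_dim(cs$n_eff, 4))
  expect_true(cs$q >= -1 && cs$q <= 1)
  # identical inputs give Q = 1 and the table is order-invariant
  self <- contact_similarity(pr$a, pr$a, ent3c_params(c = 4))
  expect_equal(self$q, 1)
  swap <- contact_similarity(pr$b, pr$a, ent3c_params(c = 4))
  expect_equal(swap$q, cs$q)
})

test_that("similarity_table enumerates unordered pairs", {
  spec <- synthetic_spec(N = 150, depth = 2e5, seed = 4)
  gt <- expected_intensity(spec)
  mats <- list(r1 = sample_counts(gt, seed = 1, sample_id = "r1"),
               r2 = sample_counts(gt, seed = 2, sample_id = "r2"),
               r3 = sample_counts(gt, seed = 3, sample_id = "r3"))
  tab <- similarity_table(mats, ent3c_params(c = 3))
  expect_identical(nrow(tab), 3L)
  expect_setequal(paste(tab$sample_a, tab$sample_b),
                  c("r1 r2", "r1 r3", "r2 r3"))
  expect_true(all(tab$q >= -1 & tab$q <= 1))
})

test_that("benchmark aggregation matches the worked margin example", {
  # one line with Q_BR = 0.9 against three others with Q_NR 0.3, 0.5, 0.2
  qtable <- tibble::tibble(
    sample_a = c("A1", "A1", "A1", "A1"),
    sample_b = c("A2", "B1", "C1", "D1"),
    chrom = "chrS",
    q = c(0.9, 0.3, 0.5, 0.2))
  sheet <- tibble::tibble(sample_id = c("A1", "A2", "B1", "C1", "D1"),
                          cell_line = c("A", "A", "B", "C", "D"))
  bench <- suppressWarnings(aggregate_benchmark(qtable, sheet))
  expect_equal(bench$br$q_br, 0.9)
  expect_equal(bench$br$d, 0.9 - 0.3)   # median of {0.3, 0.5, 0.2}
})

test_that("all-equal scores collapse the benchmark to zero margin", {
  qtable <- tidyr::expand_grid(sample_a = c("A1", "A2"),
                               sample_b = c("B1", "B2")) |>
    dplyr::bind_rows(tibble::tibble(sample_a = c("A1", "B1"),
                                    sample_b = c("A2", "B2"))) |>
    dplyr::mutate(chrom = "chrS", q = 0.7)
  sheet <- tibble::tibble(sample_id = c("A1", "A2", "B1", "B2"),
                          cell_line = c("A", "A", "B", "B"))
  bench <- aggregate_benchmark(qtable, sheet)
  expect_equal(bench$q_br_bar, 0.7)
  expect_equal(bench$q_nr_bar, 0.7)
  expect_equal(bench$d_bar, 0)
})

test_that("aggregation follows chromosome-first averaging and brute force", {
  # 2 lines x 2 replicates, 2 chromosomes, hand-built scores
  set.seed(31)
  samples <- c("A1", "A2", "B1", "B2")
  pairs <- t(utils::combn(samples, 2))
  qtable <- purrr::map_dfr(c("chr1", "chr2"), function(ch) {
    tibble::tibble(sample_a = pairs[, 1], sample_b = pairs[, 2], chrom = ch,
                   q = round(stats::runif(nrow(pairs), -0.2, 0.95), 3))
  })
  sheet <- tibble::tibble(sample_id = samples,
                          cell_line = substr(samples, 1, 1))
  bench <- aggregate_benchmark(qtable, sheet)

  # brute-force oracle: enumerate pair means explicitly
  pm <- function(a, b) mean(qtable$q[(qtable$sample_a == a & qtable$sample_b == b) |
                                       (qtable$sample_a == b & qtable$sample_b == a)])
  q_br_A <- pm("A1", "A2"); q_br_B <- pm("B1", "B2")
  q_nr_AB <- mean(c(pm("A1", "B1"), pm("A1", "B2"),
                    pm("A2", "B1"), pm("A2", "B2")))
  expect_equal(bench$q_br_bar, mean(c(q_br_A, q_br_B)))
  expect_equal(bench$q_nr_bar, q_nr_AB)
  expect_equal(bench$d_bar, mean(c(q_br_A - q_nr_AB, q_br_B - q_nr_AB)))

  # invariant to sample order in the table
  perm <- qtable[sample(nrow(qtable)), ]
  flip <- perm
  flip$sample_a <- perm$sample_b
  flip$sample_b <- perm$sample_a
  bench2 <- aggregate_benchmark(flip, sheet)
  expect_equal(bench2$q_br_bar, bench$q_br_bar)
  expect_equal(bench2$q_nr_bar, bench$q_nr_bar)
  expect_equal(bench2$d_bar, bench$d_bar)

  g <- glance(bench)
  expect_named(g, c("q_br_bar", "q_nr_bar", "d_bar"))
  td <- tidy(bench)
  expect_true(all(c("BR", "NR") %in% td$relationship))
})

test_that("single-replicate cell lines are skipped with a warning", {
  qtable <- tibble::tibble(sample_a = "A1", sample_b = "B1",
                           chrom = "chrS", q = 0.4)
  sheet <- tibble::tibble(sample_id = c("A1", "B1"),
                          cell_line = c("A", "B"))
  expect_warning(aggregate_benchmark(qtable, sheet), "single replicate")
})
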