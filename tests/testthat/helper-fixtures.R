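# Fixture builders used across test files. The cooler writer here is kept
# independent of hicentropy::write_cool so reader tests do not certify the
# reader against itself.

# Minimal single-chromosome cooler written with raw rhdf5 calls.
# counts: dense symmetric matrix; only the upper triangle is stored.
write_fixture_cool <- function(path, counts, chrom = "chrF",
                               resolution = 1000, weights = NULL,
                               root = "", chrom_length = NULL) {
  N <- nrow(counts)
  if (is.null(chrom_length)) chrom_length <- N * resolution
  if (!file.exists(path)) rhdf5::h5createFile(path)
  if (root != "") {
    acc <- ""
    for (p in strsplit(root, "/")[[1]]) {
      acc <- if (acc == "") p else paste0(acc, "/", p)
      suppressMessages(try(rhdf5::h5createGroup(path, acc), silent = TRUE))
    }
  }
  g <- function(x) if (root == "") x else paste0(root, "/", x)
  for (grp in c("chroms", "bins", "pixels", "indexes")) {
    suppressMessages(try(rhdf5::h5createGroup(path, g(grp)), silent = TRUE))
  }
  starts <- (seq_len(N) - 1) * resolution
  ends <- pmin(starts + resolution, chrom_length)
  rhdf5::h5write(chrom, path, g("chroms/name"))
  rhdf5::h5write(as.double(chrom_length), path, g("chroms/length"))
  rhdf5::h5write(rep(0L, N), path, g("bins/chrom"))
  rhdf5::h5write(as.double(starts), path, g("bins/start"))
  rhdf5::h5write(as.double(ends), path, g("bins/end"))
  if (!is.null(weights)) rhdf5::h5write(as.double(weights), path, g("bins/weight"))
  ut <- which(upper.tri(counts, diag = TRUE) & counts != 0, arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  rhdf5::h5write(as.integer(ut[, 1] - 1L), path, g("pixels/bin1_id"))
  rhdf5::h5write(as.integer(ut[, 2] - 1L), path, g("pixels/bin2_id"))
  rhdf5::h5write(as.double(counts[ut]), path, g("pixels/count"))
  off <- c(0L, cumsum(tabulate(ut[, 1], nbins = N)))
  rhdf5::h5write(as.integer(off), path, g("indexes/bin1_offset"))
  fid <- rhdf5::H5Fopen(path)
  tgt <- if (root == "") fid else rhdf5::H5Gopen(fid, root)
  rhdf5::h5writeAttribute(as.integer(resolution), tgt, "bin-size")
  if (root != "") rhdf5::H5Gclose(tgt)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

# Symmetric random count matrix with structure (seeded), for property tests.
random_count_matrix <- function(N, seed = 1, depth = 10 * N^2) {
  spec <- hicentropy::random_synthetic_spec(N = N, seed = seed, depth = depth,
                                            empty_fraction = 0)
  hicentropy::sample_counts(hicentropy::expected_intensity(spec))
}

# Hand-rolled Pearson correlation of two vectors: the brute-force oracle.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Entropy signal fixture small enough for repeated use.
small_signal <- function(N = 160, seed = 5, params = ent3c_params(c = 4, phi_max = Inf)) {
  m <- random_count_matrix(N, seed = seed, depth = 5 * N^2)
  hicentropy::entropy_signal(m, params)
}
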