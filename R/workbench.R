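#' Build a run configuration
#'
#' Normalises and validates the configuration shared by the workbench
#' commands ([run_entropy()], [run_compare()], [run_pca()],
#' [run_simulate()]). Accepts a list or a path to a YAML/JSON file with the
#' same fields; exactly one of `c` or `n` may be set (defaults to `c = 7`).
#'
#' @param x A list of fields, or a path to a YAML or JSON config file.
#' @param ... Field overrides (applied after reading `x`).
#' @return A `run_config` object: `samples` (sample-sheet path or tibble),
#'   `chroms`, `resolution`, `balanced`, `params` ([ent3c_params()]),
#'   `out_dir`, `seed`, `quantile`.
#' @export
run_config <- function(x = list(), ...) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.ya?ml$", x)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML configs", call. = FALSE)
      }
      yaml::read_yaml(x)
    } else {
      jsonlite::read_json(x, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(x))
  x <- utils::modifyList(x, list(...))
  # [[ ]] access throughout: `$` partial matching would let `c` pick up
  # `chroms` and `phi` pick up `phi_max`
  if (!is.null(x[["c"]]) && !is.null(x[["n"]])) {
    stop("set exactly one of `c` or `n`", call. = FALSE)
  }
  params <- ent3c_params(c = if (is.null(x[["c"]])) 7L else x[["c"]],
                         n = x[["n"]],
                         phi = if (is.null(x[["phi"]])) 1L else x[["phi"]],
                         phi_max = if (is.null(x[["phi_max"]])) 1000L else x[["phi_max"]])
  structure(list(samples = x[["samples"]],
                 chroms = x[["chroms"]],
                 resolution = x[["resolution"]],
                 balanced = isTRUE(x[["balanced"]]),
                 params = params,
                 out_dir = if (is.null(x[["out_dir"]])) "." else x[["out_dir"]],
                 seed = if (is.null(x[["seed"]])) 1L else as.integer(x[["seed"]]),
                 quantile = if (is.null(x[["quantile"]])) 0.003 else x[["quantile"]]),
            class = "run_config")
}

read_sample_sheet <- function(samples) {
  if (is.data.frame(samples)) return(tibble::as_tibble(samples))
  sheet <- utils::read.delim(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "path") %in% names(sheet)))
  tibble::as_tibble(sheet)
}

#' Load a contact matrix by file extension
#'
#' Dispatches on extension: `.cool`/`.mcool` via [load_cooler()], anything
#' else (TSV, optionally gzipped) via [load_dense()].
#'
#' @param path Input file.
#' @param chrom Chromosome name.
#' @param resolution Binning resolution.
#' @param balanced Apply stored balancing weights (cooler inputs only).
#' @param sample_id Sample identifier.
#' @return A [contact_matrix()].
#' @export
load_matrix <- function(path, chrom, resolution = NULL, balanced = FALSE,
                        sample_id = basename(path)) {
  if (grepl("\\.m?cool$", path)) {
    load_cooler(path, chrom = chrom, resolution = resolution,
                balanced = balanced, sample_id = sample_id)
  } else {
    if (balanced) stop("dense inputs carry no balancing weights", call. = FALSE)
    if (is.null(resolution)) stop("dense inputs need a resolution", call. = FALSE)
    load_dense(path, resolution = resolution, chrom = chrom,
               sample_id = sample_id)
  }
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Compute and write entropy signals for every sample and chromosome
#'
#' For each row of the sample sheet and each requested chromosome, loads the
#' matrix, excludes empty bins, computes the entropy signal and writes it as
#' TSV (`signal_<sample>_<chrom>.tsv`). A JSON run manifest records the
#' resolved geometry (`N_eff`, `n`, `phi_eff`, `Phi`) per signal. A failing
#' sample is reported and skipped; the run continues.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `signals` (named list of
#'   [entropy_signal()]), `failures` (named character vector of error
#'   messages) and `manifest`.
#' @export
run_entropy <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sheet <- read_sample_sheet(config$samples)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  signals <- list()
  failures <- character(0)
  manifest <- list()
  for (i in seq_len(nrow(sheet))) {
    for (chrom in config$chroms) {
      key <- paste0(sheet$sample_id[i], "_", chrom)
      res <- tryCatch({
        m <- load_matrix(sheet$path[i], chrom = chrom,
                         resolution = config$resolution,
                         balanced = config$balanced,
                         sample_id = sheet$sample_id[i])
        m <- exclude_empty_bins(m)
        s <- entropy_signal(m, config$params)
        write_signal(s, file.path(config$out_dir,
                                  paste0("signal_", key, ".tsv")))
        manifest[[key]] <- c(list(N_eff = nrow(m$values)), s$params)
        s
      }, error = function(e) {
        message("[entropy] ", key, " failed: ", conditionMessage(e))
        failures[[key]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(res)) signals[[key]] <- res
    }
  }
  write_manifest(manifest, file.path(config$out_dir, "entropy_manifest.json"))
  invisible(list(signals = signals, failures = failures, manifest = manifest))
}

#' Pairwise similarity and benchmark aggregation for a sample sheet
#'
#' Loads every sample on every requested chromosome, computes `Q` for each
#' unordered sample pair (common-bin exclusion per pair) and writes the
#' similarity table as TSV. When the sheet carries a `cell_line` column the
#' replicate benchmark ([aggregate_benchmark()]) is computed and written too.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `qtable` and (when labels permit)
#'   `benchmark`.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sheet <- read_sample_sheet(config$samples)
  if (nrow(sheet) < 2L) stop("need at least 2 samples to compare", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  qtable <- purrr::map_dfr(config$chroms, function(chrom) {
    mats <- lapply(seq_len(nrow(sheet)), function(i) {
      load_matrix(sheet$path[i], chrom = chrom,
                  resolution = config$resolution,
                  balanced = config$balanced, sample_id = sheet$sample_id[i])
    })
    names(mats) <- sheet$sample_id
    similarity_table(mats, config$params)
  })
  utils::write.table(qtable, file.path(config$out_dir, "similarity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(qtable = qtable)
  if ("cell_line" %in% names(sheet)) {
    bench <- aggregate_benchmark(qtable, sheet)
    utils::write.table(tidy(bench),
                       file.path(config$out_dir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(glance(bench),
                       file.path(config$out_dir, "benchmark_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$benchmark <- bench
  }
  invisible(out)
}

#' Simulate a synthetic contact matrix fixture
#'
#' Samples a matrix from a [synthetic_spec()] (or a YAML/JSON file of spec
#' fields), writes it as a single-chromosome `.cool` plus dense TSV, and
#' records the spec and seeds in a JSON manifest.
#'
#' @param spec A [synthetic_spec()], a list of its fields, or a YAML/JSON
#'   path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the matrix and the written paths.
#' @export
run_simulate <- function(spec, out_dir = ".") {
  if (is.character(spec) && length(spec) == 1L) {
    fields <- if (grepl("\\.ya?ml$", spec)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML specs", call. = FALSE)
      }
      yaml::read_yaml(spec)
    } else {
      jsonlite::read_json(spec, simplifyVector = TRUE)
    }
    spec <- fields
  }
  if (!inherits(spec, "synthetic_spec")) {
    ok <- names(formals(synthetic_spec))
    bad <- setdiff(names(spec), ok)
    if (length(bad)) stop("unknown spec field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    spec <- do.call(synthetic_spec, spec)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt <- expected_intensity(spec)
  m <- sample_counts(gt)
  cool_path <- file.path(out_dir, paste0(spec$sample_id, ".cool"))
  if (file.exists(cool_path)) file.remove(cool_path)
  write_cool(m, cool_path)
  tsv_path <- file.path(out_dir, paste0(spec$sample_id, ".tsv.gz"))
  write_dense(m, tsv_path)
  manifest <- spec
  class(manifest) <- NULL
  manifest$empty_bins <- gt$empty_bins
  write_manifest(list(spec = manifest,
                      files = c(cool = cool_path, dense = tsv_path)),
                 file.path(out_dir, paste0(spec$sample_id, "_manifest.json")))
  invisible(list(matrix = m, cool = cool_path, dense = tsv_path))
}

#' Region analytics for one or two samples
#'
#' Writes BED files of the `k` lowest/highest-entropy windows of the first
#' sample and, when a second sample is given, of the most similar regions
#' between the two (both signals recomputed on their common non-empty bins).
#'
#' @param config A [run_config()] whose sheet holds one or two samples.
#' @param k Windows per extreme.
#' @return Invisibly, a list of the region tibbles.
#' @export
run_regions <- function(config, k = 1L) {
  stopifnot(inherits(config, "run_config"))
  sheet <- read_sample_sheet(config$samples)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (chrom in config$chroms) {
    m1 <- load_matrix(sheet$path[1L], chrom = chrom,
                      resolution = config$resolution,
                      balanced = config$balanced,
                      sample_id = sheet$sample_id[1L])
    if (nrow(sheet) >= 2L) {
      m2 <- load_matrix(sheet$path[2L], chrom = chrom,
                        resolution = config$resolution,
                        balanced = config$balanced,
                        sample_id = sheet$sample_id[2L])
      cs <- contact_similarity(m1, m2, config$params)
      ext <- extreme_windows(cs$signal_a, k)
      sim <- similar_regions(cs$signal_a, cs$signal_b, config$quantile)
      write_bed(sim, file.path(config$out_dir,
                               paste0("similar_", chrom, ".bed")))
      out[[chrom]] <- list(extremes = ext, similar = sim)
    } else {
      s <- entropy_signal(m1, config$params)
      ext <- extreme_windows(s, k)
      out[[chrom]] <- list(extremes = ext)
    }
    write_bed(out[[chrom]]$extremes,
              file.path(config$out_dir, paste0("extremes_", chrom, ".bed")))
  }
  invisible(out)
}

#' PCA of entropy signals across a sample sheet
#'
#' Restricts all samples to their common non-empty bins (so the signals share
#' geometry), computes each entropy signal, and writes per-sample principal
#' component coordinates and variance fractions.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of [signal_pca()] objects per chromosome.
#' @export
run_pca <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sheet <- read_sample_sheet(config$samples)
  if (nrow(sheet) < 2L) stop("need at least 2 samples for PCA", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (chrom in config$chroms) {
    mats <- lapply(seq_len(nrow(sheet)), function(i) {
      load_matrix(sheet$path[i], chrom = chrom,
                  resolution = config$resolution,
                  balanced = config$balanced, sample_id = sheet$sample_id[i])
    })
    common <- intersect_nonempty(mats)
    resolved <- resolve_params(config$params, nrow(common[[1L]]$values))
    fixed <- ent3c_params(c = config$params$c, n = resolved$n,
                          phi = config$params$phi,
                          phi_max = config$params$phi_max)
    signals <- lapply(common, entropy_signal, params = fixed)
    names(signals) <- sheet$sample_id
    pca <- signal_pca(signals)
    utils::write.table(tidy(pca),
                       file.path(config$out_dir, paste0("pca_", chrom, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[chrom]] <- pca
  }
  invisible(out)
}
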