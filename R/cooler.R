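#' @importFrom rhdf5 h5read h5ls h5createFile h5createGroup h5write
#'   h5readAttributes H5Fopen H5Fclose H5Gopen H5Gclose h5writeAttribute
NULL

cooler_root <- function(path, resolution) {
  ls <- rhdf5::h5ls(path)
  if (!any(ls$group == "/" & ls$name == "resolutions")) return("")
  available <- unique(ls$name[ls$group == "/resolutions"])
  if (is.null(resolution)) {
    stop("multi-resolution cooler: specify `resolution` (available: ",
         paste(sort(as.numeric(available)), collapse = ", "), ")",
         call. = FALSE)
  }
  sel <- as.character(as.integer(resolution))
  if (!sel %in% available) {
    stop("resolution ", resolution, " not found in ", basename(path),
         " (available: ", paste(sort(as.numeric(available)), collapse = ", "),
         ")", call. = FALSE)
  }
  paste0("resolutions/", sel, "/")
}

chrom_of_bins <- function(bchrom, chrom_names) {
  if (is.factor(bchrom)) return(as.character(bchrom))
  if (is.numeric(bchrom)) return(chrom_names[as.integer(bchrom) + 1L])
  as.character(bchrom)
}

#' Read an intrachromosomal matrix from a cooler file
#'
#' Loads the dense contact matrix of one chromosome from a `.cool` file, or
#' from one resolution of a multi-resolution `.mcool` file (internal layout
#' `resolutions/<res>`). Balancing, when requested, applies the stored
#' per-bin weights `w` as `w_k * A_kl * w_l`; bins with undefined weights
#' become missing. No empty-bin exclusion is performed here — pass the result
#' through [exclude_empty_bins()] (done automatically by [entropy_signal()]).
#'
#' @param path Path to a `.cool` or `.mcool` file.
#' @param chrom Chromosome name to extract.
#' @param resolution Required for `.mcool` files; for a plain `.cool` it is
#'   checked against the stored bin size when given.
#' @param balanced Apply the stored `weight` column. Default `FALSE` (raw
#'   counts).
#' @param sample_id Sample identifier; defaults to file name plus chromosome.
#' @return A [contact_matrix()] with all bins retained.
#' @export
load_cooler <- function(path, chrom, resolution = NULL, balanced = FALSE,
                        sample_id = paste0(basename(path), ":", chrom)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  root <- cooler_root(path, resolution)
  rd <- function(name) rhdf5::h5read(path, paste0(root, name),
                                     bit64conversion = "double")
  attrs <- rhdf5::h5readAttributes(path, if (root == "") "/" else sub("/$", "", root))
  binsize <- as.numeric(attrs[["bin-size"]])
  if (length(binsize) == 0 || is.na(binsize)) {
    b <- rd("bins/start"); binsize <- as.numeric(b[2L] - b[1L])
  }
  if (!is.null(resolution) && root == "" && !isTRUE(all.equal(binsize, as.numeric(resolution)))) {
    stop("requested resolution ", resolution, " but file is binned at ",
         binsize, call. = FALSE)
  }
  chrom_names <- as.character(rd("chroms/name"))
  if (!chrom %in% chrom_names) {
    stop("chromosome '", chrom, "' not found in ", basename(path),
         " (available: ", paste(chrom_names, collapse = ", "), ")",
         call. = FALSE)
  }
  bchrom <- chrom_of_bins(rd("bins/chrom"), chrom_names)
  sel <- which(bchrom == chrom)             # contiguous by cooler convention
  lo <- min(sel); hi <- max(sel)            # 1-based bin range
  N <- hi - lo + 1L
  starts <- as.numeric(rd("bins/start"))[sel]
  ends <- as.numeric(rd("bins/end"))[sel]

  weights <- NULL
  if (balanced) {
    ls <- rhdf5::h5ls(path)
    have_weight <- any(ls$group == paste0("/", root, "bins") &
                         ls$name == "weight")
    if (!have_weight) stop("no balancing weights in ", basename(path), call. = FALSE)
    weights <- as.numeric(rd("bins/weight"))[sel]
  }

  b1 <- as.numeric(rd("pixels/bin1_id"))
  b2 <- as.numeric(rd("pixels/bin2_id"))
  cnt <- as.numeric(rd("pixels/count"))
  inr <- b1 >= (lo - 1L) & b1 <= (hi - 1L) & b2 >= (lo - 1L) & b2 <= (hi - 1L)
  i <- as.integer(b1[inr]) - (lo - 1L) + 1L
  j <- as.integer(b2[inr]) - (lo - 1L) + 1L
  v <- cnt[inr]

  A <- matrix(0, N, N)
  A[cbind(i, j)] <- v
  A[cbind(j, i)] <- v
  if (balanced) {
    A <- A * outer(weights, weights)        # NA weights poison row and column
  }
  bins <- tibble::tibble(chrom = chrom, start = starts, end = ends,
                         index = seq_len(N) - 1L)
  contact_matrix(A, binsize, chrom = chrom, bins = bins,
                 sample_id = sample_id, balanced = balanced)
}

#' Write a contact matrix as a single-chromosome cooler file
#'
#' Writes the upper triangle of a contact matrix in cooler's HDF5 layout
#' (`chroms`, `bins`, `pixels`, `indexes` plus root attributes). Counts are
#' written as stored; missing entries are dropped from the pixel table. With
#' `root = "resolutions/<res>"` several matrices can be stacked into an
#' `.mcool`-style multi-resolution file.
#'
#' @param m A [contact_matrix()].
#' @param path Output file path. Created on first write; reused (for
#'   multi-resolution layouts) when it already exists.
#' @param root Internal HDF5 group, `""` for a plain `.cool`.
#' @param weights Optional per-bin balancing weights to store as
#'   `bins/weight`.
#' @return `path`, invisibly.
#' @export
write_cool <- function(m, path, root = "", weights = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!file.exists(path)) rhdf5::h5createFile(path)
  grp <- function(g) paste0(if (root == "") "" else paste0(root, "/"), g)
  if (root != "") {
    parts <- strsplit(root, "/")[[1L]]
    acc <- ""
    for (p in parts) {
      acc <- if (acc == "") p else paste0(acc, "/", p)
      suppressMessages(try(rhdf5::h5createGroup(path, acc), silent = TRUE))
    }
  }
  for (g in c("chroms", "bins", "pixels", "indexes")) {
    suppressMessages(try(rhdf5::h5createGroup(path, grp(g)), silent = TRUE))
  }
  N <- nrow(m$values)
  chrom_len <- max(m$bins$end)
  rhdf5::h5write(m$chrom, path, grp("chroms/name"))
  rhdf5::h5write(as.double(chrom_len), path, grp("chroms/length"))
  rhdf5::h5write(rep(0L, N), path, grp("bins/chrom"))
  rhdf5::h5write(as.double(m$bins$start), path, grp("bins/start"))
  rhdf5::h5write(as.double(m$bins$end), path, grp("bins/end"))
  if (!is.null(weights)) {
    stopifnot(length(weights) == N)
    rhdf5::h5write(as.double(weights), path, grp("bins/weight"))
  }
  ut <- which(upper.tri(m$values, diag = TRUE) & !is.na(m$values) &
                m$values != 0, arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  b1 <- ut[, 1L] - 1L
  rhdf5::h5write(as.integer(b1), path, grp("pixels/bin1_id"))
  rhdf5::h5write(as.integer(ut[, 2L] - 1L), path, grp("pixels/bin2_id"))
  rhdf5::h5write(as.double(m$values[ut]), path, grp("pixels/count"))
  # bin1_offset[k] = first pixel row whose bin1_id >= k-1 (0-based CSR index)
  off <- c(0L, cumsum(tabulate(b1 + 1L, nbins = N)))
  rhdf5::h5write(as.integer(off), path, grp("indexes/bin1_offset"))
  rhdf5::h5write(c(0L, N), path, grp("indexes/chrom_offset"))

  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  tgt <- if (root == "") fid else {
    gid <- rhdf5::H5Gopen(fid, root)
    on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
    gid
  }
  rhdf5::h5writeAttribute("HDF5::Cooler", tgt, "format")
  rhdf5::h5writeAttribute(3L, tgt, "format-version")
  rhdf5::h5writeAttribute(as.integer(m$resolution), tgt, "bin-size")
  rhdf5::h5writeAttribute(as.integer(N), tgt, "nbins")
  rhdf5::h5writeAttribute(1L, tgt, "nchroms")
  rhdf5::h5writeAttribute(nrow(ut), tgt, "nnz")
  rhdf5::h5writeAttribute("symmetric-upper", tgt, "storage-mode")
  invisible(path)
}
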