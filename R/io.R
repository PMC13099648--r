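# Tabular, MatrixMarket and event-table I/O. TSV is the canonical dialect
# (UTF-8, '.' decimal, header row); counts use 1-based MatrixMarket
# coordinates; event tables are BED-like with half-open intervals.

#' Read / write tab-separated tables
#'
#' Thin wrappers guaranteeing round-trip identity and reporting the line
#' number on malformed input.
#'
#' @param path File path.
#' @param x `data.frame` to write.
#' @return `read_tabular()` returns a `data.frame`.
#' @export
read_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- tryCatch(count.fields(path, sep = "\t", quote = ""),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("malformed TSV at line ", bad, " of ", path,
         ": expected ", nf[1], " fields, found ", nf[bad])
  }
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tabular
#' @export
write_tabular <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an LFP recording as TSV plus JSON sidecar
#'
#' The TSV carries `time_s` and one `ch<i>_uv` column per channel; the
#' sidecar stores the sampling rate, channel metadata and activity mask as
#' intervals.
#'
#' @param rec An `lfp_recording`.
#' @param path TSV path; the sidecar is `<path>.json`.
#' @return `read_lfp()` returns an `lfp_recording`.
#' @export
write_lfp <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  n <- nrow(rec$samples)
  d <- data.frame(time_s = (seq_len(n) - 1) / rec$fs_hz)
  for (j in seq_len(ncol(rec$samples)))
    d[[sprintf("ch%d_uv", j)]] <- rec$samples[, j]
  write_tabular(d, path)
  mask_iv <- NULL
  if (!is.null(rec$activity_mask)) {
    r <- rle(rec$activity_mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    on <- which(r$values)
    mask_iv <- data.frame(start_s = (starts[on] - 1L) / rec$fs_hz,
                          end_s = ends[on] / rec$fs_hz)
  }
  jsonlite::write_json(
    list(fs_hz = rec$fs_hz, channel_meta = rec$channel_meta,
         activity_mask = mask_iv),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  d <- read_tabular(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(d[, grep("^ch", names(d)), drop = FALSE])
  mask <- NULL
  if (!is.null(side$activity_mask) && length(side$activity_mask)) {
    mask <- rep(FALSE, nrow(x))
    iv <- as.data.frame(side$activity_mask)
    for (i in seq_len(nrow(iv))) {
      a <- max(1L, floor(iv$start_s[i] * side$fs_hz) + 1L)
      b <- min(nrow(x), round(iv$end_s[i] * side$fs_hz))
      if (b >= a) mask[a:b] <- TRUE
    }
  }
  lfp_recording(x, side$fs_hz, channel_meta = as.data.frame(side$channel_meta),
                activity_mask = mask)
}

#' Write / read detected events as BED-like TSV
#'
#' @param events Event table (e.g. from [detect_iis()]).
#' @param path File path.
#' @return `read_events()` returns the `data.frame`.
#' @export
write_events <- function(events, path) write_tabular(events, path)

#' @rdname write_events
#' @export
read_events <- function(path) read_tabular(path)

#' Write / read a count matrix as MatrixMarket plus TSVs
#'
#' Writes `<dir>/matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#' `cellmeta.tsv` in the conventional layout.
#'
#' @param sim List with `counts`, `genes`, `barcodes`, `meta` (as returned
#'   by [simulate_counts()]).
#' @param dir Output directory (created if missing).
#' @return `read_counts_mtx()` returns the same list structure.
#' @export
write_counts_mtx <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sim$counts, file.path(dir, "matrix.mtx"))
  writeLines(sim$genes, file.path(dir, "genes.tsv"))
  writeLines(sim$barcodes, file.path(dir, "barcodes.tsv"))
  write_tabular(sim$meta, file.path(dir, "cellmeta.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes, barcodes)
  meta <- read_tabular(file.path(dir, "cellmeta.tsv"))
  list(counts = counts, genes = genes, barcodes = barcodes, meta = meta)
}
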