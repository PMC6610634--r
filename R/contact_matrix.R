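#' Binned contact matrices
#'
#' A `contact_matrix` holds a symmetric `n_bins x n_bins` matrix of contact
#' values for one chromosome, together with its binning, an allele label
#' (`mus` = Xi, `cas` = Xa, `comp` = all reads), a per-bin mappability mask
#' (`TRUE` = unmappable/excluded), and a `balanced` flag.
#'
#' @param values Symmetric numeric matrix, no negative entries.
#' @param binning A [genome_binning()] with `n_bins == nrow(values)`.
#' @param allele One of "mus", "cas", "comp".
#' @param mask Logical vector per bin; `TRUE` marks unmappable bins.
#' @param balanced Has iterative correction been applied?
#' @param metadata Free-form list (sample, regime, seeds...).
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(values, binning, allele = "comp",
                           mask = rep(FALSE, binning$n_bins),
                           balanced = FALSE, metadata = list()) {
  values <- as.matrix(values)
  if (nrow(values) != binning$n_bins || ncol(values) != binning$n_bins)
    stop("matrix dimensions do not match binning")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("contact matrix must be symmetric")
  if (any(values < 0, na.rm = TRUE)) stop("negative contact values")
  if (!allele %in% c("mus", "cas", "comp"))
    stop("allele must be one of 'mus', 'cas', 'comp'")
  stopifnot(length(mask) == binning$n_bins)
  structure(list(values = values, binning = binning, allele = allele,
                 mask = as.logical(mask), balanced = balanced,
                 metadata = metadata),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s [%s] %d bins of %s bp; %d masked; total %.4g%s\n",
    x$binning$chrom, x$allele, x$binning$n_bins,
    format(x$binning$bin_size_bp, big.mark = ","), sum(x$mask),
    matrix_total(x), if (x$balanced) "; balanced" else ""))
  invisible(x)
}

#' Total contact count of a matrix
#'
#' Sums each unordered bin pair once (the diagonal once, each off-diagonal
#' pair once), so the total matches the number of contacts in the sparse
#' upper-triangular representation.
#'
#' @param m A `contact_matrix`.
#' @export
matrix_total <- function(m) {
  v <- m$values
  sum(v[upper.tri(v, diag = TRUE)], na.rm = TRUE)
}

#' Read a sparse contact matrix
#'
#' Reads whitespace/tab-separated `bin_i bin_j count` triples (0-based bin
#' indices, upper-triangular or full; symmetrized on read). Lines starting
#' with `#` and an optional header line are skipped. Gzip files are handled
#' transparently.
#'
#' @param path Path to the triple file.
#' @param binning A [genome_binning()] giving `n_bins`.
#' @param ... Passed to [contact_matrix()] (allele, metadata...).
#' @return A `contact_matrix`.
#' @export
read_sparse_matrix <- function(path, binning, ...) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("[A-Za-z]", lines[[1]])) {  # header
    lines <- lines[-1]; ln <- ln[-1]
  }
  n <- binning$n_bins
  values <- matrix(0, n, n)
  if (length(lines)) {
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(vapply(parts, length, 1L) < 3L)
    if (length(bad))
      stop(sprintf("malformed line %d in %s", ln[bad[1]], path))
    i <- as.numeric(vapply(parts, `[[`, "", 1L))
    j <- as.numeric(vapply(parts, `[[`, "", 2L))
    cnt <- as.numeric(vapply(parts, `[[`, "", 3L))
    if (anyNA(i) || anyNA(j) || anyNA(cnt))
      stop(sprintf("malformed line %d in %s",
                   ln[which(is.na(i) | is.na(j) | is.na(cnt))[1]], path))
    oob <- which(i < 0 | i >= n | j < 0 | j >= n)
    if (length(oob))
      stop(sprintf("bin index out of range on line %d: '%s'",
                   ln[oob[1]], lines[oob[1]]))
    neg <- which(cnt < 0)
    if (length(neg))
      stop(sprintf("negative count on line %d: '%s'",
                   ln[neg[1]], lines[neg[1]]))
    # accumulate; symmetrize so each off-diagonal triple is counted once
    lo <- pmin(i, j) + 1L; hi <- pmax(i, j) + 1L
    idx <- (hi - 1L) * n + lo  # upper triangle linear index
    acc <- tapply(cnt, idx, sum)
    pos <- as.integer(names(acc))
    values[pos] <- acc
    values[lower.tri(values)] <- 0
    values <- values + t(values) - diag(diag(values), n)
  }
  contact_matrix(values, binning, ...)
}

#' Write a sparse contact matrix
#'
#' Writes the upper triangle (including the diagonal) as 0-based
#' `bin1 bin2 count` triples with full numeric precision; zero cells are
#' omitted. Masked bins' rows are written as stored (typically zero).
#'
#' @param m A `contact_matrix`.
#' @param path Output path (`.gz` for gzip).
#' @export
write_sparse_matrix <- function(m, path) {
  v <- m$values
  ut <- which(upper.tri(v, diag = TRUE) & v != 0 & !is.na(v), arr.ind = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("bin1\tbin2\tcount", con)
  if (nrow(ut))
    writeLines(sprintf("%d\t%d\t%s", ut[, 1] - 1L, ut[, 2] - 1L,
                       format(v[ut], digits = 17, trim = TRUE,
                              scientific = FALSE)), con)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path Path to chrom.sizes.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  stats::setNames(d$length, d$chrom)
}
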