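#' Coverage tracks
#'
#' A `coverage_track` is a piecewise-constant signal over one chromosome,
#' stored as sorted, non-overlapping 0-based half-open intervals with finite
#' values. Bases not covered by any interval have value 0.
#'
#' @param chrom Chromosome name.
#' @param start,end,value Interval columns (0-based half-open).
#' @param norm Normalization tag: "raw", "fpm", "input_subtracted", "scaled".
#' @return A `coverage_track` (data frame with columns start, end, value).
#' @export
coverage_track <- function(chrom, start = numeric(0), end = numeric(0),
                           value = numeric(0), norm = "raw") {
  start <- as.numeric(start); end <- as.numeric(end)
  value <- rep(as.numeric(value), length.out = length(start))
  o <- order(start)
  start <- start[o]; end <- end[o]; value <- value[o]
  if (any(end <= start)) stop("intervals must have end > start")
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("overlapping intervals in coverage track")
  if (any(!is.finite(value))) stop("track values must be finite")
  structure(data.frame(start = start, end = end, value = value),
            chrom = chrom, norm = norm,
            class = c("coverage_track", "data.frame"))
}

track_chrom <- function(track) attr(track, "chrom")

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s [%s]: %d intervals spanning [%g, %g)\n",
              attr(x, "chrom"), attr(x, "norm"), nrow(x),
              if (nrow(x)) min(x$start) else 0,
              if (nrow(x)) max(x$end) else 0))
  invisible(x)
}

#' Read / write bedGraph
#'
#' bedGraph is the package's normative text dialect for coverage tracks:
#' `chrom start end value`, 0-based half-open, tab- or space-separated.
#' `track` and comment lines are skipped; gzip files are handled
#' transparently. Writing preserves full numeric precision so that
#' `read_bedgraph(write_bedgraph(t))` reproduces `t` at every base.
#'
#' @param path File path (`.gz` allowed).
#' @param chrom Restrict to one chromosome (default: the file's single
#'   chromosome; multi-chromosome files require `chrom`).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom = NULL) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  ln <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    if (is.null(chrom)) chrom <- "chrUnknown"
    return(coverage_track(chrom))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) < 4L)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d in %s", ln[bad[1]], path))
  chr <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  val <- as.numeric(vapply(parts, `[[`, "", 4L))
  if (anyNA(start) || anyNA(end) || anyNA(val))
    stop(sprintf("malformed bedGraph line %d in %s",
                 ln[which(is.na(start) | is.na(end) | is.na(val))[1]], path))
  if (is.null(chrom)) {
    u <- unique(chr)
    if (length(u) > 1)
      stop("multi-chromosome bedGraph; supply `chrom`")
    chrom <- u
  } else {
    sel <- chr == chrom
    start <- start[sel]; end <- end[sel]; val <- val[sel]
  }
  tryCatch(coverage_track(chrom, start, end, val),
           error = function(e)
             stop(sprintf("invalid bedGraph %s: %s", path, conditionMessage(e))))
}

#' @param track A [coverage_track()].
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(track))
    writeLines(sprintf("%s\t%s\t%s\t%s", attr(track, "chrom"),
                       format(track$start, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       format(track$end, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       format(track$value, digits = 17, trim = TRUE,
                              scientific = FALSE)), con)
  invisible(path)
}

#' Read a BED file
#'
#' BED3/BED6, 0-based half-open, preserved verbatim. Returns a region data
#' frame as produced by [region()].
#'
#' @param path File path (`.gz` allowed).
#' @param category Optional category label attached to every region.
#' @return Data frame with columns chrom, start, end, name, strand, category
#'   (and score for BED6 input).
#' @export
read_bed <- function(path, category = NA_character_) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  ln <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      strand = character(0), category = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d in %s", ln[which(nf < 3L)[1]], path))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  if (any(start >= end, na.rm = TRUE) || anyNA(start) || anyNA(end))
    stop(sprintf("invalid interval on BED line %d in %s",
                 ln[which(is.na(start) | is.na(end) | start >= end)[1]], path))
  name <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))], ""), ".")
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(
                    vapply(parts, function(p) p[min(5L, length(p))], ""))), NA)
  strand <- ifelse(nf >= 6L, vapply(parts, function(p) p[min(6L, length(p))], ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  r <- region(chrom, start, end, name, strand, category)
  r$score <- score
  r
}

#' Write regions as BED
#'
#' @param regions A region data frame.
#' @param path Output path.
#' @param score Optional numeric vector for the BED score column.
#' @export
write_bed <- function(regions, path, score = NULL) {
  if (is.null(score)) score <- if ("score" %in% names(regions) &&
                                   !all(is.na(regions$score)))
    regions$score else rep(0, nrow(regions))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(regions))
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                       regions$chrom,
                       format(regions$start, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       format(regions$end, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       regions$name,
                       format(score, trim = TRUE),
                       regions$strand), con)
  invisible(path)
}

#' Read an allelic gene count table
#'
#' Tab-separated with header; required columns `gene_id`, `gene_length_bp`,
#' `sample_id`, `condition`, `clone`, `mus_reads`, `cas_reads`, `fpkm`.
#'
#' @param path File path.
#' @return A validated allelic gene table (data frame).
#' @export
read_allelic_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_allelic_table(d)
}

#' @rdname read_allelic_table
#' @param table Data frame to validate in place.
#' @export
validate_allelic_table <- function(table) {
  need <- c("gene_id", "gene_length_bp", "sample_id", "condition", "clone",
            "mus_reads", "cas_reads", "fpkm")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("allelic table missing columns: ", paste(miss, collapse = ", "))
  if (any(table$mus_reads < 0) || any(table$cas_reads < 0))
    stop("negative read counts")
  if (any(table$mus_reads != round(table$mus_reads)) ||
      any(table$cas_reads != round(table$cas_reads)))
    stop("read counts must be integral")
  if (any(table$fpkm < 0)) stop("negative FPKM")
  cnt <- table(table$gene_id, table$sample_id)
  if (any(cnt != 1L))
    stop("every gene must appear exactly once in every sample")
  table
}

#' Write an allelic gene count table
#' @param table Allelic gene table.
#' @param path Output path.
#' @export
write_allelic_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
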