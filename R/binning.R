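#' Genome binning
#'
#' Fixed-width binning of a single chromosome. All base-pair coordinates in
#' this package are 0-based half-open (BED convention); bin `i` (1-based in R)
#' covers `[(i-1)*bin_size, min(i*bin_size, chrom_length))`. The last bin may
#' be short.
#'
#' @param chrom Chromosome name.
#' @param chrom_length_bp Chromosome length in bp (>= 1).
#' @param bin_size_bp Bin width in bp (>= 1).
#' @return An object of class `genome_binning` with fields `chrom`,
#'   `chrom_length_bp`, `bin_size_bp`, `n_bins`.
#' @examples
#' b <- genome_binning("chrX", 166e6, 200e3)
#' b$n_bins
#' @export
genome_binning <- function(chrom, chrom_length_bp, bin_size_bp) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  chrom_length_bp <- as.numeric(chrom_length_bp)
  bin_size_bp <- as.numeric(bin_size_bp)
  if (chrom_length_bp < 1 || bin_size_bp < 1)
    stop("chromosome length and bin size must be >= 1 bp")
  structure(
    list(chrom = chrom,
         chrom_length_bp = chrom_length_bp,
         bin_size_bp = bin_size_bp,
         n_bins = as.integer(ceiling(chrom_length_bp / bin_size_bp))),
    class = "genome_binning")
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("<genome_binning> %s: %s bp, %s bins of %s bp\n",
              x$chrom, format(x$chrom_length_bp, big.mark = ","),
              x$n_bins, format(x$bin_size_bp, big.mark = ",")))
  invisible(x)
}

#' Map base-pair positions to bins
#'
#' @param binning A `genome_binning`.
#' @param bp 0-based positions (vector).
#' @return 1-based bin indices.
#' @export
bin_of <- function(binning, bp) {
  if (any(bp < 0 | bp >= binning$chrom_length_bp))
    stop("position outside chromosome")
  as.integer(bp %/% binning$bin_size_bp) + 1L
}

#' Bin start / end coordinates
#'
#' @param binning A `genome_binning`.
#' @param i 1-based bin indices.
#' @return 0-based start (or half-open end) positions.
#' @export
bin_start <- function(binning, i) (i - 1) * binning$bin_size_bp

#' @rdname bin_start
#' @export
bin_end <- function(binning, i)
  pmin(i * binning$bin_size_bp, binning$chrom_length_bp)

#' Widths of all bins (last may be short)
#' @param binning A `genome_binning`.
#' @export
bin_widths <- function(binning)
  bin_end(binning, seq_len(binning$n_bins)) -
    bin_start(binning, seq_len(binning$n_bins))

#' Construct genomic regions
#'
#' Regions are plain data frames in 0-based half-open coordinates with
#' columns `chrom`, `start`, `end`, `name`, `strand`, and optionally
#' `category`.
#'
#' @param chrom,start,end,name,strand,category Vectors (recycled).
#' @return A `data.frame` of regions.
#' @export
region <- function(chrom, start, end, name = ".", strand = ".",
                   category = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("region start must be >= 0")
  if (any(end <= start)) stop("region end must be > start")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, category = category,
             stringsAsFactors = FALSE)
}

#' Bins overlapped by a region
#'
#' @param binning A `genome_binning`.
#' @param start,end One region, 0-based half-open.
#' @return Integer vector of 1-based bin indices.
#' @export
bins_in_region <- function(binning, start, end) {
  end <- min(end, binning$chrom_length_bp)
  if (start >= binning$chrom_length_bp || end <= 0) return(integer(0))
  seq.int(bin_of(binning, max(start, 0)), bin_of(binning, end - 1))
}
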