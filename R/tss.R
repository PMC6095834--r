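#' Read transcription start sites from a BED6 file
#'
#' BED coordinates are 0-based half-open. The TSS of a `+` strand feature is
#' its start; of a `-` strand feature, `end - 1` (the last covered base).
#'
#' @param path BED file with at least 6 columns.
#' @return Data frame: chrom, tss (0-based), strand, name.
#' @export
read_bed_tss <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  raw <- raw[nzchar(raw)]
  body <- !grepl("^(#|track|browser)", raw)
  for (i in which(body)) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L)
      stop("malformed BED line ", i, ": fewer than 6 columns", call. = FALSE)
    if (is.na(suppressWarnings(as.numeric(f[2L]))) ||
        is.na(suppressWarnings(as.numeric(f[3L]))))
      stop("malformed BED line ", i, ": non-numeric coordinates",
           call. = FALSE)
    if (!f[6L] %in% c("+", "-"))
      stop("malformed BED line ", i, ": strand must be '+' or '-'",
           call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  # GRanges is 1-based closed; start(gr) - 1 recovers the BED start
  tss <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("region%05d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             tss = as.integer(tss), strand = strand, name = nm,
             stringsAsFactors = FALSE)
}

#' @rdname read_bed_tss
#' @param regions Data frame as returned by `read_bed_tss`.
#' @export
write_bed_tss <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$tss, regions$tss + 1L,
                   regions$name, 0L, regions$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a coverage track from a 4-column bedGraph
#'
#' Intervals are 0-based half-open with non-negative values; uncovered
#' positions read as zero.
#'
#' @param path bedGraph file.
#' @return A `signal_track`: a per-chromosome `RleList` of base-level
#'   values.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("bedGraph values must be >= 0")
  cov <- GenomicRanges::coverage(gr, weight = "score")
  structure(list(coverage = cov), class = "signal_track")
}

#' Build a signal track directly from intervals
#'
#' @param chrom,start,end,value Parallel vectors of 0-based half-open
#'   intervals with non-negative values.
#' @return A `signal_track`.
#' @export
signal_track <- function(chrom, start, end, value) {
  if (any(value < 0)) stop("track values must be >= 0")
  if (any(end <= start)) stop("intervals must have end > start")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               score = value)
  if (!IRanges::isDisjoint(gr)) stop("track intervals must not overlap")
  structure(list(coverage = GenomicRanges::coverage(gr, weight = "score")),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track over %d chromosome(s): %s\n",
              length(x$coverage),
              paste(names(x$coverage), collapse = ", ")))
  invisible(x)
}

## Base-level values of one chromosome over 1-based positions from..to,
## zero-padded outside the covered range.
.track_window <- function(cov, chrom, from, to) {
  n <- to - from + 1L
  if (!chrom %in% names(cov)) return(NULL)
  r <- cov[[chrom]]
  v <- numeric(n)
  lo <- max(from, 1L)
  hi <- min(to, length(r))
  if (hi >= lo)
    v[(lo - from + 1L):(hi - from + 1L)] <-
      as.numeric(S4Vectors::window(r, lo, hi))
  v
}

#' Signal matrix over TSS-centred windows
#'
#' For each region, averages base-level track values within consecutive bins
#' of the window `[tss - flank, tss + flank)` (0-based). Windows of `-`
#' strand regions are reversed so that downstream of the TSS is always to
#' the right. Positions outside the covered genome read zero; regions on
#' chromosomes absent from the track get all-zero rows and are counted in
#' the `missing_chrom` attribute.
#'
#' @param track A `signal_track`.
#' @param regions TSS regions (see [read_bed_tss()]).
#' @param flank Half-window size in bp (default 3000).
#' @param bin_size Bin width in bp (default 50); must divide `flank`.
#' @return Numeric matrix regions x bins with bin-start offsets (bp relative
#'   to the TSS) as column names.
#' @export
tss_matrix <- function(track, regions, flank = 3000L, bin_size = 50L) {
  stopifnot(inherits(track, "signal_track"))
  if (flank %% bin_size != 0)
    stop("flank must be a multiple of bin_size")
  n_bins <- as.integer(2L * flank / bin_size)
  offsets <- seq(-flank, flank - bin_size, by = bin_size)
  m <- matrix(0, nrow(regions), n_bins,
              dimnames = list(regions$name, offsets))
  missing_chrom <- 0L
  for (i in seq_len(nrow(regions))) {
    # 0-based [tss - flank, tss + flank) is 1-based [tss - flank + 1, tss + flank]
    v <- .track_window(track$coverage, regions$chrom[i],
                       regions$tss[i] - flank + 1L,
                       regions$tss[i] + flank)
    if (is.null(v)) {
      missing_chrom <- missing_chrom + 1L
      next
    }
    if (regions$strand[i] == "-") v <- rev(v)
    m[i, ] <- colMeans(matrix(v, nrow = bin_size))
  }
  if (missing_chrom > 0L)
    warning(missing_chrom,
            " region(s) on chromosomes absent from the track read as zero")
  attr(m, "missing_chrom") <- missing_chrom
  attr(m, "bin_size") <- as.integer(bin_size)
  attr(m, "flank") <- as.integer(flank)
  m
}

#' Average signal profile over aligned TSS windows
#'
#' Per-bin mean and standard error (sd / sqrt(n)) over regions.
#'
#' @param matrix Output of [tss_matrix()].
#' @return Object of class `meta_profile`: data-frame-backed list with
#'   `offset` (bp, bin starts relative to TSS), `mean`, `stderr` and
#'   `n_regions`.
#' @export
average_profile <- function(matrix) {
  if (nrow(matrix) == 0L) stop("empty region matrix")
  n <- nrow(matrix)
  mu <- colMeans(matrix)
  se <- if (n > 1L) apply(matrix, 2L, stats::sd) / sqrt(n) else rep(0, ncol(matrix))
  structure(list(offset = as.integer(colnames(matrix)),
                 mean = unname(mu), stderr = unname(se),
                 n_regions = n,
                 bin_size = attr(matrix, "bin_size")),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf(
    "meta_profile: %d bins of %d bp over %d regions; peak mean %.4g at %+d bp\n",
    length(x$offset), x$bin_size, x$n_regions,
    max(x$mean), x$offset[which.max(x$mean)]))
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, shade = "grey80", ...) {
  lo <- x$mean - x$stderr
  hi <- x$mean + x$stderr
  graphics::plot(x$offset, x$mean, type = "n",
                 xlab = "distance from TSS (bp)", ylab = "mean signal",
                 ylim = range(lo, hi), ...)
  graphics::polygon(c(x$offset, rev(x$offset)), c(hi, rev(lo)),
                    col = shade, border = NA)
  graphics::lines(x$offset, x$mean, lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Write a metaprofile to TSV (offset, mean, stderr, n)
#' @param profile A `meta_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  write_tsv_strict(data.frame(offset = profile$offset,
                              mean = profile$mean,
                              stderr = profile$stderr,
                              n = profile$n_regions), path)
}
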