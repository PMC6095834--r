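#' Read a tab-separated table
#'
#' All tabular files handled by this package share one dialect: tab-separated,
#' UTF-8, a header row, lines starting with `#` ignored, first column the row
#' key. This helper enforces it.
#'
#' @param path File path.
#' @param row_key Logical; if `TRUE` the first column becomes row names and
#'   must be unique.
#' @return A `data.frame`.
#' @keywords internal
read_tsv_strict <- function(path, row_key = FALSE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (row_key) {
    keys <- as.character(df[[1L]])
    dup <- keys[duplicated(keys)]
    if (length(dup) > 0L) {
      stop("duplicate row keys in ", path, ": ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    rownames(df) <- keys
    df <- df[, -1L, drop = FALSE]
  }
  df
}

write_tsv_strict <- function(df, path, key_name = NULL) {
  if (!is.null(key_name)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                key_name),
                df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a screen count table
#'
#' Bundles an integer hairpin-by-sample count matrix with its per-sample
#' metadata and validates the pairing: counts must be non-negative integers,
#' sample ids must match the metadata, and every cell line present must carry
#' both a T0 (reference) and a T1 (endpoint) timepoint.
#'
#' @param counts Integer matrix, rows named by hairpin id, columns by sample
#'   id.
#' @param samples `data.frame` with columns `sample_id`, `cell_line`,
#'   `timepoint` (values `"T0"`/`"T1"`) and `replicate`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `samples`.
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have hairpin row names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate hairpin ids in count matrix")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count at hairpin '%s', sample '%s'",
                 rownames(counts)[bad[1L, 1L]],
                 colnames(counts)[bad[1L, 2L]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  need <- c("sample_id", "cell_line", "timepoint", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L)
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$timepoint <- as.character(samples$timepoint)
  if (!all(samples$timepoint %in% c("T0", "T1")))
    stop("timepoint must be 'T0' or 'T1'")
  key <- paste(samples$cell_line, samples$timepoint, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicate (cell_line, timepoint, replicate) in sample metadata")
  if (is.null(colnames(counts)))
    stop("counts must have sample column names")
  unmatched <- setdiff(colnames(counts), samples$sample_id)
  if (length(unmatched) > 0L)
    stop("count columns without metadata: ", paste(unmatched, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  for (line in unique(samples$cell_line)) {
    tp <- samples$timepoint[samples$cell_line == line]
    if (!all(c("T0", "T1") %in% tp))
      stop("cell line '", line, "' lacks a T0 or T1 sample", call. = FALSE)
  }
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d hairpins x %d samples (%d cell lines)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$cell_line))))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read screen counts and sample metadata from TSV
#'
#' @param path Counts TSV: first column hairpin id, one column per sample.
#' @param metadata_path Metadata TSV with columns `sample_id`, `cell_line`,
#'   `timepoint`, `replicate`.
#' @return A [count_table()].
#' @export
read_counts <- function(path, metadata_path) {
  df <- read_tsv_strict(path, row_key = TRUE)
  samples <- read_tsv_strict(metadata_path)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("counts file contains non-numeric entries", call. = FALSE)
  count_table(m, samples)
}

#' Write screen counts and sample metadata to TSV
#'
#' @param table A [count_table()].
#' @param path Output counts TSV path.
#' @param metadata_path Output metadata TSV path.
#' @export
write_counts <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "count_table"))
  write_tsv_strict(as.data.frame(table$counts), path, key_name = "hairpin_id")
  write_tsv_strict(table$samples, metadata_path)
  invisible(path)
}

#' Construct or validate a hairpin library table
#'
#' @param hairpin_id Character, unique hairpin identifiers.
#' @param gene_symbol Character, non-empty gene symbols (one per hairpin).
#' @param sequence Optional character of A/C/G/T sequences, length >= 18.
#' @return `data.frame` of class `hairpin_library`.
#' @export
hairpin_library <- function(hairpin_id, gene_symbol, sequence = NULL) {
  hairpin_id <- as.character(hairpin_id)
  gene_symbol <- as.character(gene_symbol)
  if (anyDuplicated(hairpin_id)) stop("hairpin ids must be unique")
  if (any(!nzchar(gene_symbol))) stop("gene symbols must be non-empty")
  lib <- data.frame(hairpin_id = hairpin_id, gene_symbol = gene_symbol,
                    stringsAsFactors = FALSE)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (any(nchar(sequence) < 18L))
      stop("library sequences must be at least 18 nt")
    if (any(grepl("[^ACGT]", sequence)))
      stop("library sequences must be over the alphabet {A,C,G,T}")
    lib$sequence <- sequence
  }
  class(lib) <- c("hairpin_library", "data.frame")
  lib
}

#' Read a hairpin library TSV (hairpin_id, gene, optional sequence)
#' @param path Library TSV path.
#' @return A [hairpin_library()].
#' @export
read_library <- function(path) {
  df <- read_tsv_strict(path)
  names(df)[names(df) == "gene"] <- "gene_symbol"
  hairpin_library(df$hairpin_id, df$gene_symbol,
                  sequence = if ("sequence" %in% names(df)) df$sequence)
}

#' @rdname read_library
#' @param library A [hairpin_library()].
#' @export
write_library <- function(library, path) {
  write_tsv_strict(as.data.frame(library), path)
}

#' Read a cell-line genotype table (cell_line, genotype)
#'
#' Genotype values must be `"wildtype"` or `"mutant"`.
#' @param path Genotype TSV path.
#' @return Named character vector of genotypes, names = cell lines.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_strict(path)
  g <- as.character(df$genotype)
  if (!all(g %in% c("wildtype", "mutant")))
    stop("genotype must be 'wildtype' or 'mutant'")
  stats::setNames(g, as.character(df$cell_line))
}

#' @rdname read_genotypes
#' @param genotypes Named character vector as returned by `read_genotypes`.
#' @export
write_genotypes <- function(genotypes, path) {
  write_tsv_strict(data.frame(cell_line = names(genotypes),
                              genotype = unname(genotypes),
                              stringsAsFactors = FALSE), path)
}

#' Count hairpin barcodes in raw reads
#'
#' Assigns each read by exact substring matching of the first `match_len`
#' bases of every library hairpin sequence. A read increments a hairpin only
#' when exactly one library prefix occurs in it; reads matching zero or two
#' or more hairpins are tallied as discarded, so assigned + discarded always
#' equals the number of reads processed.
#'
#' @param fastq Path to a FASTQ file (gzip allowed).
#' @param library A [hairpin_library()] with sequences.
#' @param match_len Prefix length used for matching (default 21, the TRC
#'   hairpin target length).
#' @return Named integer vector of per-hairpin counts with attribute
#'   `discarded` (number of unassigned reads).
#' @export
count_barcodes <- function(fastq, library, match_len = 21L) {
  if (is.null(library$sequence))
    stop("library has no sequences; barcode counting needs them")
  if (any(nchar(library$sequence) < match_len))
    stop("all library sequences must be at least match_len long")
  prefixes <- substr(library$sequence, 1L, match_len)
  if (anyDuplicated(prefixes)) {
    dup <- library$hairpin_id[duplicated(prefixes) |
                                duplicated(prefixes, fromLast = TRUE)]
    stop("ambiguous library: hairpins share a ", match_len,
         "-nt prefix: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  counts <- stats::setNames(integer(nrow(library)), library$hairpin_id)
  discarded <- 0L
  if (length(reads) > 0L) {
    pdict <- Biostrings::PDict(Biostrings::DNAStringSet(prefixes))
    hit_idx <- Biostrings::vwhichPDict(pdict, reads)
    n_hits <- lengths(hit_idx)
    uniq <- n_hits == 1L
    discarded <- sum(!uniq)
    if (any(uniq)) {
      assigned <- unlist(hit_idx[uniq], use.names = FALSE)
      tab <- tabulate(assigned, nbins = nrow(library))
      counts[] <- tab
    }
  }
  attr(counts, "discarded") <- discarded
  counts
}
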