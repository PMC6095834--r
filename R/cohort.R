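#' Assemble a gene x cell-line hit matrix
#'
#' @param hit_lists Named list, one element per cell line: either a
#'   character vector of hit genes or a `line_hits` object / summaries data
#'   frame (from which `is_hit` genes and their `gene_rank`s are taken).
#' @param genotypes Named character vector (`"wildtype"`/`"mutant"`), one
#'   entry per screened line.
#' @return Object of class `hit_matrix`: list with `hits` (logical gene x
#'   line matrix over the union of genes), `ranks` (numeric gene x line
#'   matrix of gene ranks, `NA` where unavailable) and `genotypes`.
#' @export
build_hit_matrix <- function(hit_lists, genotypes) {
  lines <- names(hit_lists)
  if (is.null(lines) || any(!nzchar(lines)))
    stop("hit_lists must be named by cell line")
  missing_g <- setdiff(lines, names(genotypes))
  if (length(missing_g) > 0L)
    stop("no genotype for line(s): ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  per_line <- lapply(hit_lists, function(x) {
    if (inherits(x, "line_hits")) x <- x$summaries
    if (is.data.frame(x)) {
      list(genes = x$gene_symbol[x$is_hit],
           ranks = stats::setNames(x$gene_rank, x$gene_symbol))
    } else {
      list(genes = as.character(x), ranks = NULL)
    }
  })
  genes <- sort(unique(unlist(lapply(per_line, `[[`, "genes"))))
  hits <- matrix(FALSE, length(genes), length(lines),
                 dimnames = list(genes, lines))
  ranks <- matrix(NA_real_, length(genes), length(lines),
                  dimnames = list(genes, lines))
  for (ln in lines) {
    hits[per_line[[ln]]$genes, ln] <- TRUE
    r <- per_line[[ln]]$ranks
    if (!is.null(r)) {
      common <- intersect(genes, names(r))
      ranks[common, ln] <- r[common]
    }
  }
  structure(list(hits = hits, ranks = ranks,
                 genotypes = genotypes[lines]),
            class = "hit_matrix")
}

#' @export
print.hit_matrix <- function(x, ...) {
  cat(sprintf("hit_matrix: %d genes x %d lines (%d wildtype, %d mutant)\n",
              nrow(x$hits), ncol(x$hits),
              sum(x$genotypes == "wildtype"), sum(x$genotypes == "mutant")))
  invisible(x)
}

#' Common lethal genes across the panel
#'
#' Genes hit in at least `min_fraction` of lines, ranked by descending hit
#' fraction then ascending mean gene rank across lines where a rank is
#' known.
#'
#' @param matrix A [build_hit_matrix()] result.
#' @param min_fraction Minimum fraction of lines in which the gene is a hit
#'   (default 1, i.e. hit everywhere).
#' @return Data frame: gene_symbol, n_hit, fraction, mean_rank.
#' @export
common_lethals <- function(matrix, min_fraction = 1) {
  stopifnot(inherits(matrix, "hit_matrix"))
  frac <- rowMeans(matrix$hits)
  mean_rank <- rowMeans(matrix$ranks, na.rm = TRUE)
  keep <- frac >= min_fraction
  out <- data.frame(gene_symbol = rownames(matrix$hits)[keep],
                    n_hit = rowSums(matrix$hits)[keep],
                    fraction = frac[keep],
                    mean_rank = mean_rank[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fraction, out$mean_rank, out$gene_symbol), , drop = FALSE]
}

#' Genotype-stratified hit association
#'
#' Per gene, counts hit lines by genotype and computes a specificity score
#' (mutant hit fraction minus wildtype hit fraction, in [-1, 1]) and a
#' two-sided Fisher exact p-value on the 2x2 genotype-by-hit table. Ranked
#' by descending specificity, ties by ascending p — genes lethal in most
#' mutant lines and few wildtype lines rise to the top.
#'
#' @param matrix A [build_hit_matrix()] result with both genotypes present.
#' @return Data frame: gene_symbol, n_hit_mut, n_mut, n_hit_wt, n_wt,
#'   specificity_score, fisher_p.
#' @export
genotype_specific <- function(matrix) {
  stopifnot(inherits(matrix, "hit_matrix"))
  mut <- matrix$genotypes == "mutant"
  if (!any(mut) || all(mut))
    stop("both genotypes must be present in the panel")
  n_mut <- sum(mut); n_wt <- sum(!mut)
  hm <- rowSums(matrix$hits[, mut, drop = FALSE])
  hw <- rowSums(matrix$hits[, !mut, drop = FALSE])
  p <- mapply(function(a, b) {
    fisher_exact_2x2(matrix(c(a, n_mut - a, b, n_wt - b), 2L, 2L,
                            byrow = TRUE))
  }, hm, hw)
  out <- data.frame(gene_symbol = rownames(matrix$hits),
                    n_hit_mut = hm, n_mut = n_mut,
                    n_hit_wt = hw, n_wt = n_wt,
                    specificity_score = hm / n_mut - hw / n_wt,
                    fisher_p = as.numeric(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$specificity_score, out$fisher_p, out$gene_symbol), ,
      drop = FALSE]
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities, at fixed margins, of every table no
#' more probable than the observed one (the minimum-likelihood two-sided
#' rule).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1]; attribute `degenerate` is `TRUE` when a
#'   margin is empty (p = 1 by convention).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  a <- table[1L, 1L]
  r1 <- sum(table[1L, ]); r2 <- sum(table[2L, ]); c1 <- sum(table[, 1L])
  if (r1 == 0L || r2 == 0L || c1 == 0L || sum(table[, 2L]) == 0L) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  x <- max(0L, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(x, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Relative growth at a dose
#'
#' Mean signal at the target dose divided by the mean untreated (dose 0)
#' signal, replicates averaged before the ratio.
#'
#' @param dr Dose-response data frame with columns `cell_line`, `dose`,
#'   `signal` (and optionally `drug`, `replicate`).
#' @param line Cell line.
#' @param dose Target dose (same units as `dr$dose`, typically nM).
#' @return Relative growth (>= 0).
#' @export
relative_growth <- function(dr, line, dose) {
  d <- dr[dr$cell_line == line, , drop = FALSE]
  s0 <- d$signal[d$dose == 0]
  s1 <- d$signal[d$dose == dose]
  if (length(s0) == 0L)
    stop("no untreated (dose 0) measurement for line ", line, call. = FALSE)
  if (length(s1) == 0L)
    stop("no dose ", dose, " measurement for line ", line, call. = FALSE)
  mean(s1) / mean(s0)
}

#' Classify drug sensitivity by a single-dose cutoff
#'
#' A line is called sensitive when its relative growth at `reference_dose`
#' falls strictly below `cutoff`.
#'
#' @param dr Dose-response data frame (see [relative_growth()]).
#' @param reference_dose Dose at which to classify (default 250, i.e. nM).
#' @param cutoff Relative-growth cutoff (default 0.5).
#' @return Data frame: cell_line, relative_growth, sensitive, cutoff,
#'   reference_dose.
#' @export
classify_sensitivity <- function(dr, reference_dose = 250, cutoff = 0.5) {
  lines <- unique(dr$cell_line)
  rg <- vapply(lines, function(ln) relative_growth(dr, ln, reference_dose),
               numeric(1))
  data.frame(cell_line = lines, relative_growth = unname(rg),
             sensitive = unname(rg) < cutoff,
             cutoff = cutoff, reference_dose = reference_dose,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-tabulate sensitivity calls against genotype
#'
#' Builds the 2x2 table (rows wildtype/mutant, columns sensitive/resistant)
#' from per-line sensitivity calls and genotype labels.
#'
#' @param calls Output of [classify_sensitivity()].
#' @param genotypes Named character vector of genotypes.
#' @return 2x2 integer matrix suitable for [fisher_exact_2x2()].
#' @export
sensitivity_table <- function(calls, genotypes) {
  g <- genotypes[calls$cell_line]
  if (anyNA(g)) stop("missing genotype for some lines")
  m <- matrix(0L, 2L, 2L,
              dimnames = list(c("wildtype", "mutant"),
                              c("sensitive", "resistant")))
  m["wildtype", ] <- c(sum(calls$sensitive & g == "wildtype"),
                       sum(!calls$sensitive & g == "wildtype"))
  m["mutant", ] <- c(sum(calls$sensitive & g == "mutant"),
                     sum(!calls$sensitive & g == "mutant"))
  m
}

#' Two-group sample size by the normal approximation
#'
#' Closed-form per-group sample size for detecting a relative reduction
#' `effect` between two groups whose standard deviation is `cv` times the
#' control mean:
#' `n = ceil( 2 * (z_{1-alpha/2} + z_{power})^2 * (cv / effect)^2 )`.
#'
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param effect Relative reduction in the treated group, in (0, 1)
#'   (default 0.5).
#' @param cv Coefficient of variation, > 0 (default 0.25).
#' @return Integer sample size per group.
#' @export
sample_size_two_group <- function(alpha = 0.05, power = 0.8,
                                  effect = 0.5, cv = 0.25) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (effect <= 0 || effect >= 1)
    stop("effect must be a relative reduction in (0, 1)")
  if (cv <= 0) stop("cv must be > 0")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- 2 * z^2 * (cv / effect)^2
  as.integer(max(1, ceiling(n)))
}

#' Write a hit matrix to TSV (0/1 genes x lines, genotype row on top)
#' @param matrix A `hit_matrix`.
#' @param path Output path.
#' @export
write_hit_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "hit_matrix"))
  df <- as.data.frame(matrix$hits * 1L)
  df <- rbind(stats::setNames(as.data.frame(as.list(unname(matrix$genotypes)),
                                            stringsAsFactors = FALSE),
                              colnames(df)),
              df)
  rownames(df)[1L] <- "#genotype"
  write_tsv_strict(df, path, key_name = "gene_symbol")
}
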