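#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample so that counts become
#' comparable across sequencing depths: each sample's counts are divided by
#' the per-hairpin geometric mean across samples, and the sample's size
#' factor is the median of those ratios over hairpins with strictly positive
#' counts in every sample.
#'
#' @param counts Integer matrix (hairpins x samples) or a [count_table()].
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  counts <- as.matrix(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("no hairpin has strictly positive counts in all samples; ",
         "size factors undefined", call. = FALSE)
  lk <- log(counts[allpos, , drop = FALSE])
  loggeo <- rowMeans(lk)
  sf <- exp(apply(lk - loggeo, 2L, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Estimate per-hairpin negative-binomial dispersions
#'
#' Method-of-moments raw dispersions from replicate variance of normalized
#' counts, pooled across the two conditions, followed by a robust fit of the
#' mean-dispersion relation `alpha_fit(mu) = a0 + a1 / mu`. The working
#' dispersion for each hairpin is the maximum of its raw estimate and the
#' fitted value at its mean, a conservative sharing rule.
#'
#' @param counts Matrix or [count_table()].
#' @param factors Size factors from [size_factors()].
#' @param condition Character/factor of length `ncol(counts)` giving each
#'   sample's condition (e.g. `"T0"`/`"T1"`).
#' @param method `"per-condition"` (default) pools replicate variances within
#'   condition and requires >= 2 replicates per condition; `"blind"` treats
#'   all samples as replicates of one condition (the only option when a
#'   condition has a single sample, and it must be requested explicitly).
#' @return A list of class `dispersion_fit` with elements `mean` (normalized
#'   base mean), `alpha_raw`, `coef` (a0, a1) and `alpha` (final, floored at
#'   the fitted curve).
#' @export
estimate_dispersions <- function(counts, factors, condition,
                                 method = c("per-condition", "blind")) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  method <- match.arg(method)
  q <- sweep(counts, 2L, factors, "/")
  mu <- rowMeans(q)
  if (method == "per-condition") {
    tab <- table(condition)
    if (any(tab < 2L))
      stop("condition '", names(tab)[which.min(tab)], "' has fewer than 2 ",
           "replicates; rerun with method = \"blind\" to pool all samples",
           call. = FALSE)
    groups <- split(seq_along(condition), condition)
  } else {
    groups <- list(all = seq_along(condition))
  }
  ss <- 0; df <- 0; zbar <- 0
  for (idx in groups) {
    qg <- q[, idx, drop = FALSE]
    mg <- rowMeans(qg)
    ss <- ss + rowSums((qg - mg)^2)
    df <- df + length(idx) - 1L
    zbar <- zbar + mg * mean(1 / factors[idx]) * (length(idx) - 1L)
  }
  w <- ss / df          # pooled within-condition variance of normalized counts
  z <- zbar / df        # shot-noise part, rescaled by the size factors
  alpha_raw <- ifelse(mu > 0, pmax(0, (w - z) / mu^2), 0)

  ok <- mu > 0
  fit_df <- data.frame(a = alpha_raw[ok], x = 1 / mu[ok])
  coefs <- tryCatch({
    f <- suppressWarnings(MASS::rlm(a ~ x, data = fit_df, maxit = 50))
    stats::coef(f)
  }, error = function(e) stats::coef(stats::lm(a ~ x, data = fit_df)))
  a0 <- max(0, unname(coefs[1L]))
  a1 <- max(0, unname(coefs[2L]))
  alpha_fit <- ifelse(mu > 0, a0 + a1 / mu, a0)
  structure(list(mean = mu, alpha_raw = alpha_raw,
                 coef = c(a0 = a0, a1 = a1),
                 alpha = pmax(alpha_raw, alpha_fit)),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf(
    "dispersion_fit: %d hairpins; alpha_fit(mu) = %.4g + %.4g/mu; median final alpha %.4g\n",
    length(x$alpha), x$coef[["a0"]], x$coef[["a1"]],
    stats::median(x$alpha)))
  invisible(x)
}

## Negative-binomial density with a Poisson limit at alpha = 0.
## mu is the mean of a summed count with size-factor total s and per-sample
## squared totals s2: variance = mu + alpha * q^2 * s2.
.nb_dens <- function(x, q, s, s2, alpha) {
  mu <- q * s
  extra <- alpha * q^2 * s2
  if (extra <= 0) return(stats::dpois(x, mu))
  stats::dnbinom(x, mu = mu, size = mu^2 / extra)
}

#' Exact conditional test of depletion between two count groups
#'
#' Two-sided test of equal abundance from replicate counts at T0 and T1,
#' conditioning on the total K of both groups' summed counts. Each group's
#' sum is modelled as negative binomial with mean proportional to its summed
#' size factors and variance carrying the overdispersion `alpha`; the
#' p-value sums the conditional probabilities of all splits (a, K - a) no
#' more probable than the observed one (minimum-likelihood two-sided rule).
#'
#' For totals above `enum_limit` the sum runs over the 1 - 1e-14 quantile
#' window of each group's marginal instead of all K + 1 splits; the excluded
#' terms carry negligible mass in both numerator and denominator.
#'
#' @param k_T0,k_T1 Integer vectors of replicate counts for one hairpin.
#' @param sf_T0,sf_T1 Size factors of the corresponding samples.
#' @param alpha Dispersion (>= 0) for this hairpin.
#' @param enum_limit Largest total enumerated in full (default 5000).
#' @return p-value in (0, 1]; attribute `degenerate` is `TRUE` when all
#'   counts are zero (p = 1 by convention).
#' @export
nb_exact_test <- function(k_T0, k_T1, sf_T0, sf_T1, alpha,
                          enum_limit = 5000L) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (any(c(sf_T0, sf_T1) <= 0)) stop("size factors must be positive")
  KA <- sum(k_T0); KB <- sum(k_T1); K <- KA + KB
  if (K == 0) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  q <- (sum(k_T0 / sf_T0) + sum(k_T1 / sf_T1)) /
    (length(k_T0) + length(k_T1))
  sA <- sum(sf_T0); sB <- sum(sf_T1)
  s2A <- sum(sf_T0^2); s2B <- sum(sf_T1^2)

  if (K <= enum_limit) {
    a <- 0:K
  } else {
    qlo <- function(q_, s, s2) {
      mu <- q_ * s; extra <- alpha * q_^2 * s2
      if (extra <= 0)
        stats::qpois(c(1e-14, 1 - 1e-14), mu)
      else
        stats::qnbinom(c(1e-14, 1 - 1e-14), mu = mu, size = mu^2 / extra)
    }
    bA <- qlo(q, sA, s2A)
    bB <- qlo(q, sB, s2B)
    lo <- max(0, min(bA[1L], K - bB[2L]))
    hi <- min(K, max(bA[2L], K - bB[1L]))
    a <- seq.int(min(lo, KA), max(hi, KA))
  }
  pa <- .nb_dens(a, q, sA, s2A, alpha) * .nb_dens(K - a, q, sB, s2B, alpha)
  pobs <- .nb_dens(KA, q, sA, s2A, alpha) * .nb_dens(KB, q, sB, s2B, alpha)
  tot <- sum(pa)
  if (tot <= 0) return(structure(1, degenerate = TRUE))
  p <- sum(pa[pa <= pobs * (1 + 1e-7)]) / tot
  min(1, p)
}

#' Per-hairpin depletion table for one cell line
#'
#' Runs the full per-line differential-abundance stage: size factors on the
#' line's samples, dispersion estimation across T0/T1 replicates, and the
#' exact conditional test per hairpin. Hairpins whose normalized T0 mean
#' falls below `floor` are dropped (a hairpin that was never represented
#' cannot show depletion) and reported separately. Fold changes use a
#' pseudocount on the normalized means; p-values never do.
#'
#' @param table A [count_table()].
#' @param line Cell line name to analyse.
#' @param library Optional [hairpin_library()] supplying gene symbols.
#' @param floor Minimum normalized T0 mean to retain a hairpin (default 30).
#' @param pseudocount Pseudocount added to both normalized means for the
#'   fold change only (default 0.5).
#' @param dispersion_method Passed to [estimate_dispersions()].
#' @param enum_limit Passed to [nb_exact_test()].
#' @return An object of class `depletion_result`: list with `results` (a
#'   data.frame of retained hairpins: hairpin_id, gene_symbol,
#'   mean_T0_norm, mean_T1_norm, fc, log2fc, p_value, padj), `dropped`
#'   (hairpin ids below the floor), `line`, `size_factors`, `dispersion`.
#' @export
hairpin_depletion <- function(table, line, library = NULL, floor = 30,
                              pseudocount = 0.5,
                              dispersion_method = "per-condition",
                              enum_limit = 5000L) {
  stopifnot(inherits(table, "count_table"))
  sel <- table$samples$cell_line == line
  if (!any(sel))
    stop("unknown cell line: ", line, call. = FALSE)
  counts <- table$counts[, sel, drop = FALSE]
  info <- table$samples[sel, , drop = FALSE]
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf, info$timepoint,
                               method = dispersion_method)
  i0 <- info$timepoint == "T0"
  i1 <- info$timepoint == "T1"
  qn <- sweep(counts, 2L, sf, "/")
  m0 <- rowMeans(qn[, i0, drop = FALSE])
  m1 <- rowMeans(qn[, i1, drop = FALSE])

  keep <- m0 >= floor
  ids <- rownames(counts)
  gene <- if (!is.null(library)) {
    library$gene_symbol[match(ids, library$hairpin_id)]
  } else {
    sub("_sh[0-9]+$", "", ids)
  }
  kidx <- which(keep)
  pval <- vapply(kidx, function(i) {
    as.numeric(nb_exact_test(counts[i, i0], counts[i, i1],
                             sf[i0], sf[i1], disp$alpha[i],
                             enum_limit = enum_limit))
  }, numeric(1))
  fc <- (m1[kidx] + pseudocount) / (m0[kidx] + pseudocount)
  res <- data.frame(hairpin_id = ids[kidx],
                    gene_symbol = gene[kidx],
                    mean_T0_norm = m0[kidx],
                    mean_T1_norm = m1[kidx],
                    fc = fc,
                    log2fc = log2(fc),
                    p_value = pval,
                    padj = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = res, dropped = ids[!keep], line = line,
                 size_factors = sf, dispersion = disp,
                 floor = floor, pseudocount = pseudocount),
            class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf(
    "depletion_result for %s: %d hairpins tested, %d below floor (%g)\n",
    x$line, nrow(x$results), length(x$dropped), x$floor))
  cat(sprintf("  depleted at p < 0.1 and fc < 0.3: %d hairpins\n",
              sum(x$results$p_value < 0.1 & x$results$fc < 0.3)))
  invisible(x)
}

#' @export
summary.depletion_result <- function(object, ...) {
  r <- object$results
  out <- list(line = object$line, n_tested = nrow(r),
              n_dropped = length(object$dropped),
              median_fc = stats::median(r$fc),
              n_depleted = sum(r$p_value < 0.1 & r$fc < 0.3))
  class(out) <- "summary.depletion_result"
  out
}

#' @export
print.summary.depletion_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Line %s: %d hairpins tested (%d dropped), median fold change %.3f,\n",
    "  %d hairpins depleted at p < 0.1 with fc < 0.3\n"),
    x$line, x$n_tested, x$n_dropped, x$median_fc, x$n_depleted))
  invisible(x)
}

#' Write a per-line depletion table to TSV
#' @param x A `depletion_result`.
#' @param path Output path.
#' @export
write_depletion <- function(x, path) {
  stopifnot(inherits(x, "depletion_result"))
  res <- x$results
  res$retained <- TRUE
  if (length(x$dropped) > 0L) {
    drop_df <- data.frame(hairpin_id = x$dropped, gene_symbol = NA,
                          mean_T0_norm = NA, mean_T1_norm = NA, fc = NA,
                          log2fc = NA, p_value = NA, padj = NA,
                          retained = FALSE, stringsAsFactors = FALSE)
    res <- rbind(res, drop_df)
  }
  write_tsv_strict(res, path)
}
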