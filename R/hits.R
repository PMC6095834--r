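#' Lethal-hit criteria
#'
#' The four-part definition of a lethal hit in one cell line: at least one
#' hairpin significantly depleted (p below `p_max`) with fold change below
#' `fc_hairpin_max`; the gene's geometric-mean fold change below
#' `geomean_max` (the majority of hairpins must agree); a gene rank of at
#' most `rank_max` under second-best-hairpin ranking; and at least two
#' retained hairpins (implied by the second-best rule).
#'
#' @param p_max Per-hairpin p-value threshold (default 0.1, unadjusted).
#' @param fc_hairpin_max Per-hairpin fold-change threshold (default 0.3).
#' @param geomean_max Gene geometric-mean fold-change threshold (default 0.8).
#' @param rank_max Maximum second-best gene rank (default 100).
#' @param p_scope `"hairpin"` (default) requires the p and fold-change
#'   thresholds to be met by the same hairpin; `"gene"` accepts the gene's
#'   minimum p over all retained hairpins.
#' @return A list of class `hit_criteria`.
#' @export
hit_criteria <- function(p_max = 0.1, fc_hairpin_max = 0.3,
                         geomean_max = 0.8, rank_max = 100L,
                         p_scope = c("hairpin", "gene")) {
  if (any(c(p_max, fc_hairpin_max, geomean_max, rank_max) <= 0))
    stop("all thresholds must be > 0")
  if (rank_max != round(rank_max)) stop("rank_max must be an integer")
  structure(list(p_max = p_max, fc_hairpin_max = fc_hairpin_max,
                 geomean_max = geomean_max, rank_max = as.integer(rank_max),
                 p_scope = match.arg(p_scope)),
            class = "hit_criteria")
}

#' Aggregate hairpin depletion results to genes
#'
#' One summary row per gene over its retained hairpins: hairpin count,
#' minimum and geometric-mean fold change, and the minimum p-value among
#' hairpins below the per-hairpin fold-change threshold (`NA` when none
#' qualifies). Ranks are filled by [second_best_ranking()].
#'
#' @param results Data frame of hairpin results (from
#'   [hairpin_depletion()]`$results`) or a `depletion_result`.
#' @param criteria A [hit_criteria()] (supplies `fc_hairpin_max` and
#'   `p_scope` used for `best_depleted_p`).
#' @return Data frame: gene_symbol, n_hairpins, min_fc, geom_mean_fc,
#'   best_depleted_p, min_p.
#' @export
gene_aggregate <- function(results, criteria = hit_criteria()) {
  if (inherits(results, "depletion_result")) results <- results$results
  if (nrow(results) == 0L) stop("no hairpin results to aggregate")
  sp <- split(results, results$gene_symbol)
  out <- do.call(rbind, lapply(sp, function(d) {
    dep <- d$fc < criteria$fc_hairpin_max
    data.frame(gene_symbol = d$gene_symbol[1L],
               n_hairpins = nrow(d),
               min_fc = min(d$fc),
               geom_mean_fc = exp(mean(log(d$fc))),
               best_depleted_p = if (any(dep)) min(d$p_value[dep]) else NA_real_,
               min_p = min(d$p_value),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank genes by their second-best hairpin
#'
#' Hairpins are ranked 1..H ascending by log2 fold change (most depleted
#' first; ties broken by smaller p-value, then hairpin id). Each gene's
#' score is the rank of its second-most-depleted hairpin, so a gene needs at
#' least two well-scoring hairpins to rank well — a single off-target
#' hairpin cannot carry it. Genes with fewer than two retained hairpins get
#' a sentinel rank worse than any real one.
#'
#' @param results Hairpin results data frame or `depletion_result`.
#' @param summaries Gene summaries from [gene_aggregate()].
#' @return `summaries` with columns `second_best_rank` and `gene_rank`
#'   (position when genes are ordered by second-best rank) appended.
#' @export
second_best_ranking <- function(results, summaries) {
  if (inherits(results, "depletion_result")) results <- results$results
  H <- nrow(results)
  ord <- order(results$log2fc, results$p_value, results$hairpin_id)
  hrank <- integer(H)
  hrank[ord] <- seq_len(H)
  sentinel <- H + 1L
  sbr <- vapply(summaries$gene_symbol, function(g) {
    r <- sort(hrank[results$gene_symbol == g])
    if (length(r) < 2L) sentinel else r[2L]
  }, integer(1))
  summaries$second_best_rank <- unname(sbr)
  gord <- order(summaries$second_best_rank, summaries$gene_symbol)
  grank <- integer(nrow(summaries))
  grank[gord] <- seq_len(nrow(summaries))
  summaries$gene_rank <- grank
  summaries
}

#' Call lethal hits from ranked gene summaries
#'
#' Applies the four criteria in [hit_criteria()]: a hairpin both
#' significantly depleted and below the fold-change threshold, gene
#' geometric mean below threshold, second-best gene rank within the top
#' `rank_max`, and at least two retained hairpins.
#'
#' @param summaries Output of [second_best_ranking()].
#' @param criteria A [hit_criteria()]. Must match the one used in
#'   [gene_aggregate()] for the per-hairpin p/fc coupling to be consistent.
#' @return `summaries` with logical columns `crit_depleted_hairpin`,
#'   `crit_geomean`, `crit_rank`, `crit_two_hairpins` and `is_hit`, sorted
#'   by `gene_rank`.
#' @export
call_hits <- function(summaries, criteria = hit_criteria()) {
  if (!"gene_rank" %in% names(summaries))
    stop("summaries lack ranks; run second_best_ranking() first")
  pcol <- if (criteria$p_scope == "hairpin") summaries$best_depleted_p
          else ifelse(is.na(summaries$best_depleted_p), NA, summaries$min_p)
  summaries$crit_depleted_hairpin <-
    !is.na(pcol) & pcol < criteria$p_max
  summaries$crit_geomean <- summaries$geom_mean_fc < criteria$geomean_max
  summaries$crit_rank <- summaries$gene_rank <= criteria$rank_max
  summaries$crit_two_hairpins <- summaries$n_hairpins >= 2L
  summaries$is_hit <- summaries$crit_depleted_hairpin &
    summaries$crit_geomean & summaries$crit_rank & summaries$crit_two_hairpins
  summaries[order(summaries$gene_rank), , drop = FALSE]
}

#' Full per-line hit calling
#'
#' Convenience pipeline for one cell line: depletion testing
#' ([hairpin_depletion()]), gene aggregation, second-best ranking and hit
#' calling.
#'
#' @param table A [count_table()].
#' @param line Cell line name.
#' @param library Optional [hairpin_library()].
#' @param criteria A [hit_criteria()].
#' @param ... Passed to [hairpin_depletion()].
#' @return An object of class `line_hits`: list with `summaries` (ranked,
#'   flagged gene table), `depletion` (the `depletion_result`) and `line`.
#' @export
screen_hits <- function(table, line, library = NULL,
                        criteria = hit_criteria(), ...) {
  dep <- hairpin_depletion(table, line, library = library, ...)
  summ <- gene_aggregate(dep$results, criteria)
  summ <- second_best_ranking(dep$results, summ)
  summ <- call_hits(summ, criteria)
  structure(list(summaries = summ, depletion = dep, line = line,
                 criteria = criteria),
            class = "line_hits")
}

#' @export
print.line_hits <- function(x, ...) {
  hits <- x$summaries[x$summaries$is_hit, ]
  cat(sprintf("line_hits for %s: %d genes summarized, %d lethal hits\n",
              x$line, nrow(x$summaries), nrow(hits)))
  if (nrow(hits) > 0L) {
    cat("top hits (by gene rank):\n")
    print(utils::head(hits[, c("gene_symbol", "min_fc", "geom_mean_fc",
                               "best_depleted_p", "gene_rank")], 10L),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a per-line gene summary table to TSV
#' @param x A `line_hits` object or its `summaries` data frame.
#' @param path Output path.
#' @export
write_hits <- function(x, path) {
  if (inherits(x, "line_hits")) x <- x$summaries
  write_tsv_strict(x, path)
}
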