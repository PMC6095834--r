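#' Describe a synthetic pooled dropout screen
#'
#' Fixes the dimensions and sampling model of a simulated screen: a kinome-
#' scale hairpin library (default 535 genes x 5 hairpins), a panel of cell
#' lines with wildtype/mutant genotype labels, replicate infections per
#' timepoint, and sequencing representation expressed as expected mean count
#' per hairpin per sample (the in-silico analog of library coverage).
#'
#' @param n_lines Number of cell lines.
#' @param genotype Character vector of length `n_lines` with values
#'   `"wildtype"` or `"mutant"`; one label per line.
#' @param n_genes Number of genes in the library (default 535).
#' @param hairpins_per_gene Hairpins per gene (default 5).
#' @param replicates Replicate samples per (line, timepoint) (default 3).
#' @param coverage Expected mean count per hairpin per sample (default 1000).
#' @param dispersion Negative-binomial overdispersion of counts, >= 0
#'   (default 0.05); variance = mu + dispersion * mu^2.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_lines, genotype,
                       n_genes = 535L, hairpins_per_gene = 5L,
                       replicates = 3L, coverage = 1000,
                       dispersion = 0.05, seed = NULL) {
  n_lines <- as.integer(n_lines)
  if (length(genotype) != n_lines)
    stop("genotype must have one label per line")
  if (!all(genotype %in% c("wildtype", "mutant")))
    stop("genotype labels must be 'wildtype' or 'mutant'")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (replicates < 2L) stop("replicates must be >= 2")
  if (coverage <= 0) stop("coverage must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 hairpins_per_gene = as.integer(hairpins_per_gene),
                 n_lines = n_lines,
                 genotype = as.character(genotype),
                 replicates = as.integer(replicates),
                 coverage = coverage,
                 dispersion = dispersion,
                 seed = seed),
            class = "sim_design")
}

#' Describe the planted effects of a simulated screen
#'
#' Two kinds of true lethality are planted: common lethals (toxic in every
#' line) and genotype-specific lethals (toxic only in mutant lines),
#' mirroring the common-vs-background-specific dichotomy a panel screen is
#' designed to resolve. Effects are specified per gene; per-hairpin true fold
#' changes are drawn uniformly from `fc_range` when only gene names are
#' given, or taken verbatim from a named list of numeric vectors. A small
#' fraction of hairpins in non-lethal genes receive a single off-target
#' depletion effect (the failure mode that second-best ranking guards
#' against).
#'
#' @param common_lethals Character vector of gene names, or named list of
#'   per-hairpin fold-change vectors.
#' @param genotype_lethals Same, active only in mutant lines.
#' @param fc_range Range per-hairpin true fold changes are drawn from when
#'   genes are given by name (default `c(0.1, 0.3)`).
#' @param off_target_rate Fraction of hairpins in non-lethal genes given a
#'   random depletion effect (default 0.02).
#' @param off_target_fc_range Fold-change range of off-target effects
#'   (default `c(0.2, 0.8)`).
#' @param baseline_log10_sd Spread (sd in log10) of hairpin baseline
#'   abundances (default 0.5); real hairpin libraries are strongly skewed.
#' @return A list of class `effect_model`.
#' @export
effect_model <- function(common_lethals = character(0),
                         genotype_lethals = character(0),
                         fc_range = c(0.1, 0.3),
                         off_target_rate = 0.02,
                         off_target_fc_range = c(0.2, 0.8),
                         baseline_log10_sd = 0.5) {
  cg <- if (is.list(common_lethals)) names(common_lethals) else common_lethals
  gg <- if (is.list(genotype_lethals)) names(genotype_lethals)
        else genotype_lethals
  if (length(intersect(cg, gg)) > 0L)
    stop("a gene cannot be both a common and a genotype-specific lethal")
  if (off_target_rate < 0 || off_target_rate > 1)
    stop("off_target_rate must be in [0, 1]")
  chk_fc <- function(x) {
    v <- if (is.list(x)) unlist(x) else numeric(0)
    if (any(v <= 0)) stop("all true fold changes must be > 0")
  }
  chk_fc(common_lethals); chk_fc(genotype_lethals)
  structure(list(common_lethals = common_lethals,
                 genotype_lethals = genotype_lethals,
                 fc_range = fc_range,
                 off_target_rate = off_target_rate,
                 off_target_fc_range = off_target_fc_range,
                 baseline_log10_sd = baseline_log10_sd),
            class = "effect_model")
}

#' Simulate a hairpin library
#'
#' Generates `n_genes * hairpins_per_gene` hairpin records with unique ids
#' and random 21-nt target sequences. Deterministic under `design$seed`.
#'
#' @param design A [sim_design()].
#' @return A [hairpin_library()].
#' @export
simulate_library <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  genes <- sprintf("GENE%04d", seq_len(design$n_genes))
  gene_of <- rep(genes, each = design$hairpins_per_gene)
  ids <- paste0(gene_of, "_sh",
                rep(seq_len(design$hairpins_per_gene), design$n_genes))
  n <- length(ids)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE), collapse = ""),
    character(1))
  # regenerate any prefix collision so exact matching stays unambiguous
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(dup, function(i)
      paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE),
            collapse = ""), character(1))
  }
  hairpin_library(ids, gene_of, sequence = seqs)
}

## Resolve an effect specification to a per-hairpin fold-change vector for
## the given genes, drawing from fc_range when only names were supplied.
.effect_fcs <- function(spec, fc_range, library) {
  genes <- if (is.list(spec)) names(spec) else spec
  miss <- setdiff(genes, library$gene_symbol)
  if (length(miss) > 0L)
    stop("effect genes absent from library: ", paste(miss, collapse = ", "),
         call. = FALSE)
  fc <- stats::setNames(rep(1, nrow(library)), library$hairpin_id)
  for (g in genes) {
    idx <- which(library$gene_symbol == g)
    fc[idx] <- if (is.list(spec)) {
      v <- spec[[g]]
      if (length(v) == 1L) rep(v, length(idx)) else v[seq_along(idx)]
    } else {
      stats::runif(length(idx), fc_range[1L], fc_range[2L])
    }
  }
  fc
}

#' Simulate a pooled dropout screen with known truth
#'
#' For every cell line, draws `replicates` T0 and T1 samples. Hairpin
#' baseline abundances are log-normal; per-sample sequencing depth is
#' `coverage * n_hairpins`, allocated to hairpins by a multinomial draw whose
#' probabilities carry gamma noise, giving negative-binomial-like marginal
#' counts (gamma-Poisson construction) while coupling hairpins through the
#' fixed depth. T1 expected abundances are the T0 expectations multiplied by
#' each hairpin's true fold change in that line.
#'
#' @param library A [hairpin_library()] from [simulate_library()].
#' @param design The [sim_design()] the library was built from.
#' @param effects An [effect_model()].
#' @return A list with elements `counts` (a [count_table()]), `genotypes`
#'   (named character vector) and `truth` (list with `hairpin_fc`, a hairpin
#'   x line matrix of true fold changes, and `gene_status`, a gene x line
#'   logical matrix of planted lethality).
#' @export
simulate_screen <- function(library, design, effects = effect_model()) {
  stopifnot(inherits(design, "sim_design"), inherits(effects, "effect_model"))
  H <- nrow(library)
  if (H != design$n_genes * design$hairpins_per_gene)
    stop("library does not match design dimensions")
  if (!is.null(design$seed)) set.seed(design$seed + 1L)
  lines <- sprintf("LINE%02d", seq_len(design$n_lines))
  genotypes <- stats::setNames(design$genotype, lines)

  baseline <- 10 ^ stats::rnorm(H, 0, effects$baseline_log10_sd)

  fc_common <- .effect_fcs(effects$common_lethals, effects$fc_range, library)
  fc_geno <- .effect_fcs(effects$genotype_lethals, effects$fc_range, library)

  lethal_genes <- unique(c(
    if (is.list(effects$common_lethals)) names(effects$common_lethals)
    else effects$common_lethals,
    if (is.list(effects$genotype_lethals)) names(effects$genotype_lethals)
    else effects$genotype_lethals))
  neutral_idx <- which(!(library$gene_symbol %in% lethal_genes))
  n_off <- round(effects$off_target_rate * length(neutral_idx))
  fc_off <- rep(1, H)
  if (n_off > 0L) {
    off <- sample(neutral_idx, n_off)
    fc_off[off] <- stats::runif(n_off, effects$off_target_fc_range[1L],
                                effects$off_target_fc_range[2L])
  }

  hairpin_fc <- matrix(1, H, design$n_lines,
                       dimnames = list(library$hairpin_id, lines))
  for (j in seq_len(design$n_lines)) {
    fc <- fc_common * fc_off
    if (genotypes[j] == "mutant") fc <- fc * fc_geno
    hairpin_fc[, j] <- fc
  }

  depth <- round(design$coverage * H)
  disp <- design$dispersion
  draw_sample <- function(mu) {
    rate <- if (disp > 0)
      stats::rgamma(H, shape = 1 / disp, scale = mu * disp)
    else mu
    as.integer(stats::rmultinom(1L, depth, prob = pmax(rate, 1e-12)))
  }

  n_samp <- design$n_lines * 2L * design$replicates
  counts <- matrix(0L, H, n_samp, dimnames = list(library$hairpin_id, NULL))
  meta <- vector("list", n_samp)
  k <- 0L
  for (j in seq_len(design$n_lines)) {
    for (tp in c("T0", "T1")) {
      mu <- if (tp == "T0") baseline else baseline * hairpin_fc[, j]
      for (r in seq_len(design$replicates)) {
        k <- k + 1L
        counts[, k] <- draw_sample(mu)
        meta[[k]] <- data.frame(sample_id = paste(lines[j], tp, r, sep = "_"),
                                cell_line = lines[j], timepoint = tp,
                                replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, meta)
  colnames(counts) <- samples$sample_id

  genes <- unique(library$gene_symbol)
  gene_status <- matrix(FALSE, length(genes), design$n_lines,
                        dimnames = list(genes, lines))
  cg <- if (is.list(effects$common_lethals)) names(effects$common_lethals)
        else effects$common_lethals
  gg <- if (is.list(effects$genotype_lethals)) names(effects$genotype_lethals)
        else effects$genotype_lethals
  gene_status[cg, ] <- TRUE
  if (length(gg) > 0L)
    gene_status[gg, genotypes == "mutant"] <- TRUE

  list(counts = count_table(counts, samples),
       genotypes = genotypes,
       truth = list(hairpin_fc = hairpin_fc, gene_status = gene_status))
}

#' Simulate a full genotype-stratified screen cohort
#'
#' Convenience wrapper reproducing the study design the package targets: a
#' panel of wildtype and mutant lines (default 5 + 9) screened in triplicate
#' with a 535-gene x 5-hairpin library at 1000x representation, with planted
#' common and mutant-specific lethal genes at per-hairpin fold changes drawn
#' from 0.1-0.3.
#'
#' @param n_wt,n_mut Numbers of wildtype and mutant lines (defaults 5, 9).
#' @param n_common,n_specific Numbers of planted common and mutant-specific
#'   lethal genes (defaults 5, 5).
#' @param seed Integer seed.
#' @param ... Passed to [sim_design()] (e.g. `n_genes`, `coverage`,
#'   `dispersion`).
#' @return As [simulate_screen()], plus `library` and elements `common_genes`
#'   and `specific_genes` naming the planted sets.
#' @export
simulate_cohort <- function(n_wt = 5L, n_mut = 9L, n_common = 5L,
                            n_specific = 5L, seed = 1L, ...) {
  design <- sim_design(n_lines = n_wt + n_mut,
                       genotype = rep(c("wildtype", "mutant"),
                                      c(n_wt, n_mut)),
                       seed = seed, ...)
  lib <- simulate_library(design)
  genes <- unique(lib$gene_symbol)
  planted <- sample(genes, n_common + n_specific)
  common <- planted[seq_len(n_common)]
  specific <- setdiff(planted, common)
  eff <- effect_model(common_lethals = common, genotype_lethals = specific)
  out <- simulate_screen(lib, design, eff)
  out$library <- lib
  out$common_genes <- common
  out$specific_genes <- specific
  out
}

#' Write a simulated screen to TSV files
#'
#' Writes library, counts, sample metadata, genotype and truth tables under
#' `dir` with fixed file names.
#'
#' @param sim Result of [simulate_screen()] or [simulate_cohort()].
#' @param library The [hairpin_library()] (taken from `sim$library` when
#'   present).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, library = sim$library) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(library))
    write_library(library, file.path(dir, "library.tsv"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"),
               file.path(dir, "samples.tsv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  fc <- sim$truth$hairpin_fc
  write_tsv_strict(as.data.frame(fc), file.path(dir, "truth_fc.tsv"),
                   key_name = "hairpin_id")
  invisible(dir)
}
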