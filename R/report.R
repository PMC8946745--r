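# Phenome-level aggregation: significance tally, size-vs-effect rank
# correlation, medically-relevant-allele enrichment, percentile-bin odds
# ratios, cross-population transferability slopes.

#' Spearman correlation between model size and incremental performance
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value from
#' the t approximation.
#'
#' @param sizes number of variants selected per trait.
#' @param incremental_values incremental predictive performance per trait.
#' @return list: rho, p_value, n.
#' @export
spearman_size_effect <- function(sizes, incremental_values) {
  if (length(sizes) != length(incremental_values))
    stop_config("sizes and incremental_values must have equal length")
  ok <- complete.cases(sizes, incremental_values)
  x <- rank(sizes[ok], ties.method = "average")
  y <- rank(incremental_values[ok], ties.method = "average")
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- cor(x, y)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Enrichment fold of medically relevant alleles
#'
#' `(a/b) / (c/d)`: the fraction of selected variants that are medically
#' relevant under penalty-factor prioritization, divided by the same fraction
#' without prioritization. Reported at 2 decimals elsewhere; this returns the
#' unrounded fold.
#'
#' @param selected_relevant_pf,selected_total_pf numerator and denominator
#'   counts for the penalty-factor model.
#' @param selected_relevant_nopf,selected_total_nopf same for the
#'   no-penalty-factor model.
#' @return numeric fold; NA when a denominator is zero.
#' @export
enrichment_fold <- function(selected_relevant_pf, selected_total_pf,
                            selected_relevant_nopf, selected_total_nopf) {
  if (selected_total_pf == 0 || selected_total_nopf == 0 ||
      selected_relevant_nopf == 0) return(NA_real_)
  (selected_relevant_pf / selected_total_pf) /
    (selected_relevant_nopf / selected_total_nopf)
}

#' Default PRS percentile bins
#'
#' Tail-refined bins `[0-0.5, 0.5-1, 1-5, 5-10]`, decile steps with a merged
#' 40-60 reference bin, and the mirrored upper tail.
#'
#' @return numeric vector of bin edges on the (0,1) percentile scale.
#' @export
default_percentile_bins <- function() {
  c(0, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9,
    0.95, 0.99, 0.995, 1)
}

#' Odds ratios by PRS percentile bin
#'
#' Samples are binned by PRS percentile; each bin's disease odds ratio is
#' computed from the 2x2 table against the reference (40-60th percentile)
#' bin, with `SE(log OR) = sqrt(sum 1/cell)`. Zero cells get the
#' Haldane-Anscombe 0.5 correction and are flagged.
#'
#' @param scores PRS values.
#' @param labels 0/1 case status.
#' @param bin_edges percentile bin edges (see [default_percentile_bins()]).
#' @param reference length-2 percentile range of the reference bin.
#' @return data.frame: bin, lo, hi, n_case, n_control, or, log_or, se_log_or,
#'   corrected.
#' @export
percentile_bin_or <- function(scores, labels, bin_edges = default_percentile_bins(),
                              reference = c(0.4, 0.6)) {
  pct <- (rank(scores, ties.method = "average") - 0.5) / length(scores)
  bin <- cut(pct, bin_edges, include.lowest = TRUE)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  ref_bin <- which(lo <= reference[1] + 1e-9 & hi >= reference[2] - 1e-9)[1]
  if (is.na(ref_bin)) stop_config("reference range is not a bin")
  tab <- table(bin, factor(labels, levels = 0:1))
  a_ref <- tab[ref_bin, "1"]
  b_ref <- tab[ref_bin, "0"]
  out <- lapply(seq_len(nrow(tab)), function(b) {
    cells <- c(tab[b, "1"], tab[b, "0"], a_ref, b_ref)
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    lor <- log(cells[1] / cells[2]) - log(cells[3] / cells[4])
    data.frame(bin = rownames(tab)[b], lo = lo[b], hi = hi[b],
               n_case = tab[b, "1"], n_control = tab[b, "0"],
               or = exp(lor), log_or = lor,
               se_log_or = sqrt(sum(1 / cells)),
               reference = b == ref_bin, corrected = corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-population transferability slope
#'
#' Through-origin least-squares slope of the target population's per-trait
#' incremental performance on the source population's (`y = b x`), with its
#' standard error.
#'
#' @param incremental_target per-trait incremental performance in the target
#'   population.
#' @param incremental_source same traits, source (development) population.
#' @return list: slope, se, n.
#' @export
transfer_slope <- function(incremental_target, incremental_source) {
  ok <- complete.cases(incremental_target, incremental_source)
  y <- incremental_target[ok]
  x <- incremental_source[ok]
  sxx <- sum(x^2)
  if (sxx == 0) stop_config("source values are all zero")
  b <- sum(x * y) / sxx
  n <- length(x)
  se <- if (n > 1) sqrt(sum((y - b * x)^2) / (n - 1) / sxx) else NA_real_
  list(slope = b, se = se, n = n)
}

#' Build the phenome summary table
#'
#' Aggregates per-trait evaluation rows into one summary row per trait:
#' the headline metric (R2 for gaussian, Nagelkerke for binomial) for each
#' model type, the incremental performance, model size, p-value and the
#' Bonferroni significance flag.
#'
#' @param eval_results data.frame of rows from [evaluate_models()] (may span
#'   traits and populations).
#' @param sizes named vector: number of selected variants per trait.
#' @param families named character vector: glm family per trait.
#' @param population population label to summarize (default "test").
#' @param n_tests Bonferroni correction count.
#' @return list of class `phenome_summary`: `table` (per-trait data.frame),
#'   `n_significant`, `spearman` (per family, when >= 3 traits).
#' @export
build_phenome_table <- function(eval_results, sizes, families,
                                population = "test", n_tests = 2000) {
  traits <- unique(eval_results$trait)
  if (!length(traits)) {
    empty <- data.frame(trait = character(), family = character(),
                        metric = character(), n_variants_selected = integer(),
                        genotype_only = numeric(), covariate_only = numeric(),
                        full = numeric(), incremental = numeric(),
                        p_value = numeric(), significant = logical())
    return(structure(list(table = empty, n_significant = 0L,
                          spearman = list()), class = "phenome_summary"))
  }
  rows <- lapply(traits, function(tr) {
    fam <- families[[tr]]
    metric <- if (fam == "gaussian") "R2" else "NagelkerkeR2"
    sub <- eval_results[eval_results$trait == tr &
                        eval_results$population == population &
                        eval_results$metric == metric, ]
    val <- function(mt) {
      v <- sub$value[sub$model_type == mt]
      if (length(v)) v[1] else NA_real_
    }
    pv <- sub$p_value[sub$model_type == "full"]
    pv <- if (length(pv)) pv[1] else NA_real_
    data.frame(trait = tr, family = fam, metric = metric,
               n_variants_selected = sizes[[tr]] %||% NA_integer_,
               genotype_only = val("genotype_only"),
               covariate_only = val("covariate_only"),
               full = val("full"),
               incremental = val("full") - val("covariate_only"),
               p_value = pv,
               significant = is_significant(pv, n_tests),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  spearman <- lapply(split(tab, tab$family), function(d) {
    if (nrow(d) >= 3) spearman_size_effect(d$n_variants_selected, d$incremental)
    else NULL
  })
  structure(list(table = tab, n_significant = sum(tab$significant, na.rm = TRUE),
                 spearman = spearman), class = "phenome_summary")
}

#' @export
print.phenome_summary <- function(x, ...) {
  cat(sprintf("Phenome summary: %d traits, %d significant\n",
              nrow(x$table), x$n_significant))
  print(x$table, digits = 3)
  invisible(x)
}
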