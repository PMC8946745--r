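# Variant QC, consequence grouping, penalty-factor assignment, HLA dosage
# rounding. Coordinates are 1-based inclusive throughout (PLINK .bim
# convention).

CONSEQUENCE_GROUPS <- c("PTV", "PAV", "PCV", "Intronic", "UTR", "Others")
CLINVAR_CLASSES <- c("pathogenic", "likely_pathogenic", "none")

#' QC thresholds
#'
#' Defaults: missingness < 1%, MAF > 0.01%, HWE exact p >= 1e-7, and exclusion
#' of the MHC region (hg19 chr6:25,477,797-36,448,354, 1-based inclusive).
#'
#' @param max_missingness maximum variant missingness (exclusive bound).
#' @param min_maf minimum minor allele frequency (exclusive bound).
#' @param hwe_p_cutoff variants with HWE exact p below this are removed.
#' @param mhc_region list(chrom, start, end), 1-based inclusive.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missingness = 0.01, min_maf = 1e-4,
                          hwe_p_cutoff = 1e-7,
                          mhc_region = list(chrom = 6L, start = 25477797L,
                                            end = 36448354L)) {
  check_prob(max_missingness, "max_missingness")
  check_prob(min_maf, "min_maf")
  check_prob(hwe_p_cutoff, "hwe_p_cutoff")
  structure(list(max_missingness = max_missingness, min_maf = min_maf,
                 hwe_p_cutoff = hwe_p_cutoff, mhc_region = mhc_region),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test conditioning on the allele counts: the p-value is the
#' sum of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (plain cumulative
#' definition, no mid-p). Symmetric in the two homozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop_config("negative counts")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop_config("all-zero genotype counts")
  n_a <- 2 * n_hom_ref + n_het          # allele A count
  n_b <- 2 * n_hom_alt + n_het
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible het counts share parity
  # log P(het = h | n, n_a) up to a constant
  lp <- hets * log(2) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Keeps a variant iff missingness < `max_missingness`, MAF > `min_maf`
#' (computed on non-missing calls), HWE exact p >= `hwe_p_cutoff`, outside the
#' MHC region, and not on the optional blocklist (stand-in for the external
#' frequency-comparison and cluster-plot review filters).
#'
#' @param G n x m dosage matrix (NA = missing), columns named by variant id.
#' @param annotation data.frame with variant_id, chrom, pos (1-based).
#' @param thresholds a [qc_thresholds()] object.
#' @param blocklist optional character vector of variant ids to drop.
#' @return list with `keep` (logical mask), `report` (per-variant data.frame
#'   with the measured values and per-criterion pass flags) and `removed`
#'   (named counts removed per criterion).
#' @export
variant_qc <- function(G, annotation, thresholds = qc_thresholds(),
                       blocklist = character()) {
  if (nrow(annotation) != ncol(G)) stop_config("annotation must cover all variants")
  if (!is.null(annotation$pos) && any(annotation$pos == 0))
    stop_config("position 0 found: coordinates must be 1-based (0-based input?)")
  m <- ncol(G)
  miss <- colMeans(is.na(G))
  p_hat <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- G[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }, 0)
  chrom <- annotation$chrom %||% rep(NA_integer_, m)
  pos <- annotation$pos %||% rep(NA_integer_, m)
  mhc <- thresholds$mhc_region
  in_mhc <- !is.na(chrom) & chrom == mhc$chrom &
    !is.na(pos) & pos >= mhc$start & pos <= mhc$end
  ids <- annotation$variant_id %||% colnames(G)
  blocked <- ids %in% blocklist
  pass_miss <- miss < thresholds$max_missingness
  pass_maf <- maf > thresholds$min_maf
  pass_hwe <- hwe_p >= thresholds$hwe_p_cutoff
  keep <- pass_miss & pass_maf & pass_hwe & !in_mhc & !blocked
  report <- data.frame(variant_id = ids, missingness = miss, maf = maf,
                       hwe_p = hwe_p, in_mhc = in_mhc, blocked = blocked,
                       pass_missingness = pass_miss, pass_maf = pass_maf,
                       pass_hwe = pass_hwe, kept = keep,
                       stringsAsFactors = FALSE)
  removed <- c(missingness = sum(!pass_miss), maf = sum(!pass_maf),
               hwe = sum(!pass_hwe), mhc = sum(in_mhc),
               blocklist = sum(blocked))
  list(keep = keep, report = report, removed = removed)
}

#' Assign penalty factors for medically relevant alleles
#'
#' Three levels: 0.5 for ClinVar-pathogenic or protein-truncating variants;
#' 0.75 for ClinVar likely-pathogenic, protein-altering variants, or imputed
#' allelotypes; 1.0 otherwise. Lower values make selection in the L1-penalized
#' model cheaper, prioritizing these alleles. Vectorized.
#'
#' @param consequence_group one of PTV, PAV, PCV, Intronic, UTR, Others.
#' @param clinvar_class one of pathogenic, likely_pathogenic, none.
#' @param is_allelotype logical.
#' @return numeric vector with values in {0.5, 0.75, 1}.
#' @export
assign_penalty_factor <- function(consequence_group, clinvar_class, is_allelotype) {
  if (!all(consequence_group %in% CONSEQUENCE_GROUPS))
    stop_config("unknown consequence group")
  if (!all(clinvar_class %in% CLINVAR_CLASSES))
    stop_config("unknown ClinVar class")
  ifelse(clinvar_class == "pathogenic" | consequence_group == "PTV", 0.5,
  ifelse(clinvar_class == "likely_pathogenic" | consequence_group == "PAV" |
           is_allelotype, 0.75, 1.0))
}

#' Round imputed HLA allelotype dosages
#'
#' Dosages within +/- 0.1 of 0, 1 or 2 are rounded to that integer; all other
#' values become missing (NA).
#'
#' @param dosage numeric vector in `[0, 2]`.
#' @return integer dosages with NA for unresolvable entries.
#' @export
round_hla_dosage <- function(dosage) {
  r <- round(dosage)
  out <- ifelse(!is.na(dosage) & abs(dosage - r) <= 0.1 + 1e-12, r, NA_real_)
  as.integer(out)
}

#' Medically relevant allele mask
#'
#' TRUE iff protein-truncating, protein-altering, an imputed allelotype, or
#' ClinVar pathogenic / likely pathogenic -- equivalently, penalty factor < 1.
#'
#' @param annotation data.frame with consequence_group, clinvar_class,
#'   is_allelotype.
#' @return logical vector.
#' @export
medically_relevant_mask <- function(annotation) {
  annotation$consequence_group %in% c("PTV", "PAV") |
    annotation$clinvar_class %in% c("pathogenic", "likely_pathogenic") |
    annotation$is_allelotype
}
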