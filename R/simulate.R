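# Synthetic multi-population cohort generator.
#
# Everything here is a stated stand-in for biobank-scale data: diploid dosages
# with Balding-Nichols allele-frequency drift between populations, blockwise
# equicorrelated-Gaussian-copula LD on haplotypes, consequence/ClinVar
# annotation categories, basic covariates, and quantitative or
# liability-threshold binary phenotypes with a specified SNP heritability.
# Every generator is a pure function of (arguments, seed).

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic cohort generator. Defaults describe a
#' small biobank-like world: several populations with modest differentiation,
#' block LD, a largely non-coding variant panel, and a polygenic trait.
#'
#' @param n_per_population named integer vector, samples per population label.
#' @param m_variants number of variants.
#' @param maf_range length-2 numeric, ancestral MAF range (0 < low <= high <= 0.5).
#' @param fst_per_population named numeric vector of Fst values in `[0, 1)`,
#'   one per population (0 = identical to the ancestral frequencies).
#' @param ld_block_size variants per LD block.
#' @param ld_rho within-block haplotype copula correlation in `[0, 1)`; a
#'   scalar, or a vector recycled over blocks for heterogeneous LD.
#' @param n_causal number of causal variants.
#' @param h2_true target SNP heritability in `[0, 1]`.
#' @param prevalence_K case fraction in (0, 1) for binary traits.
#' @param causal_enrichment relative odds that a causal variant is medically
#'   relevant (1 = no enrichment).
#' @param covariate_betas named numeric vector of covariate effects on the
#'   trait/liability scale; defaults give age and sex nonzero effects so
#'   covariate-only models have known, nontrivial performance.
#' @param family `"gaussian"` or `"binomial"`.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_population = c(WB = 1000),
                       m_variants = 500,
                       maf_range = c(0.05, 0.5),
                       fst_per_population = setNames(rep(0, length(n_per_population)),
                                                     names(n_per_population)),
                       ld_block_size = 10,
                       ld_rho = 0.3,
                       n_causal = 20,
                       h2_true = 0.5,
                       prevalence_K = 0.1,
                       causal_enrichment = 1,
                       covariate_betas = c(age = 0.01, sex = 0.25),
                       family = c("gaussian", "binomial"),
                       seed = 1L) {
  family <- match.arg(family)
  if (is.null(names(n_per_population)))
    names(n_per_population) <- paste0("pop", seq_along(n_per_population))
  if (is.null(names(fst_per_population)))
    names(fst_per_population) <- names(n_per_population)
  if (!setequal(names(fst_per_population), names(n_per_population)))
    stop_config("fst_per_population labels must match n_per_population labels")
  if (any(fst_per_population < 0) || any(fst_per_population >= 1))
    stop_config("all Fst must be in [0, 1)")
  if (n_causal > m_variants) stop_config("n_causal must be <= m_variants")
  check_prob(h2_true, "h2_true")
  check_prob(prevalence_K, "prevalence_K", open_lo = TRUE, open_hi = TRUE)
  structure(list(
    n_per_population = n_per_population, m_variants = m_variants,
    maf_range = maf_range, fst_per_population = fst_per_population,
    ld_block_size = ld_block_size, ld_rho = ld_rho, n_causal = n_causal,
    h2_true = h2_true, prevalence_K = prevalence_K,
    causal_enrichment = causal_enrichment, covariate_betas = covariate_betas,
    family = family, seed = as.integer(seed)), class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Draw ancestral allele frequencies
#'
#' @param m number of variants.
#' @param maf_range length-2 numeric `(low, high]` with 0 < low <= high <= 0.5.
#' @param seed integer seed.
#' @return numeric vector of length `m`, uniform on `[low, high]`.
#' @export
draw_base_frequencies <- function(m, maf_range, seed) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] < maf_range[1] ||
      maf_range[2] > 0.5)
    stop_config("maf_range must satisfy 0 < low <= high <= 0.5")
  with_seed(seed, runif(m, maf_range[1], maf_range[2]))
}

#' Drift allele frequencies under the Balding-Nichols model
#'
#' Population frequencies are drawn as Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral frequency p, so the between-population variance is F p (1-p).
#' F = 0 returns the input unchanged. Frequencies are clamped away from 0 and
#' 1 by `1/(4 n)` so variants cannot become monomorphic in expectation.
#'
#' @param base_freq ancestral frequencies.
#' @param fst differentiation parameter in `[0, 1)`.
#' @param seed integer seed.
#' @param n population size used for the clamping bound (default 1000).
#' @return drifted frequency vector, same length as `base_freq`.
#' @export
drift_frequencies <- function(base_freq, fst, seed, n = 1000) {
  if (fst < 0 || fst >= 1) stop_config("fst must be in [0, 1)")
  if (fst == 0) return(base_freq)
  q <- with_seed(seed, {
    a <- base_freq * (1 - fst) / fst
    b <- (1 - base_freq) * (1 - fst) / fst
    rbeta(length(base_freq), a, b)
  })
  eps <- 1 / (4 * n)
  pmin(pmax(q, eps), 1 - eps)
}

#' Simulate diploid genotypes with block LD
#'
#' Dosages in {0,1,2} are the sum of two haplotypes. Within an LD block each
#' haplotype's alleles come from a latent equicorrelated Gaussian (correlation
#' `ld_rho`) thresholded at the per-variant frequency quantile; blocks are
#' independent. Marginal allele frequencies equal `pop_freq`.
#'
#' @param pop_freq per-variant allele frequency.
#' @param n number of individuals.
#' @param ld_block_size variants per block (last block may be shorter).
#' @param ld_rho scalar or per-block vector of copula correlations in `[0, 1)`.
#' @param seed integer seed.
#' @return n x m integer dosage matrix.
#' @export
simulate_genotypes <- function(pop_freq, n, ld_block_size, ld_rho, seed) {
  if (n < 1) stop_config("n must be >= 1")
  m <- length(pop_freq)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / ld_block_size))
  rho <- rep_len(ld_rho, length(blocks))
  if (any(rho < 0) || any(rho >= 1)) stop_config("ld_rho must be in [0, 1)")
  with_seed(seed, {
    G <- matrix(0L, n, m)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      thr <- qnorm(pop_freq[idx])
      for (h in 1:2) {
        u <- rnorm(n)                                   # shared block factor
        z <- sqrt(rho[b]) * u +
          sqrt(1 - rho[b]) * matrix(rnorm(n * length(idx)), n)
        G[, idx] <- G[, idx] + (sweep(z, 2, thr, "<") * 1L)
      }
    }
    storage.mode(G) <- "integer"
    G
  })
}

#' Simulate variant annotations
#'
#' Assigns each variant one consequence group (PTV, PAV, PCV, Intronic, UTR,
#' Others), one ClinVar class (pathogenic, likely_pathogenic, none) and an
#' allelotype flag, multinomially with the given proportions. Defaults are a
#' coding-enriched genotyping-array-like mix.
#'
#' @param m number of variants.
#' @param category_proportions list with elements `consequence` (named
#'   proportions over the six groups), `clinvar` (named proportions for
#'   pathogenic / likely_pathogenic; remainder is none) and `allelotype`
#'   (scalar probability).
#' @param seed integer seed.
#' @return data.frame with variant_id, consequence_group, clinvar_class,
#'   is_allelotype and the derived penalty_factor.
#' @export
simulate_annotations <- function(m,
                                 category_proportions = list(
                                   consequence = c(PTV = 0.005, PAV = 0.15,
                                                   PCV = 0.05, Intronic = 0.30,
                                                   UTR = 0.05, Others = 0.445),
                                   clinvar = c(pathogenic = 0.002,
                                               likely_pathogenic = 0.003),
                                   allelotype = 0.002),
                                 seed = 1L) {
  cq <- category_proportions$consequence
  cv <- category_proportions$clinvar %||% c(pathogenic = 0, likely_pathogenic = 0)
  al <- category_proportions$allelotype %||% 0
  groups <- c("PTV", "PAV", "PCV", "Intronic", "UTR", "Others")
  if (!all(names(cq) %in% groups) || any(cq < 0) || sum(cq) > 1 + 1e-12)
    stop_config("invalid consequence proportions")
  if (any(cv < 0) || sum(cv) > 1 + 1e-12 || al < 0 || al > 1)
    stop_config("invalid clinvar/allelotype proportions")
  cq_full <- setNames(numeric(6), groups)
  cq_full[names(cq)] <- cq
  if (sum(cq_full) < 1) cq_full["Others"] <- cq_full["Others"] + 1 - sum(cq_full)
  with_seed(seed, {
    consequence <- sample(groups, m, replace = TRUE, prob = cq_full)
    clin <- sample(c(names(cv), "none"), m, replace = TRUE,
                   prob = c(cv, 1 - sum(cv)))
    allelo <- runif(m) < al
    ann <- data.frame(
      variant_id = sprintf("var%06d", seq_len(m)),
      consequence_group = consequence,
      clinvar_class = clin,
      is_allelotype = allelo,
      stringsAsFactors = FALSE)
    ann$penalty_factor <- assign_penalty_factor(ann$consequence_group,
                                                ann$clinvar_class,
                                                ann$is_allelotype)
    ann
  })
}

#' Simulate causal effects (truth set)
#'
#' Causal indices are sampled without replacement with probability weights
#' `causal_enrichment` for medically relevant variants and 1 otherwise.
#' Nonzero effects are i.i.d. Normal on the standardized-genotype scale,
#' rescaled so the sum of squared effects equals `h2_true` (the genetic
#' variance of the standardized linear predictor under linkage equilibrium).
#'
#' @param annotation annotation data.frame (see [simulate_annotations()]).
#' @param n_causal number of causal variants (>= 1 unless `h2_true = 0`).
#' @param causal_enrichment relative sampling odds for medically relevant variants.
#' @param h2_true target heritability.
#' @param seed integer seed.
#' @return list of class `truth_set`: beta_true, causal_mask.
#' @export
simulate_effects <- function(annotation, n_causal, causal_enrichment, h2_true, seed) {
  m <- nrow(annotation)
  if (n_causal < 1) stop_config("n_causal must be >= 1")
  if (n_causal > m) stop_config("n_causal exceeds number of variants")
  relevant <- medically_relevant_mask(annotation)
  with_seed(seed, {
    w <- ifelse(relevant, causal_enrichment, 1)
    causal <- sample.int(m, n_causal, prob = w)
    beta <- numeric(m)
    if (h2_true > 0) {
      b <- rnorm(n_causal)
      beta[causal] <- b * sqrt(h2_true / sum(b^2))
    }
    mask <- logical(m)
    mask[causal] <- TRUE
    structure(list(beta_true = beta, causal_mask = mask), class = "truth_set")
  })
}

#' Simulate baseline covariates
#'
#' age ~ Normal(57, 8), sex ~ Bernoulli(0.5), array ~ Bernoulli(0.1) (about
#' one in ten samples on the secondary genotyping array), PC1..PC10 ~ Normal(0,1).
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @return data.frame with columns age, sex, array, PC1..PC10.
#' @export
simulate_covariates <- function(n, seed) {
  if (n < 1) stop_config("n must be >= 1")
  with_seed(seed, {
    cv <- data.frame(age = rnorm(n, 57, 8),
                     sex = rbinom(n, 1, 0.5),
                     array = rbinom(n, 1, 0.1))
    pcs <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("PC", 1:10)))
    cbind(cv, as.data.frame(pcs))
  })
}

#' Simulate a phenotype from genotypes, truth and covariates
#'
#' The genetic score `G_std %*% beta_true` is rescaled to have empirical
#' variance `h2_true`; covariate effects act additively (on the liability for
#' binary traits). Gaussian noise variance is `1 - h2_true - var(covariate
#' score)` so the genetic fraction of phenotypic variance equals `h2_true` and
#' total variance is ~1. Binary traits threshold the liability at its
#' `(1 - K)` Normal quantile.
#'
#' @param G dosage matrix.
#' @param truth `truth_set` from [simulate_effects()].
#' @param covariates covariate data.frame.
#' @param covariate_betas named effects for covariate columns (on trait scale).
#' @param family `"gaussian"` or `"binomial"`.
#' @param h2_true heritability used to scale the genetic score and noise.
#' @param prevalence_K case fraction for binomial.
#' @param seed integer seed.
#' @return numeric (gaussian) or integer 0/1 (binomial) vector.
#' @export
simulate_phenotype <- function(G, truth, covariates, covariate_betas, family,
                               h2_true, prevalence_K = 0.1, seed = 1L) {
  family <- match.arg(family, c("gaussian", "binomial"))
  if (family == "binomial")
    check_prob(prevalence_K, "prevalence_K", open_lo = TRUE, open_hi = TRUE)
  g <- genetic_score(G, truth$beta_true)
  vg <- var(g)
  if (h2_true > 0 && vg > 0) g <- g * sqrt(h2_true / vg) else g <- g * 0
  cs <- covariate_effect(covariates, covariate_betas)
  vc <- var(cs)
  ve <- 1 - h2_true - vc
  if (ve < 0)
    stop_config("covariate effects too strong: residual variance would be negative")
  with_seed(seed, {
    e <- rnorm(nrow(G), 0, sqrt(ve))
    l <- g + cs + e
    if (family == "gaussian") l
    else {
      thr <- qnorm(1 - prevalence_K, mean = mean(l), sd = sd(l))
      as.integer(l > thr)
    }
  })
}

# standardized genetic score G_std beta; columns with zero variance contribute 0
genetic_score <- function(G, beta) {
  j <- which(beta != 0)
  if (!length(j)) return(numeric(nrow(G)))
  Gs <- scale(G[, j, drop = FALSE])
  Gs[, attr(Gs, "scaled:scale") == 0] <- 0
  drop(Gs %*% beta[j])
}

covariate_effect <- function(covariates, covariate_betas) {
  cs <- numeric(nrow(covariates))
  for (nm in names(covariate_betas)) {
    if (!nm %in% names(covariates)) stop_config("unknown covariate '%s'", nm)
    x <- covariates[[nm]]
    cs <- cs + covariate_betas[[nm]] * (x - mean(x))
  }
  cs
}

#' Split samples into train / validation / test
#'
#' Random partition with floor-rounding for the train and validation counts
#' and the remainder to test, so sizes are reproducible. The same split
#' (given the same seed) is reused for all traits.
#'
#' @param n number of samples.
#' @param fractions length-3 nonnegative vector summing to 1.
#' @param seed integer seed.
#' @return factor of length `n` with levels train, validation, test.
#' @export
split_samples <- function(n, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stop_config("fractions must be 3 nonnegative values summing to 1")
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  with_seed(seed, {
    perm <- sample.int(n)
    out <- character(n)
    out[perm[seq_len(n_tr)]] <- "train"
    out[perm[n_tr + seq_len(n_va)]] <- "validation"
    out[perm[(n_tr + n_va + 1):n]] <- "test"
    factor(out, levels = c("train", "validation", "test"))
  })
}

#' Simulate a complete multi-population cohort
#'
#' Draws ancestral frequencies, drifts them per population, simulates
#' genotypes with block LD, annotations, causal effects, covariates and a
#' phenotype, and records variant metadata (chrom/pos/alleles) suitable for
#' PLINK export. All randomness derives from `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return list of class `prs_cohort` with elements G, population (factor),
#'   variants (data.frame: variant_id, chrom, pos, a1, a2), annotation, truth,
#'   base_freq, pop_freq (matrix m x populations), covariates, y, config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$seed
  m <- config$m_variants
  pops <- names(config$n_per_population)
  base_freq <- draw_base_frequencies(m, config$maf_range, s)
  pop_freq <- sapply(seq_along(pops), function(k) {
    drift_frequencies(base_freq, config$fst_per_population[[pops[k]]],
                      s + 1000L + k, n = config$n_per_population[[pops[k]]])
  })
  colnames(pop_freq) <- pops
  G <- do.call(rbind, lapply(seq_along(pops), function(k) {
    simulate_genotypes(pop_freq[, k], config$n_per_population[[pops[k]]],
                       config$ld_block_size, config$ld_rho, s + 2000L + k)
  }))
  population <- factor(rep(pops, config$n_per_population), levels = pops)
  annotation <- simulate_annotations(m, seed = s + 3000L)
  truth <- simulate_effects(annotation, config$n_causal,
                            config$causal_enrichment, config$h2_true,
                            s + 4000L)
  covariates <- simulate_covariates(nrow(G), s + 5000L)
  y <- simulate_phenotype(G, truth, covariates, config$covariate_betas,
                          config$family, config$h2_true, config$prevalence_K,
                          s + 6000L)
  variants <- with_seed(s + 7000L, {
    acgt <- c("A", "C", "G", "T")
    a1 <- sample(acgt, m, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(acgt, a), 1), "")
    data.frame(variant_id = annotation$variant_id, chrom = 1L,
               pos = 10000L * seq_len(m), a1 = a1, a2 = unname(a2),
               stringsAsFactors = FALSE)
  })
  colnames(G) <- variants$variant_id
  # drop monomorphic columns, if any arise, with a logged warning
  mono <- which(apply(G, 2, function(x) length(unique(x))) == 1)
  if (length(mono)) {
    warning(sprintf("dropping %d monomorphic variant(s)", length(mono)))
    keep <- setdiff(seq_len(m), mono)
    G <- G[, keep, drop = FALSE]
    variants <- variants[keep, ]
    annotation <- annotation[keep, ]
    truth$beta_true <- truth$beta_true[keep]
    truth$causal_mask <- truth$causal_mask[keep]
    base_freq <- base_freq[keep]
    pop_freq <- pop_freq[keep, , drop = FALSE]
  }
  structure(list(G = G, population = population, variants = variants,
                 annotation = annotation, truth = truth,
                 base_freq = base_freq, pop_freq = pop_freq,
                 covariates = covariates, y = y, config = config),
            class = "prs_cohort")
}
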