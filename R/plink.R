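# PLINK 1 binary genotype codec and PRS score-file I/O.
#
# .bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then
# ceil(n/4) bytes per variant, two bits per sample (low bits first within a
# byte): 00 = homozygous A1 (dosage 2 of the counted A1 allele),
# 01 = missing, 10 = heterozygous, 11 = homozygous A2 (dosage 0).

# 256 x 4 lookup: dosage of each of the 4 samples packed in a byte
.bed_lut <- local({
  code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  lut <- matrix(NA_real_, 256, 4)
  for (b in 0:255)
    for (s in 0:3)
      lut[b + 1, s + 1] <- code_to_dosage[[as.character(bitwAnd(bitwShiftR(b, 2 * s), 3L))]]
  lut
})

#' Read a PLINK 1 binary fileset
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` must exist.
#' @return list: `G` (n x m dosage matrix counting the A1 allele, NA =
#'   missing, columns named by variant id), `variants` (.bim as data.frame:
#'   chrom, variant_id, cm, pos, a1, a2), `samples` (.fam as data.frame).
#' @export
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"),
                    colClasses = c("integer", "character", "numeric", "integer",
                                   "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    col.names = c("fid", "iid", "father", "mother", "sex", "pheno"),
                    colClasses = c("character", "character", "character",
                                   "character", "integer", "numeric"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_config("%s: not a PLINK .bed file (magic byte mismatch)", bed)
  if (raw[3] == as.raw(0x00))
    stop_config("%s: sample-major .bed files are not supported", bed)
  if (raw[3] != as.raw(0x01))
    stop_config("%s: unknown .bed mode byte", bed)
  bpv <- ceiling(n / 4)
  if (length(raw) != 3 + bpv * m)
    stop_config("%s: truncated .bed (expected %d data bytes, found %d)",
                bed, bpv * m, length(raw) - 3)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv)
  G <- matrix(NA_real_, n, m)
  for (s in 1:4) {
    if (s > n) next
    rows <- seq(s, n, by = 4)
    bytes <- body[seq_along(rows), , drop = FALSE]
    G[rows, ] <- .bed_lut[bytes + 1, s]
  }
  colnames(G) <- bim$variant_id
  list(G = G, variants = bim, samples = fam)
}

#' Write a PLINK 1 binary fileset
#'
#' @param G n x m dosage matrix counting the A1 allele (values 0/1/2/NA).
#' @param variants data.frame with chrom, variant_id, pos, a1, a2 (cm
#'   optional, defaults 0).
#' @param samples optional data.frame with fid, iid, sex, pheno; generated
#'   when absent.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink_bed <- function(G, variants, samples = NULL, prefix) {
  n <- nrow(G)
  m <- ncol(G)
  stopifnot(nrow(variants) == m)
  if (is.null(samples))
    samples <- data.frame(fid = sprintf("F%06d", seq_len(n)),
                          iid = sprintf("S%06d", seq_len(n)),
                          father = "0", mother = "0", sex = 0L, pheno = -9)
  # dosage -> 2-bit code
  code <- matrix(1L, n, m)                 # default: missing (01)
  code[!is.na(G) & G == 2] <- 0L
  code[!is.na(G) & G == 1] <- 2L
  code[!is.na(G) & G == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  shifted <- code * rep(c(1L, 4L, 16L, 64L), times = bpv)
  dim(shifted) <- c(4, bpv * m)
  bytes <- as.raw(colSums(shifted))
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), paste0(prefix, ".bed"))
  bim <- data.frame(chrom = variants$chrom, id = variants$variant_id,
                    cm = variants$cm %||% 0, pos = variants$pos,
                    a1 = variants$a1, a2 = variants$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(samples, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write a PRS model as a score file
#'
#' Three-column TSV (ID, A1, BETA) compatible with the de-facto `--score`
#' format, at 17 significant digits so round trips are lossless. Covariate
#' coefficients, the chosen lambda, family and training allele frequencies go
#' to a JSON sidecar `<path>.json`.
#'
#' @param model a `prs_model`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_score_file <- function(model, path) {
  df <- data.frame(ID = names(model$weights),
                   A1 = unname(model$alleles[names(model$weights)]),
                   BETA = sprintf("%.17g", unname(model$weights)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(covariate_coef = as.list(model$covariate_coef),
                  lambda = model$lambda, family = model$family,
                  freq = as.list(model$freq))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a PRS score file
#'
#' @param path score TSV written by [write_score_file()] (the JSON sidecar is
#'   read when present; otherwise covariate terms are empty and allele
#'   frequencies default to 0, i.e. missing dosages impute to 0).
#' @return a `prs_model`.
#' @export
read_score_file <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "character"))
  weights <- setNames(as.numeric(df$BETA), df$ID)
  alleles <- setNames(df$A1, df$ID)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    covariate_coef <- unlist(sc$covariate_coef)
    lambda <- sc$lambda
    family <- sc$family
    freq <- unlist(sc$freq)
    if (is.null(freq)) freq <- setNames(numeric(0), character(0))
  } else {
    covariate_coef <- numeric(0)
    lambda <- NA_real_
    family <- NA_character_
    freq <- setNames(rep(0, length(weights)), names(weights))
  }
  structure(list(weights = weights, alleles = alleles,
                 covariate_coef = covariate_coef, lambda = lambda,
                 family = family, freq = freq[names(weights)]),
            class = "prs_model")
}
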