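#' Genotype matrix container
#'
#' Holds a samples x variants table of allele dosages together with variant
#' metadata. Dosages count copies of the ALT allele: 0 (hom ref), 1 (het),
#' 2 (hom alt); missing genotypes are `NA`.
#'
#' @param dosage integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data frame with one row per variant and columns
#'   `chrom`, `pos` (1-based), `id`, `ref`, `alt`. A canonical `key`
#'   column (`chrom:pos:ref:alt`) is added if absent.
#' @param sample_ids character vector of sample identifiers, one per row.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosage`, `variants`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                       data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                                  id = ".", ref = "A", alt = "G"),
#'                       c("S1", "S2"))
#' n_variants(gm)
#' @export
genotype_matrix <- function(dosage, variants, sample_ids) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosage),
            length(sample_ids) == nrow(dosage))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  if (is.null(variants$id)) variants$id <- "."
  if (is.null(variants$key))
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- variants$key
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = as.character(sample_ids)),
            class = "geno_matrix")
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt vectors of chromosome, 1-based position and
#'   single-base alleles.
#' @return character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname genotype_matrix
#' @param x a `geno_matrix`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname genotype_matrix
#' @export
n_variants <- function(x) nrow(x$variants)

#' @export
print.geno_matrix <- function(x, ...) {
  nm <- sum(is.na(x$dosage))
  cat(sprintf("geno_matrix: %d samples x %d variants (%d missing genotypes)\n",
              n_samples(x), n_variants(x), nm))
  invisible(x)
}

#' Subset a genotype matrix by variant index
#'
#' @param x a `geno_matrix`.
#' @param j integer indices of variants to keep.
#' @return a `geno_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(x, j) {
  genotype_matrix(x$dosage[, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  x$sample_ids)
}

# Folded minor-allele count per variant, over non-missing genotypes.
minor_allele_counts <- function(x) {
  d <- x$dosage
  alt <- colSums(d, na.rm = TRUE)
  nn <- colSums(!is.na(d))
  pmin(alt, 2L * nn - alt)
}

# Deterministic 31-bit child seed from a base seed and a tag string; keeps
# independent streams for the simulator, the imputer and each (gene, stage)
# permutation run.
derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}
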