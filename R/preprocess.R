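#' Read a VCF into a genotype matrix
#'
#' Loads bi-allelic SNV records from a VCF (v4.2, GT field required) and
#' codes each genotype as the count of ALT alleles: `0/0` -> 0, `0/1` -> 1,
#' `1/1` -> 2, `./.` -> `NA`. Phased separators are accepted. Multi-allelic
#' or non-SNV lines are skipped with a message.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    ids <- colnames(v@gt)
    ids <- ids[ids != "FORMAT"]
    return(genotype_matrix(matrix(integer(), length(ids), 0),
                           data.frame(chrom = character(), pos = integer(),
                                      id = character(), ref = character(),
                                      alt = character()), ids))
  }
  snv <- !is.na(fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snv))
    message(sum(!snv), " non-SNV or multi-allelic line(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  d <- t(apply(gt, 1, code))
  if (nrow(fix) == 1) d <- matrix(as.integer(d), nrow = 1)
  genotype_matrix(t(d),
                  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                             id = ifelse(is.na(fix$ID), ".", fix$ID),
                             ref = fix$REF, alt = fix$ALT,
                             stringsAsFactors = FALSE),
                  colnames(gt))
}

#' Read a phenotype table
#'
#' Accepts either a binary table (`sample_id`, `y`) or a longitudinal table
#' with columns `HTN1..HTN4`, which is collapsed through
#' [collapse_longitudinal_phenotype()].
#'
#' @param path tab-separated file with a header.
#' @return data frame with columns `sample_id` and `y` (1 = case), plus any
#'   extra columns present in the input (e.g. `subpop`).
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("phenotype table needs sample_id")
  if (all(paste0("HTN", 1:4) %in% names(tab)))
    return(collapse_longitudinal_phenotype(tab))
  if (!"y" %in% names(tab)) stop("phenotype table needs y or HTN1..HTN4")
  if (!all(tab$y %in% 0:1)) stop("y must be binary")
  tab
}

#' Collapse a longitudinal binary phenotype to ever-affected
#'
#' A sample is a case (`y = 1`) if it was affected at any of the recorded
#' time points, considering non-missing observations only. Samples with all
#' time points missing are excluded with a warning.
#'
#' @param tab data frame with `sample_id` and columns `HTN1..HTN4` coded
#'   0/1/NA.
#' @return data frame with `sample_id` and `y`.
#' @examples
#' collapse_longitudinal_phenotype(data.frame(
#'   sample_id = c("a", "b"), HTN1 = c(0, NA), HTN2 = c(0, NA),
#'   HTN3 = c(1, NA), HTN4 = c(0, 1)))
#' @export
collapse_longitudinal_phenotype <- function(tab) {
  cols <- paste0("HTN", 1:4)
  stopifnot(all(cols %in% names(tab)))
  m <- as.matrix(tab[cols])
  all_miss <- rowSums(!is.na(m)) == 0
  if (any(all_miss))
    warning(sum(all_miss), " sample(s) with all time points missing excluded")
  y <- as.integer(rowSums(m == 1, na.rm = TRUE) > 0)
  data.frame(sample_id = tab$sample_id[!all_miss], y = y[!all_miss],
             stringsAsFactors = FALSE)
}

#' Read a known-site exclusion list
#'
#' One entry per line, either a canonical `chrom:pos:ref:alt` key or an
#' rsID; both are matched by [filter_variants()]. Blank lines and `#`
#' comments are ignored.
#'
#' @param path text file path.
#' @return character vector of keys/IDs.
#' @export
read_known_sites <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Minor-allele frequency of one variant
#'
#' Folded frequency of the less common allele among non-missing genotypes;
#' always in `[0, 0.5]`.
#'
#' @param geno a [genotype_matrix()].
#' @param j variant column index.
#' @return the MAF as a fraction.
#' @examples
#' gm <- genotype_matrix(matrix(c(1L, rep(0L, 102)), ncol = 1),
#'                       data.frame(chrom = "chr1", pos = 1, id = ".",
#'                                  ref = "A", alt = "G"),
#'                       sprintf("S%03d", 1:103))
#' compute_maf(gm, 1)  # 1/206
#' @export
compute_maf <- function(geno, j) {
  g <- geno$dosage[, j]
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("variant ", j, " has no non-missing genotypes")
  alt <- sum(g)
  min(alt, 2 * length(g) - alt) / (2 * length(g))
}

#' Per-variant minor-allele frequencies and missing rates
#'
#' @param geno a [genotype_matrix()].
#' @return numeric vector, one entry per variant.
#' @export
variant_mafs <- function(geno) {
  d <- geno$dosage
  nn <- colSums(!is.na(d))
  if (any(nn == 0)) stop("variant(s) with no non-missing genotypes")
  alt <- colSums(d, na.rm = TRUE)
  pmin(alt, 2 * nn - alt) / (2 * nn)
}

#' @rdname variant_mafs
#' @export
variant_missing_rates <- function(geno) {
  colMeans(is.na(geno$dosage))
}

#' Filter variants by known-site membership, MAF and missingness
#'
#' Retains variants that are absent from the known-site list, have MAF
#' `<= maf_max`, and missing rate `<= miss_max` (both bounds inclusive:
#' only strictly larger values are removed). The report counts each removed
#' variant once, at the first rule that removes it, in the order
#' known -> MAF -> missingness; the retained set itself is
#' order-independent (the intersection of the three single-rule sets).
#'
#' @param geno a [genotype_matrix()].
#' @param known_keys character vector of `chrom:pos:ref:alt` keys and/or
#'   rsIDs to exclude (e.g. from [read_known_sites()]).
#' @param maf_max maximum minor-allele frequency (default 0.01).
#' @param miss_max maximum genotype missing rate (default 0.05).
#' @return list with `geno` (the filtered matrix) and `report`, a one-row
#'   data frame with columns `n_input`, `n_removed_known`, `n_removed_maf`,
#'   `n_removed_missing`, `n_retained`.
#' @export
filter_variants <- function(geno, known_keys = character(),
                            maf_max = 0.01, miss_max = 0.05) {
  p <- n_variants(geno)
  if (p == 0)
    return(list(geno = geno,
                report = data.frame(n_input = 0L, n_removed_known = 0L,
                                    n_removed_maf = 0L,
                                    n_removed_missing = 0L, n_retained = 0L)))
  known <- geno$variants$key %in% known_keys |
    geno$variants$id %in% known_keys
  miss <- variant_missing_rates(geno) > miss_max
  all_miss <- colSums(!is.na(geno$dosage)) == 0
  maf <- rep(FALSE, p)
  maf[!all_miss] <- variant_mafs(subset_variants(geno, which(!all_miss))) >
    maf_max
  first <- ifelse(known, 1L, ifelse(maf | all_miss, 2L, ifelse(miss, 3L, 0L)))
  keep <- first == 0L
  list(geno = subset_variants(geno, which(keep)),
       report = data.frame(n_input = p,
                           n_removed_known = sum(first == 1L),
                           n_removed_maf = sum(first == 2L),
                           n_removed_missing = sum(first == 3L),
                           n_retained = sum(keep)))
}

#' Impute missing genotypes by resampling
#'
#' Each missing genotype is replaced by a uniform draw, with replacement,
#' from the non-missing genotype values of the same variant. Non-missing
#' entries are untouched; results are reproducible from the seed.
#'
#' @param geno a [genotype_matrix()]; every variant must have at least one
#'   non-missing genotype (enforced by [filter_variants()]).
#' @param seed integer seed.
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute_missing <- function(geno, seed = 1) {
  d <- geno$dosage
  nmiss <- colSums(is.na(d))
  if (!any(nmiss > 0)) return(geno)
  set.seed(derive_seed(seed, "impute"))
  for (j in which(nmiss > 0)) {
    obs <- d[!is.na(d[, j]), j]
    if (length(obs) == 0)
      stop("variant ", j, " is entirely missing; filter before imputing")
    d[is.na(d[, j]), j] <- sample(obs, nmiss[j], replace = TRUE)
  }
  genotype_matrix(d, geno$variants, geno$sample_ids)
}

#' Group variants into genes by transcript span
#'
#' A variant joins every gene whose `[txStart, txEnd]` interval (1-based,
#' inclusive at both ends) contains its position on the matching
#' chromosome. Variants inside no gene are dropped from analysis; genes
#' containing no variants are dropped from testing.
#'
#' @param geno a [genotype_matrix()].
#' @param models named list of [gene_model()]s.
#' @return named list of gene variant sets, each a list with `gene` (the
#'   model) and `idx` (variant column indices sorted by position).
#' @export
assign_to_genes <- function(geno, models) {
  out <- list()
  for (m in models) {
    hit <- which(geno$variants$chrom == m$chrom &
                   geno$variants$pos >= m$txStart &
                   geno$variants$pos <= m$txEnd)
    if (length(hit) == 0) next
    hit <- hit[order(geno$variants$pos[hit])]
    out[[m$name]] <- structure(list(gene = m, idx = hit),
                               class = "gene_variant_set")
  }
  out
}

#' Harmonize genotype and phenotype samples
#'
#' Drops samples present in only one of the two inputs (with a warning) and
#' reorders the genotype matrix to the phenotype's sample order.
#'
#' @param geno a [genotype_matrix()].
#' @param phen data frame with `sample_id`, `y`.
#' @return list with the harmonized `geno` and `phen`.
#' @export
harmonize_samples <- function(geno, phen) {
  common <- intersect(phen$sample_id, geno$sample_ids)
  drop_g <- setdiff(geno$sample_ids, common)
  drop_p <- setdiff(phen$sample_id, common)
  if (length(drop_g) || length(drop_p))
    warning(length(drop_g), " genotype-only and ", length(drop_p),
            " phenotype-only sample(s) dropped")
  if (length(common) == 0) stop("no samples in common")
  phen <- phen[phen$sample_id %in% common, , drop = FALSE]
  i <- match(phen$sample_id, geno$sample_ids)
  geno <- genotype_matrix(geno$dosage[i, , drop = FALSE], geno$variants,
                          geno$sample_ids[i])
  list(geno = geno, phen = phen)
}
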