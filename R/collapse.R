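#' Find the singletons of a gene
#'
#' A singleton is a variant whose minor allele is observed exactly once
#' across all samples in the cohort, i.e. a single heterozygote. A lone
#' homozygote (minor-allele count 2) is not a singleton. Singleton status
#' is determined jointly over cases and controls, before any phenotype
#' information is used, as required for validity of the permutation null.
#'
#' @param geneset a gene variant set from [assign_to_genes()].
#' @param geno a [genotype_matrix()] with no missing genotypes (impute
#'   first).
#' @return integer vector of variant column indices (a subset of
#'   `geneset$idx`).
#' @export
find_singletons <- function(geneset, geno) {
  sub <- geno$dosage[, geneset$idx, drop = FALSE]
  if (anyNA(sub))
    stop("missing genotypes present; run impute_missing() first")
  alt <- colSums(sub)
  mac <- pmin(alt, 2 * nrow(sub) - alt)
  geneset$idx[mac == 1]
}

#' Build the per-gene supervariant
#'
#' Collapses all singletons of a gene into one binary carrier indicator:
#' `X[i] = 1` if sample `i` carries at least one of the gene's singletons,
#' `0` otherwise. Genes with zero singletons yield an all-zero indicator
#' flagged untestable.
#'
#' @param geneset a gene variant set from [assign_to_genes()]. If the set
#'   carries a `singleton_idx` field (as produced by
#'   [subset_by_region()]), that gene-level singleton list is used instead
#'   of recomputing singleton status on the subset.
#' @param geno a [genotype_matrix()] with no missing genotypes.
#' @return an object of class `supervariant`: list with `gene`, `X`
#'   (binary vector over samples), `n_singletons_used`, `singleton_idx`,
#'   `testable`.
#' @export
build_supervariant <- function(geneset, geno) {
  sidx <- geneset$singleton_idx
  if (is.null(sidx)) sidx <- find_singletons(geneset, geno)
  sidx <- intersect(sidx, geneset$idx)
  if (length(sidx) == 0) {
    X <- rep(0L, n_samples(geno))
  } else {
    X <- as.integer(rowSums(geno$dosage[, sidx, drop = FALSE] >= 1) > 0)
  }
  structure(list(gene = geneset$gene$name, X = X,
                 n_singletons_used = length(sidx), singleton_idx = sidx,
                 testable = length(sidx) > 0),
            class = "supervariant")
}

#' @export
print.supervariant <- function(x, ...) {
  cat(sprintf("supervariant %s: %d carriers from %d singletons%s\n",
              x$gene, sum(x$X), x$n_singletons_used,
              if (x$testable) "" else " (untestable)"))
  invisible(x)
}

#' Classify positions into CDS, UTR or intron
#'
#' Every position inside the transcript maps to exactly one class: `CDS` if
#' it falls in an exon and inside the coding interval, `UTR` if exonic but
#' outside the coding interval (or the transcript is non-coding), `INTRON`
#' otherwise. Positions outside `[txStart, txEnd]` are an error.
#'
#' @param pos integer vector of 1-based positions.
#' @param model a [gene_model()].
#' @return character vector in `{"CDS", "UTR", "INTRON"}`.
#' @examples
#' gm <- gene_model("G1", "chr1", "+", 100, 1000, 200, 900,
#'                  c(100, 400, 800), c(250, 500, 1000))
#' classify_region(c(150, 300, 450), gm)
#' @export
classify_region <- function(pos, model) {
  if (any(pos < model$txStart | pos > model$txEnd))
    stop("position(s) outside the transcript span of ", model$name)
  exonic <- vapply(pos, function(p)
    any(p >= model$exonStarts & p <= model$exonEnds), TRUE)
  in_cds <- !is.na(model$cdsStart) & pos >= model$cdsStart &
    pos <= model$cdsEnd
  ifelse(exonic & in_cds, "CDS", ifelse(exonic, "UTR", "INTRON"))
}

#' Restrict a gene's variant set to one region class
#'
#' Returns the subset of the gene's variants classifying as `cls`. The
#' gene-level singleton list is inherited, not recomputed: a singleton of
#' the gene remains a singleton of the region subset, so region singleton
#' counts partition the gene's singleton count.
#'
#' @param geneset a gene variant set from [assign_to_genes()].
#' @param geno a [genotype_matrix()] with no missing genotypes.
#' @param cls one of `"CDS"`, `"UTR"`, `"INTRON"`.
#' @return a `gene_variant_set` with fields `idx` (restricted),
#'   `singleton_idx` (gene-level singletons within the region) and
#'   `region`; empty subsets are legal and flagged by downstream builders.
#' @export
subset_by_region <- function(geneset, geno, cls) {
  cls <- match.arg(cls, c("CDS", "UTR", "INTRON"))
  sidx <- geneset$singleton_idx
  if (is.null(sidx)) sidx <- find_singletons(geneset, geno)
  reg <- classify_region(geno$variants$pos[geneset$idx], geneset$gene)
  keep <- geneset$idx[reg == cls]
  structure(list(gene = geneset$gene, idx = keep,
                 singleton_idx = intersect(sidx, keep), region = cls),
            class = "gene_variant_set")
}

#' Export supervariants as TSV or pseudo-VCF
#'
#' The TSV has one row per (gene, sample) pair with the binary carrier
#' indicator; the pseudo-VCF has one line per gene with genotypes `0/0`
#' (non-carrier) or `0/1` (carrier), positioned at the gene's txStart.
#'
#' @param svs list of [build_supervariant()] results.
#' @param models named list of [gene_model()]s (pseudo-VCF only).
#' @param sample_ids character vector of sample identifiers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_supervariants_tsv <- function(svs, sample_ids, path) {
  rows <- do.call(rbind, lapply(svs, function(s)
    data.frame(gene = s$gene, sample_id = sample_ids, X = s$X,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_supervariants_tsv
#' @export
write_supervariants_vcf <- function(svs, models, sample_ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=supervar collapsed supervariants",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Carrier">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  for (s in svs) {
    m <- models[[s$gene]]
    writeLines(paste(c(m$chrom, format(m$txStart, scientific = FALSE),
                       paste0(s$gene, "_SUPER"), "N", "<COLLAPSED>", ".",
                       ".", paste0("NSINGLETON=", s$n_singletons_used), "GT",
                       ifelse(s$X == 1, "0/1", "0/0")), collapse = "\t"), con)
  }
  invisible(path)
}
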