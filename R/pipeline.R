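#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: [simulate_cohort()] then [write_cohort()].
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return named vector of written file paths, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  cohort <- simulate_cohort(config)
  paths <- write_cohort(cohort, out_dir)
  message("wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

#' End-to-end gene-based rare-variant scan
#'
#' Reads the cohort files, applies the known-site / MAF / missingness
#' filters, resamples remaining missing genotypes, groups variants into
#' genes, collapses singletons into per-gene supervariants, and runs the
#' two-step permutation scan. The filter report and, if `out_dir` is
#' given, the results table are written as TSV.
#'
#' @param vcf,genes,phenotype input file paths.
#' @param known_sites optional known-site list path (see
#'   [read_known_sites()]).
#' @param out_dir optional output directory for `results.tsv` and
#'   `filter_report.tsv`.
#' @param plan a [permutation_plan()].
#' @param maf_max,miss_max filter thresholds, see [filter_variants()].
#' @param seed seed for the missing-genotype resampling.
#' @param ... further arguments passed to [two_step_scan()].
#' @return the [two_step_scan()] results data frame, with the filter
#'   report attached as attribute `"filter_report"`.
#' @export
run_scan <- function(vcf, genes, phenotype, known_sites = NULL,
                     out_dir = NULL, plan = permutation_plan(),
                     maf_max = 0.01, miss_max = 0.05, seed = 1, ...) {
  geno <- read_vcf_matrix(vcf)
  models <- read_gene_models(genes)
  phen <- read_phenotype(phenotype)
  h <- harmonize_samples(geno, phen)
  known <- if (is.null(known_sites)) character() else
    read_known_sites(known_sites)
  fl <- filter_variants(h$geno, known, maf_max = maf_max,
                        miss_max = miss_max)
  message(sprintf(paste0("filter: %d input, %d known, %d MAF, %d missing ",
                         "removed; %d retained"),
                  fl$report$n_input, fl$report$n_removed_known,
                  fl$report$n_removed_maf, fl$report$n_removed_missing,
                  fl$report$n_retained))
  geno <- impute_missing(fl$geno, seed = seed)
  gsets <- assign_to_genes(geno, models)
  if (length(gsets) == 0) stop("no gene contains any retained variant")
  res <- two_step_scan(gsets, geno, h$phen, plan = plan, ...)
  attr(res, "filter_report") <- fl$report
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(out_dir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fl$report, file.path(out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Region-stratified report for one gene
#'
#' Re-tests one gene over its whole span and separately over its CDS, UTR
#' and intronic variants: the supervariant Fisher exact test (p,
#' conditional-MLE OR, 95% CI) and the three permutation statistics at a
#' single permutation depth. Gene-level singleton status is inherited by
#' the region subsets.
#'
#' @param geneset the gene's variant set from [assign_to_genes()].
#' @param geno a [genotype_matrix()] with no missing genotypes.
#' @param phen data frame with binary `y`.
#' @param B permutation count per region.
#' @param seed integer seed.
#' @param methods statistics to run, see [two_step_scan()].
#' @param cmc_breaks bin edges for [cmc_indicators()].
#' @return data frame with one row per region (`ALL`, `CDS`, `UTR`,
#'   `INTRON`): variant and singleton counts, Fisher columns, one p-value
#'   column per method. Untestable regions carry `NA`s.
#' @export
run_region <- function(geneset, geno, phen, B = 10000, seed = 1,
                       methods = c("ssu", "calpha", "cmc"),
                       cmc_breaks = c(1, 2, Inf)) {
  sidx <- find_singletons(geneset, geno)
  geneset$singleton_idx <- sidx
  sets <- c(list(ALL = geneset),
            lapply(stats::setNames(nm = c("CDS", "UTR", "INTRON")),
                   function(cl) subset_by_region(geneset, geno, cl)))
  rows <- lapply(names(sets), function(nm) {
    gs <- sets[[nm]]
    out <- data.frame(gene = geneset$gene$name, region = nm,
                      n_variants = length(gs$idx),
                      n_singletons = length(intersect(sidx, gs$idx)),
                      fisher_p = NA_real_, or = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_,
                      stringsAsFactors = FALSE)
    for (m in methods) out[[paste0(m, "_p_display")]] <- NA_character_
    if (length(gs$idx) == 0) return(out)
    sv <- build_supervariant(gs, geno)
    if (sv$testable && sum(sv$X) > 0 && sum(sv$X) < length(sv$X)) {
      ft <- fisher_exact_2x2(supervariant_table(sv, phen))
      out$fisher_p <- ft$p; out$or <- ft$or
      out$ci_lo <- ft$ci[1]; out$ci_hi <- ft$ci[2]
    }
    fm <- build_feature_matrix(gs, geno, sv = sv)
    if (!fm$testable) return(out)
    G <- if ("cmc" %in% methods) cmc_indicators(fm, cmc_breaks) else NULL
    if (!is.null(G) && ncol(G) == 0) G <- NULL
    use <- if (is.null(G)) setdiff(methods, "cmc") else methods
    sc <- perm_scan_gene(fm, G, phen$y, B,
                         derive_seed(seed, paste0(geneset$gene$name, ":",
                                                  nm)), use)
    for (m in use)
      out[[paste0(m, "_p_display")]] <- format_p(sc$b[[m]], B)
    out
  })
  do.call(rbind, rows)
}

#' Principal-component-adjusted re-test of a gene's supervariant
#'
#' Selects common variants, computes the top principal components and runs
#' the adjusted logistic test of [logistic_adjusted_test()].
#'
#' @param geneset the gene's variant set (singletons taken gene-wide).
#' @param geno_rare imputed rare-variant matrix carrying the gene.
#' @param geno_all full matrix to draw common variants from (may be the
#'   same object).
#' @param phen data frame with binary `y`.
#' @param k number of principal components.
#' @param n_common number of common variants to select.
#' @param maf_min common-variant MAF bound.
#' @param seed integer seed.
#' @return the [logistic_adjusted_test()] result, with the `pc_set`
#'   attached as attribute `"pcs"`.
#' @export
run_adjust_pca <- function(geneset, geno_rare, geno_all, phen, k = 10,
                           n_common = 100000, maf_min = 0.1, seed = 1) {
  sv <- build_supervariant(geneset, geno_rare)
  common <- select_common_variants(geno_all, maf_min = maf_min,
                                   n = n_common, seed = seed)
  pcs <- pca_top_k(common, k = k)
  res <- logistic_adjusted_test(sv, phen, pcs)
  attr(res, "pcs") <- pcs
  res
}
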