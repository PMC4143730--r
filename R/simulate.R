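#' Gene shape specification for the cohort simulator
#'
#' Describes one simulated gene: how many rare variants it carries, how many
#' of them are singletons, and its transcript geometry. Defaults mirror a
#' large, intron-heavy human gene: a ~93.5 kb span with 26 exons, ~8 kb of
#' coding sequence, and rare variants falling overwhelmingly in introns.
#'
#' @param name gene symbol.
#' @param n_variants number of rare variants in the gene.
#' @param n_singletons how many of those variants are singletons
#'   (minor-allele count exactly 1); must not exceed `n_variants`.
#' @param span_bp transcript span in base pairs (`txEnd - txStart`).
#' @param n_exons number of exons.
#' @param coding_bp total coding length spread evenly over the exons.
#' @param utr_bp total untranslated exonic length (split between the
#'   transcript ends).
#' @param region_props expected proportion of variants falling in CDS, UTR
#'   and intron; converted to exact per-region counts by largest remainder.
#'   The default is the 14:6:360 split of a 380-variant intron-dominated
#'   gene.
#' @param is_signal if `TRUE`, singleton carriage in this gene is linked to
#'   case status through the configured carrier odds ratio; otherwise the
#'   gene is phenotype-independent.
#' @return an object of class `gene_spec`.
#' @examples
#' gene_spec("SETXlike", 380, 135, is_signal = TRUE)
#' @export
gene_spec <- function(name, n_variants, n_singletons,
                      span_bp = 93545, n_exons = 26, coding_bp = 8034,
                      utr_bp = 400,
                      region_props = c(CDS = 14, UTR = 6, INTRON = 360) / 380,
                      is_signal = FALSE) {
  stopifnot(n_variants >= 1, n_singletons >= 0)
  if (n_singletons > n_variants)
    stop("n_singletons must not exceed n_variants")
  if (span_bp < coding_bp + utr_bp)
    stop("span_bp must cover the exonic length")
  region_props <- region_props / sum(region_props)
  structure(list(name = name, n_variants = as.integer(n_variants),
                 n_singletons = as.integer(n_singletons),
                 span_bp = span_bp, n_exons = n_exons,
                 coding_bp = coding_bp, utr_bp = utr_bp,
                 region_props = region_props,
                 is_signal = isTRUE(is_signal)),
            class = "gene_spec")
}

#' Simulation configuration
#'
#' Defines the cohort the simulator emits: a retrospective case-control
#' sample, genes with a singleton-rich site-frequency spectrum, an optional
#' carrier-level effect in signal genes, optional two-subpopulation
#' confounding, and an optional background of common variants for
#' principal-component analysis.
#'
#' The effect model is retrospective: controls carry at least one singleton
#' of a signal gene with probability `control_carrier_rate` (q0) and cases
#' with the probability q1 solving `q1/(1-q1) = carrier_or * q0/(1-q0)`.
#' The defaults (64 cases, 39 controls, carrier OR 8.8, q0 = 0.44) give a
#' supervariant 2x2 table in the regime where singleton collapsing is
#' informative at very small sample size.
#'
#' @param genes list of [gene_spec()] objects (a single `gene_spec` is
#'   accepted).
#' @param n_cases,n_controls cohort composition.
#' @param carrier_or odds ratio of case status for singleton carriers in
#'   signal genes; must be positive. `1` means no effect anywhere.
#' @param control_carrier_rate probability that a control carries >= 1
#'   singleton of a signal gene; in (0, 1).
#' @param maf_max upper bound on rare-variant minor-allele frequency;
#'   non-singleton counts are drawn uniformly in
#'   `{2, ..., floor(2 * n * maf_max)}`.
#' @param confounding `NULL`, or a list with elements `p_case_B` and
#'   `p_control_B` (probability that a case resp. control belongs to
#'   subpopulation B), `divergence` in [0, 1] (how strongly a gene's
#'   rare-variant carriers are skewed toward the gene's ancestral
#'   subpopulation), and `fst` (Balding-Nichols divergence of the common
#'   background variants).
#' @param n_common number of common background variants (MAF drawn uniformly
#'   from `common_maf_range`) emitted on a separate chromosome.
#' @param common_maf_range range of common-variant allele frequencies.
#' @param chrom chromosome name carrying the simulated genes.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genes, n_cases = 64, n_controls = 39,
                       carrier_or = 8.8, control_carrier_rate = 0.44,
                       maf_max = 0.01, confounding = NULL,
                       n_common = 0, common_maf_range = c(0.1, 0.5),
                       chrom = "chr1", seed = 1) {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  stopifnot(length(genes) >= 1,
            all(vapply(genes, inherits, TRUE, "gene_spec")))
  if (n_cases < 1 || n_controls < 1)
    stop("need at least one case and one control")
  if (!(carrier_or > 0)) stop("carrier_or must be > 0")
  if (control_carrier_rate <= 0 || control_carrier_rate >= 1)
    stop("control_carrier_rate must be in (0, 1)")
  if (!is.null(confounding)) {
    stopifnot(all(c("p_case_B", "p_control_B", "divergence", "fst") %in%
                    names(confounding)),
              confounding$divergence >= 0, confounding$divergence <= 1,
              confounding$fst > 0, confounding$fst < 1)
  }
  structure(list(genes = genes, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 carrier_or = carrier_or,
                 control_carrier_rate = control_carrier_rate,
                 maf_max = maf_max, confounding = confounding,
                 n_common = as.integer(n_common),
                 common_maf_range = common_maf_range,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

# Largest-remainder apportionment of n into integer counts ~ props.
apportion <- function(n, props) {
  raw <- n * props / sum(props)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  as.integer(k)
}

# Build the transcript geometry for a gene_spec at a genomic offset.
spec_to_model <- function(spec, chrom, txStart) {
  exonic <- spec$coding_bp + spec$utr_bp
  exon_len <- apportion(exonic, rep(1, spec$n_exons))
  gap <- floor((spec$span_bp - exonic) / max(1, spec$n_exons - 1))
  starts <- ends <- numeric(spec$n_exons)
  p <- txStart
  for (i in seq_len(spec$n_exons)) {
    starts[i] <- p
    ends[i] <- p + exon_len[i] - 1
    p <- ends[i] + 1 + gap
  }
  txEnd <- txStart + spec$span_bp
  ends[spec$n_exons] <- min(ends[spec$n_exons], txEnd)
  utr5 <- ceiling(spec$utr_bp / 2)
  utr3 <- spec$utr_bp - utr5
  gene_model(spec$name, chrom, "+", txStart, txEnd,
             cdsStart = starts[1] + utr5,
             cdsEnd = ends[spec$n_exons] - utr3,
             exonStarts = starts, exonEnds = ends)
}

# Integer positions of a model's CDS / UTR / intron bases.
region_positions <- function(model) {
  exonic <- unlist(lapply(seq_along(model$exonStarts), function(i)
    seq(model$exonStarts[i], model$exonEnds[i])))
  all_pos <- seq(model$txStart, model$txEnd)
  in_cds <- !is.na(model$cdsStart) & exonic >= model$cdsStart &
    exonic <= model$cdsEnd
  list(CDS = exonic[in_cds], UTR = exonic[!in_cds],
       INTRON = setdiff(all_pos, exonic))
}

#' Simulate a case-control sequencing cohort
#'
#' Generates a genotype matrix, binary phenotype and gene models following a
#' [sim_config()]. Each gene receives exactly `n_singletons` variants of
#' minor-allele count 1 (single heterozygotes) and `n_variants -
#' n_singletons` variants of minor-allele count >= 2 with MAF <= `maf_max`,
#' all placed as heterozygotes in distinct samples. Signal-gene singleton
#' carriage follows the retrospective carrier-odds-ratio model; all other
#' genotypes are phenotype-independent.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_cohort` with elements `geno`
#'   (a [genotype_matrix()]), `phenotype` (data frame with `sample_id`, `y`,
#'   and `subpop` under confounding), and `models` (named list of
#'   [gene_model()]s). The truth columns `gene`, `region` and
#'   `is_singleton` are carried in `geno$variants` for diagnostics.
#' @examples
#' cfg <- sim_config(gene_spec("G1", 40, 15, span_bp = 20000, n_exons = 5,
#'                             coding_bp = 2000, utr_bp = 200,
#'                             is_signal = TRUE),
#'                   seed = 7)
#' coh <- simulate_cohort(cfg)
#' coh$geno
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_cases + config$n_controls
  sample_ids <- sprintf("S%04d", seq_len(n))
  y <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))

  conf <- config$confounding
  subpop <- NULL
  if (!is.null(conf)) {
    pB <- ifelse(y == 1, conf$p_case_B, conf$p_control_B)
    subpop <- ifelse(stats::runif(n) < pB, "B", "A")
  }

  q0 <- config$control_carrier_rate
  odds1 <- config$carrier_or * q0 / (1 - q0)
  q1 <- odds1 / (1 + odds1)
  max_ac <- max(2L, floor(2 * n * config$maf_max))

  models <- list()
  cols <- list()
  meta <- list()
  offset <- 1
  for (spec in config$genes) {
    model <- spec_to_model(spec, config$chrom, offset)
    offset <- model$txEnd + 10000
    models[[spec$name]] <- model

    rp <- region_positions(model)
    counts <- apportion(spec$n_variants, spec$region_props)
    for (k in 1:3) if (counts[k] > length(rp[[k]]))
      stop("gene ", spec$name, " has too few ", names(rp)[k],
           " bases for the requested variant count")
    pos <- unlist(lapply(1:3, function(k)
      sort(sample(rp[[k]], counts[k]))))
    region <- rep(c("CDS", "UTR", "INTRON"), counts)
    o <- order(pos)
    pos <- pos[o]; region <- region[o]

    is_single <- rep(FALSE, spec$n_variants)
    is_single[sample.int(spec$n_variants, spec$n_singletons)] <- TRUE

    # carrier weights for phenotype-independent placement
    w <- rep(1, n)
    if (!is.null(conf) && conf$divergence > 0) {
      origin <- sample(c("A", "B"), 1)
      w <- ifelse(subpop == origin, (1 + conf$divergence) / 2,
                  (1 - conf$divergence) / 2)
    }

    d <- matrix(0L, n, spec$n_variants)
    single_idx <- which(is_single)
    if (spec$is_signal && spec$n_singletons > 0) {
      carrier <- stats::runif(n) < ifelse(y == 1, q1, q0)
      n_carr <- sum(carrier)
      if (n_carr == 0)
        stop("signal gene ", spec$name, ": no singleton carriers drawn; ",
             "increase carrier rates or singleton count")
      if (n_carr > spec$n_singletons)
        stop("signal gene ", spec$name, ": ", n_carr, " carriers drawn but ",
             "only ", spec$n_singletons, " singleton slots; infeasible config")
      who <- which(carrier)
      first <- sample(single_idx, n_carr)
      for (i in seq_len(n_carr)) d[who[i], first[i]] <- 1L
      rest <- setdiff(single_idx, first)
      if (length(rest))
        for (j in rest) d[who[sample.int(n_carr, 1)], j] <- 1L
    } else if (spec$n_singletons > 0) {
      for (j in single_idx)
        d[sample.int(n, 1, prob = w), j] <- 1L
    }
    for (j in which(!is_single)) {
      ac <- if (max_ac > 2) sample(2:max_ac, 1) else 2L
      d[sample.int(n, ac, prob = w), j] <- 1L
    }

    cols[[spec$name]] <- d
    meta[[spec$name]] <- data.frame(
      chrom = config$chrom, pos = pos, id = ".",
      ref = sample(c("A", "C", "G", "T"), spec$n_variants, replace = TRUE),
      gene = spec$name, region = region, is_singleton = is_single,
      stringsAsFactors = FALSE)
  }

  vmeta <- do.call(rbind, meta)
  vmat <- do.call(cbind, cols)
  rownames(vmeta) <- NULL
  alt_of <- function(r) vapply(r, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  vmeta$alt <- alt_of(vmeta$ref)

  if (config$n_common > 0) {
    p <- stats::runif(config$n_common, config$common_maf_range[1],
                      config$common_maf_range[2])
    if (!is.null(conf)) {
      a <- p * (1 - conf$fst) / conf$fst
      b <- (1 - p) * (1 - conf$fst) / conf$fst
      pA <- stats::rbeta(config$n_common, a, b)
      pB <- stats::rbeta(config$n_common, a, b)
      pp <- ifelse(matrix(subpop, n, config$n_common) == "B",
                   matrix(pB, n, config$n_common, byrow = TRUE),
                   matrix(pA, n, config$n_common, byrow = TRUE))
      g <- matrix(stats::rbinom(n * config$n_common, 2, pp),
                  n, config$n_common)
    } else {
      g <- matrix(stats::rbinom(n * config$n_common, 2,
                                rep(p, each = n)), n, config$n_common)
    }
    cref <- sample(c("A", "C", "G", "T"), config$n_common, replace = TRUE)
    cmeta <- data.frame(chrom = "chr2", pos = 1000L * seq_len(config$n_common),
                        id = ".", ref = cref, gene = NA, region = NA,
                        is_singleton = FALSE, alt = alt_of(cref),
                        stringsAsFactors = FALSE)
    vmeta <- rbind(vmeta, cmeta)
    vmat <- cbind(vmat, g)
  }

  geno <- genotype_matrix(vmat, vmeta[c("chrom", "pos", "id", "ref", "alt",
                                        "gene", "region", "is_singleton")],
                          sample_ids)
  phen <- data.frame(sample_id = sample_ids, y = y,
                     stringsAsFactors = FALSE)
  if (!is.null(subpop)) phen$subpop <- subpop
  structure(list(geno = geno, phenotype = phen, models = models),
            class = "sim_cohort")
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Emits a plain-text VCF v4.2 (bi-allelic SNVs, GT-only), a refFlat-style
#' gene-model table and a phenotype TSV, all of which round-trip losslessly
#' through [read_vcf_matrix()], [read_gene_models()] and
#' [read_phenotype()].
#'
#' @param cohort a `sim_cohort` (or any list with `geno`, `phenotype`,
#'   `models`).
#' @param dir output directory, created if needed.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             genes = file.path(dir, "genes.refflat"),
             phenotype = file.path(dir, "phenotype.tsv"))
  write_vcf(cohort$geno, paths[["vcf"]])
  write_gene_models(cohort$models, paths[["genes"]])
  utils::write.table(cohort$phenotype, paths[["phenotype"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=supervar",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$sample_ids), collapse = "\t")),
             con)
  if (n_variants(geno) == 0) return(invisible(path))
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(n_variants(geno))) {
    v <- geno$variants[j, ]
    g <- geno$dosage[, j]
    gs <- ifelse(is.na(g), "./.", gt[g + 1L])
    writeLines(paste(c(v$chrom, format(v$pos, scientific = FALSE), v$id,
                       v$ref, v$alt, ".", ".", ".", "GT", gs),
                     collapse = "\t"), con)
  }
  invisible(path)
}
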