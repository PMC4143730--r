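#' Per-gene feature matrix for the rare-variant tests
#'
#' Assembles the samples x features matrix the association statistics
#' operate on. With collapsing on (the default), the features are the
#' dosages of the gene's non-singleton rare variants plus one binary
#' supervariant column labelled `"SUPER"`; with collapsing off, all variant
#' dosages enter individually. Constant (zero-variance) features carry no
#' association information and are dropped with a message.
#'
#' @param geneset a gene variant set from [assign_to_genes()].
#' @param geno a [genotype_matrix()] with no missing genotypes.
#' @param sv optional precomputed [build_supervariant()]; built on the fly
#'   if `NULL`.
#' @param collapse_singletons logical flag.
#' @return object of class `feature_matrix`: list with `F` (numeric
#'   matrix), `labels`, `mac` (per-feature minor-allele count; the
#'   supervariant column is tagged with count 1, the singleton class it
#'   represents), `n_dropped`, `testable`.
#' @export
build_feature_matrix <- function(geneset, geno, sv = NULL,
                                 collapse_singletons = TRUE) {
  if (collapse_singletons) {
    if (is.null(sv)) sv <- build_supervariant(geneset, geno)
    keep <- setdiff(geneset$idx, sv$singleton_idx)
    F <- geno$dosage[, keep, drop = FALSE]
    labels <- geno$variants$key[keep]
    alt <- colSums(F)
    mac <- pmin(alt, 2 * nrow(F) - alt)
    if (sv$testable) {
      F <- cbind(F, SUPER = sv$X)
      labels <- c(labels, "SUPER")
      mac <- c(mac, 1)
    }
  } else {
    F <- geno$dosage[, geneset$idx, drop = FALSE]
    labels <- geno$variants$key[geneset$idx]
    alt <- colSums(F)
    mac <- pmin(alt, 2 * nrow(F) - alt)
  }
  storage.mode(F) <- "double"
  v <- apply(F, 2, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " constant feature(s) dropped in ",
            geneset$gene$name)
    F <- F[, v > 0, drop = FALSE]
    labels <- labels[v > 0]
    mac <- mac[v > 0]
  }
  colnames(F) <- labels
  structure(list(F = F, labels = labels, mac = as.numeric(mac),
                 n_dropped = sum(v == 0), testable = ncol(F) > 0),
            class = "feature_matrix")
}

#' C-alpha homogeneity statistic
#'
#' Compares the case/control split of the minor-allele copies of each
#' feature against a common binomial expectation. With `n_i` total copies
#' of feature `i`, `y_i` of them in cases, and `p0` the case fraction of
#' the cohort, `T = sum_i (y_i - n_i p0)^2 - n_i p0 (1 - p0)`. Significance
#' is assessed by permutation (no asymptotic variance is used).
#'
#' @param y_case per-feature minor-allele count in cases.
#' @param n_total per-feature minor-allele count in the whole cohort.
#' @param p0 expected case fraction (`n_cases / n_samples`).
#' @return the statistic value.
#' @examples
#' calpha_statistic(1, 1, 0.5)  # a balanced singleton contributes 0
#' @export
calpha_statistic <- function(y_case, n_total, p0) {
  stopifnot(length(y_case) == length(n_total), all(y_case >= 0),
            all(y_case <= n_total), p0 > 0, p0 < 1)
  sum((y_case - n_total * p0)^2 - n_total * p0 * (1 - p0))
}

#' @rdname calpha_statistic
#' @param fm a [build_feature_matrix()] result or plain numeric matrix.
#' @param y binary phenotype vector.
#' @export
calpha_from_features <- function(fm, y) {
  F <- if (inherits(fm, "feature_matrix")) fm$F else fm
  calpha_statistic(as.numeric(crossprod(F, y)), colSums(F), mean(y))
}

#' Sum of squared score components (SSU / linear-kernel SKAT)
#'
#' Score vector `U = F' (y - mean(y))` and statistic `S = U'U` with flat
#' weights (linear kernel); the quality-unweighted multivariate score test
#' reduces to this form. Significance by permutation.
#'
#' @param fm a [build_feature_matrix()] result or plain numeric matrix.
#' @param y binary phenotype vector (both classes non-empty).
#' @return the statistic value.
#' @export
ssu_statistic <- function(fm, y) {
  F <- if (inherits(fm, "feature_matrix")) fm$F else fm
  if (length(unique(y)) < 2)
    stop("phenotype is constant; both classes must be non-empty")
  U <- crossprod(F, y - mean(y))
  sum(U^2)
}

#' Frequency-bin carrier indicators for the CMC test
#'
#' Groups features into minor-allele-count bins and records, per sample,
#' carriage of at least one feature in each bin. The default bins are
#' `{count = 1}` (the singleton class, where the supervariant column lives)
#' and `{count >= 2}`. Empty bins are dropped.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param breaks increasing numeric vector of bin edges on the minor-allele
#'   count; bin `k` is `[breaks[k], breaks[k+1])`.
#' @return binary samples x bins matrix (zero columns if no bin is
#'   populated).
#' @export
cmc_indicators <- function(fm, breaks = c(1, 2, Inf)) {
  stopifnot(inherits(fm, "feature_matrix"))
  bin <- findInterval(fm$mac, breaks)
  G <- sapply(seq_len(length(breaks) - 1), function(k) {
    cols <- which(bin == k)
    if (length(cols) == 0) return(NULL)
    as.integer(rowSums(fm$F[, cols, drop = FALSE] >= 1) > 0)
  })
  if (is.list(G)) G <- do.call(cbind, G)
  if (is.null(G)) G <- matrix(integer(), nrow(fm$F), 0)
  if (is.vector(G)) G <- matrix(G, ncol = 1)
  G
}

#' Hotelling's T-squared on bin indicators (CMC)
#'
#' Two-sample multivariate statistic
#' `T2 = n1 n2 / (n1 + n2) * (m1 - m2)' S^+ (m1 - m2)` with pooled
#' covariance `S` and its Moore-Penrose pseudo-inverse, which keeps the
#' statistic finite on the rank-deficient indicator matrices that
#' singleton-heavy genes routinely produce. Significance by permutation.
#'
#' @param G binary samples x bins matrix from [cmc_indicators()].
#' @param y binary phenotype vector (both classes non-empty).
#' @return the statistic value.
#' @export
cmc_hotelling <- function(G, y) {
  if (inherits(G, "feature_matrix")) G <- cmc_indicators(G)
  if (ncol(G) == 0) stop("no populated bins; gene is untestable for CMC")
  if (length(unique(y)) < 2)
    stop("phenotype is constant; both classes must be non-empty")
  n1 <- sum(y == 1); n2 <- sum(y == 0)
  m1 <- colMeans(G[y == 1, , drop = FALSE])
  m2 <- colMeans(G[y == 0, , drop = FALSE])
  c1 <- sweep(G[y == 1, , drop = FALSE], 2, m1)
  c2 <- sweep(G[y == 0, , drop = FALSE], 2, m2)
  S <- (crossprod(c1) + crossprod(c2)) / (n1 + n2 - 2)
  dm <- m1 - m2
  as.numeric(n1 * n2 / (n1 + n2) * crossprod(dm, MASS::ginv(S) %*% dm))
}

# Permutation stream: n x B matrix of permuted phenotype vectors,
# reproducible from the seed. All statistics of one gene/stage share it.
perm_matrix <- function(y, B, seed) {
  set.seed(seed)
  n <- length(y)
  vapply(seq_len(B), function(i) y[sample.int(n)], numeric(n))
}

# relative tolerance for exceedance ties under float recomputation
exceed <- function(perm_stats, obs) {
  sum(perm_stats >= obs - 1e-9 * (1 + abs(obs)))
}

new_test_result <- function(method, statistic, b, B,
                            convention = c("b_over_B", "plus_one")) {
  convention <- match.arg(convention)
  p <- if (convention == "plus_one") (b + 1) / (B + 1) else b / B
  structure(list(method = method, statistic = statistic, b = b, B = B,
                 p = p, p_display = format_p(b, B, convention)),
            class = "test_result")
}

#' Display convention for permutation p-values
#'
#' `b/B` when at least one permutation meets or exceeds the observed
#' statistic; `"<1/B"` (e.g. `<1.0e-06` at B = 10^6) when none does.
#'
#' @param b exceedance count.
#' @param B permutation count.
#' @param convention `"b_over_B"` (default) or the conservative
#'   `"plus_one"` for `(b+1)/(B+1)`.
#' @return character scalar.
#' @export
format_p <- function(b, B, convention = "b_over_B") {
  if (convention == "plus_one") return(sprintf("%.3g", (b + 1) / (B + 1)))
  if (b == 0) sprintf("<%.1e", 1 / B) else sprintf("%.3g", b / B)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p %s (b = %d of B = %d)\n",
              x$method, x$statistic,
              if (x$b == 0) x$p_display else paste("=", x$p_display),
              x$b, x$B), sep = "")
  invisible(x)
}

#' Permutation p-value for an association statistic
#'
#' Permutes the phenotype labels uniformly at random `B` times and counts
#' permutations whose statistic meets or exceeds the observed one (ties
#' count against significance). All three built-in statistics are oriented
#' so that larger means more associated.
#'
#' @param stat_fn function of `(features, y)` returning a scalar statistic.
#' @param features whatever `stat_fn` expects (feature or indicator
#'   matrix).
#' @param y binary phenotype vector.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param convention p-value convention, see [format_p()].
#' @param method label stored in the result.
#' @return a `test_result`: list with `method`, `statistic`, `b`, `B`, `p`,
#'   `p_display`.
#' @export
permutation_pvalue <- function(stat_fn, features, y, B, seed = 1,
                               convention = "b_over_B",
                               method = "custom") {
  stopifnot(B >= 1)
  obs <- stat_fn(features, y)
  b <- 0L
  chunk <- 10000L
  done <- 0L
  set.seed(seed)
  n <- length(y)
  while (done < B) {
    m <- min(chunk, B - done)
    for (i in seq_len(m)) {
      s <- stat_fn(features, y[sample.int(n)])
      if (s >= obs - 1e-9 * (1 + abs(obs))) b <- b + 1L
    }
    done <- done + m
  }
  new_test_result(method, obs, b, B, convention)
}

# Vectorized exceedance counts for ssu / calpha / cmc over one shared
# permutation stream. Returns named list of b counts and observed values.
perm_scan_gene <- function(fm, G, y, B, seed, methods, chunk = 5000L) {
  F <- fm$F
  n <- length(y)
  p0 <- mean(y)
  n_i <- colSums(F)
  calpha_const <- sum(n_i * p0 * (1 - p0))
  obs <- list()
  if ("ssu" %in% methods) obs$ssu <- ssu_statistic(fm, y)
  if ("calpha" %in% methods) obs$calpha <- calpha_from_features(fm, y)
  if ("cmc" %in% methods) obs$cmc <- cmc_hotelling(G, y)
  b <- stats::setNames(rep(0L, length(obs)), names(obs))
  if ("cmc" %in% methods) {
    GtG <- crossprod(G)
    csG <- colSums(G)
    n1 <- sum(y == 1); n2 <- n - n1
  }
  set.seed(seed)
  done <- 0L
  while (done < B) {
    m <- min(chunk, B - done)
    Y <- vapply(seq_len(m), function(i) y[sample.int(n)], numeric(n))
    if (any(c("ssu", "calpha") %in% methods)) {
      M <- crossprod(F, Y)                      # p x m
      if ("ssu" %in% methods) {
        s <- colSums((M - n_i * p0)^2)          # centering by mean(y) = p0
        b["ssu"] <- b["ssu"] + exceed(s, obs$ssu)
      }
      if ("calpha" %in% methods) {
        s <- colSums((M - n_i * p0)^2) - calpha_const
        b["calpha"] <- b["calpha"] + exceed(s, obs$calpha)
      }
    }
    if ("cmc" %in% methods) {
      MY <- crossprod(G, Y)                     # bins x m
      for (i in seq_len(m)) {
        m1 <- MY[, i] / n1
        m2 <- (csG - MY[, i]) / n2
        S <- (GtG - n1 * tcrossprod(m1) - n2 * tcrossprod(m2)) / (n - 2)
        dm <- m1 - m2
        t2 <- as.numeric(n1 * n2 / n * crossprod(dm, MASS::ginv(S) %*% dm))
        if (t2 >= obs$cmc - 1e-9 * (1 + abs(obs$cmc)))
          b["cmc"] <- b["cmc"] + 1L
      }
    }
    done <- done + m
  }
  list(b = b, obs = obs)
}

#' Two-step adaptive permutation plan
#'
#' All genes are screened at `B1` permutations; genes reaching an estimated
#' p below `alpha_promote` for at least one method are re-tested at `B2`
#' permutations for all methods, resolving p-values near a genome-wide
#' threshold without paying the full permutation cost everywhere.
#'
#' @param B1 screen permutation count (default 1000).
#' @param alpha_promote promotion threshold on the screen p (default
#'   0.001).
#' @param B2 confirmation permutation count (default 10^6).
#' @param seed integer seed; per-(gene, stage) child seeds are derived from
#'   it.
#' @return object of class `permutation_plan`.
#' @export
permutation_plan <- function(B1 = 1000, alpha_promote = 0.001, B2 = 1e6,
                             seed = 1) {
  stopifnot(B1 >= 1, B2 >= B1, alpha_promote > 0, alpha_promote < 1)
  structure(list(B1 = as.integer(B1), alpha_promote = alpha_promote,
                 B2 = as.integer(B2), seed = as.integer(seed)),
            class = "permutation_plan")
}

#' Bonferroni gene-based significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_genes number of genes tested.
#' @return `alpha / n_genes`.
#' @examples
#' bonferroni_threshold(0.05, 10000)  # 5e-6
#' @export
bonferroni_threshold <- function(alpha, n_genes) {
  stopifnot(n_genes >= 1, alpha > 0)
  alpha / n_genes
}

#' Two-step permutation scan over genes
#'
#' Runs the requested statistics for every gene at the screen permutation
#' count, promotes genes with any estimated p below the plan's
#' `alpha_promote`, re-tests promoted genes at the confirmation count for
#' all methods, and flags genes whose final p clears the Bonferroni
#' threshold. The three methods of one gene and stage share a single
#' permutation stream, making them directly comparable. When `B1 == B2`
#' the scan collapses to single-stage testing.
#'
#' @param genesets named list from [assign_to_genes()].
#' @param geno a [genotype_matrix()] with no missing genotypes.
#' @param phen data frame with binary `y` aligned to the samples.
#' @param plan a [permutation_plan()].
#' @param methods subset of `c("ssu", "calpha", "cmc")`.
#' @param collapse_singletons build feature matrices with the supervariant
#'   (default `TRUE`).
#' @param cmc_breaks bin edges for [cmc_indicators()].
#' @param alpha family-wise error rate for the significance flag.
#' @param n_genes_denominator Bonferroni denominator; defaults to the
#'   number of testable genes in this scan.
#' @param convention p-value convention, see [format_p()].
#' @return data frame with one row per gene x method x stage: `gene`,
#'   `chrom`, `n_variants`, `n_singletons`, `method`, `stage`, `statistic`,
#'   `b`, `B`, `p`, `p_display`, `final`, `promoted`, `significant`.
#' @export
two_step_scan <- function(genesets, geno, phen, plan = permutation_plan(),
                          methods = c("ssu", "calpha", "cmc"),
                          collapse_singletons = TRUE,
                          cmc_breaks = c(1, 2, Inf), alpha = 0.05,
                          n_genes_denominator = NULL,
                          convention = "b_over_B") {
  stopifnot(inherits(plan, "permutation_plan"), length(genesets) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  y <- phen$y

  prep <- lapply(genesets, function(gs) {
    sv <- build_supervariant(gs, geno)
    fm <- build_feature_matrix(gs, geno, sv = sv,
                               collapse_singletons = collapse_singletons)
    list(gs = gs, sv = sv, fm = fm,
         G = if ("cmc" %in% methods && fm$testable)
           cmc_indicators(fm, cmc_breaks) else NULL)
  })
  testable <- vapply(prep, function(x)
    x$fm$testable && (!"cmc" %in% methods || ncol(x$G) > 0), TRUE)
  if (!any(testable)) stop("no testable genes")
  denom <- if (is.null(n_genes_denominator)) sum(testable) else
    n_genes_denominator
  thr <- bonferroni_threshold(alpha, denom)

  run_stage <- function(x, B, stage) {
    sd <- derive_seed(plan$seed, paste0(x$gs$gene$name, ":", stage))
    sc <- perm_scan_gene(x$fm, x$G, y, B, sd, methods)
    do.call(rbind, lapply(methods, function(m) {
      tr <- new_test_result(m, sc$obs[[m]], sc$b[[m]], B, convention)
      data.frame(gene = x$gs$gene$name, chrom = x$gs$gene$chrom,
                 n_variants = length(x$gs$idx),
                 n_singletons = x$sv$n_singletons_used,
                 method = m, stage = stage, statistic = tr$statistic,
                 b = tr$b, B = tr$B, p = tr$p, p_display = tr$p_display,
                 stringsAsFactors = FALSE)
    }))
  }

  res1 <- do.call(rbind, lapply(prep[testable], run_stage,
                                B = plan$B1, stage = 1L))
  rownames(res1) <- NULL
  single_stage <- plan$B1 == plan$B2
  promoted_genes <- if (single_stage) character() else
    unique(res1$gene[res1$p < plan$alpha_promote])
  res1$final <- single_stage | !(res1$gene %in% promoted_genes)
  res1$promoted <- res1$gene %in% promoted_genes
  res <- res1
  if (length(promoted_genes)) {
    res2 <- do.call(rbind, lapply(prep[promoted_genes], run_stage,
                                  B = plan$B2, stage = 2L))
    rownames(res2) <- NULL
    res2$final <- TRUE
    res2$promoted <- TRUE
    res <- rbind(res1, res2)
  }
  res$significant <- res$final & res$p < thr
  attr(res, "bonferroni_threshold") <- thr
  attr(res, "untestable") <- names(genesets)[!testable]
  res
}
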