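#' Select common variants for principal-component analysis
#'
#' Uniform random sample, without replacement, from the variants with no
#' missing genotypes and MAF strictly above `maf_min`. If fewer than `n`
#' qualify, all qualifying variants are returned with a warning.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min lower MAF bound (exclusive; default 0.1).
#' @param n number of variants to draw (default 100000).
#' @param seed integer seed.
#' @return a [genotype_matrix()] restricted to the selection.
#' @export
select_common_variants <- function(geno, maf_min = 0.1, n = 100000,
                                   seed = 1) {
  no_miss <- colSums(is.na(geno$dosage)) == 0
  eligible <- which(no_miss)
  if (length(eligible))
    eligible <- eligible[variant_mafs(subset_variants(geno, eligible)) >
                           maf_min]
  if (length(eligible) == 0)
    stop("no variants with complete genotypes and MAF > ", maf_min)
  if (length(eligible) < n) {
    warning("only ", length(eligible), " qualifying variants (requested ",
            n, "); taking all")
    sel <- eligible
  } else {
    set.seed(derive_seed(seed, "common-select"))
    sel <- sort(sample(eligible, n))
  }
  subset_variants(geno, sel)
}

#' Top principal components of a genotype matrix
#'
#' Columns are centered and scaled to unit variance (zero-variance columns
#' dropped), scores are the projections onto the top-`k` eigenvectors of
#' the sample covariance, and each component's sign is fixed so that its
#' largest-magnitude loading is positive. If `k` exceeds the matrix rank,
#' `k` is reduced with a warning.
#'
#' @param geno a [genotype_matrix()] (typically from
#'   [select_common_variants()]) with no missing entries.
#' @param k number of components (default 10).
#' @return object of class `pc_set`: list with `scores` (samples x k),
#'   `varexp` (explained-variance fractions), `k`.
#' @export
pca_top_k <- function(geno, k = 10) {
  d <- geno$dosage
  if (anyNA(d)) stop("missing genotypes; PCA input must be complete")
  storage.mode(d) <- "double"
  v <- apply(d, 2, stats::var)
  d <- d[, v > 0, drop = FALSE]
  if (ncol(d) == 0) stop("no variable columns for PCA")
  if (nrow(d) < k + 1)
    stop("need at least k + 1 samples for k components")
  pr <- stats::prcomp(d, center = TRUE, scale. = TRUE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-8)
  if (k > rank) {
    warning("rank ", rank, " < requested k = ", k, "; k reduced")
    k <- rank
  }
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pr$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- geno$sample_ids
  structure(list(scores = scores,
                 varexp = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)],
                 k = k),
            class = "pc_set")
}

# Firth bias-reduced logistic regression: IRLS on the penalized score
# U*(beta) = X'(y - mu + h (1/2 - mu)), h the hat diagonals. Finite
# estimates exist under separation, where plain ML diverges.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- MASS::ginv(info)
    h <- rowSums((X %*% info_inv) * XW)
    U <- as.numeric(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- as.numeric(info_inv %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(info_inv))
  z <- beta / se
  list(coef = stats::setNames(beta, colnames(X)), se = se,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Stratification-adjusted test of a supervariant
#'
#' Logistic regression of case status on the supervariant carrier
#' indicator together with the top principal components as covariates;
#' per-coefficient Wald p-values. Perfect or quasi-perfect separation is
#' detected (diverging ML estimates) and handled by a Firth
#' penalized-likelihood refit, labelled in the result.
#'
#' @param sv a [build_supervariant()] result or 0/1 carrier vector.
#' @param phen data frame with binary `y` aligned to the samples.
#' @param pcs a [pca_top_k()] result, or `NULL`/`k = 0` for the unadjusted
#'   model.
#' @return list with `p_super` (Wald p of the carrier coefficient),
#'   `p_pcs` (named vector of PC Wald p-values), `coef`, `separation`
#'   (logical), `method` (`"ml"` or `"firth"`).
#' @export
logistic_adjusted_test <- function(sv, phen, pcs = NULL) {
  X <- if (inherits(sv, "supervariant")) sv$X else as.integer(sv)
  y <- phen$y
  stopifnot(length(X) == length(y))
  covars <- if (!is.null(pcs) && pcs$k > 0)
    pcs$scores[, seq_len(pcs$k), drop = FALSE] else NULL
  M <- cbind(SUPER = X, covars)
  df <- data.frame(.y = y, M, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                     family = stats::binomial()))
  coefs <- stats::coef(fit)
  separation <- !fit$converged || any(is.na(coefs)) ||
    any(abs(coefs) > 15, na.rm = TRUE)
  if (separation) {
    fr <- firth_logistic(M, y)
    p <- fr$p[-1]
    names(p) <- colnames(M)
    return(list(p_super = unname(p["SUPER"]), p_pcs = p[names(p) != "SUPER"],
                coef = fr$coef, separation = TRUE, method = "firth"))
  }
  sm <- summary(fit)$coefficients
  p <- sm[-1, "Pr(>|z|)"]
  names(p) <- rownames(sm)[-1]
  list(p_super = unname(p["SUPER"]), p_pcs = p[names(p) != "SUPER"],
       coef = coefs, separation = FALSE, method = "ml")
}

#' Write principal-component scores as TSV
#'
#' @param pcs a [pca_top_k()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pc_scores <- function(pcs, path) {
  df <- data.frame(sample_id = rownames(pcs$scores), pcs$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
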