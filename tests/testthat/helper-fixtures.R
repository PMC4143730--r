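# Small fixtures and independent oracles used across the suite.

# Build a geno_matrix from a plain dosage matrix.
toy_geno <- function(dosage, chrom = "chr1", pos = NULL, ref = NULL,
                     alt = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  p <- ncol(dosage)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = p)
  if (is.null(ref)) ref <- rep("A", p)
  if (is.null(alt)) alt <- rep("G", p)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(dosage)))
  genotype_matrix(dosage,
                  data.frame(chrom = rep_len(chrom, p), pos = pos,
                             id = rep_len(".", p), ref = ref, alt = alt,
                             stringsAsFactors = FALSE),
                  ids)
}

toy_geneset <- function(geno, model = NULL, idx = seq_len(n_variants(geno))) {
  if (is.null(model))
    model <- gene_model("TOY", geno$variants$chrom[1], "+",
                        min(geno$variants$pos) - 1,
                        max(geno$variants$pos) + 1,
                        exonStarts = min(geno$variants$pos) - 1,
                        exonEnds = max(geno$variants$pos) + 1)
  structure(list(gene = model, idx = idx), class = "gene_variant_set")
}

# Exhaustive permutation p-value: average the exceedance indicator over all
# distinct arrangements of the labels, weighting arrangements by their
# multiplicity (equivalently, enumerate case-index subsets).
enum_perm_p <- function(stat_fn, features, y) {
  n <- length(y)
  k <- sum(y == 1)
  obs <- stat_fn(features, y)
  sets <- utils::combn(n, k)
  hits <- apply(sets, 2, function(s) {
    yy <- rep(0L, n); yy[s] <- 1L
    stat_fn(features, yy) >= obs - 1e-9 * (1 + abs(obs))
  })
  mean(hits)
}

# --- Independent exact-2x2 oracle: hypergeometric enumeration ------------
# Table (a, b, c, d): rows cases/controls, columns carrier/non-carrier.
# Row margins n1 = a+b, n2 = c+d and carrier total k = a+c are fixed.

fisher_p_enum <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  x <- max(0, k - n2):min(k, n1)
  pr <- stats::dhyper(x, n1, n2, k)
  sum(pr[pr <= stats::dhyper(a, n1, n2, k) * (1 + 1e-7)])
}

# log unnormalized noncentral hypergeometric weights at log-odds lpsi
.nch_logw <- function(x, n1, n2, k, lpsi) {
  stats::dhyper(x, n1, n2, k, log = TRUE) + x * lpsi
}

.nch_mean <- function(n1, n2, k, lpsi) {
  x <- max(0, k - n2):min(k, n1)
  lw <- .nch_logw(x, n1, n2, k, lpsi)
  w <- exp(lw - max(lw))
  sum(x * w) / sum(w)
}

.nch_tail <- function(a, n1, n2, k, lpsi, upper) {
  x <- max(0, k - n2):min(k, n1)
  lw <- .nch_logw(x, n1, n2, k, lpsi)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  if (upper) sum(w[x >= a]) else sum(w[x <= a])
}

fisher_cmle_enum <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, n1)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  f <- function(lpsi) .nch_mean(n1, n2, k, lpsi) - a
  exp(stats::uniroot(f, c(-40, 40), tol = 1e-10)$root)
}

fisher_ci_enum <- function(a, b, c, d, conf_level = 0.95) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, n1)
  alpha <- (1 - conf_level) / 2
  lower <- if (a == lo) 0 else
    exp(stats::uniroot(function(l) .nch_tail(a, n1, n2, k, l, TRUE) - alpha,
                       c(-40, 40), tol = 1e-10)$root)
  upper <- if (a == hi) Inf else
    exp(stats::uniroot(function(l) .nch_tail(a, n1, n2, k, l, FALSE) - alpha,
                       c(-40, 40), tol = 1e-10)$root)
  c(lower, upper)
}

# Agreement check absorbing the root-finding precision of both exact-CI
# solvers (absolute 5e-3 + 0.5% relative; far inside printed precision).
close_enough <- function(x, y, abs_tol = 5e-3, rel_tol = 0.005) {
  abs(x - y) <= abs_tol + rel_tol * abs(y)
}

# Upper exact-CI bounds can be very large; the reference solver finds them
# as roots on the reciprocal-odds scale with ~1e-4 absolute precision, so
# agreement is assessed there once bounds exceed the rel/abs rule.
ci_upper_close <- function(x, y) {
  close_enough(x, y, rel_tol = 0.01) || abs(1 / x - 1 / y) <= 2e-4
}

# all 2x2 tables with row margins n1, n2 and no zero margin
all_tables <- function(n1, n2) {
  g <- expand.grid(a = 0:n1, c = 0:n2)
  g <- g[g$a + g$c > 0 & g$a + g$c < n1 + n2, ]
  data.frame(a = g$a, b = n1 - g$a, c = g$c, d = n2 - g$c)
}

# Small compact gene spec used by several statistical tests. Signal genes
# need enough singleton slots for the ~52 expected carriers at the default
# carrier odds ratio, so they get the canonical singleton-rich shape.
small_gene <- function(name, nv = 30, ns = 10, signal = FALSE) {
  if (signal) { nv <- max(nv, 150); ns <- max(ns, 135) }
  gene_spec(name, nv, ns, span_bp = 20000, n_exons = 5,
            coding_bp = 2000, utr_bp = 200, is_signal = signal)
}
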