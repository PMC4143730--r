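#' Carrier-by-status contingency table for a supervariant
#'
#' Tallies the 2x2 table of case/control by carrier/non-carrier for a
#' gene's supervariant.
#'
#' @param sv a [build_supervariant()] result (or any 0/1 vector).
#' @param phen data frame with binary `y` aligned to the samples.
#' @return an object of class `contingency_2x2`: named integer vector
#'   `(a, b, c, d)` = (case carriers, case non-carriers, control carriers,
#'   control non-carriers).
#' @export
supervariant_table <- function(sv, phen) {
  X <- if (inherits(sv, "supervariant")) sv$X else as.integer(sv)
  y <- phen$y
  stopifnot(length(X) == length(y), all(X %in% 0:1), all(y %in% 0:1))
  structure(c(a = sum(X == 1 & y == 1), b = sum(X == 0 & y == 1),
              c = sum(X == 1 & y == 0), d = sum(X == 0 & y == 0)),
            class = "contingency_2x2")
}

#' Exact inference for a 2x2 table
#'
#' Two-sided Fisher exact p (summing hypergeometric probabilities no larger
#' than that of the observed table, margins fixed), the conditional
#' maximum-likelihood odds ratio under the noncentral hypergeometric
#' distribution, and the 95% exact confidence interval obtained by
#' inverting one-sided tests at 0.025 per side. Empty cells give 0 or
#' infinite OR estimates with one-sided intervals.
#'
#' @param a,b,c,d cell counts: (case carriers, case non-carriers, control
#'   carriers, control non-carriers). Alternatively `a` may be a
#'   `contingency_2x2` or a 2x2 matrix (rows = case/control,
#'   columns = carrier/non-carrier).
#' @param conf_level confidence level of the interval.
#' @return list with `p`, `or` (conditional MLE), `ci` (length-2 vector)
#'   and `table`.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)  # p = 1, OR = 1
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             conf_level = 0.95) {
  if (inherits(a, "contingency_2x2")) {
    d <- a[["d"]]; c <- a[["c"]]; b <- a[["b"]]; a <- a[["a"]]
  } else if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  tb <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(tb < 0)) stop("negative cell count")
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("zero margin: table is degenerate")
  ft <- stats::fisher.test(tb, conf.level = conf_level)
  list(p = ft$p.value, or = unname(ft$estimate),
       ci = as.numeric(ft$conf.int), table = tb)
}

# number of significant digits in a printed value such as 3.7e-6 -> 2
printed_sigfigs <- function(x) {
  s <- gsub("[-+.]", "", sub("[eE].*$", "", format(x, scientific = TRUE)))
  s <- sub("0+$", "", s)
  max(1L, nchar(s))
}

#' Recover candidate 2x2 tables from printed summaries
#'
#' Published analyses often print only the Fisher p, odds ratio and CI of a
#' 2x2 table, not the table itself. Given the group sizes, this enumerates
#' every table `(a, c)` with `0 <= a <= n_cases`, `0 <= c <= n_controls`
#' and returns those whose two-sided Fisher p matches `p_target` at its
#' printed precision and (optionally) whose confidence interval rounds to
#' `ci_target`.
#'
#' @param n_cases,n_controls fixed group sizes (row margins).
#' @param p_target printed two-sided Fisher p; matched on
#'   `signif(p, digits)` where `digits` defaults to the number of
#'   significant digits `p_target` itself carries.
#' @param ci_target optional length-2 vector; matched after rounding both
#'   interval ends to `ci_decimals` decimals.
#' @param digits significant digits for the p match.
#' @param ci_decimals decimal places for the CI match.
#' @return data frame with one row per matching table: `a`, `b`, `c`, `d`,
#'   `p`, `or`, `ci_lo`, `ci_hi`; zero rows if nothing matches.
#' @examples
#' reconstruct_table(2, 2, p_target = 1.0)
#' @export
reconstruct_table <- function(n_cases, n_controls, p_target,
                              ci_target = NULL,
                              digits = printed_sigfigs(p_target),
                              ci_decimals = 2) {
  stopifnot(p_target > 0, p_target <= 1)
  hits <- list()
  for (a in 0:n_cases) {
    for (cc in 0:n_controls) {
      if (a + cc == 0 || a + cc == n_cases + n_controls) next
      ft <- fisher_exact_2x2(a, n_cases - a, cc, n_controls - cc)
      if (signif(ft$p, digits) != signif(p_target, digits)) next
      if (!is.null(ci_target) &&
          !isTRUE(all.equal(round(ft$ci, ci_decimals),
                            round(ci_target, ci_decimals),
                            check.attributes = FALSE))) next
      hits[[length(hits) + 1L]] <-
        data.frame(a = a, b = n_cases - a, c = cc, d = n_controls - cc,
                   p = ft$p, or = ft$or, ci_lo = ft$ci[1], ci_hi = ft$ci[2])
    }
  }
  if (length(hits) == 0)
    return(data.frame(a = integer(), b = integer(), c = integer(),
                      d = integer(), p = numeric(), or = numeric(),
                      ci_lo = numeric(), ci_hi = numeric()))
  do.call(rbind, hits)
}

#' Per-variant exact tests within a gene
#'
#' Dichotomizes each variant of a gene to carrier (dosage >= 1) versus
#' non-carrier and applies [fisher_exact_2x2()]. Used to contrast
#' single-variant signal with the collapsed supervariant.
#'
#' @param geneset a gene variant set from [assign_to_genes()].
#' @param geno a [genotype_matrix()] with no missing genotypes.
#' @param phen data frame with binary `y`.
#' @return list with `results` (data frame: `key`, `carriers`, `p`, `or`)
#'   and `min_p` (`NA` for an empty gene).
#' @export
per_variant_fisher <- function(geneset, geno, phen) {
  if (length(geneset$idx) == 0)
    return(list(results = data.frame(key = character(), carriers = integer(),
                                     p = numeric(), or = numeric()),
                min_p = NA_real_))
  rows <- lapply(geneset$idx, function(j) {
    X <- as.integer(geno$dosage[, j] >= 1)
    ft <- fisher_exact_2x2(supervariant_table(X, phen))
    data.frame(key = geno$variants$key[j], carriers = sum(X),
               p = ft$p, or = ft$or, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  list(results = res, min_p = min(res$p))
}
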