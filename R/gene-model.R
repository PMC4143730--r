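#' Transcript gene model
#'
#' One transcript per gene, refFlat-style. All coordinates are 1-based and
#' inclusive for membership tests; the gene *length* is reported as
#' `txEnd - txStart`, the convention used for transcript span arithmetic in
#' genome annotation tables.
#'
#' @param name gene symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"` (read for reporting only).
#' @param txStart,txEnd transcript bounds, 1-based inclusive.
#' @param cdsStart,cdsEnd coding-sequence bounds within the transcript;
#'   `NA` for non-coding transcripts.
#' @param exonStarts,exonEnds integer vectors of exon bounds, sorted,
#'   disjoint, within `[txStart, txEnd]`.
#' @return an object of class `gene_model`.
#' @examples
#' gm <- gene_model("G1", "chr9", "+", 100, 1000, 200, 900,
#'                  c(100, 400, 800), c(250, 500, 1000))
#' gene_length(gm)
#' @export
gene_model <- function(name, chrom, strand = "+", txStart, txEnd,
                       cdsStart = NA, cdsEnd = NA,
                       exonStarts, exonEnds) {
  exonStarts <- as.numeric(exonStarts)
  exonEnds <- as.numeric(exonEnds)
  stopifnot(length(exonStarts) == length(exonEnds),
            all(exonStarts <= exonEnds),
            txStart <= txEnd)
  o <- order(exonStarts)
  exonStarts <- exonStarts[o]; exonEnds <- exonEnds[o]
  if (length(exonStarts) > 1 &&
      any(exonStarts[-1] <= exonEnds[-length(exonEnds)]))
    stop("exons must be disjoint")
  if (any(exonStarts < txStart) || any(exonEnds > txEnd))
    stop("exons must lie within the transcript bounds")
  if (!is.na(cdsStart) && !is.na(cdsEnd)) {
    if (cdsStart > cdsEnd) stop("cdsStart must be <= cdsEnd")
    if (cdsStart < txStart || cdsEnd > txEnd)
      stop("CDS must lie within the transcript bounds")
  }
  structure(list(name = name, chrom = chrom, strand = strand,
                 txStart = as.numeric(txStart), txEnd = as.numeric(txEnd),
                 cdsStart = as.numeric(cdsStart), cdsEnd = as.numeric(cdsEnd),
                 exonStarts = exonStarts, exonEnds = exonEnds),
            class = "gene_model")
}

#' @rdname gene_model
#' @param model a `gene_model`.
#' @export
gene_length <- function(model) model$txEnd - model$txStart

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%s-%s (%s) %d exons\n", x$name, x$chrom,
              format(x$txStart, big.mark = ","),
              format(x$txEnd, big.mark = ","),
              x$strand, length(x$exonStarts)))
  invisible(x)
}

#' Write gene models as a refFlat-style table
#'
#' Ten tab-separated columns (geneName, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds), exon bounds as
#' comma-joined lists. A header comment declares the 1-based inclusive
#' coordinate convention.
#'
#' @param models list of `gene_model` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# refFlat-like gene models; coordinates 1-based, inclusive",
               paste("#geneName", "chrom", "strand", "txStart", "txEnd",
                     "cdsStart", "cdsEnd", "exonCount", "exonStarts",
                     "exonEnds", sep = "\t")), con)
  for (m in models) {
    writeLines(paste(m$name, m$chrom, m$strand,
                     format(m$txStart, scientific = FALSE),
                     format(m$txEnd, scientific = FALSE),
                     ifelse(is.na(m$cdsStart), ".",
                            format(m$cdsStart, scientific = FALSE)),
                     ifelse(is.na(m$cdsEnd), ".",
                            format(m$cdsEnd, scientific = FALSE)),
                     length(m$exonStarts),
                     paste(format(m$exonStarts, scientific = FALSE,
                                  trim = TRUE), collapse = ","),
                     paste(format(m$exonEnds, scientific = FALSE,
                                  trim = TRUE), collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read refFlat-style gene models
#'
#' @param path file written by [write_gene_models()] or any tab-separated
#'   table with the same ten columns; lines starting with `#` are ignored.
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(tab) != 10)
    stop("expected 10 refFlat columns, got ", ncol(tab))
  models <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    num <- function(x) if (x == ".") NA else as.numeric(x)
    gene_model(name = r[[1]], chrom = r[[2]], strand = r[[3]],
               txStart = as.numeric(r[[4]]), txEnd = as.numeric(r[[5]]),
               cdsStart = num(r[[6]]), cdsEnd = num(r[[7]]),
               exonStarts = as.numeric(strsplit(r[[9]], ",")[[1]]),
               exonEnds = as.numeric(strsplit(r[[10]], ",")[[1]]))
  })
  names(models) <- vapply(models, `[[`, "", "name")
  models
}
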