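# SNP annotation: map SNPs to nearby genes, pool gene-level keyword flags to
# SNP level, and collapse the 8 flag combinations into prior categories.

.gene_table <- function(genes) {
  if (is.data.frame(genes)) {
    need <- c("gene_id", "chrom", "start", "end")
    miss <- setdiff(need, names(genes))
    if (length(miss) > 0L) {
      stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
    }
    return(genes)
  }
  data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    start = vapply(genes, `[[`, numeric(1), "start"),
    end = vapply(genes, `[[`, numeric(1), "end"),
    stringsAsFactors = FALSE)
}

#' Map a SNP to genes within a base-pair window
#'
#' A gene is returned when the minimum distance from the SNP position to the
#' closed interval `[start, end]` is at most `window` base pairs (distance 0
#' inside the interval; boundary inclusive, so a SNP exactly `window` bp from
#' a gene end is mapped).
#'
#' @param chrom chromosome label of the SNP.
#' @param pos 1-based SNP position.
#' @param genes list of [gene_document()] objects or a data frame with
#'   columns `gene_id`, `chrom`, `start`, `end`.
#' @param window mapping window in base pairs (default 50000).
#' @return character vector of gene ids (possibly empty).
#' @export
map_snp_to_genes <- function(chrom, pos, genes, window = 50000) {
  stopifnot(length(chrom) == 1L, length(pos) == 1L, window >= 0, pos >= 1)
  gt <- .gene_table(genes)
  same <- gt$chrom == as.character(chrom)
  if (!any(same)) return(character(0))
  gt <- gt[same, , drop = FALSE]
  dist <- pmax(0, gt$start - pos, pos - gt$end)
  gt$gene_id[dist <= window]
}

#' Pool gene-level flags to SNP level
#'
#' Evidence from all mapped genes is pooled by element-wise OR, which equals
#' classifying the concatenation of all mapped genes' documents.
#'
#' @param flags logical matrix or data frame with columns `g1`, `g2`, `g3`,
#'   one row per mapped gene (zero rows allowed).
#' @return named logical vector `c(g1 =, g2 =, g3 =)`.
#' @export
snp_flags <- function(flags) {
  if (is.null(flags) || nrow(flags) == 0L) {
    return(c(g1 = FALSE, g2 = FALSE, g3 = FALSE))
  }
  c(g1 = any(flags[, "g1"]), g2 = any(flags[, "g2"]), g3 = any(flags[, "g3"]))
}

#' Collapse keyword flags into a prior category
#'
#' `C1` when no keyword group matched, `C3` when all three matched, `C2`
#' otherwise (at least one but not all). Vectorized.
#'
#' @param g1,g2,g3 logical vectors of equal length.
#' @return character vector of `"C1"`, `"C2"`, `"C3"`.
#' @examples
#' assign_category(c(FALSE, TRUE, TRUE), c(FALSE, FALSE, TRUE),
#'                 c(FALSE, TRUE, TRUE))
#' @export
assign_category <- function(g1, g2, g3) {
  stopifnot(is.logical(g1), is.logical(g2), is.logical(g3),
            length(g1) == length(g2), length(g2) == length(g3))
  n_hit <- g1 + g2 + g3
  ifelse(n_hit == 0L, "C1", ifelse(n_hit == 3L, "C3", "C2"))
}

#' Annotate SNPs with pooled keyword flags and prior categories
#'
#' Runs the full annotation chain: classify each gene's literature (unless
#' pre-computed `gene_flags` are supplied), map each SNP to genes within
#' `window` bp, pool flags by OR across mapped genes, and collapse to
#' categories C1/C2/C3.
#'
#' @param snps data frame with columns `rsid`, `chrom`, `pos`.
#' @param genes list of [gene_document()] objects (or a gene table when
#'   `gene_flags` is supplied).
#' @param config a [keyword_config()]; ignored when `gene_flags` is given.
#' @param gene_flags optional pre-computed output of [classify_corpus()].
#' @param window mapping window in base pairs.
#' @return data frame with `rsid`, `chrom`, `pos`, `mapped_genes`
#'   (comma-joined ids), logical `g1`, `g2`, `g3`, and `category`.
#' @export
annotate_snps <- function(snps, genes, config = NULL, gene_flags = NULL,
                          window = 50000) {
  need <- c("rsid", "chrom", "pos")
  miss <- setdiff(need, names(snps))
  if (length(miss) > 0L) {
    stop("SNP table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(snps$rsid)) {
    stop("duplicated rsid(s) in SNP table: ",
         paste(unique(snps$rsid[duplicated(snps$rsid)]), collapse = ", "))
  }
  if (is.null(gene_flags)) {
    if (is.null(config)) stop("either config or gene_flags must be supplied")
    gene_flags <- classify_corpus(genes, config)
  }
  gt <- .gene_table(gene_flags)
  n <- nrow(snps)
  g1 <- g2 <- g3 <- logical(n)
  mapped <- character(n)
  for (i in seq_len(n)) {
    ids <- map_snp_to_genes(snps$chrom[i], snps$pos[i], gt, window = window)
    mapped[i] <- paste(ids, collapse = ",")
    if (length(ids) > 0L) {
      fl <- snp_flags(gene_flags[match(ids, gene_flags$gene_id), ,
                                 drop = FALSE])
      g1[i] <- fl[["g1"]]; g2[i] <- fl[["g2"]]; g3[i] <- fl[["g3"]]
    }
  }
  data.frame(rsid = snps$rsid, chrom = snps$chrom, pos = snps$pos,
             mapped_genes = mapped, g1 = g1, g2 = g2, g3 = g3,
             category = assign_category(g1, g2, g3),
             stringsAsFactors = FALSE)
}

#' Count SNPs per prior category
#'
#' @param annot annotation table from [annotate_snps()], or a character
#'   vector of categories.
#' @return named integer vector with entries `C1`, `C2`, `C3` (zero-filled).
#' @export
category_counts <- function(annot) {
  cat <- if (is.data.frame(annot)) annot$category else annot
  out <- table(factor(cat, levels = c("C1", "C2", "C3")))
  stats::setNames(as.integer(out), names(out))
}

#' Read SNP loci from TSV or BED
#'
#' TSV requires a header with columns `rsid`, `chrom`, `pos` (1-based). BED
#' input (`chrom`, `start`, `end`, `name`; 0-based half-open, no header) is
#' converted to 1-based positions (`pos = start + 1`); the conversion is
#' reported via a message.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return data frame with `rsid`, `chrom`, `pos`.
#' @export
read_snp_loci <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("rsid", "chrom", "pos"), names(x))
    if (length(miss) > 0L) {
      stop("SNP TSV is missing column(s): ", paste(miss, collapse = ", "))
    }
    return(x[, c("rsid", "chrom", "pos")])
  }
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 4L) stop("BED input needs at least 4 columns")
  message("BED input: converting 0-based half-open starts to 1-based positions")
  data.frame(rsid = x[[4L]], chrom = as.character(x[[1L]]),
             pos = x[[2L]] + 1, stringsAsFactors = FALSE)
}
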