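# Keyword corpus: normalize per-gene abstract text and classify each gene's
# literature into binary keyword-group flags (tiers G1/G2/G3).

#' Construct a keyword configuration
#'
#' The three tiers carry keywords of decreasing disease specificity: `g1`
#' holds phrases specific to the phenotype (e.g. "oral cancer"), `g2` phrases
#' that are relevant but not exclusive (e.g. "smoking"), and `g3` generic
#' disease-process terms (e.g. "carcinogen", "DNA damage"). Multi-word
#' phrases match as contiguous stem sequences. An optional `date_cutoff`
#' restricts classification to documents published strictly before that date
#' (used to avoid feedback from post-GWAS literature).
#'
#' @param g1,g2,g3 character vectors of keyword phrases.
#' @param date_cutoff optional `Date` (or ISO-8601 string); documents dated on
#'   or after this date are ignored during classification.
#' @return an object of class `keyword_config`.
#' @examples
#' keyword_config(g1 = "oral cancer", g2 = c("smoking", "alcohol"),
#'                g3 = c("carcinogen", "apoptosis"))
#' @export
keyword_config <- function(g1, g2, g3, date_cutoff = NULL) {
  groups <- list(g1 = g1, g2 = g2, g3 = g3)
  for (nm in names(groups)) {
    ph <- groups[[nm]]
    if (!is.character(ph) || length(ph) == 0L) {
      stop("keyword group '", nm, "' must be a non-empty character vector")
    }
    stems <- lapply(ph, normalize_text)
    if (any(lengths(stems) == 0L)) {
      stop("keyword group '", nm, "' contains a phrase that is empty after ",
           "normalization")
    }
    groups[[nm]] <- ph
    attr(groups[[nm]], "stems") <- stems
  }
  if (!is.null(date_cutoff)) {
    date_cutoff <- as.Date(date_cutoff)
    if (is.na(date_cutoff)) stop("date_cutoff is not a valid date")
  }
  structure(list(g1 = groups$g1, g2 = groups$g2, g3 = groups$g3,
                 date_cutoff = date_cutoff),
            class = "keyword_config")
}

#' @export
print.keyword_config <- function(x, ...) {
  cat("Keyword configuration\n")
  for (nm in c("g1", "g2", "g3")) {
    cat(sprintf("  %s (%d): %s\n", toupper(nm), length(x[[nm]]),
                paste(x[[nm]], collapse = "; ")))
  }
  cat("  date cutoff:",
      if (is.null(x$date_cutoff)) "none" else format(x$date_cutoff), "\n")
  invisible(x)
}

#' Construct a per-gene document record
#'
#' One gene together with its genomic interval and linked abstracts; the unit
#' of literature evidence consumed by [classify_gene()].
#'
#' @param gene_id opaque gene identifier.
#' @param symbol gene symbol (display only).
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive interval on `chrom`.
#' @param documents list of documents, each a list with elements `doc_id`,
#'   `text` and optional `date` (ISO-8601 string or `Date`).
#' @return an object of class `gene_document`.
#' @export
gene_document <- function(gene_id, symbol = gene_id, chrom, start, end,
                          documents = list()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end || start < 1) {
    stop("gene '", gene_id, "': invalid interval [", start, ", ", end, "]")
  }
  documents <- lapply(documents, function(d) {
    if (is.null(d$doc_id)) stop("document without doc_id in gene ", gene_id)
    d$text <- if (is.null(d$text)) "" else as.character(d$text)
    d$date <- if (is.null(d$date) || is.na(d$date)[1L]) {
      as.Date(NA)
    } else {
      dd <- as.Date(d$date)
      if (is.na(dd)) stop("document ", d$doc_id, ": invalid date '",
                          d$date, "'")
      dd
    }
    d[c("doc_id", "text", "date")]
  })
  structure(list(gene_id = as.character(gene_id),
                 symbol = as.character(symbol),
                 chrom = as.character(chrom), start = start, end = end,
                 documents = documents),
            class = "gene_document")
}

#' Normalize free text to ordered token stems
#'
#' Lowercases, splits on any non-alphanumeric characters and Porter-stems the
#' resulting word tokens. Punctuation-only tokens vanish; token order is
#' preserved. Deterministic for fixed input.
#'
#' @param text a single character string (may be empty).
#' @return character vector of token stems (possibly empty).
#' @examples
#' normalize_text("Lung CANCERS were studied.")
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  porter_stem(toks)
}

#' Test whether a keyword phrase occurs in a stemmed document
#'
#' A phrase matches when its stem sequence occurs contiguously (in order)
#' anywhere in the document's stem sequence, so "lung cancer" matches "lung
#' cancers were studied" but not "cancer of the lung".
#'
#' @param doc_stems character vector of document token stems, as produced by
#'   [normalize_text()].
#' @param phrase keyword phrase (raw text; normalized internally) or an
#'   already-stemmed character vector when `stemmed = TRUE`.
#' @param stemmed set to `TRUE` when `phrase` is already a stem vector.
#' @return `TRUE` or `FALSE`.
#' @export
match_phrase <- function(doc_stems, phrase, stemmed = FALSE) {
  ph <- if (stemmed) phrase else normalize_text(phrase)
  if (length(ph) == 0L) {
    stop("invalid keyword: phrase is empty after normalization")
  }
  n <- length(doc_stems)
  k <- length(ph)
  if (n < k) return(FALSE)
  hit <- doc_stems[seq_len(n - k + 1L)] == ph[1L]
  if (k > 1L) {
    for (j in 2L:k) {
      hit <- hit & doc_stems[seq.int(j, n - k + j)] == ph[j]
      if (!any(hit)) return(FALSE)
    }
  }
  any(hit)
}

.retained_documents <- function(gene, cutoff) {
  docs <- gene$documents
  if (is.null(cutoff) || length(docs) == 0L) return(docs)
  dates <- as.Date(vapply(docs, function(d) {
    if (is.null(d$date)) NA_character_ else as.character(d$date)
  }, character(1)))
  undated <- is.na(dates)
  if (any(undated)) {
    warning("gene ", gene$gene_id, ": ", sum(undated),
            " undated document(s) retained despite date cutoff",
            call. = FALSE)
  }
  docs[undated | dates < cutoff]
}

#' Classify a gene's literature into keyword-group flags
#'
#' Each flag is `TRUE` when any phrase of the corresponding keyword tier
#' matches any retained document of the gene. Matching is presence-based: the
#' number of matching documents or occurrences is ignored. When the
#' configuration carries a `date_cutoff`, only documents dated strictly
#' before the cutoff are considered; undated documents are retained with a
#' warning.
#'
#' @param gene a [gene_document()].
#' @param config a [keyword_config()].
#' @return named logical vector `c(g1 =, g2 =, g3 =)`.
#' @export
classify_gene <- function(gene, config) {
  stopifnot(inherits(gene, "gene_document"), inherits(config, "keyword_config"))
  flags <- c(g1 = FALSE, g2 = FALSE, g3 = FALSE)
  docs <- .retained_documents(gene, config$date_cutoff)
  if (length(docs) == 0L) return(flags)
  group_stems <- lapply(c("g1", "g2", "g3"),
                        function(nm) attr(config[[nm]], "stems"))
  names(group_stems) <- c("g1", "g2", "g3")
  for (d in docs) {
    ds <- normalize_text(d$text)
    if (length(ds) == 0L) next
    for (nm in names(flags)) {
      if (flags[[nm]]) next
      for (ph in group_stems[[nm]]) {
        if (match_phrase(ds, ph, stemmed = TRUE)) {
          flags[[nm]] <- TRUE
          break
        }
      }
    }
    if (all(flags)) break
  }
  flags
}

#' Classify every gene of a corpus
#'
#' @param genes list of [gene_document()] objects.
#' @param config a [keyword_config()].
#' @return data frame with one row per gene: `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, and logical flags `g1`, `g2`, `g3`.
#' @export
classify_corpus <- function(genes, config) {
  stopifnot(is.list(genes))
  rows <- lapply(genes, function(g) {
    fl <- classify_gene(g, config)
    data.frame(gene_id = g$gene_id, symbol = g$symbol, chrom = g$chrom,
               start = g$start, end = g$end,
               g1 = fl[["g1"]], g2 = fl[["g2"]], g3 = fl[["g3"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), symbol = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), g1 = logical(0), g2 = logical(0),
                      g3 = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Read a gene corpus from JSON Lines
#'
#' One gene per line:
#' `{"gene_id","symbol","chrom","start","end","documents":[{"doc_id","text","date"}]}`
#' with ISO-8601 dates (`null` allowed).
#'
#' @param path file path.
#' @return list of [gene_document()] objects.
#' @export
read_gene_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop("malformed corpus record at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    for (f in c("gene_id", "chrom", "start", "end")) {
      if (is.null(rec[[f]])) {
        stop("corpus line ", i, ": missing field '", f, "'", call. = FALSE)
      }
    }
    gene_document(rec$gene_id,
                  symbol = if (is.null(rec$symbol)) rec$gene_id else rec$symbol,
                  chrom = rec$chrom, start = rec$start, end = rec$end,
                  documents = if (is.null(rec$documents)) list()
                              else rec$documents)
  })
}

#' Write a gene corpus as JSON Lines
#'
#' @param genes list of [gene_document()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_corpus <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    docs <- lapply(g$documents, function(d) {
      list(doc_id = d$doc_id, text = d$text,
           date = if (is.na(d$date)) NULL else format(d$date))
    })
    jsonlite::toJSON(list(gene_id = g$gene_id, symbol = g$symbol,
                          chrom = g$chrom, start = g$start, end = g$end,
                          documents = docs),
                     auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a keyword configuration from JSON
#'
#' Format: `{"g1": [...], "g2": [...], "g3": [...], "date_cutoff":
#' "YYYY-MM-DD"|null}`.
#'
#' @param path file path.
#' @return a [keyword_config()].
#' @export
read_keyword_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  keyword_config(g1 = x$g1, g2 = x$g2, g3 = x$g3,
                 date_cutoff = x$date_cutoff)
}

#' Write a keyword configuration to JSON
#'
#' @param config a [keyword_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_keyword_config <- function(config, path) {
  stopifnot(inherits(config, "keyword_config"))
  x <- list(g1 = as.vector(config$g1), g2 = as.vector(config$g2),
            g3 = as.vector(config$g3),
            date_cutoff = if (is.null(config$date_cutoff)) NULL
                          else format(config$date_cutoff))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                              pretty = TRUE), path)
  invisible(path)
}
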