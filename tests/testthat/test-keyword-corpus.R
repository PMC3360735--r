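test_that("normalize_text lowercases, strips punctuation and stems", {
  expect_identical(normalize_text(""), character(0))
  expect_identical(normalize_text("... !! --"), character(0))
  expect_identical(normalize_text("Lung CANCER."), normalize_text("lung cancer"))
  # frozen hand-derived stems
  expect_identical(normalize_text("smoking and nicotine dependence"),
                   c("smoke", "and", "nicotin", "depend"))
})

test_that("match_phrase requires the stem sequence to be contiguous", {
  doc <- normalize_text("lung cancers were studied")
  expect_true(match_phrase(doc, "lung cancer"))
  expect_false(match_phrase(normalize_text("cancer of the lung"),
                            "lung cancer"))
  expect_error(match_phrase(doc, "..."), "empty after normalization")
})

test_that("match_phrase agrees with a brute-force sliding-window scan", {
  set.seed(11)
  vocab <- c("aa", "bb", "cc", "dd")
  for (rep in 1:25) {
    doc <- sample(vocab, 1000, replace = TRUE)
    phrase <- sample(vocab, 2, replace = TRUE)
    expect_identical(match_phrase(doc, phrase, stemmed = TRUE),
                     brute_phrase_scan(doc, phrase))
  }
  # phrase longer than document
  expect_false(match_phrase(c("aa"), c("aa", "bb"), stemmed = TRUE))
})

test_that("classify_gene sets flags by presence across tiers", {
  cfg <- test_config()
  empty <- make_gene("g0", "chr1", 100, 200)
  expect_identical(classify_gene(empty, cfg),
                   c(g1 = FALSE, g2 = FALSE, g3 = FALSE))
  g13 <- make_gene("g1", "chr1", 100, 200,
                   "Lung cancer cells showed apoptosis after treatment.")
  expect_identical(classify_gene(g13, cfg),
                   c(g1 = TRUE, g2 = FALSE, g3 = TRUE))
  # frequency ignored: repeating a phrase changes nothing
  g13rep <- make_gene("g1", "chr1", 100, 200,
                      paste(rep("lung cancer apoptosis", 5), collapse = " "))
  expect_identical(classify_gene(g13rep, cfg), classify_gene(g13, cfg))
})

test_that("date cutoff excludes later documents and keeps undated ones", {
  cfg <- test_config(cutoff = "2008-01-01")
  late <- make_gene("g", "chr1", 1, 10, "lung cancer", dates = "2010-06-01")
  expect_identical(classify_gene(late, cfg),
                   c(g1 = FALSE, g2 = FALSE, g3 = FALSE))
  early <- make_gene("g", "chr1", 1, 10, "lung cancer", dates = "2005-06-01")
  expect_identical(classify_gene(early, cfg)[["g1"]], TRUE)
  undated <- make_gene("g", "chr1", 1, 10, "lung cancer")
  expect_warning(fl <- classify_gene(undated, cfg), "undated")
  expect_true(fl[["g1"]])
})

test_that("evidence is monotone and order/duplication invariant", {
  cfg <- test_config()
  set.seed(21)
  texts <- c("smoking increases risk", "dna damage response",
             "a study of lung carcinoma", "no relevant words here",
             "nicotine dependence was measured")
  for (rep in 1:20) {
    sub <- sample(texts, sample(1:4, 1))
    g <- make_gene("g", "chr1", 1, 10, sub)
    base <- classify_gene(g, cfg)
    # adding a document never turns a flag off
    extra <- make_gene("g", "chr1", 1, 10, c(sub, sample(texts, 1)))
    expect_true(all(classify_gene(extra, cfg) >= base))
    # permutation and duplication leave flags unchanged
    perm <- make_gene("g", "chr1", 1, 10, sample(rep(sub, 2)))
    expect_identical(classify_gene(perm, cfg), base)
    # concatenated corpus equals OR of per-document flags
    concat <- make_gene("g", "chr1", 1, 10, paste(sub, collapse = " xx "))
    per_doc <- vapply(sub, function(tx) {
      classify_gene(make_gene("g", "chr1", 1, 10, tx), cfg)
    }, logical(3))
    expect_identical(classify_gene(concat, cfg),
                     c(g1 = any(per_doc[1, ]), g2 = any(per_doc[2, ]),
                       g3 = any(per_doc[3, ])))
  }
})

test_that("corpus and keyword config round-trip through their file formats", {
  cfg <- test_config(cutoff = "2008-01-01")
  genes <- list(
    make_gene("gA", "chr2", 1000, 5000,
              c("lung cancer study", "smoking cohort"),
              dates = c("2001-05-02", NA)),
    make_gene("gB", "chr3", 10, 20))
  fc <- tempfile(fileext = ".jsonl")
  write_gene_corpus(genes, fc)
  back <- read_gene_corpus(fc)
  # the undated document triggers the documented retention warning
  expect_identical(suppressWarnings(classify_corpus(back, cfg)),
                   suppressWarnings(classify_corpus(genes, cfg)))
  expect_identical(back[[1]]$documents[[1]]$date, as.Date("2001-05-02"))
  fk <- tempfile(fileext = ".json")
  write_keyword_config(cfg, fk)
  cfg2 <- read_keyword_config(fk)
  expect_identical(as.vector(cfg2$g1), as.vector(cfg$g1))
  expect_identical(cfg2$date_cutoff, cfg$date_cutoff)
  # malformed line reports its line number
  writeLines(c("{\"gene_id\":\"x\",\"chrom\":\"1\",\"start\":1,\"end\":2}",
               "{not json"), fc)
  expect_error(read_gene_corpus(fc), "line 2")
})

test_that("keyword_config rejects empty groups and invalid phrases", {
  expect_error(keyword_config(character(0), "b", "c"), "non-empty")
  expect_error(keyword_config("a", "!!", "c"), "empty after")
})
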