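# Independent oracles used across tests. These deliberately re-derive results
# by the most transparent route available (expansion, brute force, bisection)
# and never call the implementation paths they check.

# Newton-Raphson logistic regression on an explicit per-subject design matrix
nr_logistic_oracle <- function(X, y, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- crossprod(X, X * W)
    step <- solve(H, crossprod(X, y - p))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  list(coef = beta, vcov = solve(crossprod(X, X * p * (1 - p))))
}

# expand a genotype-count row set into per-subject (dose, stratum, y)
expand_counts <- function(tab) {
  rows <- list()
  strat <- if (is.null(tab$stratum)) rep("all", nrow(tab)) else tab$stratum
  for (i in seq_len(nrow(tab))) {
    for (g in 0:2) {
      nc <- tab[[paste0("case", g)]][i]
      nt <- tab[[paste0("ctrl", g)]][i]
      if (nc > 0) rows[[length(rows) + 1L]] <-
          data.frame(dose = g, stratum = strat[i], y = rep(1L, nc))
      if (nt > 0) rows[[length(rows) + 1L]] <-
          data.frame(dose = g, stratum = strat[i], y = rep(0L, nt))
    }
  }
  do.call(rbind, rows)
}

# oracle per-allele trend fit via the expanded design
trend_oracle <- function(tab) {
  d <- expand_counts(tab)
  X <- cbind(1, d$dose)
  if (length(unique(d$stratum)) > 1L) {
    X <- cbind(X, stats::model.matrix(~ factor(stratum), d)[, -1, drop = FALSE])
  }
  fit <- nr_logistic_oracle(X, d$y)
  list(theta = fit$coef[2L], se = sqrt(fit$vcov[2L, 2L]))
}

# brute-force sliding-window phrase scan
brute_phrase_scan <- function(doc, phrase) {
  k <- length(phrase)
  n <- length(doc)
  if (n < k) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    if (all(doc[i:(i + k - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

# brute-force SNP-to-gene distance scan
brute_map <- function(chrom, pos, gene_df, window) {
  hits <- character(0)
  for (i in seq_len(nrow(gene_df))) {
    if (gene_df$chrom[i] != chrom) next
    d <- if (pos < gene_df$start[i]) {
      gene_df$start[i] - pos
    } else if (pos > gene_df$end[i]) {
      pos - gene_df$end[i]
    } else 0
    if (d <= window) hits <- c(hits, gene_df$gene_id[i])
  }
  hits
}

# random non-degenerate genotype count table
random_count_table <- function(rsid = "s1", n_case = 200, n_ctrl = 300) {
  repeat {
    pc <- as.vector(stats::rmultinom(1, n_case, c(0.5, 0.35, 0.15)))
    pt <- as.vector(stats::rmultinom(1, n_ctrl, c(0.5, 0.35, 0.15)))
    if (sum(pc[2:3] + pt[2:3]) > 0 && all(pc + pt > 0)) break
  }
  data.frame(rsid = rsid, case0 = pc[1], case1 = pc[2], case2 = pc[3],
             ctrl0 = pt[1], ctrl1 = pt[2], ctrl2 = pt[3],
             stringsAsFactors = FALSE)
}

make_gene <- function(id, chrom, start, end, texts = character(0),
                      dates = NULL) {
  docs <- lapply(seq_along(texts), function(i) {
    list(doc_id = paste0(id, "_d", i), text = texts[i],
         date = if (is.null(dates)) NULL else dates[i])
  })
  gene_document(id, chrom = chrom, start = start, end = end,
                documents = docs)
}

test_config <- function(cutoff = NULL) {
  keyword_config(g1 = c("lung cancer", "lung carcinoma"),
                 g2 = c("smoking", "nicotine dependence"),
                 g3 = c("carcinogen", "dna damage", "apoptosis"),
                 date_cutoff = cutoff)
}
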