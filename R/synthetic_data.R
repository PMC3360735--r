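# Synthetic data: corpora with planted keyword evidence, case-control
# genotype counts with known effects, and the subsampling rank-comparison
# experiment.

.default_keywords <- function() {
  keyword_config(
    g1 = c("oral cancer", "oral carcinoma", "mouth neoplasm"),
    g2 = c("smoking", "alcohol consumption", "tobacco"),
    g3 = c("carcinogen", "dna damage", "apoptosis", "neoplastic"))
}

# filler vocabulary sharing no stems with the default keywords and unable to
# form any default keyword phrase
.filler_words <- c(
  "patients", "cohort", "enzyme", "kinase", "pathway", "expression",
  "binding", "promoter", "sequence", "genotype", "variant", "regulatory",
  "measured", "observed", "levels", "protein", "cells", "receptor",
  "signaling", "transcription", "polymorphism", "allele", "samples",
  "analysis", "results", "were", "with", "the", "report", "study")

.sentence <- function(n_words) {
  paste(sample(.filler_words, n_words, replace = TRUE), collapse = " ")
}

#' Generate a synthetic gene corpus with planted prior categories
#'
#' Lays one gene per SNP on synthetic chromosomes (spaced far beyond the
#' mapping window so each SNP maps to exactly its own gene), seeds each
#' gene's documents with keyword phrases from the tiers its planted category
#' requires, and places the SNP within `window` bp of the gene. Running the
#' classification pipeline ([annotate_snps()]) on the output recovers the
#' planted category of every SNP.
#'
#' @param n_snps number of SNPs (= genes).
#' @param fractions length-3 vector of category probabilities (C1, C2, C3);
#'   defaults to the 87.5/10/2.5 split typical of a genome-wide panel.
#' @param window mapping window in base pairs.
#' @param docs_per_gene integer range to draw the per-gene document count
#'   from.
#' @param seed optional RNG seed; fixed seeds give byte-identical output.
#' @return list with `genes` (list of [gene_document()]), `keywords`
#'   ([keyword_config()]), `snps` (data frame `rsid`, `chrom`, `pos`) and
#'   `truth` (data frame `rsid`, `gene_id`, `g1`, `g2`, `g3`, `category`).
#' @export
generate_corpus <- function(n_snps = 100, fractions = c(0.875, 0.10, 0.025),
                            window = 50000, docs_per_gene = 1:3,
                            seed = NULL) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, n_snps >= 1)
  if (!is.null(seed)) set.seed(seed)
  config <- .default_keywords()
  categories <- sample(c("C1", "C2", "C3"), n_snps, replace = TRUE,
                       prob = fractions)
  # proper non-empty subsets of {g1, g2, g3} for C2
  mixed <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  gene_len <- 20000
  spacing <- 1e6  # >> gene length + 2 * window: no cross-gene mapping
  n_chrom <- 22L
  chrom_idx <- ((seq_len(n_snps) - 1L) %% n_chrom) + 1L
  within_idx <- ((seq_len(n_snps) - 1L) %/% n_chrom) + 1L
  genes <- vector("list", n_snps)
  snps <- data.frame(rsid = sprintf("rs%06d", seq_len(n_snps)),
                     chrom = paste0("chr", chrom_idx),
                     pos = NA_real_, stringsAsFactors = FALSE)
  flags <- matrix(FALSE, n_snps, 3L, dimnames = list(NULL, c("g1", "g2", "g3")))
  for (i in seq_len(n_snps)) {
    start <- (within_idx[i] - 1L) * spacing + 100000
    end <- start + gene_len - 1L
    planted <- switch(categories[i],
                      C1 = c(FALSE, FALSE, FALSE),
                      C2 = mixed[[sample.int(6L, 1L)]],
                      C3 = c(TRUE, TRUE, TRUE))
    flags[i, ] <- planted
    n_docs <- sample(docs_per_gene, 1L)
    docs <- lapply(seq_len(n_docs), function(k) {
      list(doc_id = sprintf("PM%06d%02d", i, k), text = .sentence(8L),
           date = format(as.Date("1995-01-01") +
                           sample.int(4500L, 1L)))
    })
    # distribute the planted groups' phrases over the gene's documents
    for (g in which(planted)) {
      k <- sample.int(n_docs, 1L)
      phrase <- sample(config[[c("g1", "g2", "g3")[g]]], 1L)
      docs[[k]]$text <- paste(docs[[k]]$text, phrase, .sentence(3L))
    }
    genes[[i]] <- gene_document(sprintf("GENE%05d", i),
                                symbol = sprintf("SYN%05d", i),
                                chrom = snps$chrom[i], start = start,
                                end = end, documents = docs)
    snps$pos[i] <- sample(seq(max(1, start - window), end + window), 1L)
  }
  truth <- data.frame(rsid = snps$rsid,
                      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
                      g1 = flags[, "g1"], g2 = flags[, "g2"],
                      g3 = flags[, "g3"],
                      category = categories, stringsAsFactors = FALSE)
  list(genes = genes, keywords = config, snps = snps, truth = truth)
}

.draw_genotype_counts <- function(n, p0, p1, p2) {
  # multinomial via sequential binomials, vectorized over SNPs
  x2 <- stats::rbinom(length(p0), n, p2)
  x1 <- stats::rbinom(length(p0), n - x2, ifelse(p0 + p1 > 0,
                                                 p1 / (p0 + p1), 0))
  cbind(x0 = n - x2 - x1, x1 = x1, x2 = x2)
}

#' Simulate case-control genotype counts with known truth
#'
#' Control genotypes are drawn at Hardy-Weinberg proportions for each SNP's
#' minor allele frequency; case genotype probabilities are the control
#' probabilities tilted by the per-allele odds model (probability
#' proportional to HWE frequency times OR^g), matching the log-additive
#' trend model fitted downstream. Null SNPs have OR = 1.
#'
#' @param n_snps number of independent SNPs.
#' @param fractions length-3 vector of prior-category probabilities.
#' @param n_true total number of truly associated SNPs to plant.
#' @param true_alloc length-3 integer allocation of `n_true` across
#'   categories (C1, C2, C3); must sum to `n_true`.
#' @param or_true true per-allele odds ratio(s): a scalar, a vector of length
#'   `n_true`, or a function of `n` returning `n` log ORs (e.g. draws from
#'   the analysis prior).
#' @param maf minor allele frequencies: scalar, vector of length `n_snps`,
#'   or `NULL` for Uniform(0.1, 0.4) draws.
#' @param n_cases,n_controls sample sizes.
#' @param seed optional RNG seed.
#' @return list with `counts` (data frame `rsid`, `case0`..`ctrl2`) and
#'   `truth` (data frame `rsid`, `category`, `maf`, `theta`, `true_or`,
#'   `is_true`).
#' @export
simulate_gwas <- function(n_snps = 10000, fractions = c(0.875, 0.10, 0.025),
                          n_true = 11, true_alloc = c(1, 5, 5),
                          or_true = 1.25, maf = NULL, n_cases = 1000,
                          n_controls = 1000, seed = NULL) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8,
            length(true_alloc) == 3L, sum(true_alloc) == n_true,
            n_true <= n_snps)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- stats::runif(n_snps, 0.1, 0.4)
  maf <- rep_len(maf, n_snps)
  stopifnot(all(maf > 0), all(maf < 0.5))
  category <- sample(c("C1", "C2", "C3"), n_snps, replace = TRUE,
                     prob = fractions)
  theta <- numeric(n_snps)
  true_idx <- integer(0)
  for (j in 1:3) {
    pool <- which(category == c("C1", "C2", "C3")[j])
    if (length(pool) < true_alloc[j]) {
      stop("category C", j, " has fewer SNPs than its true allocation")
    }
    true_idx <- c(true_idx, sample(pool, true_alloc[j]))
  }
  if (is.function(or_true)) {
    theta[true_idx] <- or_true(length(true_idx))
  } else {
    theta[true_idx] <- log(rep_len(or_true, length(true_idx)))
  }
  f <- maf
  p_ctrl <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  tilt <- exp(outer(theta, 0:2))
  p_case <- p_ctrl * tilt
  p_case <- p_case / rowSums(p_case)
  ctrl <- .draw_genotype_counts(n_controls, p_ctrl[, 1], p_ctrl[, 2],
                                p_ctrl[, 3])
  case <- .draw_genotype_counts(n_cases, p_case[, 1], p_case[, 2],
                                p_case[, 3])
  rsid <- sprintf("rs%07d", seq_len(n_snps))
  list(counts = data.frame(rsid = rsid,
                           case0 = case[, 1], case1 = case[, 2],
                           case2 = case[, 3],
                           ctrl0 = ctrl[, 1], ctrl1 = ctrl[, 2],
                           ctrl2 = ctrl[, 3], stringsAsFactors = FALSE),
       truth = data.frame(rsid = rsid, category = category, maf = maf,
                          theta = theta, true_or = exp(theta),
                          is_true = seq_len(n_snps) %in% true_idx,
                          stringsAsFactors = FALSE))
}

.subsample_triplet <- function(x0, x1, x2, frac) {
  tot <- x0 + x1 + x2
  k <- round(frac * tot)
  s0 <- stats::rhyper(length(x0), x0, x1 + x2, k)
  s1 <- stats::rhyper(length(x0), x1, x2, k - s0)
  cbind(s0, s1, k - s0 - s1)
}

#' Subsampling rank-comparison experiment
#'
#' For each subsample fraction and replicate, draws the stated fraction of
#' cases and of controls without replacement (multivariate hypergeometric on
#' the genotype counts, equivalent to subsampling subjects at independent
#' loci), refits the per-allele trend model on every SNP, computes BFDPs
#' using category prior odds derived from the full panel's category counts,
#' and records each planted (truly associated) SNP's rank by p-value and by
#' BFDP. SNPs whose subsample is degenerate (monomorphic/separated) are
#' assigned p = 1 and ABF = 1 so they rank last.
#'
#' @param sim a simulation from [simulate_gwas()].
#' @param fractions subsample fractions in (0, 1]; 1 reuses the full data.
#' @param n_replicates replicates per fraction.
#' @param n_true assumed number of true SNPs for the analysis priors (an
#'   analyst's assumption, independent of how many were actually planted).
#' @param allocation allocation of `n_true` across categories.
#' @param w prior variance of the log OR.
#' @param seed optional RNG seed.
#' @return data frame with one row per (fraction, replicate, planted SNP):
#'   `fraction`, `replicate`, `rsid`, `category`, `rank_p`, `rank_bfdp`.
#'   Summarize with [summarize_ranks()].
#' @export
subsample_experiment <- function(sim, fractions = c(0.5, 0.75),
                                 n_replicates = 100, n_true = 100,
                                 allocation = "even", w = w_prior(2),
                                 seed = NULL) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- sim$counts
  truth <- sim$truth
  cat_counts <- category_counts(truth$category)
  cat_counts <- cat_counts[cat_counts > 0]
  spec <- prior_probabilities(cat_counts, n_true = n_true,
                              allocation = allocation)
  po_cat <- prior_odds(spec)
  po <- po_cat[truth$category]
  planted <- which(truth$is_true)
  n <- nrow(counts)
  res <- vector("list", length(fractions) * n_replicates)
  ri <- 0L
  for (frac in fractions) {
    for (rep_i in seq_len(n_replicates)) {
      if (frac == 1) {
        sub <- counts
      } else {
        ca <- .subsample_triplet(counts$case0, counts$case1, counts$case2,
                                 frac)
        co <- .subsample_triplet(counts$ctrl0, counts$ctrl1, counts$ctrl2,
                                 frac)
        sub <- data.frame(case0 = ca[, 1], case1 = ca[, 2], case2 = ca[, 3],
                          ctrl0 = co[, 1], ctrl1 = co[, 2], ctrl2 = co[, 3])
      }
      fit <- trend_fit_counts(sub$case0, sub$case1, sub$case2,
                              sub$ctrl0, sub$ctrl1, sub$ctrl2)
      p <- ifelse(is.na(fit$p), 1, fit$p)
      abf <- ifelse(is.na(fit$z), 1,
                    approximate_bayes_factor(ifelse(is.na(fit$z), 0, fit$z),
                                             ifelse(is.na(fit$se), 1,
                                                    fit$se)^2, w))
      bf <- bfdp(abf, po)
      rank_p <- integer(n)
      rank_b <- integer(n)
      rank_p[order(p, truth$rsid)] <- seq_len(n)
      rank_b[order(bf, p, truth$rsid)] <- seq_len(n)
      ri <- ri + 1L
      res[[ri]] <- data.frame(fraction = frac, replicate = rep_i,
                              rsid = truth$rsid[planted],
                              category = truth$category[planted],
                              rank_p = rank_p[planted],
                              rank_bfdp = rank_b[planted],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize a subsampling experiment per SNP and fraction
#'
#' Median, mean, min and max of the p-value and BFDP ranks over replicates,
#' plus the rank deltas (BFDP minus p; negative means the BFDP ranking placed
#' the SNP better).
#'
#' @param results output of [subsample_experiment()].
#' @return data frame with one row per (rsid, fraction).
#' @export
summarize_ranks <- function(results) {
  key <- interaction(results$rsid, results$fraction, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    data.frame(rsid = d$rsid[1L], category = d$category[1L],
               fraction = d$fraction[1L],
               median_rank_p = stats::median(d$rank_p),
               median_rank_bfdp = stats::median(d$rank_bfdp),
               mean_rank_p = mean(d$rank_p),
               mean_rank_bfdp = mean(d$rank_bfdp),
               min_rank_bfdp = min(d$rank_bfdp),
               max_rank_bfdp = max(d$rank_bfdp),
               delta_median = stats::median(d$rank_bfdp) -
                 stats::median(d$rank_p),
               delta_mean = mean(d$rank_bfdp) - mean(d$rank_p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fraction, out$category, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
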