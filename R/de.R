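#' Gene-level count matrix container
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param gene_ids gene identifiers (rownames of `counts` if absent).
#' @param gene_length_bp positive integer gene lengths (bp).
#' @param group named character vector mapping each sample to `"patient"`
#'   or `"control"`.
#' @return object of class `famseg_counts`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         gene_length_bp, group) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) stop("count_matrix(): gene_ids required")
  sample_ids <- colnames(counts)
  if (is.null(sample_ids)) stop("count_matrix(): counts must have column names")
  stopifnot(length(gene_ids) == nrow(counts),
            length(gene_length_bp) == nrow(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("count_matrix(): counts must be non-negative integers")
  }
  if (any(gene_length_bp <= 0)) stop("count_matrix(): gene lengths must be > 0")
  group <- group[sample_ids]
  if (any(is.na(group)) || !all(group %in% c("patient", "control"))) {
    stop("count_matrix(): group must map every sample to patient/control")
  }
  if (!all(c("patient", "control") %in% group)) {
    stop("count_matrix(): both groups must be non-empty")
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids,
                 gene_length_bp = as.numeric(gene_length_bp),
                 sample_ids = sample_ids, group = group, counts = counts),
            class = "famseg_counts")
}

#' @export
print.famseg_counts <- function(x, ...) {
  cat(sprintf("<famseg_counts>: %d genes x %d samples (%d patient, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$group == "patient"), sum(x$group == "control")))
  invisible(x)
}

#' Read a count matrix from TSV plus a group map CSV
#'
#' Count TSV columns: `gene_id`, `length_bp`, then one column per sample.
#' Group CSV columns: `sample_id`, `group` (patient/control).
#'
#' @param counts_path count TSV path.
#' @param groups_path group CSV path.
#' @return a `famseg_counts`.
#' @export
read_counts <- function(counts_path, groups_path) {
  tab <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  grp <- utils::read.csv(groups_path, stringsAsFactors = FALSE)
  samples <- setdiff(names(tab), c("gene_id", "length_bp"))
  m <- as.matrix(tab[, samples, drop = FALSE])
  rownames(m) <- tab$gene_id
  count_matrix(m, gene_length_bp = tab$length_bp,
               group = stats::setNames(grp$group, grp$sample_id))
}

#' Counts per million mapped reads
#'
#' CPM is library-size-only normalization: `count / library_size * 1e6`;
#' gene length enters FPKM, not CPM. Every column of the result sums to
#' 1e6 (when the sample has any reads).
#'
#' @param cm a `famseg_counts`.
#' @return numeric matrix, genes x samples.
#' @export
cpm <- function(cm) {
  lib <- colSums(cm$counts)
  if (any(lib == 0)) stop("cpm(): zero library size in sample(s): ",
                          paste(cm$sample_ids[lib == 0], collapse = ", "))
  sweep(cm$counts, 2, lib, "/") * 1e6
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' `count / (length_kb * library_size_in_millions)`; equivalently
#' `cpm / length_kb` elementwise.
#'
#' @param cm a `famseg_counts`.
#' @return numeric matrix, genes x samples.
#' @export
fpkm <- function(cm) {
  cpm(cm) / (cm$gene_length_bp / 1000)
}

# counts rescaled to the geometric-mean library size (common scale for
# pooling and dispersion estimation; no TMM)
.equalized_counts <- function(cm) {
  lib <- colSums(cm$counts)
  common <- exp(mean(log(lib)))
  sweep(cm$counts, 2, common / lib, "*")
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Counts are scaled to the geometric-mean library size; per gene, the
#' pooled within-group sample variance s2 and grand mean m give
#' `phi_g = max(0, (s2 - m) / m^2)`, and the common dispersion is the
#' median of `phi_g` over genes with positive mean. Because the median of
#' a variance estimate on few degrees of freedom sits below its mean
#' (`median(chi2_df)/df < 1`), s2 is first divided by that factor; without
#' the correction the median systematically underestimates the dispersion
#' at this design's 4 within-group degrees of freedom and inflates the
#' downstream false-discovery rate. With fewer than two samples in every
#' group the dispersion is inestimable and a fallback of 0.1 is returned
#' with a warning.
#'
#' @param cm a `famseg_counts`.
#' @param fallback dispersion returned when inestimable (default 0.1).
#' @return scalar dispersion (>= 0).
#' @export
estimate_common_dispersion <- function(cm, fallback = 0.1) {
  if (all(colSums(cm$counts) == 0)) {
    stop("estimate_common_dispersion(): degenerate all-zero matrix")
  }
  sc <- .equalized_counts(cm)
  groups <- c("patient", "control")
  df <- sum(pmax(table(factor(cm$group, groups)) - 1, 0))
  if (df == 0) {
    warning("estimate_common_dispersion(): single sample per group; ",
            "returning fallback dispersion ", fallback)
    return(fallback)
  }
  ss <- 0
  for (g in groups) {
    cols <- names(cm$group)[cm$group == g]
    if (length(cols) < 2) next
    sub <- sc[, cols, drop = FALSE]
    mu_g <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu_g)^2)
  }
  s2 <- (ss / df) / (stats::qchisq(0.5, df) / df)  # median-bias correction
  m <- rowMeans(sc)
  keep <- m > 0
  phi_g <- pmax(0, (s2[keep] - m[keep]) / m[keep]^2)
  stats::median(phi_g)
}

#' Conditional NB exact-test p-value for one gene
#'
#' Conditioned on the pooled total t at equalized library sizes, the split
#' between groups follows a distribution proportional to
#' `C(y + rA - 1, y) * C(t - y + rB - 1, t - y)` with `rA = nA/phi`,
#' `rB = nB/phi` (the mean cancels); the Poisson limit `phi = 0` gives a
#' binomial with probability `nA / (nA + nB)`. The two-sided p doubles the
#' smaller cumulative tail mass at the observed split, capped at 1.
#'
#' @param ya observed (equalized, rounded) group-A total.
#' @param t pooled total.
#' @param na,nb group sizes.
#' @param phi common dispersion (>= 0).
#' @return p-value in (0, 1].
#' @export
nb_conditional_p <- function(ya, t, na, nb, phi) {
  if (t == 0) return(1)
  y <- 0:t
  if (phi == 0) {
    logw <- stats::dbinom(y, t, na / (na + nb), log = TRUE)
  } else {
    ra <- na / phi; rb <- nb / phi
    logw <- lgamma(y + ra) - lgamma(ra) - lfactorial(y) +
      lgamma(t - y + rb) - lgamma(rb) - lfactorial(t - y)
  }
  logw <- logw - max(logw)
  p <- exp(logw); p <- p / sum(p)
  lower <- sum(p[y <= ya])
  upper <- sum(p[y >= ya])
  min(1, 2 * min(lower, upper))
}

#' Two-group conditional NB exact test, per gene
#'
#' Scales counts to the geometric-mean library size, rounds, pools within
#' groups and computes the conditional two-sided p per gene via
#' [nb_conditional_p()].
#'
#' @param cm a `famseg_counts`.
#' @param phi common dispersion (>= 0); e.g. from
#'   [estimate_common_dispersion()].
#' @return numeric p-value vector named by gene.
#' @export
exact_test <- function(cm, phi) {
  if (phi < 0) stop("exact_test(): phi must be >= 0")
  sc <- round(.equalized_counts(cm))
  pa <- names(cm$group)[cm$group == "patient"]
  co <- names(cm$group)[cm$group == "control"]
  ya <- rowSums(sc[, pa, drop = FALSE])
  yb <- rowSums(sc[, co, drop = FALSE])
  na <- length(pa); nb <- length(co)
  p <- vapply(seq_along(ya), function(i) {
    nb_conditional_p(ya[i], ya[i] + yb[i], na, nb, phi)
  }, numeric(1))
  stats::setNames(p, cm$gene_ids)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} m p_(j) / j` mapped back to input order (the
#' standard step-up; computed via [stats::p.adjust()]).
#'
#' @param p p-values in [0,1].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("bh_adjust(): p-values must lie in [0,1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Full differential-expression table
#'
#' Runs the conditional NB exact test and BH correction and computes
#' log2 fold changes (patient over control) on group-mean CPM with a prior
#' count of 0.5 per group mean to avoid infinities.
#'
#' @param cm a `famseg_counts`.
#' @param phi common dispersion; `NULL` (default) estimates it via
#'   [estimate_common_dispersion()].
#' @param alpha FDR significance threshold (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 1, i.e.
#'   twofold).
#' @return data frame: `gene_id`, `log2fc`, `cpm_mean`, `p`, `fdr`,
#'   `direction` (up/down/ns), `significant`.
#' @export
de_table <- function(cm, phi = NULL, alpha = 0.05, lfc_min = 1.0) {
  if (is.null(phi)) phi <- estimate_common_dispersion(cm)
  x <- cpm(cm)
  pa <- names(cm$group)[cm$group == "patient"]
  co <- names(cm$group)[cm$group == "control"]
  mu_p <- rowMeans(x[, pa, drop = FALSE])
  mu_c <- rowMeans(x[, co, drop = FALSE])
  log2fc <- log2((mu_p + 0.5) / (mu_c + 0.5))
  p <- exact_test(cm, phi)
  fdr <- bh_adjust(p)
  significant <- fdr < alpha & abs(log2fc) >= lfc_min
  direction <- ifelse(!significant, "ns", ifelse(log2fc > 0, "up", "down"))
  data.frame(gene_id = cm$gene_ids, log2fc = log2fc,
             cpm_mean = rowMeans(x), p = unname(p), fdr = fdr,
             direction = direction, significant = significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split significant genes into up- and down-regulated lists
#'
#' @param res a [de_table()] data frame.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_min minimum |log2FC| (default 1).
#' @return list with `up` and `down` gene-id vectors.
#' @export
de_filter <- function(res, alpha = 0.05, lfc_min = 1.0) {
  sig <- res$fdr < alpha
  list(up = res$gene_id[sig & res$log2fc >= lfc_min],
       down = res$gene_id[sig & res$log2fc <= -lfc_min])
}

#' Top-n most up- and down-regulated significant genes
#'
#' Up-regulated genes ranked by descending log2FC, down-regulated by
#' ascending; ties broken by smaller FDR, then lexical gene id. Returns at
#' most `n` per direction.
#'
#' @param res a [de_table()] data frame.
#' @param n per-direction cap (default 100).
#' @param alpha,lfc_min significance thresholds as in [de_filter()].
#' @return list with `up` and `down` data frames (subsets of `res`).
#' @export
top_n_by_direction <- function(res, n = 100, alpha = 0.05, lfc_min = 1.0) {
  lists <- de_filter(res, alpha, lfc_min)
  pick <- function(ids, decreasing) {
    sub <- res[res$gene_id %in% ids, , drop = FALSE]
    o <- order(if (decreasing) -sub$log2fc else sub$log2fc,
               sub$fdr, sub$gene_id)
    utils::head(sub[o, , drop = FALSE], n)
  }
  list(up = pick(lists$up, TRUE), down = pick(lists$down, FALSE))
}

#' Row-average normalization for heatmap display
#'
#' Divides each selected row by its row mean; rows with zero mean become
#' all-zero and are flagged in the `zero_mean` attribute.
#'
#' @param values numeric matrix (e.g. CPM or FPKM).
#' @param genes row names to keep (default all).
#' @return normalized matrix whose nonzero rows all have mean 1.
#' @export
heatmap_matrix <- function(values, genes = rownames(values)) {
  m <- values[genes, , drop = FALSE]
  mu <- rowMeans(m)
  out <- m / ifelse(mu == 0, 1, mu)
  out[mu == 0, ] <- 0
  attr(out, "zero_mean") <- rownames(m)[mu == 0]
  out
}

#' Read gene sets from a GMT file
#' @param path GMT path (tab-delimited: set id, description, member genes).
#' @return named list of member gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(f) f[-(1:2)]),
                  vapply(lines, `[`, character(1), 1))
}

#' Hypergeometric over-representation of DE genes in gene sets
#'
#' For each set, with universe size N, set size K (restricted to the
#' universe), n DE genes and overlap k, the p-value is the upper
#' hypergeometric tail P(X >= k); q-values are BH-adjusted across sets and
#' the enrichment ratio k / K is the proportion of the pathway's genes that
#' are differentially expressed. DE genes outside the universe are dropped
#' with a warning.
#'
#' @param de_genes character vector of DE gene ids.
#' @param gene_sets named list of member-gene vectors (e.g. [read_gmt()]).
#' @param universe background gene ids.
#' @param alpha significance threshold on q (default 0.05).
#' @return data frame sorted by q then p: `set_id`, `k`, `K`, `n`, `N`,
#'   `enrichment_ratio`, `p`, `q`, `significant`.
#' @export
enrich <- function(de_genes, gene_sets, universe, alpha = 0.05) {
  outside <- setdiff(de_genes, universe)
  if (length(outside)) {
    warning("enrich(): dropping ", length(outside),
            " DE gene(s) absent from the universe")
    de_genes <- intersect(de_genes, universe)
  }
  N <- length(universe); n <- length(de_genes)
  rows <- lapply(names(gene_sets), function(s) {
    members <- intersect(gene_sets[[s]], universe)
    K <- length(members)
    k <- length(intersect(de_genes, members))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = s, k = k, K = K, n = n, N = N,
               enrichment_ratio = if (K > 0) k / K else 0,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$q, out$p, out$set_id), , drop = FALSE]
}
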