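#' End-to-end genetics pipeline: co-segregation filter, LOD, ACMG verdict
#'
#' Chains the dominant-model co-segregation filter, the population-absence
#' filter, two-point LOD scoring of each passing variant and the ACMG
#' evidence combination. PP1 is derived from the LOD via [pp1_strength()];
#' PM2 can be auto-derived from population absence; further criteria (e.g.
#' PS3 functional support) are supplied as asserted evidence codes.
#'
#' @param gm a `famseg_genotypes`.
#' @param ped a `famseg_pedigree`.
#' @param max_af population-frequency ceiling (default 0, absent from
#'   controls).
#' @param require_panels frequency panels to enforce (default all present).
#' @param asserted_evidence character vector of additionally asserted ACMG
#'   codes at default strengths (e.g. `"PS3"`), applied to every passing
#'   variant.
#' @param auto_pm2 add PM2 for variants passing the absence filter
#'   (default TRUE).
#' @param pp1_thresholds threshold map for [pp1_strength()].
#' @param grid_step LOD maximization grid (default 0.001).
#' @param strict_missing passed to [dominant_filter()].
#' @return list of class `famseg_genetics_report`: `verdicts` (all
#'   variants), `passing` (after both filters), `lod` (per passing variant:
#'   NR, R, lod_max, theta_max, lod_reported), `classifications` (named
#'   list of `famseg_classification`).
#' @export
run_genetics <- function(gm, ped, max_af = 0, require_panels = NULL,
                         asserted_evidence = character(0), auto_pm2 = TRUE,
                         pp1_thresholds = c(supporting = 0.6,
                                            moderate = 1.5, strong = 3.0),
                         grid_step = 0.001, strict_missing = FALSE) {
  verdicts <- dominant_filter(gm, ped, strict_missing = strict_missing)
  seg <- verdicts[verdicts$segregates, , drop = FALSE]
  passing <- population_absence_filter(seg, gm, max_af = max_af,
                                       require_panels = require_panels)
  keys <- paste(passing$chrom, passing$pos, passing$ref, passing$alt, sep = ":")
  lod_rows <- list(); classifications <- list()
  for (k in keys) {
    counts <- classify_meioses(ped, gm, k)
    lr <- max_lod(counts, grid_step = grid_step)
    lod_rows[[k]] <- data.frame(
      variant = k, non_recombinant = counts$non_recombinant,
      recombinant = counts$recombinant, n_excluded = nrow(counts$excluded),
      lod_max = lr$lod_max, theta_max = lr$theta_max,
      lod_reported = lr$lod_max_rounded, stringsAsFactors = FALSE)
    ev <- list()
    pp1 <- pp1_strength(lr$lod_max, thresholds = pp1_thresholds)
    if (!is.null(pp1)) ev <- c(ev, list(pp1))
    if (auto_pm2) {
      ev <- c(ev, list(evidence_item("PM2", note = sprintf(
        "frequency <= %g in all required panels", max_af))))
    }
    for (code in asserted_evidence) ev <- c(ev, list(evidence_item(code)))
    classifications[[k]] <- combine_evidence(ev)
  }
  structure(list(verdicts = verdicts, passing = passing,
                 lod = if (length(lod_rows)) do.call(rbind, lod_rows) else NULL,
                 classifications = classifications),
            class = "famseg_genetics_report")
}

#' @export
print.famseg_genetics_report <- function(x, ...) {
  cat(sprintf("<famseg_genetics_report>: %d variants, %d segregating, %d passing filters\n",
              nrow(x$verdicts), sum(x$verdicts$segregates), nrow(x$passing)))
  if (!is.null(x$lod)) {
    for (i in seq_len(nrow(x$lod))) {
      cat(sprintf("  %s: LOD %.1f (NR=%d R=%d) -> %s\n",
                  x$lod$variant[i], x$lod$lod_reported[i],
                  x$lod$non_recombinant[i], x$lod$recombinant[i],
                  x$classifications[[x$lod$variant[i]]]$verdict))
    }
  }
  invisible(x)
}

#' End-to-end expression pipeline: DE test, top lists, enrichment
#'
#' Runs dispersion estimation, the conditional NB exact test with BH
#' correction, significance filtering, top-n selection per direction, the
#' row-average heatmap normalization of the top genes' CPM, and (when gene
#' sets are supplied) hypergeometric enrichment over an expressed-gene
#' universe (CPM >= `min_cpm` in >= `min_samples` samples by default).
#'
#' @param cm a `famseg_counts`.
#' @param gene_sets optional named list of gene sets (e.g. [read_gmt()]).
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_min minimum |log2FC| (default 1).
#' @param top_n per-direction top-gene cap (default 100).
#' @param phi common dispersion; `NULL` estimates it.
#' @param min_cpm,min_samples expressed-gene universe filter (defaults 1
#'   and 2).
#' @return list of class `famseg_expression_report`: `phi`, `de` (full
#'   table), `up`, `down` (gene ids), `top` (list of up/down data frames),
#'   `heatmap` (normalized matrix of top genes), `enrichment` (or NULL),
#'   `universe`.
#' @export
run_expression <- function(cm, gene_sets = NULL, alpha = 0.05, lfc_min = 1.0,
                           top_n = 100, phi = NULL, min_cpm = 1,
                           min_samples = 2) {
  if (is.null(phi)) phi <- estimate_common_dispersion(cm)
  de <- de_table(cm, phi = phi, alpha = alpha, lfc_min = lfc_min)
  lists <- de_filter(de, alpha = alpha, lfc_min = lfc_min)
  top <- top_n_by_direction(de, n = top_n, alpha = alpha, lfc_min = lfc_min)
  x <- cpm(cm)
  top_genes <- c(top$up$gene_id, top$down$gene_id)
  hm <- if (length(top_genes)) heatmap_matrix(x, top_genes) else NULL
  expressed <- cm$gene_ids[rowSums(x >= min_cpm) >= min_samples]
  enr <- NULL
  if (!is.null(gene_sets)) {
    enr <- enrich(intersect(c(lists$up, lists$down), expressed),
                  gene_sets, universe = expressed, alpha = alpha)
  }
  structure(list(phi = phi, de = de, up = lists$up, down = lists$down,
                 top = top, heatmap = hm, enrichment = enr,
                 universe = expressed),
            class = "famseg_expression_report")
}

#' @export
print.famseg_expression_report <- function(x, ...) {
  cat(sprintf("<famseg_expression_report>: phi = %.3f; %d DE genes (%d up, %d down) of %d\n",
              x$phi, length(x$up) + length(x$down), length(x$up),
              length(x$down), nrow(x$de)))
  invisible(x)
}
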