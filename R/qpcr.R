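#' Read a qPCR Ct table from CSV
#'
#' Expected columns: `sample_id`, `group`, `gene`, `replicate`, `ct`.
#'
#' @param path CSV path.
#' @return validated Ct data frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("read_ct_table(): missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(tab$ct <= 0)) stop("read_ct_table(): Ct values must be > 0")
  tab
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale; per sample,
#' `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean dCt of the control
#' group`; relative expression is `2^(-ddCt)` (amplification efficiency
#' fixed at 2, no standard-curve correction). Samples without a reference
#' measurement are dropped with a warning. The control group's relative
#' expressions have geometric mean exactly 1 by construction.
#'
#' @param ct_table data frame as from [read_ct_table()].
#' @param target target gene name.
#' @param reference reference (internal-control) gene name, e.g. 18S rRNA.
#' @param control_group group label used as the calibrator (e.g. "Sc").
#' @return data frame: `sample_id`, `group`, `dct`, `ddct`, `rel_expr`.
#' @export
ddct <- function(ct_table, target, reference, control_group) {
  avg <- function(gene) {
    sub <- ct_table[ct_table$gene == gene, , drop = FALSE]
    stats::aggregate(ct ~ sample_id + group, data = sub, FUN = mean)
  }
  tg <- avg(target); rf <- avg(reference)
  i <- match(tg$sample_id, rf$sample_id)
  drop <- is.na(i)
  if (any(drop)) {
    warning("ddct(): dropping sample(s) without reference measurement: ",
            paste(tg$sample_id[drop], collapse = ", "))
    tg <- tg[!drop, , drop = FALSE]
    i <- i[!drop]
  }
  if (!any(tg$group == control_group)) {
    stop("ddct(): control group '", control_group, "' is empty")
  }
  dct <- tg$ct - rf$ct[i]
  dd <- dct - mean(dct[tg$group == control_group])
  data.frame(sample_id = tg$sample_id, group = tg$group,
             dct = dct, ddct = dd, rel_expr = 2^(-dd),
             stringsAsFactors = FALSE)
}

#' Two-group comparison of relative expression
#'
#' Student's two-sided pooled-variance t-test (Welch available via
#' `var_equal = FALSE`); means reported with SEM and the usual significance
#' stars (`*` p < 0.05, `**` p < 0.01, `N.S.` otherwise).
#'
#' @param rel a [ddct()] result (or any data frame with `group` and
#'   `rel_expr`).
#' @param group_a,group_b group labels to compare.
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return list: `mean_a`, `sem_a`, `mean_b`, `sem_b`, `p`, `stars`.
#' @export
group_compare <- function(rel, group_a, group_b, var_equal = TRUE) {
  a <- rel$rel_expr[rel$group == group_a]
  b <- rel$rel_expr[rel$group == group_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("group_compare(): need >= 2 values per group")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate noise-free case: identical groups are indistinguishable,
    # distinct constant groups are separated with certainty
    if (mean(a) == mean(b)) 1 else 0
  } else {
    stats::t.test(a, b, var.equal = var_equal)$p.value
  }
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else "N.S."
  list(mean_a = mean(a), sem_a = sem(a),
       mean_b = mean(b), sem_b = sem(b), p = p, stars = stars)
}
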