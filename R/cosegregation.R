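#' Dominant-model co-segregation filter
#'
#' Retains variants whose genotypes fit a fully penetrant autosomal-dominant
#' model: every genotyped affected individual carries at least one alt
#' allele (het or, atypically for a rare dominant variant, hom-alt) and
#' every genotyped unaffected individual is hom-ref. `require_het = TRUE`
#' instead demands heterozygous carriage in affected members, the strict
#' reading of a rare dominant model (a variant rare enough to be absent
#' from controls is not expected homozygous in a carrier). Missing calls
#' are compatible by default but counted and flagged; `strict_missing =
#' TRUE` treats a missing call as a violation.
#'
#' @param gm a `famseg_genotypes`.
#' @param ped a `famseg_pedigree`; samples are matched on id.
#' @param strict_missing reject variants with missing calls in informative
#'   individuals (default FALSE).
#' @param require_het affected members must be heterozygous, not merely
#'   carry an alt allele (default FALSE).
#' @param detail build the per-variant violation tables (default TRUE).
#'   `detail = FALSE` skips them (the `violations` column is absent) for
#'   large simulation sweeps; the verdicts are identical.
#' @return data frame of per-variant verdicts: variant key columns,
#'   `segregates`, `n_affected_carrier`, `n_unaffected_noncarrier`,
#'   `n_missing`, `n_hom_alt_affected`, `violations` (list column of
#'   data frames `sample_id`, `reason`).
#' @export
dominant_filter <- function(gm, ped, strict_missing = FALSE,
                            require_het = FALSE, detail = TRUE) {
  ind <- ped$individuals
  aff_ids <- intersect(ind$id[ind$affected == "affected" & ind$genotyped],
                       gm$sample_ids)
  una_ids <- intersect(ind$id[ind$affected == "unaffected" & ind$genotyped],
                       gm$sample_ids)
  if (!length(aff_ids) && !length(una_ids)) {
    stop("dominant_filter(): no overlap between pedigree and genotype samples")
  }
  aff <- gm$calls[, aff_ids, drop = FALSE]
  una <- gm$calls[, una_ids, drop = FALSE]
  bad_a <- if (require_het) {
    !is.na(aff) & aff != 1              # affected not heterozygous
  } else {
    !is.na(aff) & aff == 0              # affected without the alt allele
  }
  bad_u <- !is.na(una) & una >= 1       # unaffected carrying it
  n_miss <- rowSums(is.na(aff)) + rowSums(is.na(una))
  n_bad <- rowSums(bad_a) + rowSums(bad_u)
  seg <- n_bad == 0 & (!strict_missing | n_miss == 0)
  verdicts <- data.frame(
    chrom = gm$variants$chrom, pos = gm$variants$pos,
    ref = gm$variants$ref, alt = gm$variants$alt,
    gene = if ("gene" %in% names(gm$variants)) gm$variants$gene else NA,
    segregates = seg,
    n_affected_carrier = rowSums(!is.na(aff) & aff >= 1),
    n_unaffected_noncarrier = rowSums(!is.na(una) & una == 0),
    n_missing = n_miss,
    n_hom_alt_affected = rowSums(!is.na(aff) & aff == 2),
    stringsAsFactors = FALSE)
  if (detail) {
    none <- data.frame(sample_id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
    aff_reason <- if (require_het) "affected not heterozygous" else
      "affected without alt allele"
    verdicts$violations <- lapply(seq_len(nrow(verdicts)), function(i) {
      ids <- c(aff_ids[bad_a[i, ]], una_ids[bad_u[i, ]])
      reasons <- rep(c(aff_reason, "unaffected carries alt allele"),
                     c(sum(bad_a[i, ]), sum(bad_u[i, ])))
      if (strict_missing && n_miss[i] > 0) {
        ids <- c(ids, aff_ids[is.na(aff[i, ])], una_ids[is.na(una[i, ])])
        reasons <- c(reasons, rep("missing genotype (strict mode)",
                                  n_miss[i]))
      }
      if (!length(ids)) none else
        data.frame(sample_id = ids, reason = reasons, stringsAsFactors = FALSE)
    })
  }
  verdicts
}

#' Population-absence filter
#'
#' Keeps variants whose frequency is at most `max_af` in every required
#' population panel. A variant with no entry for a panel (NA frequency) is
#' treated as unobserved there, i.e. frequency 0, and flagged.
#'
#' @param verdicts output of [dominant_filter()] (or any data frame with
#'   `af_<panel>` columns merged in) joined with variant annotations; the
#'   convenient form is to pass the verdict table plus the `famseg_genotypes`
#'   whose `variants` carry the `af_` columns.
#' @param gm the `famseg_genotypes` providing `af_<panel>` columns.
#' @param max_af maximum tolerated frequency, in [0,1].
#' @param require_panels panel names (without the `af_` prefix); default all
#'   panels present.
#' @return `verdicts` subset to passing variants, with an added
#'   `pop_unobserved` flag (TRUE when absent from every required panel's
#'   table).
#' @export
population_absence_filter <- function(verdicts, gm, max_af = 0,
                                      require_panels = NULL) {
  if (max_af < 0 || max_af > 1) {
    stop("population_absence_filter(): max_af must lie in [0,1]")
  }
  panels <- sub("^af_", "", grep("^af_", names(gm$variants), value = TRUE))
  if (is.null(require_panels)) require_panels <- panels
  unknown <- setdiff(require_panels, panels)
  if (length(unknown)) {
    stop("population_absence_filter(): unknown panel(s): ",
         paste(unknown, collapse = ", "))
  }
  key_v <- variant_keys(gm)
  key_f <- paste(verdicts$chrom, verdicts$pos, verdicts$ref, verdicts$alt,
                 sep = ":")
  idx <- match(key_f, key_v)
  if (!length(require_panels)) {
    verdicts$pop_unobserved <- TRUE
    return(verdicts)
  }
  af <- as.matrix(gm$variants[idx, paste0("af_", require_panels), drop = FALSE])
  unobserved <- apply(is.na(af), 1, all)
  af[is.na(af)] <- 0
  keep <- apply(af <= max_af, 1, all)
  out <- verdicts[keep, , drop = FALSE]
  out$pop_unobserved <- unobserved[keep]
  out
}

#' Concordance between discovery and validation genotype sets
#'
#' Compares per-sample calls for one variant between a discovery matrix
#' (e.g. the WES subset) and a validation matrix (e.g. Sanger genotyping of
#' the full family), and evaluates dominant-model segregation on the union
#' of samples.
#'
#' @param gm_wes discovery `famseg_genotypes`.
#' @param gm_validation validation `famseg_genotypes`.
#' @param variant one-row variant data frame (chrom, pos, ref, alt) or key
#'   string "chrom:pos:ref:alt".
#' @param ped a `famseg_pedigree` for the segregation re-check.
#' @return list: `n_concordant`, `n_discordant`, `discordant_ids`,
#'   `full_family_segregates`.
#' @export
validation_concordance <- function(gm_wes, gm_validation, variant, ped) {
  key <- if (is.character(variant)) variant else
    paste(variant$chrom, variant$pos, variant$ref, variant$alt, sep = ":")
  i_w <- match(key, variant_keys(gm_wes))
  i_v <- match(key, variant_keys(gm_validation))
  if (is.na(i_w) || is.na(i_v)) {
    stop("validation_concordance(): variant ", key, " absent from ",
         if (is.na(i_w)) "discovery" else "validation", " matrix")
  }
  shared <- intersect(gm_wes$sample_ids, gm_validation$sample_ids)
  cw <- gm_wes$calls[i_w, shared]
  cv <- gm_validation$calls[i_v, shared]
  disc <- shared[!is.na(cw) & !is.na(cv) & cw != cv]
  # union matrix: validation calls take precedence on shared samples
  extra <- setdiff(gm_wes$sample_ids, gm_validation$sample_ids)
  union_ids <- c(gm_validation$sample_ids, extra)
  union_calls <- matrix(c(gm_validation$calls[i_v, ],
                          gm_wes$calls[i_w, extra]), nrow = 1,
                        dimnames = list(NULL, union_ids))
  gm_union <- genotype_matrix(gm_validation$variants[i_v, , drop = FALSE],
                              union_ids, union_calls)
  fv <- dominant_filter(gm_union, ped)
  list(n_concordant = length(shared) - length(disc),
       n_discordant = length(disc),
       discordant_ids = disc,
       full_family_segregates = fv$segregates[1])
}
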