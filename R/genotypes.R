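#' Genotype matrix container
#'
#' Variants x samples diploid calls. `calls` is an integer matrix with
#' 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing; one row per
#' (decomposed) alt allele. `variants` is a data frame with `chrom`,
#' `pos` (1-based), `ref`, `alt` and, when annotated, `gene`,
#' `region_class`, `hgvs_c` plus one `af_<panel>` column per population
#' frequency panel.
#'
#' @param variants variant data frame.
#' @param sample_ids character vector.
#' @param calls integer matrix, `nrow(variants)` x `length(sample_ids)`.
#' @return object of class `famseg_genotypes`.
#' @export
genotype_matrix <- function(variants, sample_ids, calls) {
  stopifnot(nrow(calls) == nrow(variants), ncol(calls) == length(sample_ids))
  if (any(variants$pos < 1)) stop("genotype_matrix(): pos must be >= 1")
  if (any(variants$ref == variants$alt)) {
    stop("genotype_matrix(): ref and alt alleles must differ")
  }
  af_cols <- grep("^af_", names(variants), value = TRUE)
  for (cc in af_cols) {
    v <- variants[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("genotype_matrix(): population frequencies must lie in [0,1]")
    }
  }
  dimnames(calls) <- list(NULL, sample_ids)
  structure(list(variants = variants, sample_ids = sample_ids, calls = calls),
            class = "famseg_genotypes")
}

#' @export
print.famseg_genotypes <- function(x, ...) {
  cat(sprintf("<famseg_genotypes>: %d variants x %d samples\n",
              nrow(x$variants), length(x$sample_ids)))
  invisible(x)
}

#' Variant key strings ("chrom:pos:ref:alt")
#' @param gm a `famseg_genotypes` or variant data frame.
#' @return character vector of keys.
#' @export
variant_keys <- function(gm) {
  v <- if (inherits(gm, "famseg_genotypes")) gm$variants else gm
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

# decode one GT string vector against alt-allele index k -> 0/1/2/NA
.decode_gt <- function(gt, k) {
  gt <- sub(":.*", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == "." | is.na(a))) return(NA_integer_)
    sum(a == as.character(k))
  }, integer(1))
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT fields of a VCF 4.x file (via \pkg{vcfR}); multi-allelic sites
#' are decomposed into one row per alt allele, with the call for allele k
#' being the count of k alleles in the genotype. An optional annotation
#' sidecar TSV keyed by `chrom`, `pos`, `ref`, `alt` supplies `gene`,
#' `region_class`, `hgvs_c` and `af_<panel>` frequency columns; unannotated
#' variants keep `NA` gene and no frequency entries.
#'
#' @param path VCF path.
#' @param annotations optional annotation TSV path.
#' @return a `famseg_genotypes`.
#' @export
read_vcf <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop("read_vcf(): file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("read_vcf(): VCF has no GT genotype field")
  samples <- colnames(gt)
  rows <- list(); calls <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
      calls[[length(calls) + 1L]] <- .decode_gt(gt[i, ], k)
    }
  }
  variants <- do.call(rbind, rows)
  variants$gene <- NA_character_
  variants$region_class <- NA_character_
  variants$hgvs_c <- NA_character_
  mat <- do.call(rbind, calls)
  if (!is.null(annotations)) {
    ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)
    key_v <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
    key_a <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
    i <- match(key_v, key_a)
    for (cc in intersect(c("gene", "region_class", "hgvs_c"), names(ann))) {
      variants[[cc]] <- ann[[cc]][i]
    }
    for (cc in grep("^af_", names(ann), value = TRUE)) {
      variants[[cc]] <- ann[[cc]][i]
    }
  }
  genotype_matrix(variants, samples, mat)
}

#' Write a genotype matrix as an uncompressed multi-sample VCF 4.2
#'
#' @param gm a `famseg_genotypes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_str <- c("0/0", "0/1", "1/1")[gm$calls + 1L]
  gt_str[is.na(gt_str)] <- "./."
  gt_mat <- matrix(gt_str, nrow = nrow(gm$calls))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famseg",
    paste0("##contig=<ID=", unique(gm$variants$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(gm$variants)), function(i) {
    paste(c(gm$variants$chrom[i], gm$variants$pos[i], ".",
            gm$variants$ref[i], gm$variants$alt[i], ".", "PASS", ".",
            "GT", gt_mat[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Subset a genotype matrix by sample ids
#' @param gm a `famseg_genotypes`.
#' @param ids sample ids to keep (order preserved as given).
#' @return a `famseg_genotypes`.
#' @export
subset_samples <- function(gm, ids) {
  missing <- setdiff(ids, gm$sample_ids)
  if (length(missing)) {
    stop("subset_samples(): samples not in matrix: ",
         paste(missing, collapse = ", "))
  }
  genotype_matrix(gm$variants, ids, gm$calls[, ids, drop = FALSE])
}
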