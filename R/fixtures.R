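#' The reconstructed four-generation HGF family pedigree
#'
#' 25 individuals: two deceased, ungenotyped generation-I founders (the
#' affected founder is an obligate carrier) and 23 alive genotyped members
#' across generations II-IV. The topology is one reconstruction consistent
#' with the published member table (12 affected heterozygous carriers, 11
#' unaffected wild-type) and with 12 phase-known informative meioses; see
#' the header of `extdata/family_hgf.ped` for the choices made.
#'
#' @return a `famseg_pedigree`.
#' @export
hgf_pedigree <- function() {
  read_ped(system.file("extdata", "family_hgf.ped", package = "famseg"),
           sidecar = system.file("extdata", "family_hgf_info.tsv",
                                 package = "famseg"))
}

#' Fixture genotypes for the HGF family
#'
#' 23-sample genotype matrix with five variants: the causal ZNF862-like
#' missense variant (het in every affected member, hom-ref in every
#' unaffected member), two decoy variants that co-segregate only within
#' the 10-member WES subset (ATP7B-like and CDADC1-like analogs), and two
#' background variants. Annotated with gene, region class, HGVS and
#' population frequencies from the sidecar TSV.
#'
#' @return a `famseg_genotypes`.
#' @export
hgf_genotypes <- function() {
  read_vcf(system.file("extdata", "family_hgf.vcf", package = "famseg"),
           annotations = system.file("extdata", "family_hgf_annotations.tsv",
                                     package = "famseg"))
}

#' Members of the WES discovery subset
#'
#' The study sequenced the proband plus nine relatives; which ten is a
#' reconstruction here (five affected, five unaffected, spanning
#' generations II-IV).
#'
#' @return character vector of 10 sample ids.
#' @export
hgf_wes_samples <- function() {
  c("II-1", "II-2", "II-3", "II-4", "III-1",
    "III-2", "III-6", "III-9", "IV-1", "IV-4")
}

#' Key of the fixture's causal variant
#' @return "chrom:pos:ref:alt" string.
#' @export
hgf_causal_key <- function() "chr7:149832310:G:A"
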