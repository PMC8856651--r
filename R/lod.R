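#' Classify informative meioses as recombinant or non-recombinant
#'
#' Under the fully penetrant autosomal-dominant model with zero phenocopy
#' rate, each informative meiosis (genotyped child of exactly one carrier
#' parent) is non-recombinant when the child's carrier status matches its
#' affection status (carrier & affected, or non-carrier & unaffected), and
#' recombinant otherwise. Meioses with unresolvable phase (both parents
#' carriers) are excluded and reported by [informative_meioses()].
#'
#' @param ped a `famseg_pedigree`.
#' @param gm a `famseg_genotypes` holding the variant's calls.
#' @param variant one-row variant data frame or "chrom:pos:ref:alt" key.
#' @param affection_proxy use affection status as carrier proxy for
#'   ungenotyped individuals (deceased founders); default TRUE.
#' @return list of class `famseg_meiosis_counts`: `non_recombinant`,
#'   `recombinant`, `meioses` (scored data frame), `excluded`.
#' @export
classify_meioses <- function(ped, gm, variant, affection_proxy = TRUE) {
  key <- if (is.character(variant)) variant else
    paste(variant$chrom, variant$pos, variant$ref, variant$alt, sep = ":")
  i <- match(key, variant_keys(gm))
  if (is.na(i)) stop("classify_meioses(): variant ", key, " not in matrix")
  calls <- gm$calls[i, ]
  carriers <- resolve_carriers(ped, genotype_calls = calls,
                               affection_proxy = affection_proxy)
  ms <- informative_meioses(ped, carriers)
  ind <- ped$individuals
  aff <- stats::setNames(ind$affected, ind$id)
  scored <- ms$meioses
  if (nrow(scored)) {
    child_carrier <- carriers[scored$child_id]
    child_affected <- aff[scored$child_id] == "affected"
    scored$recombinant <- child_carrier != child_affected
  } else {
    scored$recombinant <- logical(0)
  }
  meiosis_counts(non_recombinant = sum(!scored$recombinant),
                 recombinant = sum(scored$recombinant),
                 meioses = scored, excluded = ms$excluded)
}

#' Construct a meiosis-count object
#' @param non_recombinant NR count (>= 0).
#' @param recombinant R count (>= 0).
#' @param meioses optional scored meiosis data frame.
#' @param excluded optional excluded-meiosis data frame.
#' @return object of class `famseg_meiosis_counts`.
#' @export
meiosis_counts <- function(non_recombinant, recombinant,
                           meioses = NULL, excluded = NULL) {
  stopifnot(non_recombinant >= 0, recombinant >= 0)
  structure(list(non_recombinant = as.integer(non_recombinant),
                 recombinant = as.integer(recombinant),
                 meioses = meioses, excluded = excluded),
            class = "famseg_meiosis_counts")
}

#' @export
print.famseg_meiosis_counts <- function(x, ...) {
  cat(sprintf("<famseg_meiosis_counts>: NR = %d, R = %d\n",
              x$non_recombinant, x$recombinant))
  invisible(x)
}

#' Two-point LOD score at a recombination fraction
#'
#' Phase-known two-point LOD under full penetrance and zero phenocopy rate:
#' \deqn{LOD(\theta) = \log_{10}\frac{(1-\theta)^{NR}\,\theta^{R}}{0.5^{NR+R}}}
#' At `theta = 0` with `R > 0` the likelihood ratio is zero and `-Inf` is
#' returned as a sentinel (excluded from maximization by [max_lod()]).
#'
#' @param counts a `famseg_meiosis_counts` (or list with `non_recombinant`,
#'   `recombinant`).
#' @param theta recombination fraction(s) in [0, 0.5]; vectorized.
#' @return numeric LOD value(s).
#' @export
lod_at_theta <- function(counts, theta) {
  if (any(theta < 0 | theta > 0.5)) {
    stop("lod_at_theta(): theta must lie in [0, 0.5]")
  }
  nr <- counts$non_recombinant; r <- counts$recombinant
  n <- nr + r
  # log10(theta^R) with the 0^0 = 1 convention
  lt <- if (r == 0) rep(0, length(theta)) else r * log10(theta)
  nr * log10(1 - theta) + lt - n * log10(0.5)
}

#' Maximize the two-point LOD over a recombination-fraction grid
#'
#' Evaluates [lod_at_theta()] on the grid `{0, step, 2*step, ..., 0.5}`
#' (0.5 always included). `-Inf` values (theta = 0 with recombinants) are
#' excluded from the maximization; ties break toward smaller theta.
#'
#' @param counts a `famseg_meiosis_counts`.
#' @param grid_step grid resolution (default 0.001).
#' @return list of class `famseg_lod`: `counts`, `theta_grid`, `lod_at`
#'   (numeric vector named by theta), `theta_max`, `lod_max`, and
#'   `lod_max_rounded` (one decimal, the headline reporting convention).
#' @export
max_lod <- function(counts, grid_step = 0.001) {
  if (grid_step <= 0) stop("max_lod(): grid_step must be > 0")
  grid <- unique(c(seq(0, 0.5, by = grid_step), 0.5))
  lod <- lod_at_theta(counts, grid)
  finite <- is.finite(lod)
  i <- which(finite)[which.max(lod[finite])]
  structure(list(counts = counts, theta_grid = grid,
                 lod_at = stats::setNames(lod, grid),
                 theta_max = grid[i], lod_max = lod[i],
                 lod_max_rounded = round(lod[i], 1)),
            class = "famseg_lod")
}

#' @export
print.famseg_lod <- function(x, ...) {
  cat(sprintf("<famseg_lod>: max LOD %.4f (reported %.1f) at theta = %g (NR = %d, R = %d)\n",
              x$lod_max, x$lod_max_rounded, x$theta_max,
              x$counts$non_recombinant, x$counts$recombinant))
  invisible(x)
}
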