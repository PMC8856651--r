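#' Configuration for family genotype simulation
#'
#' Defaults encode the study family: the reconstructed four-generation
#' pedigree (two deceased founders, 23 alive genotyped members), a fully
#' penetrant dominant causal variant entering through the affected founder,
#' and a rare-skewed background allele-frequency distribution
#' (Beta(0.2, 5)).
#'
#' @param pedigree_template a `famseg_pedigree`; default [hgf_pedigree()].
#' @param causal_variant one-row variant data frame; default the ZNF862-like
#'   missense fixture variant.
#' @param carrier_founder id of the founder carrying the causal variant;
#'   default the affected founder of the template.
#' @param penetrance probability a carrier is affected (default 1).
#' @param n_background_variants background variant count (default 5000).
#' @param af_shape1,af_shape2 Beta parameters of background founder allele
#'   frequencies (default 0.2, 5).
#' @param genotype_missing_rate per-call missingness (default 0).
#' @param genotype_error_rate per-call error rate (default 0).
#' @param seed integer seed fixing all randomness.
#' @return config list of class `famseg_family_config`.
#' @export
family_sim_config <- function(pedigree_template = hgf_pedigree(),
                              causal_variant = NULL,
                              carrier_founder = NULL,
                              penetrance = 1.0,
                              n_background_variants = 5000,
                              af_shape1 = 0.2, af_shape2 = 5,
                              genotype_missing_rate = 0,
                              genotype_error_rate = 0,
                              seed = 1L) {
  if (is.null(causal_variant)) {
    causal_variant <- data.frame(chrom = "chr7", pos = 149832310L,
                                 ref = "G", alt = "A",
                                 stringsAsFactors = FALSE)
  }
  ind <- pedigree_template$individuals
  if (is.null(carrier_founder)) {
    founders <- ind$id[is.na(ind$father_id) & ind$affected == "affected"]
    if (!length(founders)) stop("family_sim_config(): no affected founder in template")
    carrier_founder <- founders[1]
  }
  rates <- c(penetrance, genotype_missing_rate, genotype_error_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("family_sim_config(): rates must lie in [0,1]")
  }
  structure(list(pedigree_template = pedigree_template,
                 causal_variant = causal_variant,
                 carrier_founder = carrier_founder,
                 penetrance = penetrance,
                 n_background_variants = n_background_variants,
                 af_shape1 = af_shape1, af_shape2 = af_shape2,
                 genotype_missing_rate = genotype_missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "famseg_family_config")
}

# topological order: founders first, then children once both parents placed
.topo_order <- function(ind) {
  done <- is.na(ind$father_id)
  order_ids <- ind$id[done]
  while (length(order_ids) < nrow(ind)) {
    ready <- !done & ind$father_id %in% order_ids & ind$mother_id %in% order_ids
    order_ids <- c(order_ids, ind$id[ready])
    done <- done | ready
  }
  order_ids
}

#' Simulate family genotypes with a planted dominant causal variant
#'
#' The causal variant enters through the configured founder and follows the
#' template's realized transmission: its carriers are exactly the template's
#' affected members (the template encodes one Mendelian-consistent
#' transmission history, so under the fully penetrant dominant model
#' affection marks carriage). Affection status is then re-derived as
#' carrier AND Bernoulli(penetrance) (no phenocopies), so the default
#' configuration reproduces the study composition (13 affected including
#' the founder, 23 genotyped alive members) while penetrance < 1 decouples
#' the two. Background variants draw founder alleles at Beta-distributed
#' population frequencies and gene-drop through the pedigree. Missing-call
#' and genotyping-error processes apply to genotyped members only. All
#' randomness is fixed by `cfg$seed`.
#'
#' @param cfg a [family_sim_config()].
#' @return list: `gm` (a `famseg_genotypes` over genotyped members), `ped`
#'   (template pedigree with simulated affection), `truth` manifest
#'   (causal key, per-individual carrier status, affected ids, config).
#' @export
simulate_family <- function(cfg) {
  set.seed(cfg$seed)
  ind <- cfg$pedigree_template$individuals
  n_ind <- nrow(ind)
  nv <- cfg$n_background_variants + 1L  # causal first
  af <- c(0, stats::rbeta(cfg$n_background_variants, cfg$af_shape1, cfg$af_shape2))

  # per-individual allele pairs, variants x individuals
  a1 <- matrix(0L, nv, n_ind, dimnames = list(NULL, ind$id))
  a2 <- a1
  ord <- .topo_order(ind)
  for (id in ord) {
    j <- match(id, ind$id)
    if (is.na(ind$father_id[j])) {
      a1[, j] <- stats::rbinom(nv, 1, af)
      a2[, j] <- stats::rbinom(nv, 1, af)
    } else {
      gf <- a1[, ind$father_id[j]] + a2[, ind$father_id[j]]
      gm_ <- a1[, ind$mother_id[j]] + a2[, ind$mother_id[j]]
      a1[, j] <- stats::rbinom(nv, 1, gf / 2)
      a2[, j] <- stats::rbinom(nv, 1, gm_ / 2)
    }
  }
  # causal variant: het in the template's affected members (the template's
  # realized transmission from the carrier founder), hom-ref elsewhere
  carrier <- stats::setNames(ind$affected == "affected", ind$id)
  if (!carrier[cfg$carrier_founder]) {
    stop("simulate_family(): carrier founder is not affected in the template")
  }
  a1[1, ] <- as.integer(carrier)
  a2[1, ] <- 0L
  geno <- a1 + a2

  affected <- carrier & (stats::runif(n_ind) < cfg$penetrance)
  ind$affected <- ifelse(affected, "affected", "unaffected")
  ped <- pedigree(ind, name = cfg$pedigree_template$name)

  gt_ids <- ind$id[ind$genotyped]
  calls <- geno[, gt_ids, drop = FALSE]
  nc <- length(calls)
  if (cfg$genotype_error_rate > 0) {
    err <- which(stats::runif(nc) < cfg$genotype_error_rate)
    if (length(err)) {
      calls[err] <- (calls[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    }
  }
  if (cfg$genotype_missing_rate > 0) {
    calls[stats::runif(nc) < cfg$genotype_missing_rate] <- NA_integer_
  }

  variants <- data.frame(
    chrom = c(cfg$causal_variant$chrom,
              rep("chr1", cfg$n_background_variants)),
    pos = c(cfg$causal_variant$pos,
            seq_len(cfg$n_background_variants) * 1000L),
    ref = c(cfg$causal_variant$ref, rep("A", cfg$n_background_variants)),
    alt = c(cfg$causal_variant$alt, rep("G", cfg$n_background_variants)),
    stringsAsFactors = FALSE)
  variants$af_sim <- af
  gm <- genotype_matrix(variants, gt_ids, calls)
  truth <- list(causal_key = variant_keys(variants[1, , drop = FALSE]),
                carrier = carrier,
                affected_ids = ind$id[affected],
                background_af = af[-1],
                seed = cfg$seed)
  list(gm = gm, ped = ped, truth = truth)
}

#' Write simulated family data to VCF + PED + truth manifest
#'
#' @param sim a [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "family").
#' @return named vector of the paths written, invisibly.
#' @export
write_family_sim <- function(sim, dir, prefix = "family") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             ped = file.path(dir, paste0(prefix, ".ped")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_vcf(sim$gm, paths["vcf"])
  write_ped(sim$ped, paths["ped"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Configuration for RNA-seq count simulation
#'
#' Defaults emulate the study's expression design: 2 patient vs 4 control
#' fibroblast libraries, a log-normal baseline expression profile, common
#' NB dispersion 0.15, and a planted profibrotic-style DE signature of 40
#' up- and 30 down-regulated genes at |log2FC| = 2.
#'
#' @param n_genes gene count (default 5000).
#' @param n_patients,n_controls group sizes (default 2 and 4).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline-mean
#'   parameters (default 4.5 and 1.3, i.e. median ~90 counts).
#' @param phi common NB dispersion (default 0.15; 0 gives Poisson).
#' @param n_up,n_down planted DE gene counts (default 40 and 30).
#' @param de_log2fc planted absolute log2 fold change (default 2).
#' @param depth_factors per-sample relative sequencing depths (default all
#'   1; recycled to the sample count).
#' @param seed integer seed.
#' @return config list of class `famseg_counts_config`.
#' @export
counts_sim_config <- function(n_genes = 5000, n_patients = 2, n_controls = 4,
                              baseline_meanlog = 4.5, baseline_sdlog = 1.3,
                              phi = 0.15, n_up = 40, n_down = 30,
                              de_log2fc = 2, depth_factors = 1, seed = 1L) {
  stopifnot(n_patients >= 1, n_controls >= 1, phi >= 0,
            n_up + n_down <= n_genes)
  structure(list(n_genes = n_genes, n_patients = n_patients,
                 n_controls = n_controls,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, phi = phi,
                 n_up = n_up, n_down = n_down, de_log2fc = de_log2fc,
                 depth_factors = depth_factors, seed = as.integer(seed)),
            class = "famseg_counts_config")
}

#' Simulate a two-group NB count matrix with planted DE genes
#'
#' Baseline means are log-normal; planted DE genes multiply the patient
#' mean by `2^(+-de_log2fc)`; counts are NB with common dispersion `phi`
#' (Poisson at `phi = 0`), scaled by per-sample depth factors. Gene lengths
#' are drawn uniformly in 0.5-10 kb. Truth (planted gene ids and signs) is
#' returned as a manifest.
#'
#' @param cfg a [counts_sim_config()].
#' @return list: `cm` (a `famseg_counts`), `truth` (data frame `gene_id`,
#'   `sign`, `log2fc`).
#' @export
simulate_counts <- function(cfg) {
  set.seed(cfg$seed)
  ns <- cfg$n_patients + cfg$n_controls
  samples <- c(sprintf("patient_%d", seq_len(cfg$n_patients)),
               sprintf("control_%d", seq_len(cfg$n_controls)))
  group <- stats::setNames(rep(c("patient", "control"),
                               c(cfg$n_patients, cfg$n_controls)), samples)
  baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                            cfg$baseline_sdlog)
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  de_idx <- sample.int(cfg$n_genes, cfg$n_up + cfg$n_down)
  sign <- rep(c(1, -1), c(cfg$n_up, cfg$n_down))
  fold <- rep(1, cfg$n_genes)
  fold[de_idx] <- 2^(sign * cfg$de_log2fc)
  depth <- rep_len(cfg$depth_factors, ns)
  mu <- outer(baseline, depth)
  mu[, group == "patient"] <- mu[, group == "patient"] * fold
  counts <- if (cfg$phi == 0) {
    matrix(stats::rpois(length(mu), mu), nrow = cfg$n_genes)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$phi),
           nrow = cfg$n_genes)
  }
  colnames(counts) <- samples
  lengths <- round(stats::runif(cfg$n_genes, 500, 10000))
  cm <- count_matrix(counts, gene_ids, lengths, group)
  truth <- data.frame(gene_id = gene_ids[de_idx], sign = sign,
                      log2fc = sign * cfg$de_log2fc,
                      stringsAsFactors = FALSE)
  list(cm = cm, truth = truth)
}

#' Write a simulated count matrix as TSV + group CSV + truth manifest
#' @param sim a [simulate_counts()] result.
#' @param dir output directory.
#' @param prefix file-name prefix (default "counts").
#' @return named vector of written paths, invisibly.
#' @export
write_counts_sim <- function(sim, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- sim$cm
  paths <- c(counts = file.path(dir, paste0(prefix, ".tsv")),
             groups = file.path(dir, paste0(prefix, "_groups.csv")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  tab <- data.frame(gene_id = cm$gene_ids, length_bp = cm$gene_length_bp,
                    cm$counts, check.names = FALSE)
  utils::write.table(tab, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(data.frame(sample_id = cm$sample_ids,
                              group = unname(cm$group)),
                   paths["groups"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Simulate a qPCR Ct table
#'
#' Target Ct per sample is `base_ct - log2(group fold) + N(0, noise_sd)`;
#' the reference gene has no group effect (`ref_ct` plus the same noise
#' process). With zero noise, [ddct()] recovers the configured folds
#' exactly.
#'
#' @param target_fold_changes named numeric vector of expression folds per
#'   group, e.g. `c(Un = 1, Sc = 1, S1 = 4, S2 = 3)`; all > 0.
#' @param noise_sd Gaussian Ct noise (cycles; default 0.15).
#' @param n_per_group biological replicates per group (default 3).
#' @param n_technical technical replicates per measurement (default 2).
#' @param base_ct,ref_ct baseline target and reference Ct (default 24, 12).
#' @param target,reference gene names used in the table.
#' @param seed integer seed.
#' @return Ct data frame (`sample_id`, `group`, `gene`, `replicate`, `ct`).
#' @export
simulate_ct <- function(target_fold_changes, noise_sd = 0.15,
                        n_per_group = 3, n_technical = 2,
                        base_ct = 24, ref_ct = 12,
                        target = "COL1A1", reference = "18srRNA",
                        seed = 1L) {
  if (any(target_fold_changes <= 0)) {
    stop("simulate_ct(): fold changes must be > 0")
  }
  set.seed(seed)
  rows <- list()
  for (g in names(target_fold_changes)) {
    for (s in seq_len(n_per_group)) {
      sid <- sprintf("%s_%d", g, s)
      for (r in seq_len(n_technical)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = target, replicate = r,
          ct = base_ct - log2(target_fold_changes[[g]]) +
            stats::rnorm(1, 0, noise_sd),
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = reference, replicate = r,
          ct = ref_ct + stats::rnorm(1, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
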