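# Independent oracles used across tests. These deliberately take different
# code paths from the package implementation (density products instead of
# log-combinatorial weights; explicit graph traversal instead of the
# package's closure loop).

# Conditional two-group exact p by direct NB/Poisson density products.
# The nuisance mean mu0 cancels in the conditional distribution; evaluating
# at a fixed mu0 checks that the package's mean-free weights are right.
oracle_conditional_p <- function(ya, t, na, nb, phi, mu0 = 7.3) {
  if (t == 0) return(1)
  y <- 0:t
  if (phi == 0) {
    w <- stats::dpois(y, na * mu0) * stats::dpois(t - y, nb * mu0)
  } else {
    w <- stats::dnbinom(y, size = na / phi, mu = na * mu0) *
      stats::dnbinom(t - y, size = nb / phi, mu = nb * mu0)
  }
  p <- w / sum(w)
  min(1, 2 * min(sum(p[y <= ya]), sum(p[y >= ya])))
}

# Step-up FDR oracle computed literally from the sorted definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Carrier closure oracle: brute-force iteration over explicit child lists.
oracle_obligate <- function(ind, carriers) {
  status <- carriers
  inferred <- character(0)
  repeat {
    changed <- FALSE
    for (u in ind$id) {
      if (!is.na(status[u])) next
      for (j in which(!is.na(ind$father_id))) {
        co <- if (ind$father_id[j] == u) ind$mother_id[j] else
          if (ind$mother_id[j] == u) ind$father_id[j] else next
        if (isTRUE(status[ind$id[j]]) && isFALSE(status[co])) {
          status[u] <- TRUE
          inferred <- c(inferred, u)
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(unique(inferred))
  }
}

# Write a minimal trio PED file; returns its path.
write_trio_ped <- function(path = tempfile(fileext = ".ped")) {
  writeLines(c("FAM DAD 0 0 1 1",
               "FAM MOM 0 0 2 1",
               "FAM KID DAD MOM 1 2"), path)
  path
}

# Tiny handwritten VCF: 1 site, 3 samples, GT 0/0 0/1 1/1, plus one
# multi-allelic site.
write_tiny_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("chr1", "100", ".", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", ".", "C", "A,T", ".", "PASS", ".", "GT",
          "0/1", "1/2", "2/2", sep = "\t")), path)
  path
}
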