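make_cm <- function(counts, lengths = rep(1000, nrow(counts))) {
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  group <- stats::setNames(rep(c("patient", "control"),
                               c(1, ncol(counts) - 1)), colnames(counts))
  count_matrix(counts, paste0("g", seq_len(nrow(counts))), lengths, group)
}

test_that("cpm normalizes to a million per sample and fpkm adds length", {
  cm <- make_cm(cbind(c(5, 10, 85), c(2, 3, 5)))
  x <- cpm(cm)
  expect_equal(unname(x[, 1]), c(50000, 100000, 850000))
  expect_equal(unname(colSums(x)), c(1e6, 1e6))
  # all-zero gene is 0 everywhere
  cm0 <- make_cm(cbind(c(0, 10), c(0, 7)))
  expect_equal(unname(cpm(cm0)[1, ]), c(0, 0))
  # unit definition: count 10, 1 kb gene, 1e6 library -> 10
  counts <- cbind(c(10, 1e6 - 10), c(50, 50))
  cmf <- make_cm(counts, lengths = c(1000, 2000))
  expect_equal(unname(fpkm(cmf)[1, 1]), 10)
  # elementwise identity fpkm = cpm / length_kb; doubling length halves fpkm
  set.seed(1)
  counts <- matrix(rpois(60, 50), 10)
  lens <- sample(500:5000, 10)
  cm1 <- make_cm(counts, lens)
  cm2 <- make_cm(counts, 2 * lens)
  expect_equal(fpkm(cm1), cpm(cm1) / (lens / 1000), tolerance = 1e-12)
  expect_equal(fpkm(cm2), fpkm(cm1) / 2, tolerance = 1e-12)
  expect_equal(cpm(cm2), cpm(cm1), tolerance = 1e-12)
  # column conservation on a random matrix
  expect_equal(unname(colSums(cpm(cm1))), rep(1e6, 6), tolerance = 1e-9)
})

test_that("dispersion estimator recovers Poisson and NB truth", {
  sim0 <- simulate_counts(counts_sim_config(n_genes = 2000, phi = 0,
                                            n_up = 0, n_down = 0, seed = 5))
  expect_lte(estimate_common_dispersion(sim0$cm), 0.05)
  sim2 <- simulate_counts(counts_sim_config(n_genes = 2000, phi = 0.2,
                                            n_up = 0, n_down = 0, seed = 6))
  phi_hat <- estimate_common_dispersion(sim2$cm)
  expect_gte(phi_hat, 0.1)
  expect_lte(phi_hat, 0.3)
  # cross-check the magnitude against an established qCML estimator
  if (requireNamespace("edgeR", quietly = TRUE)) {
    d <- edgeR::estimateCommonDisp(edgeR::DGEList(
      counts = sim2$cm$counts, group = factor(sim2$cm$group)))
    expect_lt(abs(phi_hat - d$common.dispersion), 0.1)
  }
  # single sample per group is inestimable: fallback with warning
  cm1 <- count_matrix(cbind(a = c(5L, 9L), b = c(7L, 3L)), c("g1", "g2"),
                      c(1000, 1000), c(a = "patient", b = "control"))
  expect_warning(phi_f <- estimate_common_dispersion(cm1), "fallback")
  expect_equal(phi_f, 0.1)
})

test_that("conditional exact test matches density-product enumeration oracle", {
  for (phi in c(0, 0.1, 0.5)) {
    for (t in c(1, 3, 10, 57)) {
      for (ya in unique(c(0, 1, floor(t / 3), t))) {
        expect_equal(nb_conditional_p(ya, t, 2, 4, phi),
                     oracle_conditional_p(ya, t, 2, 4, phi),
                     tolerance = 1e-10,
                     label = sprintf("phi=%g t=%d ya=%d", phi, t, ya))
      }
    }
  }
})

test_that("exact test handles symmetric splits, extreme splits and zero totals", {
  # perfectly symmetric split with equal group sizes: p = 1
  expect_equal(nb_conditional_p(5, 10, 3, 3, 0.1), 1)
  # 10 vs 0 split, Poisson, equal library mass: doubled binomial tail
  expect_equal(nb_conditional_p(10, 10, 1, 1, 0), 2 * (1 / 1024)[1],
               tolerance = 1e-12)
  expect_equal(nb_conditional_p(0, 0, 2, 4, 0.2), 1)
  # via the matrix interface with equal libraries
  counts <- cbind(p1 = c(10L, 6L), c1 = c(0L, 16L))
  cm <- count_matrix(counts, c("g1", "g2"), c(1000, 1000),
                     c(p1 = "patient", c1 = "control"))
  expect_equal(unname(exact_test(cm, 0)[1]), 2 / 1024, tolerance = 1e-9)
})

test_that("type-I error of the exact test is calibrated on null NB data", {
  sim <- simulate_counts(counts_sim_config(n_genes = 2000, phi = 0.15,
                                           n_up = 0, n_down = 0, seed = 9))
  p <- exact_test(sim$cm, 0.15)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("bh_adjust reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  # monotone over sorted p, and q >= p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
})

test_that("de_filter applies both FDR and fold thresholds", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(0.9, -1.2, 2.1, 1.5),
                    cpm_mean = 10, p = c(0.001, 0.002, 0.001, 0.2),
                    fdr = c(0.04, 0.04, 0.01, 0.4),
                    stringsAsFactors = FALSE)
  lists <- de_filter(res, alpha = 0.05, lfc_min = 1)
  expect_equal(lists$up, "c")      # d fails FDR, a fails fold
  expect_equal(lists$down, "b")
})

test_that("top_n ranks by fold change with FDR then lexical tie-breaks", {
  res <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
                    log2fc = c(3, 2, 2, -2, -3, 1.5),
                    cpm_mean = 10, p = 0.001,
                    fdr = c(0.01, 0.02, 0.001, 0.01, 0.01, 0.01),
                    stringsAsFactors = FALSE)
  top <- top_n_by_direction(res, n = 2)
  expect_equal(top$up$gene_id, c("g1", "g3"))   # tie at 2: smaller FDR wins
  expect_equal(top$down$gene_id, c("g5", "g4"))
  # fewer available than requested
  top5 <- top_n_by_direction(res, n = 100)
  expect_equal(nrow(top5$up), 4)
  expect_equal(nrow(top5$down), 2)
})

test_that("heatmap row normalization conserves unit row means", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0, 0))
  hm <- heatmap_matrix(m)
  expect_equal(unname(hm["a", ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(hm["b", ]), c(1, 1, 1))
  expect_equal(unname(hm["c", ]), c(0, 0, 0))
  expect_equal(attr(hm, "zero_mean"), "c")
  set.seed(3)
  r <- matrix(rexp(50) + 0.1, 10,
              dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(unname(rowMeans(heatmap_matrix(r))), rep(1, 10),
               tolerance = 1e-12)
})

test_that("planted DE signature is recovered with controlled error", {
  # power >= 0.5 at the 5000-gene default scale; observed FDR <= 0.1
  sim <- simulate_counts(counts_sim_config(seed = 4))
  rep <- run_expression(sim$cm)
  truth_up <- sim$truth$gene_id[sim$truth$sign > 0]
  truth_dn <- sim$truth$gene_id[sim$truth$sign < 0]
  tp <- sum(rep$up %in% truth_up) + sum(rep$down %in% truth_dn)
  called <- length(rep$up) + length(rep$down)
  expect_gte(tp / nrow(sim$truth), 0.5)           # power
  expect_lte(1 - tp / max(1, called), 0.1)        # observed FDR
})
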