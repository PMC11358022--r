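test_that("gene collapsing takes the median over a gene's features", {
  v <- matrix(c(1, 3, 100,
                2, 4, 6), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  meta <- data.frame(feature_id = c("p1", "p2", "p3"),
                     gene_symbol = c("G1", "G1", "G1"),
                     stringsAsFactors = FALSE)
  out <- collapse_to_gene(quant_matrix(v, "protein"), meta)
  expect_equal(out["G1", "s1"], 3)     # median of (1, 3, 100)
  expect_equal(out["G1", "s2"], 4)
  # single-feature genes pass through; collapsing is idempotent
  meta2 <- data.frame(feature_id = c("p1", "p2", "p3"),
                      gene_symbol = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  out2 <- collapse_to_gene(quant_matrix(v, "protein"), meta2)
  expect_equal(unname(out2[order(rownames(out2)), ]), unname(v),
               ignore_attr = TRUE)
  meta3 <- data.frame(feature_id = rownames(out2),
                      gene_symbol = rownames(out2),
                      stringsAsFactors = FALSE)
  expect_equal(collapse_to_gene(out2, meta3), out2)
  # all-missing cells stay missing
  v4 <- v; v4[c(1, 2), 1] <- NA
  meta4 <- data.frame(feature_id = rownames(v), gene_symbol = "G",
                      stringsAsFactors = FALSE)
  out4 <- collapse_to_gene(quant_matrix(v4, "protein"), meta4)
  expect_equal(out4["G", "s1"], 100)
})

test_that("pairwise correlation respects the minimum-pair rule", {
  set.seed(30)
  xs <- matrix(rnorm(24), 2, 12,
               dimnames = list(c("G1", "G2"), paste0("s", 1:12)))
  ys <- 2 * xs + 1
  ys["G2", 1:3] <- NA  # 9 complete pairs -> excluded
  res <- correlate_pairs(make_qm(xs, features = rownames(xs),
                                 samples = colnames(xs)),
                         make_qm(ys, features = rownames(ys),
                                 samples = colnames(ys)))
  expect_equal(res$r[res$gene_symbol == "G1"], 1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$gene_symbol == "G2"]))
  expect_equal(res$n_pairs[res$gene_symbol == "G2"], 9L)
})

test_that("pairwise correlation matches a brute-force Pearson oracle", {
  set.seed(31)
  x <- random_qm(50, 20, miss_frac = 0.2, seed = 31)
  y <- random_qm(50, 20, miss_frac = 0.2, seed = 32)
  res <- correlate_pairs(x, y, min_pairs = 5)
  for (i in seq_len(nrow(res))) {
    g <- res$gene_symbol[i]
    ok <- !is.na(x[g, ]) & !is.na(y[g, ])
    if (sum(ok) >= 5) {
      expect_equal(res$r[i], cor(x[g, ok], y[g, ok]), tolerance = 1e-12)
    } else {
      expect_true(is.na(res$r[i]))
    }
  }
})

test_that("buffering score follows its defining formula", {
  set.seed(33)
  cn <- sample(1:4, 12, replace = TRUE)
  rna <- 0.5 * cn + rnorm(12, sd = 0.3)
  prot <- 0.1 * cn + rnorm(12, sd = 0.5)
  oracle <- (cor(rna, cn) - cor(prot, cn)) * abs(mean(cn) - 2)
  expect_equal(buffering_score(rna, prot, cn), oracle,
               tolerance = 1e-12)
  # mean CN exactly 2 zeroes the score regardless of correlations
  cn2 <- rep(c(1, 3), 6)
  expect_equal(buffering_score(rna, prot, cn2), 0, tolerance = 1e-12)
  # RNA tracking CN perfectly with independent protein gives ~ |CNbar-2|
  cn3 <- c(2, 2, 3, 3, 3, 4, 3, 3, 2, 4, 3, 3)
  rna3 <- cn3
  set.seed(34); prot3 <- rnorm(12)
  sc <- buffering_score(rna3, prot3, cn3)
  expect_equal(sc, (1 - cor(prot3, cn3)) * abs(mean(cn3) - 2),
               tolerance = 1e-12)
  # undefined cases
  expect_true(is.na(buffering_score(rna, prot, rep(2, 12))))
  expect_true(is.na(buffering_score(rna[1:5], prot[1:5], cn[1:5])))
})

test_that("buffering score is Pearson-invariant and antisymmetric", {
  set.seed(35)
  cn <- sample(2:4, 15, replace = TRUE)
  rna <- rnorm(15); prot <- rnorm(15)
  base <- buffering_score(rna, prot, cn)
  expect_equal(buffering_score(3 * rna - 7, 0.5 * prot + 2, cn), base,
               tolerance = 1e-12)
  expect_equal(buffering_score(prot, rna, cn), -base, tolerance = 1e-12)
})

test_that("buffering table matches per-gene brute force", {
  co <- shared_cohort()
  genes <- rownames(co$rna)[1:30]
  samples <- co$clinical$sample_id[co$clinical$stage == "MM"]
  cn <- co$band_cn[co$ground_truth$gene_band[genes], samples]
  rownames(cn) <- genes
  cn <- cn + 0  # integer -> double
  tab <- buffering_table(co$rna[genes, samples],
                         co$protein[genes, samples],
                         quant_matrix(cn, "score"))
  i <- which(!is.na(tab$buffering_score))[1]
  g <- tab$gene_symbol[i]
  rv <- co$rna[g, samples]; pv <- co$protein[g, samples]
  cv <- cn[g, ]
  ok <- !is.na(rv) & !is.na(pv) & !is.na(cv)
  expect_equal(tab$buffering_score[i],
               (cor(rv[ok], cv[ok]) - cor(pv[ok], cv[ok])) *
                 abs(mean(cv[ok]) - 2), tolerance = 1e-12)
})

test_that("copy-number rounding applies the diploid-vicinity rule", {
  # exhaustive check of the stated decision table
  cases <- rbind(
    c(2.30, 2), c(1.70, 2), c(2.35, 2), c(1.65, 2),  # inside vicinity
    c(2.36, 3), c(1.64, 1), c(1.60, 1), c(2.9, 3),   # called away from 2
    c(3.60, 4), c(3.4, 3), c(0.4, 0), c(0.6, 1),     # plain rounding
    c(4.5, 5), c(0.0, 0), c(3.0, 3), c(1.0, 1))
  expect_equal(round_cn(cases[, 1]), as.integer(cases[, 2]))
  expect_error(round_cn(-0.1), ">= 0")
  # plain mode is ordinary half-up rounding
  expect_equal(round_cn(c(2.36, 1.6, 2.5), plain = TRUE), c(2L, 2L, 3L))
})

test_that("band calls take the most prevalent bin and honour min_bins", {
  band_map <- data.frame(chrom = "1",
                         start = c(1, 3000001),
                         end = c(3000000, 8000000),
                         band = c("1p11", "1q11"),
                         stringsAsFactors = FALSE)
  mk_bins <- function(cns, chrom = "1", offset = 0) {
    n <- length(cns)
    data.frame(chrom = chrom,
               start = offset + (seq_len(n) - 1) * 1e6,
               end = offset + seq_len(n) * 1e6, cn = cns,
               stringsAsFactors = FALSE)
  }
  # bins rounding to (2, 2, 3) -> 2 is most prevalent
  res <- bins_to_bands(mk_bins(c(2.1, 1.9, 3.2)), band_map)
  expect_equal(res$cn[res$band == "1p11"], 2L)
  # only 2 valid bins with min_bins = 3 -> NA
  res2 <- bins_to_bands(mk_bins(c(2.0, 2.0, NA)), band_map)
  expect_true(is.na(res2$cn[res2$band == "1p11"]))
  expect_equal(bins_to_bands(mk_bins(c(2, 2, NA)), band_map,
                             min_bins = 2)$cn[1], 2L)
  # tie (2, 2, 3, 3) resolves toward diploid
  bins_tie <- rbind(mk_bins(c(2.0, 2.1), offset = 3000000),
                    mk_bins(c(3.1, 2.9), offset = 5000000),
                    mk_bins(NA_real_, offset = 7000000))
  res3 <- bins_to_bands(bins_tie, band_map)
  expect_equal(res3$cn[res3$band == "1q11"], 2L)
  # a bin outside every band warns and is skipped
  stray <- mk_bins(c(2, 2, 2, 5), chrom = "9")
  expect_warning(res4 <- bins_to_bands(rbind(mk_bins(c(2, 2, 2)), stray),
                                       band_map), "no band")
  expect_equal(res4$cn[1], 2L)
  # every band call is one of its rounded bin values or NA
  set.seed(36)
  rb <- mk_bins(runif(6, 0.5, 4.5))
  res5 <- bins_to_bands(rb, band_map)
  calls <- round_cn(rb$cn)
  expect_true(all(is.na(res5$cn) | res5$cn %in% calls))
})
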