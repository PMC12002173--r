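toy_catalog <- function() {
  data.frame(
    gene = c(rep("G1", 7), rep("G2", 2)),
    position = c(10, 20, 30, 40, 50, 60, 70, 5, 5),
    consequence = c(rep("synonymous", 5), "missense", "nonsense",
                    "missense", "frameshift"),
    sample = paste0("s", 1:9),
    stringsAsFactors = FALSE
  )
}

test_that("burden rates are exact count arithmetic per 1,000 aa", {
  lens <- c(G1 = 500L, G2 = 100L)
  b <- burden_rates(toy_catalog(), lens)
  expect_equal(b$syn_rate[b$gene == "G1"], 5 * 1000 / 500)  # 10 per 1,000 aa
  expect_equal(b$nonsyn_rate[b$gene == "G1"], 2 * 1000 / 500)
  expect_equal(b$trunc_count[b$gene == "G2"], 1L)

  # conservation: rates * length / 1000 give back the exact integer counts
  expect_equal(sum(round(b$syn_rate * b$length_aa / 1000) +
                     round(b$nonsyn_rate * b$length_aa / 1000)),
               nrow(toy_catalog()))

  # empty catalog: all-zero rates for listed genes
  empty <- toy_catalog()[0, ]
  b0 <- burden_rates(empty, lens)
  expect_true(all(b0$syn_rate == 0) && all(b0$nonsyn_rate == 0))

  expect_error(burden_rates(toy_catalog(), c(G1 = 500L)), "length")
  bad <- toy_catalog(); bad$consequence[1] <- "weird"
  expect_error(burden_rates(bad, lens), "unknown consequence")
  oob <- toy_catalog(); oob$position[1] <- 501
  expect_error(burden_rates(oob, c(G1 = 500L, G2 = 100L)), "outside")
})

test_that("hotspot detection follows the binomial tail and count rule", {
  lens <- c(G = 400L)
  # one record per codon: k = 1 < 3, never a hotspot
  unif <- data.frame(gene = "G", position = 1:50, consequence = "missense",
                     sample = paste0("s", 1:50), stringsAsFactors = FALSE)
  expect_equal(nrow(detect_hotspots(unif, "G", lens)), 0L)

  # 50 of 100 missense records on one codon of a 400-aa gene
  conc <- data.frame(gene = "G",
                     position = c(rep(200L, 50), sample.int(400, 50)),
                     consequence = "missense",
                     sample = paste0("s", 1:100), stringsAsFactors = FALSE)
  hs <- detect_hotspots(conc, "G", lens)
  expect_true(200L %in% hs$codon)
  # p-value equals the independent tail summation
  expect_equal(hs$p[hs$codon == 200L], binom_tail_sum(50, 100, 1 / 400),
               tolerance = 1e-12)
  expect_true(all(diff(hs$codon) > 0))  # unique and sorted

  expect_error(detect_hotspots(unif, "NOPE", lens), "not found")
})

test_that("cnv skew arithmetic and vocabulary checks", {
  calls <- data.frame(sample = paste0("s", 1:100),
                      call = c(rep("loss", 8), rep("gain", 2), rep("neutral", 90)),
                      stringsAsFactors = FALSE)
  sk <- cnv_skew(calls)
  expect_equal(sk$skew, -0.6)
  expect_equal(sk$cnl_freq, 0.08)

  allneutral <- data.frame(sample = "s1", call = "neutral")
  expect_equal(cnv_skew(allneutral), list(cnl_freq = 0, cng_freq = 0, skew = 0))

  expect_error(cnv_skew(calls[0, ]), "empty")
  bad <- calls; bad$call[1] <- "amp"
  expect_error(cnv_skew(bad), "unknown CNV")
})

test_that("gene classification rules and precedence behave as documented", {
  mk_burden <- function(trunc_frac, nonsyn = 50L) {
    data.frame(gene = "G", length_aa = 500L, syn_count = 0L,
               nonsyn_count = nonsyn, trunc_count = round(trunc_frac * nonsyn),
               syn_rate = 0, nonsyn_rate = nonsyn * 2,
               trunc_fraction = trunc_frac)
  }
  no_hs <- data.frame(codon = integer(0), count = integer(0),
                      p = numeric(0), q = numeric(0))
  one_hs <- data.frame(codon = 10L, count = 20L, p = 1e-20, q = 1e-18)

  expect_equal(classify_gene(mk_burden(0.5), no_hs,
                             list(cnl_freq = .3, cng_freq = 0, skew = -1))$class,
               "tsg_like")
  expect_equal(classify_gene(mk_burden(0), one_hs,
                             list(cnl_freq = 0, cng_freq = .3, skew = 1))$class,
               "oncogene_like")
  expect_equal(classify_gene(mk_burden(0), no_hs,
                             list(cnl_freq = 0, cng_freq = 0, skew = 0))$class,
               "neutral_like")
  # zero-mutation gene is vacuously neutral
  expect_equal(classify_gene(mk_burden(0, nonsyn = 0L), no_hs,
                             list(cnl_freq = 0, cng_freq = 0, skew = 0))$class,
               "neutral_like")
  # both rules firing: oncogene rule wins and the conflict is flagged
  both <- classify_gene(mk_burden(0.5), one_hs,
                        list(cnl_freq = .3, cng_freq = .4, skew = 0.5))
  expect_equal(both$class, "oncogene_like")
  expect_false(both$conflict)  # tsg also needs negative skew here, so no conflict
})

test_that("simulated gene classes are recovered by the burden report", {
  specs <- default_gene_specs(10, seed = 3)
  sim <- sim_mutation_catalog(specs, 200, 4)
  rep <- burden_report(sim$catalog, sim$cnv, sim$gene_lengths)
  truth <- paste0(specs$class, "_like")
  acc <- mean(rep$class == truth)
  expect_gte(acc, 0.9)
  # record-count conservation across the whole report
  expect_equal(sum(rep$syn_count + rep$nonsyn_count), nrow(sim$catalog))
})

test_that("catalog TSV reader validates on the way in", {
  lens <- c(G1 = 500L, G2 = 100L)
  tmp <- tempfile(fileext = ".tsv")
  write.table(toy_catalog(), tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_mutation_catalog(tmp, lens)
  expect_equal(nrow(back), 9L)
  bad <- toy_catalog(); bad$consequence[2] <- "splice"
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_catalog(tmp, lens), "unknown consequence")
})
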