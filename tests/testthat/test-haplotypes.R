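test_that("promoter-type classification follows the triplet code", {
  expect_equal(classify_promoter_type(c("C", "G", "C")), "CGC")
  expect_equal(classify_promoter_type(c("T", "G", "T")), "TGT")
  expect_equal(classify_promoter_type(c("T", "C", "T")), "TCT")
  expect_equal(classify_promoter_type(c("C", "G", "T")), "CGT")
  expect_equal(classify_promoter_type(c("C", "N", "T")), "OTHER")
  expect_equal(classify_promoter_type(c("A", "G", "T")), "OTHER")
  expect_error(classify_promoter_type(c("C", "G")), "exactly 3")
  expect_error(classify_promoter_type(c("C", "G", "X")), "\\{A,C,G,T,N\\}")
  m <- rbind(c("T", "G", "T"), c("C", "G", "C"))
  expect_equal(classify_promoter_type(m), c("TGT", "CGC"))
})

test_that("MAF filtering uses the panel-wide frequency with N excluded", {
  # 500 haplotypes: 2 carriers -> MAF 0.004, dropped at 0.005
  n <- 500
  alleles <- matrix("A", n, 3)
  alleles[1:2, 1] <- "G"      # MAF 0.004
  alleles[1:10, 2] <- "G"     # MAF 0.02
  alleles[1:3, 3] <- "G"      # 3/500 = 0.006
  rownames(alleles) <- as.vector(rbind(
    paste0("S", 1:(n / 2), ".0"), paste0("S", 1:(n / 2), ".1")))
  panel <- toy_panel(alleles, c(120, 200, 300), 100, 400)
  kept <- filter_by_maf(panel, 0.005)
  expect_equal(kept$positions, c(200L, 300L))
  expect_identical(filter_by_maf(panel, 0)$alleles, panel$alleles)
  # N haplotypes leave the denominator: 2 alt of (500 - 100) = 0.005, kept
  alleles[11:110, 1] <- "N"
  panel2 <- toy_panel(alleles, c(120, 200, 300), 100, 400)
  expect_true(120 %in% filter_by_maf(panel2, 0.005)$positions)
})

test_that("MAF filtering agrees with a brute-force per-site recount", {
  set.seed(31)
  n <- 60
  alleles <- matrix(sample(c("A", "G", "N"), n * 20, TRUE,
                           prob = c(0.8, 0.15, 0.05)), n, 20,
                    dimnames = list(as.vector(rbind(
                      paste0("S", 1:(n / 2), ".0"),
                      paste0("S", 1:(n / 2), ".1"))), NULL))
  panel <- toy_panel(alleles, seq(101, 120), 100, 400)
  expected_keep <- vapply(seq_len(20), function(j) {
    col <- alleles[, j][alleles[, j] != "N"]
    tab <- sort(table(col), decreasing = TRUE)
    maf <- if (length(tab) < 2) 0 else 1 - tab[[1]] / sum(tab)
    maf >= 0.1
  }, logical(1))
  expect_equal(filter_by_maf(panel, 0.1)$positions,
               panel$positions[expected_keep])
})

test_that("haplotype enumeration partitions sequences and honours first-carrier naming", {
  alleles <- matrix(c("A", "C",
                      "A", "C",
                      "A", "C",
                      "A", "C"), 4, 2, byrow = TRUE,
                    dimnames = list(c("S1.0", "S1.1", "S2.0", "S2.1"),
                                    NULL))
  panel <- toy_panel(alleles, c(120, 200), 100, 400)
  g <- enumerate_haplotypes(panel)
  expect_equal(unique(g$group), "S1.0")
  expect_equal(nrow(g), 4L)

  alleles2 <- matrix(c("A", "C", "G", "T"), 4, 1,
                     dimnames = list(rownames(alleles), NULL))
  g2 <- enumerate_haplotypes(toy_panel(alleles2, 120, 100, 400))
  expect_equal(length(unique(g2$group)), 4L)

  # groups partition the panel: disjoint and exhaustive
  expect_setequal(g2$haplotype, rownames(alleles2))
  expect_false(anyDuplicated(g2$haplotype) > 0)
})

test_that("template-built panels recover the planted group structure", {
  cfg <- sim_config(seed = 9,
                    pops = tibble::tibble(subpop = "YRI", metapop = "AFR",
                                          n_samples = 30L),
                    type_freqs = list(AFR = c(TGT = 0.4, TCT = 0.4,
                                              CGC = 0.2)),
                    params = evo_params(mu = 1e-20),  # no mutations
                    recomb_expected = 0)
  sim <- simulate_panel(cfg)
  g <- enumerate_haplotypes(sim$panel)
  # with no mutations, sequences differ only at the promoter triplet
  realized_types <- unique(sim$truth$assignments$promoter_type)
  expect_equal(length(unique(g$group)), length(realized_types))
  counts <- table(sim$truth$assignments$promoter_type)
  gg <- dplyr::count(dplyr::left_join(g, sim$truth$assignments[
    , c("haplotype", "promoter_type")], by = "haplotype"),
    group, promoter_type)
  expect_equal(sort(gg$n), sort(as.integer(counts)))
})

test_that("frequency tables reproduce printed-count arithmetic and aggregate consistently", {
  # AFR TGT 612/1322 = 46.3%
  labels <- tibble::tibble(
    metapop = rep("AFR", 1322),
    subpop = rep(c("YRI", "LWK"), c(700, 622)),
    promoter_type = rep(c("TGT", "TCT", "CGT", "CGC", "OTHER"),
                        c(612, 625, 46, 11, 28)))
  ft <- frequency_table(labels, overall = FALSE)
  expect_equal(ft$frequency[ft$category == "TGT"], 612 / 1322,
               tolerance = 1e-12)
  expect_equal(round(100 * ft$frequency[ft$category == "TGT"], 1), 46.3)
  expect_equal(unique(ft$total), 1322L)
  # counts (incl. OTHER) sum to the population total
  expect_equal(sum(ft$n), 1322L)
  # metapop counts equal the aggregation of subpop counts
  ft_sub <- frequency_table(labels, level = "subpop", overall = FALSE)
  agg <- dplyr::summarise(dplyr::group_by(ft_sub, category),
                          n = sum(n))
  expect_equal(dplyr::arrange(agg, category)$n,
               dplyr::arrange(ft[, c("category", "n")], category)$n)
})

test_that("one-population one-category tables give frequency 1", {
  labels <- tibble::tibble(metapop = "EUR", subpop = "CEU",
                           promoter_type = rep("TCT", 10))
  ft <- frequency_table(labels, overall = FALSE)
  expect_equal(ft$frequency, 1)
})

test_that("fold differences divide frequencies and refuse a zero denominator", {
  expect_equal(round(fold_difference(0.963, 0.473), 2), 2.04)
  expect_equal(round(fold_difference(0.800, 0.473), 2), 1.69)
  expect_equal(fold_difference(0.25, 0.25), 1)
  expect_error(fold_difference(0.1, 0), "denominator")
})

test_that("nucleotide diversity matches its definition and a closed-form oracle", {
  a <- matrix(rep("A", 200), 2, 100)
  expect_equal(nucleotide_diversity(a), 0)
  a[2, 1] <- "G"
  expect_equal(nucleotide_diversity(a), 0.01)
  expect_error(nucleotide_diversity(a[1, , drop = FALSE]), ">= 2")
  # without missing data, mean pairwise difference per site equals the
  # per-site heterozygosity formula sum 2*x*(n-x)/(n*(n-1)) / L
  set.seed(17)
  m <- matrix(sample(c("A", "G"), 12 * 50, TRUE, prob = c(0.8, 0.2)),
              12, 50)
  n <- nrow(m)
  per_site <- apply(m, 2, function(col) {
    x <- sum(col == "G")
    2 * x * (n - x) / (n * (n - 1))
  })
  expect_equal(nucleotide_diversity(m), sum(per_site) / 50,
               tolerance = 1e-12)
  # N handling: the N-bearing site is dropped pairwise
  m2 <- rbind(c("A", "A"), c("N", "A"), c("G", "A"))
  # pairs: (1,2) compares 1 site 0 diff; (1,3) 2 sites 1 diff; (2,3) 1 site 0
  expect_equal(nucleotide_diversity(m2), mean(c(0, 0.5, 0)))
})

test_that("proportion comparison is an exact two-sided test", {
  expect_equal(compare_proportions(5, 10, 5, 10)$p_value, 1)
  expect_lt(compare_proportions(0, 10, 10, 10)$p_value, 0.001)
  # full hypergeometric enumeration oracle
  p_oracle <- function(a, na, b, nb) {
    k <- a + b
    support <- max(0, k - nb):min(na, k)
    probs <- stats::dhyper(support, na, nb, k)
    obs <- stats::dhyper(a, na, nb, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  for (case in list(c(3, 10, 4, 12), c(2, 8, 7, 9), c(0, 5, 3, 7))) {
    expect_equal(
      compare_proportions(case[1], case[2], case[3], case[4])$p_value,
      p_oracle(case[1], case[2], case[3], case[4]),
      tolerance = 1e-9)
  }
})

test_that("promoter-type counts sum to twice the sample count per population", {
  cfg <- sim_config(seed = 13,
                    pops = tibble::tibble(subpop = c("YRI", "CHB"),
                                          metapop = c("AFR", "EAS"),
                                          n_samples = c(12L, 9L)),
                    type_freqs = list(AFR = c(TGT = 0.5, TCT = 0.5),
                                      EAS = c(TCT = 0.5, CGC = 0.5)))
  sim <- simulate_panel(cfg)
  types <- panel_promoter_types(sim$panel, promoter_ids)
  ft <- frequency_table(types, overall = FALSE)
  totals <- dplyr::distinct(ft[, c("population", "total")])
  expect_equal(totals$total[totals$population == "AFR"], 24L)
  expect_equal(totals$total[totals$population == "EAS"], 18L)
})
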