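test_that("identical seeds give byte-identical simulations", {
  cfg <- function() screen_sim_config(21, 0.05)
  s1 <- plant_introgression(simulate_panel(cfg()))
  s2 <- plant_introgression(simulate_panel(cfg()))
  expect_identical(s1$panel$alleles, s2$panel$alleles)
  expect_identical(s1$panel$positions, s2$panel$positions)
  expect_identical(s1$truth$assignments, s2$truth$assignments)
  expect_identical(s1$truth$tracts, s2$truth$tracts)
  expect_identical(synthetic_age_table(s1), synthetic_age_table(s2))
  s3 <- simulate_panel(screen_sim_config(22, 0.05))
  expect_false(identical(s1$panel$alleles, s3$panel$alleles))
})

test_that("without mutation or recombination only the planted templates remain", {
  cfg <- sim_config(seed = 2,
                    pops = tibble::tibble(subpop = "YRI", metapop = "AFR",
                                          n_samples = 20L),
                    type_freqs = list(AFR = c(TGT = 0.4, TCT = 0.4,
                                              CGC = 0.2)),
                    params = evo_params(mu = 1e-20),
                    recomb_expected = 0)
  sim <- simulate_panel(cfg)
  n_distinct <- length(unique(apply(sim$panel$alleles, 1, paste0,
                                    collapse = "")))
  expect_equal(n_distinct,
               length(unique(sim$truth$assignments$promoter_type)))
})

test_that("realized promoter-type counts equal the recorded truth draws", {
  cfg <- screen_sim_config(23, 0)
  sim <- simulate_panel(cfg)
  types <- panel_promoter_types(sim$panel, promoter_ids)
  merged <- dplyr::inner_join(types,
                              sim$truth$assignments[
                                , c("haplotype", "promoter_type")],
                              by = "haplotype",
                              suffix = c("_obs", "_truth"))
  expect_equal(merged$promoter_type_obs, merged$promoter_type_truth)
})

test_that("between-type divergence matches 2 t mu L within Monte-Carlo error", {
  # cross-type pairs coalesce at the root: expected diffs 2 * t_root * mu * L
  mu <- 0.5e-9
  t_root <- 400000
  Lw <- 40000
  expected <- 2 * t_root * mu * Lw
  means <- vapply(1:15, function(s) {
    cfg <- sim_config(seed = 300 + s,
                      pops = tibble::tibble(subpop = "YRI",
                                            metapop = "AFR",
                                            n_samples = 6L),
                      type_freqs = list(AFR = c(TGT = 0.5, TCT = 0.5)),
                      t_root = t_root, recomb_expected = 0)
    sim <- simulate_panel(cfg)
    tt <- sim$truth$assignments
    keep <- !sim$panel$site_ids %in% promoter_ids  # exclude planted triplet
    a <- sim$panel$alleles[tt$haplotype[tt$promoter_type == "TGT"], keep,
                           drop = FALSE]
    b <- sim$panel$alleles[tt$haplotype[tt$promoter_type == "TCT"], keep,
                           drop = FALSE]
    skip_if(nrow(a) < 1 || nrow(b) < 1)
    d <- 0; np <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      d <- d + sum(a[i, ] != b[j, ])
      np <- np + 1
    }
    d / np
  }, numeric(1))
  # each pair is Poisson(expected); seeds are independent replicates
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 0.5)
})

test_that("introgression planting respects frequency zero and tract geometry", {
  cfg0 <- screen_sim_config(25, 0)
  sim0 <- simulate_panel(cfg0)
  planted0 <- plant_introgression(sim0)
  expect_identical(planted0$panel$alleles[, planted0$panel$site_ids %in%
                                            sim0$panel$site_ids],
                   sim0$panel$alleles)
  expect_equal(length(planted0$truth$carriers), 0L)

  cfg <- screen_sim_config(26, 0.10)
  sim <- plant_introgression(simulate_panel(cfg))
  tr <- sim$truth$tracts
  skip_if(nrow(tr) == 0)
  span <- range(cfg$promoter_positions)
  expect_true(all(tr$start <= span[1] & tr$end >= span[2]))
  expect_true(all(tr$start >= cfg$window$start &
                    tr$end <= cfg$window$end))
  # carriers carry the donor promoter type
  types <- panel_promoter_types(sim$panel, promoter_ids)
  expect_true(all(types$promoter_type[types$haplotype %in%
                                        sim$truth$carriers] == "CGT"))
})

test_that("planted tract lengths follow the exponential introgression model", {
  # pool tract draws across seeds; mean should approach g/(r t) = 17576 bp
  # (clipping to the window shortens, promoter-span flooring lengthens)
  lens <- unlist(lapply(1:8, function(s) {
    cfg <- screen_sim_config(400 + s, 0.25)
    plant_introgression(simulate_panel(cfg))$truth$tracts$length_bp
  }))
  expect_gt(length(lens), 30)
  target <- 29 / (3.3e-8 * 50000)
  expect_gt(mean(lens), 0.55 * target)
  expect_lt(mean(lens), 1.25 * target)
})

test_that("carrier-noncarrier divergence sits in the 2 t_split mu L Poisson band", {
  expected <- 2 * 600000 * 0.5e-9 * 18000  # over the 18-kb core
  obs <- vapply(1:6, function(s) {
    cfg <- screen_sim_config(500 + s, 0.10)
    sim <- plant_introgression(simulate_panel(cfg))
    core <- extract_region(sim$panel, cfg$core)
    carr <- sim$truth$carriers
    non <- setdiff(rownames(core$alleles), carr)
    d <- 0; np <- 0
    for (h in carr) for (g in sample(non, 20)) {
      d <- d + sum(core$alleles[h, ] != core$alleles[g, ]); np <- np + 1
    }
    d / np
  }, numeric(1))
  expect_lt(abs(mean(obs) - expected), 3 * sqrt(expected))
})

test_that("archaic diploid simulation honours masking, homozygosity, and truth phases", {
  cfg <- screen_sim_config(27, 0.05)
  sim <- plant_introgression(simulate_panel(cfg))
  arc <- simulate_archaic_diploids(sim, n_mask_rate = 0)
  ref <- arc$diploids$Altai
  expect_false(any(ref$geno[1, ] != ref$geno[2, ]))
  # heterozygous-site counts equal truth phase differences exactly
  for (s in c("Vindija", "Chagyrskaya", "Denisovan")) {
    dip <- arc$diploids[[s]]
    t1 <- arc$truth$haplotypes[[paste0(s, "-1")]]
    t2 <- arc$truth$haplotypes[[paste0(s, "-2")]]
    het_obs <- sum(dip$geno[1, ] != dip$geno[2, ])
    expect_equal(het_obs, sum(t1 != t2))
  }
  # masking rate is honoured
  arc2 <- simulate_archaic_diploids(sim, n_mask_rate = 0.3)
  miss <- mean(arc2$diploids$Denisovan$geno[1, ] == "N")
  expect_gt(miss, 0.15); expect_lt(miss, 0.45)
})

test_that("snp panel tables carry the configured fold distribution", {
  tab0 <- simulate_snp_panel_table(30, fold_sd = 0, fold_mean = 1.1,
                                   seed = 7)
  expect_equal(tab0$EUR / tab0$AFR, rep(1.1, 30), tolerance = 1e-12)
  tab <- simulate_snp_panel_table(400, fold_mean = 1.2, fold_sd = 0.07,
                                  seed = 11)
  folds <- tab$EUR / tab$AFR
  expect_lt(abs(mean(folds) - 1.2), 3 * 0.07 / sqrt(400))
  # round trip through the fold comparison
  res <- panel_fold_comparison(tab, 0.45, 1.0, "AFR", "EUR",
                               c(0.401, 0.492))
  expect_lt(abs(res$mean_fold - 1.2), 0.02)
  expect_lt(abs(res$sd_fold - 0.07), 0.01)
})

test_that("the emulated age table dates carrier-exclusive variants near introgression", {
  cfg <- screen_sim_config(28, 0.08)
  sim <- plant_introgression(simulate_panel(cfg))
  skip_if(length(sim$truth$carriers) == 0)
  ages <- synthetic_age_table(sim)
  intro_aged <- ages[ages$estimator == "introgression_dated", ]
  expect_gt(nrow(intro_aged), 0)
  # lognormal(log 50k, 0.15): essentially all mass within 30-80 kyr
  expect_true(all(intro_aged$age_years > 2e4 &
                    intro_aged$age_years < 1e5))
  old <- ages[ages$estimator == "branch_truth", ]
  expect_gt(nrow(old), 0)
})
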