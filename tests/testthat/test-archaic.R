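make_dip <- function(sample, a, b, positions = NULL) {
  g <- rbind(a, b)
  archaic_diploid(sample, positions %||% seq(101, 100 + length(a)), g)
}

test_that("reference-linked phasing follows the homozygous-reference rule", {
  ref <- make_dip("Altai", c("A", "A", "C", "N"), c("A", "A", "C", "N"))
  tgt <- make_dip("Den", c("A", "G", "C", "A"), c("G", "A", "T", "G"))
  ph <- phase_by_reference(tgt, ref)
  # het A/G with reference hom A: hap2 gets the reference-matching A
  expect_equal(ph$hap2[1], "A")
  expect_equal(ph$hap1[1], "G")
  expect_equal(ph$hap2[2], "A")
  expect_equal(ph$hap1[2], "G")
  # het where reference is N: unresolved, both N
  expect_equal(ph$hap1[4], "N")
  expect_equal(ph$hap2[4], "N")
  expect_equal(ph$resolution[4], "unresolved")
  expect_equal(ph$hap_ids, c("Den-1", "Den-2"))

  hom <- make_dip("Cha", c("A", "A", "T", "G"), c("A", "A", "T", "G"))
  ph2 <- phase_by_reference(hom, ref)
  expect_equal(ph2$hap1, ph2$hap2)

  badref <- make_dip("x", c("A", "G", "C", "C"), c("G", "G", "C", "C"))
  expect_error(phase_by_reference(tgt, badref), "reference not homozygous")
})

test_that("phased haplotypes re-merge to the input genotype at resolved sites", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 30
    a <- sample(c("A", "G"), n, TRUE)
    b <- sample(c("A", "G"), n, TRUE)
    ref_allele <- sample(c("A", "G", "N"), n, TRUE, prob = c(.45, .45, .1))
    ref <- make_dip("ref", ref_allele, ref_allele)
    tgt <- make_dip("t", a, b)
    ph <- phase_by_reference(tgt, ref)
    ok <- ph$resolution %in% c("homozygous", "reference_resolved")
    remerged <- rbind(pmin(ph$hap1, ph$hap2), pmax(ph$hap1, ph$hap2))
    original <- rbind(pmin(a, b), pmax(a, b))
    expect_identical(remerged[, ok], original[, ok])
  }
})

test_that("phasing a diploid built from two known haplotypes recovers both", {
  cfg <- screen_sim_config(3, 0.05)
  sim <- plant_introgression(simulate_panel(cfg))
  arc <- simulate_archaic_diploids(sim, n_mask_rate = 0, mosaic = NULL)
  ref <- arc$diploids$Altai
  expect_false(any(ref$geno[1, ] != ref$geno[2, ]))
  ph <- phase_by_reference(arc$diploids$Denisovan, ref)
  t1 <- arc$truth$haplotypes[["Denisovan-1"]]
  t2 <- arc$truth$haplotypes[["Denisovan-2"]]
  res <- ph$resolution == "reference_resolved"
  # where the reference is homozygous and matches one truth allele, the
  # matching allele must sit on haplotype -2
  match2 <- res & t2 == ref$geno[1, ] & t1 != ref$geno[1, ]
  expect_true(all(ph$hap2[match2] == t2[match2]))
  expect_true(all(ph$hap1[match2] == t1[match2]))
})

test_that("diploid distance scores 0 / half / 1 per site and sums over compared sites", {
  a <- make_dip("a", c("A", "A", "A", "A", "A", "N"),
                     c("A", "A", "G", "G", "C", "N"))
  b <- make_dip("b", c("A", "G", "A", "C", "G", "A"),
                     c("A", "G", "G", "A", "T", "A"))
  # sites: homAA vs homGG=1; hetAG vs hetAG=0; hetAG vs hetAC(share A)=1/2;
  #        hetAC vs hetGT=1; N skipped; first site 0
  d <- diploid_distance(a, b)
  expect_equal(d$distance, 0 + 1 + 0 + 0.5 + 1)
  expect_equal(d$compared_sites, 5L)
  expect_equal(diploid_distance(a, a)$distance, 0)
  # haploid vs het sharing one allele: 1/2
  hap <- rep("A", 6)
  expect_equal(diploid_distance(hap, make_dip("x", c("A", rep("A", 5)),
                                              c("G", rep("A", 5))))$distance,
               0.5)
})

test_that("diploid distance equals the exhaustive phase-pairing oracle", {
  set.seed(67)
  for (rep in 1:20) {
    n <- 25
    ga <- rbind(sample(c("A", "G", "C"), n, TRUE),
                sample(c("A", "G", "C"), n, TRUE))
    gb <- rbind(sample(c("A", "G", "C"), n, TRUE),
                sample(c("A", "G", "C"), n, TRUE))
    mask <- sample(n, 3)
    ga[, mask[1]] <- "N"; gb[, mask[2]] <- "N"
    a <- archaic_diploid("a", seq_len(n) + 100, ga)
    b <- archaic_diploid("b", seq_len(n) + 100, gb)
    oracle <- 0
    for (s in seq_len(n)) {
      if (ga[1, s] == "N" || gb[1, s] == "N") next
      pairings <- c((ga[1, s] != gb[1, s]) + (ga[2, s] != gb[2, s]),
                    (ga[1, s] != gb[2, s]) + (ga[2, s] != gb[1, s]))
      oracle <- oracle + min(pairings) / 2
    }
    expect_equal(diploid_distance(a, b)$distance, oracle)
  }
})

test_that("identical tracts span the region when sequences match and stop at mismatches", {
  reg <- genomic_region("chr15", 1000, 9000)
  pos <- seq(1500, 8500, by = 500)
  q <- rep("A", length(pos))
  s <- q
  hit <- longest_identical_tract(q, s, pos, reg, 5000)
  expect_equal(c(hit$start, hit$end), c(1000L, 9000L))
  expect_equal(hit$length_bp, 8001L)
  # single mismatch left of the anchor: tract starts just right of it
  s2 <- q; s2[pos == 3000] <- "G"
  hit2 <- longest_identical_tract(q, s2, pos, reg, 5000)
  expect_equal(hit2$start, 3001L)
  expect_equal(hit2$end, 9000L)
  # N never breaks the run
  s3 <- q; s3[pos == 4000] <- "N"
  expect_equal(longest_identical_tract(q, s3, pos, reg, 5000)$length_bp,
               8001L)
  # mismatch inside the anchor interval: degenerate hit
  s4 <- q; s4[pos == 5000] <- "G"
  expect_true(longest_identical_tract(q, s4, pos, reg,
                                      c(4900, 5100))$anchor_mismatch)
  expect_error(longest_identical_tract(q, s, pos, reg, 99), "anchor")
})

test_that("a spliced donor segment is recovered up to the informative-site limits", {
  # build the recombinant by hand so the identifiability limits are exact:
  # the detected tract must run from just after the last site where the
  # background disagrees with the donor left of the splice, to just
  # before the first disagreeing site right of it
  cfg <- screen_sim_config(19, 0)
  sim <- plant_introgression(simulate_panel(cfg))
  donor <- unname(sim$truth$donor_sequence)
  pos <- sim$panel$positions
  background <- sim$panel$alleles[1, ]
  planted <- c(92914000L, 92927000L)
  q <- background
  inside <- pos >= planted[1] & pos <= planted[2]
  q[inside] <- donor[inside]
  hit <- longest_identical_tract(q, donor, pos, cfg$window,
                                 range(cfg$promoter_positions))
  informative <- pos[background != donor & q != "N"]
  left_lim <- informative[informative < planted[1]]
  right_lim <- informative[informative > planted[2]]
  expect_equal(hit$start,
               if (length(left_lim)) max(left_lim) + 1L else
                 cfg$window$start)
  expect_equal(hit$end,
               if (length(right_lim)) min(right_lim) - 1L else
                 cfg$window$end)
  # the detected tract always contains the planted segment
  expect_lte(hit$start, planted[1])
  expect_gte(hit$end, planted[2])
})

test_that("tract partners rank the donor's own type first for a planted recombinant", {
  cfg <- screen_sim_config(5, 0.05)
  sim <- plant_introgression(simulate_panel(cfg))
  skip_if(length(sim$truth$carriers) < 1)
  carrier <- sim$truth$carriers[1]
  others <- setdiff(rownames(sim$panel$alleles), carrier)
  panel_rest <- promoterpop:::extract_haplotypes(sim$panel, others)
  types <- panel_promoter_types(sim$panel, promoter_ids)
  ranked <- rank_tract_partners(sim$panel$alleles[carrier, ], panel_rest,
                                range(cfg$promoter_positions),
                                types = types)
  top <- ranked[1, ]
  other_carriers <- intersect(others, sim$truth$carriers)
  if (length(other_carriers)) {
    # another carrier shares the whole donor tract: it must rank first
    expect_true(top$partner %in% other_carriers)
  }
  expect_error(rank_tract_partners(
    sim$panel$alleles[carrier, ],
    promoterpop:::extract_haplotypes(sim$panel, character()),
    range(cfg$promoter_positions)), "empty subject")
})

test_that("mosaic labeling recovers planted TGT-CGT-TGT and CGT-TCT-CGT structures", {
  cfg <- screen_sim_config(11, 0)
  sim <- plant_introgression(simulate_panel(cfg))
  donors <- list(TGT = promoterpop:::template_on_sites(sim, "TGT:1"),
                 CGT = unname(sim$truth$donor_sequence),
                 TCT = promoterpop:::template_on_sites(sim, "TCT:1"))
  pos <- sim$panel$positions
  mid <- pos >= 92916000 & pos <= 92925000
  q <- donors$TGT; q[mid] <- donors$CGT[mid]
  expect_equal(infer_mosaic_structure(q, donors, pos, cfg$window)$type,
               c("TGT", "CGT", "TGT"))
  q2 <- donors$CGT; q2[mid] <- donors$TCT[mid]
  expect_equal(infer_mosaic_structure(q2, donors, pos, cfg$window)$type,
               c("CGT", "TCT", "CGT"))
  expect_equal(infer_mosaic_structure(donors$TCT, donors, pos,
                                      cfg$window)$type, "TCT")
  expect_error(infer_mosaic_structure(q, donors["TGT"], pos, cfg$window),
               ">= 2 donor")
})

test_that("Beta-posterior frequency bounds match the closed form", {
  expect_equal(round(beta_frequency_lower_bound(8, 0, 0.95), 3), 0.717)
  expect_equal(beta_frequency_lower_bound(0, 0, 0.95), 0.05)
  expect_equal(round(beta_frequency_lower_bound(2, 0, 0.95), 3), 0.368)
  expect_equal(beta_frequency_lower_bound(2, 0, 0.95), 0.05^(1 / 3),
               tolerance = 1e-12)
  # with n_other = 0 the bound is (1 - level)^(1/(n+1)), always
  for (n in 0:12) for (lev in c(0.5, 0.9, 0.95, 0.99)) {
    expect_equal(beta_frequency_lower_bound(n, 0, lev),
                 (1 - lev)^(1 / (n + 1)), tolerance = 1e-12)
  }
})

test_that("tract survival is exp(-m r t / g), monotone, and matches Monte Carlo", {
  p <- evo_params()
  expect_equal(tract_survival_probability(0, p, 1e5), 1)
  m <- seq(0, 5e4, by = 1e4)
  surv <- tract_survival_probability(m, p, 4.5e5)
  expect_true(all(diff(surv) < 0))
  # strictly decreasing in t_total as well
  expect_true(all(diff(tract_survival_probability(1e4, p,
                                                  c(1e5, 5e5, 1e6))) < 0))
  # Monte-Carlo oracle: breakpoints Poisson per generation; the binomial
  # standard error is taken at the model probability so that rare-event
  # cases are handled sensibly
  set.seed(71)
  for (case in list(c(8000, 450000), c(18000, 550000))) {
    m0 <- case[1]; t0 <- case[2]
    gens <- t0 / p$g
    p_model <- tract_survival_probability(m0, p, t0)
    p_hat <- mean(stats::rpois(1e5, m0 * p$r * gens) == 0)
    se <- sqrt(p_model * (1 - p_model) / 1e5)
    expect_lt(abs(p_model - p_hat), 4 * se + 1e-12)
  }
})

test_that("difference ranges respect exclusions and planted divergence", {
  a <- matrix("A", 3, 10, dimnames = list(paste0("a", 1:3), NULL))
  b <- a; rownames(b) <- paste0("b", 1:3)
  expect_equal(amh_ah_difference_range(a, b)$min, 0)
  expect_equal(amh_ah_difference_range(a, b)$max, 0)
  # a planted recombinant inflates the max; excluding it narrows the range
  b2 <- b
  b2["b3", 1:6] <- "G"
  rng_all <- amh_ah_difference_range(a, b2)
  rng_ex <- amh_ah_difference_range(a, b2, exclusions = "b3")
  expect_equal(rng_all$max, 6)
  expect_equal(rng_ex$max, 0)
  expect_error(amh_ah_difference_range(a, b2,
                                       exclusions = paste0("b", 1:3)),
               "empty set")
})

test_that("two clades at a planted split show differences bracketing the Poisson mean", {
  cfg <- screen_sim_config(29, 0.10)
  sim <- plant_introgression(simulate_panel(cfg))
  skip_if(length(sim$truth$carriers) < 2)
  core <- extract_region(sim$panel, cfg$core)
  carr <- sim$truth$carriers
  non <- setdiff(rownames(core$alleles), carr)
  rng <- amh_ah_difference_range(core$alleles[carr, , drop = FALSE],
                                 core$alleles[non, , drop = FALSE])
  expected <- 2 * 600000 * 0.5e-9 * 18000  # 10.8
  expect_lte(rng$min, expected + 3 * sqrt(expected))
  expect_gte(rng$max, expected - 3 * sqrt(expected))
})
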