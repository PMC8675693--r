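# Shared fixtures: all built in code at test time.

promoter_ids <- c("rs3759916", "rs3759915", "rs3759914")

# Minimal panel builder: one subpopulation per sample unless given.
toy_panel <- function(alleles, positions, start, end,
                      subpop = NULL, metapop = NULL) {
  samples <- unique(sub("\\.[01]$", "", rownames(alleles)))
  pop_map <- tibble::tibble(
    sample = samples,
    subpop = subpop %||% rep("YRI", length(samples)),
    metapop = metapop %||% rep("AFR", length(samples)))
  hap_panel(alleles, positions, genomic_region("chr15", start, end),
            pop_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The screening study design: 3 African + 2 South-Asian subpopulations,
# shared template pool, CGT absent from the modern panel, optional CGT
# donor introgressed into SAS at ~5%.
screen_sim_config <- function(seed, recipient_freq) {
  pops <- tibble::tibble(
    subpop = c("YRI", "LWK", "ESN", "GIH", "PJL"),
    metapop = c("AFR", "AFR", "AFR", "SAS", "SAS"),
    n_samples = rep(20L, 5))
  fr <- c(TGT = 0.45, TCT = 0.45, CGC = 0.10)
  sim_config(seed = seed, pops = pops,
             type_freqs = list(AFR = fr, SAS = fr),
             introgression = list(donor_type = "CGT",
                                  recipient_metapop = "SAS",
                                  recipient_freq = recipient_freq,
                                  t_split = 600000))
}

# One full planted-truth screen run. For positive runs the divergence
# band is calibrated from the known carriers (as the study calibrates on
# its known introgressed lineage); negative runs use the split-time
# expectation band.
run_screen_once <- function(seed, positive) {
  cfg <- screen_sim_config(seed, if (positive) 0.05 else 0)
  sim <- plant_introgression(simulate_panel(cfg))
  core <- extract_region(sim$panel, cfg$core)
  rare <- filter_by_maf(core, 0.005, always_keep = promoter_ids)
  carriers <- sim$truth$carriers
  if (positive) {
    non <- setdiff(rownames(rare$alleles), carriers)
    rng <- amh_ah_difference_range(
      rare$alleles[carriers, , drop = FALSE],
      rare$alleles[non, , drop = FALSE])
  } else {
    rng <- round(expected_pairwise_differences(
      c(550000, 765000), 0.5e-9, 18000))
  }
  ages <- synthetic_age_table(sim)
  sas <- rownames(rare$alleles)[
    haplotype_populations(rare)$metapop == "SAS"]
  scr <- archaic_candidate_screen(rare, rng, c("YRI", "LWK", "ESN"),
                                  age_table = ages, haplotypes = sas)
  groups <- enumerate_haplotypes(rare)
  carrier_groups <- unique(groups$group[groups$haplotype %in% carriers])
  list(screen = scr, carriers = carriers,
       carrier_groups = carrier_groups,
       sensitivity = if (length(carrier_groups))
         mean(carrier_groups %in% scr$survivors) else NA_real_,
       n_survivors = length(scr$survivors))
}

# Plain-text VCF builder for IO tests: gts is a site x sample matrix of
# GT strings ("0|1", "./." ...).
write_toy_vcf <- function(path, chrom, pos, ref, alt, samples, gts,
                          ids = NULL) {
  if (is.null(ids)) ids <- rep(".", length(pos))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", chrom),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom, pos[i], ids[i], ref[i], alt[i], ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
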