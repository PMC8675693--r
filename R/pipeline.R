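#' Run the full promoter-region analysis end to end
#'
#' Orchestrates the analysis stages in the order of the study design:
#' promoter-type classification and frequency tables, haplotype
#' enumeration at the common-variant MAF threshold, fold differences
#' against the African reference, an NJ tree of haplotype groups, archaic
#' phasing and the Beta-posterior frequency bound (when archaic diploids
#' are supplied), the five-step archaic-ancestry screen at the
#' rare-variant MAF threshold, PPA per meta-population with pairwise KS
#' comparisons, and the archaic-composition PPA enumeration. Any stage
#' failure aborts with the stage name.
#'
#' @param panel A [hap_panel()] over the analysis window (e.g. from
#'   [read_vcf_panel()] or [simulate_panel()]).
#' @param core A [genomic_region()]: the low-recombination core analysed
#'   for haplotype structure (default: the panel's whole region).
#' @param promoter_sites The three promoter-SNP site ids (or positions).
#' @param maf_common MAF threshold for haplotype enumeration (default
#'   0.01).
#' @param maf_archaic MAF threshold for the archaic screen (default
#'   0.005).
#' @param archaic_diploids Optional named list of [archaic_diploid()]
#'   objects aligned to the core sites; the first fully homozygous one
#'   acts as the phasing reference.
#' @param age_table Optional variant-age tibble (`variant_id`,
#'   `age_years`) for screen step 5.
#' @param amh_ah_range Optional modern-archaic difference range; when
#'   `NULL` it is taken from [expected_pairwise_differences()] at the
#'   configured split bounds.
#' @param african_subpops Subpopulation codes counted as African.
#' @param screen_metapop Meta-population screened for archaic-ancestry
#'   candidates (default `"SAS"`).
#' @param introgression_window Step-5 age window (years).
#' @param credibility Level for the Beta frequency bound.
#' @param activity An [activity_map()].
#' @param grid_step Grid step of the archaic-composition enumeration.
#' @param params An [evo_params()].
#' @param bootstrap_reps NJ bootstrap replicates (0 disables).
#' @param seed Integer seed for the bootstrap stage.
#' @return List of class `promoter_report` with one element per stage and
#'   a `provenance` block (inputs, thresholds, seed, package version).
#' @export
run_full_analysis <- function(panel,
                              core = panel$region,
                              promoter_sites = c("rs3759916", "rs3759915",
                                                 "rs3759914"),
                              maf_common = 0.01,
                              maf_archaic = 0.005,
                              archaic_diploids = NULL,
                              age_table = NULL,
                              amh_ah_range = NULL,
                              african_subpops =
                                unique(panel$pop_map$subpop[
                                  panel$pop_map$metapop == "AFR"]),
                              screen_metapop = "SAS",
                              introgression_window = c(30000, 80000),
                              credibility = 0.95,
                              activity = activity_map(),
                              grid_step = 0.001,
                              params = evo_params(),
                              bootstrap_reps = 0,
                              seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list()
  core_panel <- stage("core_extraction", extract_region(panel, core))

  types <- stage("classify",
                 panel_promoter_types(core_panel, promoter_sites))
  report$promoter_types <- types
  report$type_frequencies <- stage("frequency_tables",
                                   frequency_table(types))

  filtered <- stage("maf_filter",
                    filter_by_maf(core_panel, maf_common,
                                  always_keep = promoter_sites))
  groups <- stage("haplotypes", enumerate_haplotypes(filtered, types))
  report$haplotype_groups <- haplotype_group_counts(groups)

  report$fold_vs_afr <- stage("fold_differences", {
    ft <- report$type_frequencies
    afr <- ft[ft$population == "AFR", c("category", "frequency")]
    non <- ft[!ft$population %in% c("AFR", "ALL"), ]
    non <- dplyr::left_join(non, stats::setNames(afr, c("category", "afr_frequency")),
                            by = "category")
    non <- non[!is.na(non$afr_frequency) & non$afr_frequency > 0, ]
    non$fold <- fold_difference(non$frequency, non$afr_frequency)
    non
  })

  report$tree <- stage("tree", {
    reps <- unique(groups$group)
    if (length(reps) >= 3) {
      if (bootstrap_reps > 0) {
        bootstrap_support(filtered$alleles[reps, , drop = FALSE],
                          n_reps = bootstrap_reps, seed = seed)
      } else {
        nj_tree(pairwise_difference_matrix(
          filtered$alleles[reps, , drop = FALSE]))
      }
    } else NULL
  })

  if (!is.null(archaic_diploids)) {
    report$archaic <- stage("phase_archaic", {
      hom <- vapply(archaic_diploids, function(d) !any(is_het(d)),
                    logical(1))
      if (!any(hom)) stop("no fully homozygous reference individual")
      ref <- archaic_diploids[[which(hom)[1]]]
      phased <- lapply(archaic_diploids[names(archaic_diploids) !=
                                          ref$sample],
                       phase_by_reference, reference = ref)
      prom_pos <- extract_sites(core_panel, promoter_sites)$positions
      idx <- match(prom_pos, ref$positions)
      arch_types <- vapply(archaic_diploids, function(d) {
        g <- d$geno[, idx, drop = FALSE]
        if (any(g[1, ] != g[2, ])) "heterozygous" else
          classify_promoter_type(g[1, ])
      }, character(1))
      cgt_n <- 2L * sum(arch_types == "CGT")
      other_n <- 2L * sum(arch_types %in%
                            setdiff(PROMOTER_TYPES, "CGT"))
      list(reference = ref$sample, phased = phased,
           promoter_types = arch_types,
           cgt_bound = beta_frequency_lower_bound(cgt_n, other_n,
                                                  credibility))
    })
  }

  report$screen <- stage("screen", {
    if (is.null(amh_ah_range)) {
      amh_ah_range <- round(expected_pairwise_differences(
        params$t_split_amh_ah, params$mu, region_length(core)))
    }
    rare <- filter_by_maf(core_panel, maf_archaic,
                          always_keep = promoter_sites)
    focal <- rownames(rare$alleles)[
      haplotype_populations(rare)$metapop == screen_metapop]
    archaic_candidate_screen(rare, amh_ah_range, african_subpops,
                             age_table = age_table,
                             introgression_window = introgression_window,
                             haplotypes = focal)
  })

  report$ppa <- stage("ppa", {
    ind <- individuals_from_types(types)
    population_ppa(ind, activity)
  })
  report$ppa_comparisons <- stage("ppa_comparisons", {
    acts <- stats::setNames(report$ppa$activities, report$ppa$population)
    pops <- names(acts)
    if (length(pops) < 2) return(NULL)
    purrr::map_dfr(utils::combn(pops, 2, simplify = FALSE), function(pr) {
      dplyr::mutate(compare_activity_distributions(acts[[pr[1]]],
                                                   acts[[pr[2]]]),
                    pop_a = pr[1], pop_b = pr[2], .before = 1)
    })
  })

  report$ah_ppa <- stage("ah_enumeration", {
    bound <- if (!is.null(report$archaic)) report$archaic$cgt_bound else
      beta_frequency_lower_bound(8, 0, credibility)
    afr_ppa <- report$ppa$ppa[report$ppa$population == "AFR"]
    if (!length(afr_ppa)) afr_ppa <- min(report$ppa$ppa)
    enumerate_ah_compositions(bound, grid_step, afr_ppa, activity)
  })

  report$provenance <- list(
    n_haplotypes = nrow(panel$alleles),
    region = unclass(panel$region), core = unclass(core),
    maf_common = maf_common, maf_archaic = maf_archaic,
    credibility = credibility, grid_step = grid_step,
    introgression_window = introgression_window,
    screen_metapop = screen_metapop,
    african_subpops = african_subpops,
    seed = seed,
    package_version = as.character(utils::packageVersion("promoterpop")))
  class(report) <- "promoter_report"
  report
}

#' @export
print.promoter_report <- function(x, ...) {
  cat("<promoter_report>\n")
  cat("  stages:", paste(setdiff(names(x), "provenance"), collapse = ", "),
      "\n")
  ppa <- tidy(x$ppa)
  cat("  PPA:", paste(sprintf("%s=%.2f", ppa$population, ppa$ppa),
                      collapse = " "), "\n")
  invisible(x)
}

#' Diploid individuals from per-haplotype promoter types
#'
#' Pairs the `.0`/`.1` phases of each sample into one row per individual,
#' ready for [population_ppa()].
#'
#' @param types Tibble from [panel_promoter_types()].
#' @param population_column Which population column becomes `population`.
#' @return Tibble: `sample`, `population`, `type1`, `type2`.
#' @export
individuals_from_types <- function(types,
                                   population_column = "metapop") {
  df <- dplyr::mutate(types, phase = sub("^.*\\.", "", .data$haplotype))
  wide <- tidyr::pivot_wider(
    df[, c("sample", population_column, "phase", "promoter_type")],
    names_from = "phase", values_from = "promoter_type")
  tibble::tibble(sample = wide$sample,
                 population = wide[[population_column]],
                 type1 = wide[["0"]], type2 = wide[["1"]])
}

#' Write a full-analysis report to JSON
#'
#' Tables are serialised row-wise; the tree as a newick string.
#'
#' @param report A `promoter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  ser <- list(
    type_frequencies = report$type_frequencies,
    haplotype_groups = report$haplotype_groups,
    fold_vs_afr = report$fold_vs_afr,
    tree_newick = if (!is.null(report$tree))
      ape::write.tree(report$tree) else NULL,
    archaic = if (!is.null(report$archaic)) list(
      reference = report$archaic$reference,
      promoter_types = report$archaic$promoter_types,
      cgt_bound = report$archaic$cgt_bound) else NULL,
    screen = list(survivors = report$screen$survivors,
                  audit = report$screen$audit),
    ppa = tidy(report$ppa),
    ppa_comparisons = report$ppa_comparisons,
    ah_ppa = glance(report$ah_ppa),
    provenance = report$provenance)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
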