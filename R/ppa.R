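#' Relative promoter activities per promoter type
#'
#' Luciferase-derived relative activities, CGC-referenced: the defaults
#' are TGT 3.6, CGT 2.9, TCT 2.1, CGC 1.0. `OTHER` is unscored.
#'
#' @param TGT,CGT,TCT,CGC Positive relative activities.
#' @return Named numeric vector of class `activity_map`.
#' @export
activity_map <- function(TGT = 3.6, CGT = 2.9, TCT = 2.1, CGC = 1.0) {
  out <- c(TGT = TGT, CGT = CGT, TCT = TCT, CGC = CGC)
  stopifnot(all(out > 0))
  structure(out, class = "activity_map")
}

#' Individual promoter activity from the two promoter-type alleles
#'
#' The two alleles contribute equally (no imprinting), so the individual
#' activity is `(a1 + a2) / 2`. Individuals carrying an unscored
#' (`OTHER`) type get `NA`.
#'
#' @param type1,type2 Promoter types (vectorised).
#' @param map An [activity_map()].
#' @return Numeric vector of individual activities (`NA` = unscored).
#' @export
#' @examples
#' individual_activity("TGT", "CGC")  # 2.3
individual_activity <- function(type1, type2, map = activity_map()) {
  (unname(map[type1]) + unname(map[type2])) / 2
}

#' Population promoter activity (PPA)
#'
#' The mean individual promoter activity of a population. Individuals
#' carrying an unscored promoter type are excluded and counted.
#'
#' @param individuals Tibble with columns `type1`, `type2` (one row per
#'   individual), optionally `population` for grouped results.
#' @param map An [activity_map()].
#' @return Object of class `ppa_result`: tibble with `population`, `n`,
#'   `ppa`, `n_excluded`, and the per-individual activities in the
#'   `activities` list-column.
#' @export
population_ppa <- function(individuals, map = activity_map()) {
  stopifnot(all(c("type1", "type2") %in% names(individuals)))
  if (!"population" %in% names(individuals)) {
    individuals$population <- "ALL"
  }
  act <- individual_activity(individuals$type1, individuals$type2, map)
  individuals$activity <- act
  out <- dplyr::summarise(
    dplyr::group_by(individuals, .data$population),
    n = sum(!is.na(.data$activity)),
    ppa = mean(.data$activity, na.rm = TRUE),
    n_excluded = sum(is.na(.data$activity)),
    activities = list(.data$activity[!is.na(.data$activity)]),
    .groups = "drop")
  if (any(out$n == 0)) stop("no scorable individuals", call. = FALSE)
  class(out) <- c("ppa_result", class(out))
  out
}

#' @export
print.ppa_result <- function(x, ...) {
  cat("<ppa_result>\n")
  print(tibble::as_tibble(x[, c("population", "n", "ppa", "n_excluded")]))
  invisible(x)
}

#' @export
tidy.ppa_result <- function(x, ...) {
  tibble::as_tibble(x[, c("population", "n", "ppa", "n_excluded")])
}

#' @export
glance.ppa_result <- function(x, ...) {
  tibble::tibble(n_populations = nrow(x),
                 ppa_min = min(x$ppa), ppa_max = max(x$ppa))
}

#' PPA of a randomly mating population from allele frequencies
#'
#' Under random mating with equal type frequencies in both sexes, the
#' expected PPA reduces to the allele-frequency-weighted mean activity
#' `sum(f_i * a_i)` (each allele enters an individual independently, and
#' the averaging is linear).
#'
#' @param freqs Named numeric vector of promoter-type frequencies
#'   (names in the activity map; must sum to 1).
#' @param map An [activity_map()].
#' @return Expected PPA (numeric scalar).
#' @export
hardy_weinberg_ppa <- function(freqs, map = activity_map()) {
  stopifnot(abs(sum(freqs) - 1) < 1e-8,
            all(names(freqs) %in% names(map)))
  sum(freqs * unname(map[names(freqs)]))
}

#' PPA from population allele counts under random mating
#'
#' Convenience wrapper: converts scored-type allele counts to frequencies
#' and applies [hardy_weinberg_ppa()]. The AFR counts of the study
#' (TGT 612, TCT 625, CGT 46, CGC 11) give 2.83.
#'
#' @param counts Named integer vector of allele counts per scored type.
#' @param map An [activity_map()].
#' @return Expected PPA.
#' @export
ppa_from_allele_counts <- function(counts, map = activity_map()) {
  hardy_weinberg_ppa(counts / sum(counts), map)
}

#' Enumerate admissible archaic promoter-type compositions and their PPA
#'
#' Grid enumeration of compositions `(f_CGT, f_TGT, f_TCT)` with
#' `f_CGT >= cgt_lower_bound` (the Beta-posterior bound from the archaic
#' samples) and `f_TGT >= f_TCT` (the ordering implied by the archaic
#' recombination mosaics), each scored by [hardy_weinberg_ppa()] and
#' compared with a reference PPA.
#'
#' @param cgt_lower_bound Lower bound on the CGT frequency, in (0, 1].
#' @param grid_step Grid resolution, default 0.001.
#' @param reference_ppa Reference PPA for the fold comparison (e.g. the
#'   AFR PPA from allele counts).
#' @param map An [activity_map()].
#' @return List of class `ah_composition_result`: `grid` tibble
#'   (compositions, `ppa`, `fold`), `min`/`max` rows, bounds used.
#' @export
enumerate_ah_compositions <- function(cgt_lower_bound, grid_step = 0.001,
                                      reference_ppa,
                                      map = activity_map()) {
  stopifnot(cgt_lower_bound > 0, cgt_lower_bound <= 1, grid_step > 0)
  f_cgt <- seq(ceiling(cgt_lower_bound / grid_step) * grid_step, 1,
               by = grid_step)
  if (!length(f_cgt)) f_cgt <- 1
  grid <- purrr::map_dfr(f_cgt, function(fc) {
    rem <- 1 - fc
    f_tct <- seq(0, rem / 2, by = grid_step)
    tibble::tibble(f_CGT = fc, f_TCT = f_tct, f_TGT = rem - f_tct)
  })
  grid$ppa <- map[["CGT"]] * grid$f_CGT + map[["TGT"]] * grid$f_TGT +
    map[["TCT"]] * grid$f_TCT
  grid$fold <- grid$ppa / reference_ppa
  structure(list(
    grid = grid,
    min = grid[which.min(grid$ppa), ],
    max = grid[which.max(grid$ppa), ],
    cgt_lower_bound = cgt_lower_bound,
    reference_ppa = reference_ppa),
    class = "ah_composition_result")
}

#' @export
print.ah_composition_result <- function(x, ...) {
  cat(sprintf(
    "<ah_composition_result> %d compositions (f_CGT >= %.3f)\n",
    nrow(x$grid), x$cgt_lower_bound))
  cat(sprintf("  PPA range %.3f-%.3f; fold vs reference %.3f-%.3f\n",
              x$min$ppa, x$max$ppa, x$min$fold, x$max$fold))
  invisible(x)
}

#' @export
glance.ah_composition_result <- function(x, ...) {
  tibble::tibble(n_compositions = nrow(x$grid),
                 ppa_min = x$min$ppa, ppa_max = x$max$ppa,
                 fold_min = x$min$fold, fold_max = x$max$fold)
}

#' Compare individual-activity distributions of two populations
#'
#' Two-sample Kolmogorov-Smirnov test on the per-individual promoter
#' activities.
#'
#' @param activities_a,activities_b Numeric vectors of individual
#'   activities.
#' @return Tibble: `D`, `p_value`.
#' @export
compare_activity_distributions <- function(activities_a, activities_b) {
  stopifnot(length(activities_a) > 0, length(activities_b) > 0)
  ks <- suppressWarnings(stats::ks.test(activities_a, activities_b))
  tibble::tibble(D = unname(ks$statistic), p_value = ks$p.value)
}

#' Frequency-fold comparison against a panel of index SNPs
#'
#' Selects panel SNPs whose focal-population frequency falls in a bin
#' around `focal_freq_a`, computes per-SNP frequency folds between the two
#' populations, fits a normal distribution (checked by a one-sample KS
#' test), and flags whether the focal fold lies inside the population
#' `level` confidence interval `mean +/- z * sd`.
#'
#' @param panel_table Tibble: `snp_id` plus one frequency column per
#'   population.
#' @param focal_freq_a Focal-locus frequency in population `pop_a`.
#' @param focal_fold Focal-locus fold (`freq_b / freq_a`) to flag.
#' @param pop_a,pop_b Column names of the two populations.
#' @param bin Length-2 frequency window selecting panel SNPs by their
#'   `pop_a` frequency.
#' @param level Interval level, default 0.99.
#' @return Tibble of class `fold_comparison`: bin, `n_snps`, `mean_fold`,
#'   `sd_fold`, `ci_lower`, `ci_upper`, `ks_p`, `normal_ok`,
#'   `focal_fold`, `focal_flag`, with per-SNP folds in attribute
#'   `"folds"`.
#' @export
panel_fold_comparison <- function(panel_table, focal_freq_a, focal_fold,
                                  pop_a, pop_b, bin, level = 0.99) {
  stopifnot(all(c("snp_id", pop_a, pop_b) %in% names(panel_table)),
            length(bin) == 2L)
  sel <- panel_table[panel_table[[pop_a]] >= bin[1] &
                       panel_table[[pop_a]] <= bin[2], ]
  if (nrow(sel) == 0L) stop("empty bin", call. = FALSE)
  if (nrow(sel) < 5L) stop("fewer than 5 SNPs in bin", call. = FALSE)
  folds <- sel[[pop_b]] / sel[[pop_a]]
  m <- mean(folds); s <- stats::sd(folds)
  degenerate <- s == 0
  ks_p <- if (degenerate) NA_real_ else
    suppressWarnings(stats::ks.test(folds, "pnorm", m, s)$p.value)
  z <- stats::qnorm((1 + level) / 2)
  ci <- c(m - z * s, m + z * s)
  out <- tibble::tibble(
    bin_lower = bin[1], bin_upper = bin[2], n_snps = nrow(sel),
    mean_fold = m, sd_fold = s, ci_lower = ci[1], ci_upper = ci[2],
    ks_p = ks_p,
    normal_ok = !degenerate && ks_p >= 0.05,
    degenerate = degenerate,
    focal_fold = focal_fold,
    focal_flag = ifelse(focal_fold >= ci[1] & focal_fold <= ci[2],
                        "inside", "outside"))
  attr(out, "folds") <- tibble::tibble(snp_id = sel$snp_id, fold = folds)
  class(out) <- c("fold_comparison", class(out))
  out
}

#' Infer an ancestral frequency from a median panel fold
#'
#' Multiplicative convention: `focal_freq * median_fold`, capped at 1.
#' The result is an approximation (the convention is recorded in the
#' output).
#'
#' @param focal_freq Present-day frequency in the focal population.
#' @param median_fold Median frequency fold of matched panel SNPs.
#' @return Tibble: `inferred_frequency`, `convention`.
#' @export
infer_ancestral_frequency <- function(focal_freq, median_fold) {
  stopifnot(focal_freq > 0, median_fold > 0)
  tibble::tibble(
    inferred_frequency = pmin(1, focal_freq * median_fold),
    convention = "approximate: focal_freq x median_fold, capped at 1")
}

#' Correlate PPA with a per-population covariate
#'
#' Pearson correlation (two-sided test) between population PPA values and
#' a covariate such as effective-population-size change.
#'
#' @param ppa Tibble with `population` and `ppa` columns.
#' @param covariate Tibble with `population` and `value` columns.
#' @return Tibble: `r`, `p_value`, `n`.
#' @export
correlate_ppa_covariate <- function(ppa, covariate) {
  merged <- dplyr::inner_join(ppa[, c("population", "ppa")],
                              covariate[, c("population", "value")],
                              by = "population")
  if (nrow(merged) < nrow(ppa) || nrow(merged) < nrow(covariate)) {
    stop("mismatched population labels", call. = FALSE)
  }
  if (nrow(merged) < 3L) stop("need >= 3 paired values", call. = FALSE)
  if (stats::sd(merged$value) == 0 || stats::sd(merged$ppa) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(merged$ppa, merged$value)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(merged))
}
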