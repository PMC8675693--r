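#' The four scored promoter types
#'
#' Ordered alleles at the three promoter SNPs (rs3759916, rs3759915,
#' rs3759914). Any other combination, or any missing allele, is `OTHER`.
#' @export
PROMOTER_TYPES <- c("TGT", "TCT", "CGT", "CGC")

#' Classify a promoter type from the three promoter-SNP alleles
#'
#' @param alleles Character vector of length 3 (alleles at rs3759916,
#'   rs3759915, rs3759914 in that order), or a matrix with 3 columns for
#'   vectorised classification.
#' @return Character scalar/vector in `{TGT, TCT, CGT, CGC, OTHER}`.
#' @export
#' @examples
#' classify_promoter_type(c("C", "G", "C"))  # "CGC"
classify_promoter_type <- function(alleles) {
  if (is.matrix(alleles)) {
    if (ncol(alleles) != 3L) stop("need exactly 3 allele columns", call. = FALSE)
    key <- paste0(alleles[, 1], alleles[, 2], alleles[, 3])
  } else {
    if (length(alleles) != 3L) stop("need exactly 3 alleles", call. = FALSE)
    key <- paste0(alleles, collapse = "")
  }
  bad <- !vapply(strsplit(key, ""), function(a)
    all(a %in% c("A", "C", "G", "T", "N")), logical(1))
  if (any(bad)) stop("alleles must be in {A,C,G,T,N}", call. = FALSE)
  ifelse(key %in% PROMOTER_TYPES, key, "OTHER")
}

#' Promoter type of every haplotype in a panel
#'
#' @param panel A [hap_panel()].
#' @param triplet_sites Site ids or positions of the three promoter SNPs,
#'   in rs3759916/rs3759915/rs3759914 order.
#' @return Tibble: `haplotype`, `sample`, `subpop`, `metapop`,
#'   `promoter_type`.
#' @export
panel_promoter_types <- function(panel, triplet_sites) {
  if (length(triplet_sites) != 3L) stop("need exactly 3 sites", call. = FALSE)
  sub <- extract_sites(panel, triplet_sites)
  # extract_sites keeps panel order; re-order columns to the requested order
  if (is.character(triplet_sites)) {
    idx <- match(triplet_sites, sub$site_ids)
  } else {
    idx <- match(as.integer(triplet_sites), sub$positions)
  }
  types <- classify_promoter_type(sub$alleles[, idx, drop = FALSE])
  out <- haplotype_populations(panel)
  out$promoter_type <- types
  out
}

#' Filter panel sites by minor allele frequency
#'
#' MAF is computed over the whole panel (all populations pooled), with `N`
#' excluded from allele counts. For multiallelic sites the minor-allele
#' frequency is `1 - max allele frequency`. Sites with MAF strictly below
#' `threshold` are dropped; `always_keep` sites (e.g. the promoter SNPs)
#' are retained regardless.
#'
#' @param panel A [hap_panel()].
#' @param threshold Fraction in `[0, 0.5]`.
#' @param always_keep Optional site ids never to drop.
#' @return The filtered [hap_panel()].
#' @export
filter_by_maf <- function(panel, threshold, always_keep = character()) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  maf <- site_maf(panel)
  keep <- maf >= threshold | panel$site_ids %in% always_keep
  extract_sites(panel, panel$site_ids[keep])
}

#' @rdname filter_by_maf
#' @return `site_maf()`: numeric vector of per-site minor allele
#'   frequencies (0 for monomorphic or all-missing sites).
#' @export
site_maf <- function(panel) {
  apply(panel$alleles, 2, function(col) {
    col <- col[col != "N"]
    if (!length(col)) return(0)
    1 - max(table(col)) / length(col)
  })
}

#' Group identical haplotype sequences
#'
#' Sequences identical over the panel's (typically MAF-filtered) sites are
#' grouped; each group is named after its first carrier in panel row order,
#' mirroring the `SAMPLE.k` naming of study haplotype tables.
#'
#' @param panel A [hap_panel()] (usually after [filter_by_maf()]).
#' @param types Optional tibble from [panel_promoter_types()] to attach a
#'   promoter type per group (groups are always type-homogeneous when the
#'   triplet sites are in the panel).
#' @return Tibble, one row per haplotype: `haplotype`, `group` (name of the
#'   first carrier), plus population columns and `promoter_type` when
#'   `types` is given. Attribute `"group_sequences"` holds the defining
#'   sequence per group.
#' @export
enumerate_haplotypes <- function(panel, types = NULL) {
  if (nrow(panel$alleles) == 0L) stop("empty panel", call. = FALSE)
  seqs <- apply(panel$alleles, 1, paste0, collapse = "")
  first <- !duplicated(seqs)
  group_of <- rownames(panel$alleles)[first][match(seqs, seqs[first])]
  out <- haplotype_populations(panel)
  out$group <- group_of
  if (!is.null(types)) {
    out <- dplyr::left_join(out,
      types[, c("haplotype", "promoter_type")], by = "haplotype")
  }
  attr(out, "group_sequences") <-
    tibble::tibble(group = rownames(panel$alleles)[first],
                   sequence = seqs[first])
  out
}

#' Per-group membership counts by population
#'
#' @param groups Output of [enumerate_haplotypes()].
#' @param level `"metapop"` or `"subpop"`.
#' @return Tibble: `group`, (promoter_type,) population, `n`, sorted by
#'   total group size descending.
#' @export
haplotype_group_counts <- function(groups, level = c("metapop", "subpop")) {
  level <- match.arg(level)
  keys <- c("group", intersect("promoter_type", names(groups)), level)
  counts <- dplyr::count(groups, !!!rlang::syms(keys))
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$group),
                             total = sum(.data$n))
  dplyr::arrange(dplyr::left_join(counts, totals, by = "group"),
                 dplyr::desc(.data$total), .data$group)
}

#' Frequency table of a categorical haplotype label per population
#'
#' @param labels Tibble with one row per haplotype carrying a population
#'   column and the category column (e.g. [panel_promoter_types()] output
#'   with `promoter_type`, or [enumerate_haplotypes()] output with
#'   `group`).
#' @param category Column name of the category (string).
#' @param level `"metapop"` or `"subpop"`.
#' @param overall Add a pooled `"ALL"` population row set.
#' @return Tibble: population, category, `n`, `total`, `frequency`.
#' @export
frequency_table <- function(labels, category = "promoter_type",
                            level = c("metapop", "subpop"),
                            overall = TRUE) {
  level <- match.arg(level)
  stopifnot(category %in% names(labels), level %in% names(labels))
  df <- labels[, c(level, category)]
  names(df) <- c("population", "category")
  if (overall) {
    df <- dplyr::bind_rows(df, dplyr::mutate(df, population = "ALL"))
  }
  counts <- dplyr::count(df, .data$population, .data$category, name = "n")
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$population),
                          total = sum(.data$n),
                          frequency = .data$n / .data$total)
  dplyr::ungroup(counts)
}

#' Fold difference between two frequencies
#'
#' @param freq_a Numerator frequency.
#' @param freq_b Denominator frequency (must be > 0).
#' @return `freq_a / freq_b`.
#' @export
#' @examples
#' fold_difference(969 / 1006, 625 / 1322)  # ~2.04, TCT EUR vs AFR
fold_difference <- function(freq_a, freq_b) {
  if (any(freq_b <= 0)) stop("zero or negative denominator", call. = FALSE)
  freq_a / freq_b
}

#' Nucleotide diversity of a set of sequences
#'
#' Mean over all sequence pairs of the per-pair proportion of differing
#' sites, with sites carrying `N` in either member of a pair excluded from
#' that pair's comparison (pairwise deletion).
#'
#' @param alleles Character matrix (sequences x sites) over `{A,C,G,T,N}`.
#' @return Mean pairwise difference per site (a proportion).
#' @export
nucleotide_diversity <- function(alleles) {
  n <- nrow(alleles)
  if (is.null(n) || n < 2L) stop("need >= 2 sequences", call. = FALSE)
  pairs <- utils::combn(n, 2)
  d <- apply(pairs, 2, function(ij) {
    a <- alleles[ij[1], ]
    b <- alleles[ij[2], ]
    ok <- a != "N" & b != "N"
    if (!any(ok)) return(NA_real_)
    mean(a[ok] != b[ok])
  })
  mean(d, na.rm = TRUE)
}

#' Exact two-sided comparison of two proportions
#'
#' Fisher's exact test on the 2x2 table of carrier counts, the convention
#' used here for comparing haplotype frequencies between populations at
#' small counts.
#'
#' @param count_a,n_a Carrier count and total in population A.
#' @param count_b,n_b Carrier count and total in population B.
#' @return Tibble: `p_value`, `odds_ratio`, plus the inputs.
#' @export
compare_proportions <- function(count_a, n_a, count_b, n_b) {
  stopifnot(count_a <= n_a, count_b <= n_b)
  ft <- stats::fisher.test(matrix(c(count_a, n_a - count_a,
                                    count_b, n_b - count_b), nrow = 2))
  tibble::tibble(count_a = count_a, n_a = n_a, count_b = count_b, n_b = n_b,
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
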