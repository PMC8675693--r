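#' Evolutionary parameters of the promoter region
#'
#' Constants used throughout tract dating and introgression tests:
#' recombination rate `r` (per bp per generation; default 3.3 cM/Mb),
#' mutation rate `mu` (per site per year), generation time `g` (years),
#' and the split/introgression times (years) of the archaic scenario.
#'
#' @param r Recombination rate per bp per generation.
#' @param mu Mutation rate per site per year.
#' @param g Generation time in years.
#' @param t_split_amh_ah Length-2 vector: modern-archaic split time
#'   bounds in years.
#' @param t_split_nea_den Neanderthal-Denisovan split time, years.
#' @param t_introgression Archaic-into-modern introgression time, years.
#' @return A list of class `evo_params`.
#' @export
evo_params <- function(r = 3.3e-8, mu = 0.5e-9, g = 29,
                       t_split_amh_ah = c(550000, 765000),
                       t_split_nea_den = 450000,
                       t_introgression = 50000) {
  stopifnot(r > 0, mu > 0, g > 0, all(t_split_amh_ah > 0),
            t_split_nea_den > 0, t_introgression > 0)
  structure(list(r = r, mu = mu, g = g, t_split_amh_ah = t_split_amh_ah,
                 t_split_nea_den = t_split_nea_den,
                 t_introgression = t_introgression),
            class = "evo_params")
}

#' Construct an unphased archaic diploid
#'
#' @param sample Sample label (e.g. `"Denisovan"`).
#' @param positions Site positions (must align with the modern panel).
#' @param geno Character matrix 2 x sites: the unordered allele pair at
#'   each site; both rows `"N"` where the call is missing.
#' @return Object of class `archaic_diploid`.
#' @export
archaic_diploid <- function(sample, positions, geno) {
  stopifnot(is.matrix(geno), nrow(geno) == 2L,
            ncol(geno) == length(positions))
  n_one <- xor(geno[1, ] == "N", geno[2, ] == "N")
  if (any(n_one)) stop("missing calls must blank both alleles", call. = FALSE)
  structure(list(sample = as.character(sample),
                 positions = as.integer(positions), geno = geno),
            class = "archaic_diploid")
}

#' @export
print.archaic_diploid <- function(x, ...) {
  het <- sum(x$geno[1, ] != x$geno[2, ] & x$geno[1, ] != "N")
  cat(sprintf("<archaic_diploid> %s: %d sites, %d heterozygous, %d missing\n",
              x$sample, ncol(x$geno), het, sum(x$geno[1, ] == "N")))
  invisible(x)
}

is_het <- function(dip) dip$geno[1, ] != dip$geno[2, ] & dip$geno[1, ] != "N"

#' Phase an archaic diploid against a fully homozygous reference
#'
#' The promoter region is homozygous in the Altai Neanderthal, so its
#' sequence fixes the allelic linkage of the other archaic genomes:
#' at each heterozygous target site the allele matching the reference is
#' assigned to haplotype `-2` (the Altai-sharing phase) and the other
#' allele to haplotype `-1`. Homozygous target sites are copied to both
#' haplotypes. Heterozygous sites where the reference is missing cannot be
#' resolved and become `N` on both haplotypes.
#'
#' @param target An [archaic_diploid()] to phase.
#' @param reference An [archaic_diploid()] homozygous (or missing) at
#'   every site.
#' @return List of class `phased_archaic`: `hap1`, `hap2` (character
#'   vectors named `"<sample>-1"`, `"<sample>-2"`), `resolution` per site
#'   in `{homozygous, reference_resolved, unresolved}`, `positions`.
#' @export
phase_by_reference <- function(target, reference) {
  stopifnot(inherits(target, "archaic_diploid"),
            inherits(reference, "archaic_diploid"),
            identical(target$positions, reference$positions))
  if (any(is_het(reference))) {
    stop("reference not homozygous", call. = FALSE)
  }
  ref <- reference$geno[1, ]
  a <- target$geno[1, ]
  b <- target$geno[2, ]
  het <- a != b & a != "N"
  hap1 <- a
  hap2 <- b
  resolution <- ifelse(a == "N", "missing", "homozygous")
  # het, reference known: reference-matching allele -> hap2
  known <- het & ref != "N"
  match_a <- known & a == ref
  match_b <- known & b == ref
  hap2[match_a] <- a[match_a]; hap1[match_a] <- b[match_a]
  hap2[match_b] <- b[match_b]; hap1[match_b] <- a[match_b]
  neither <- known & !(a == ref | b == ref)
  # het but matching neither reference allele: leave input order, flag
  resolution[known] <- "reference_resolved"
  resolution[neither] <- "unresolved"
  unres <- het & ref == "N"
  hap1[unres] <- "N"; hap2[unres] <- "N"
  resolution[unres] <- "unresolved"
  structure(list(
    hap1 = stats::setNames(hap1, NULL), hap2 = stats::setNames(hap2, NULL),
    sample = target$sample,
    hap_ids = paste0(target$sample, c("-1", "-2")),
    resolution = resolution, positions = target$positions),
    class = "phased_archaic")
}

#' @export
print.phased_archaic <- function(x, ...) {
  cat(sprintf("<phased_archaic> %s: %d sites (%d reference-resolved, %d unresolved)\n",
              x$sample, length(x$positions),
              sum(x$resolution == "reference_resolved"),
              sum(x$resolution == "unresolved")))
  invisible(x)
}

# Per-site distance between two unordered allele pairs: minimum mismatch
# count over the two phase pairings, halved.
pair_site_distance <- function(a1, a2, b1, b2) {
  p1 <- (a1 != b1) + (a2 != b2)
  p2 <- (a1 != b2) + (a2 != b1)
  pmin(p1, p2) / 2
}

#' Distance between unphased diploid (or haploid) sequences
#'
#' Per site: 0 for identical genotypes, 1/2 where a homozygote differs
#' from a heterozygote sharing one allele (and analogous one-allele
#' overlaps), 1 where no pairing matches. Haploid input is treated as a
#' homozygous diploid, so a haploid-vs-homozygote mismatch scores 1 and
#' haploid-vs-heterozygote-sharing scores 1/2, as in diploid distance
#' matrices over archaic genomes. Sites missing in either sequence are
#' skipped.
#'
#' @param a,b Each an [archaic_diploid()] or a haploid character vector
#'   aligned to the same sites.
#' @return Tibble: `distance` (sum over compared sites),
#'   `compared_sites`.
#' @export
diploid_distance <- function(a, b) {
  as_pair <- function(x) {
    if (inherits(x, "archaic_diploid")) x$geno else rbind(x, x)
  }
  ga <- as_pair(a); gb <- as_pair(b)
  stopifnot(ncol(ga) == ncol(gb))
  ok <- ga[1, ] != "N" & gb[1, ] != "N"
  d <- pair_site_distance(ga[1, ok], ga[2, ok], gb[1, ok], gb[2, ok])
  tibble::tibble(distance = sum(d), compared_sites = sum(ok))
}

#' Pairwise diploid distance matrix
#'
#' @param seqs Named list of [archaic_diploid()] objects and/or haploid
#'   character vectors over the same sites.
#' @return A `diff_matrix` (possibly half-integer entries).
#' @export
diploid_distance_matrix <- function(seqs) {
  n <- length(seqs)
  labs <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  cmp <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dd <- diploid_distance(seqs[[i]], seqs[[j]])
      d[i, j] <- d[j, i] <- dd$distance
      cmp[i, j] <- cmp[j, i] <- dd$compared_sites
    }
  }
  structure(list(differences = d, compared = cmp), class = "diff_matrix")
}

#' Longest identical tract between two haploid sequences around an anchor
#'
#' The maximal run of compared sites containing the anchor with zero
#' mismatches. Sites where either sequence is `N` are skipped and never
#' break a run. The tract interval runs from just right of the nearest
#' mismatch left of the anchor to just left of the nearest mismatch right
#' of it (region edges when there is none); its length is the bp span of
#' that interval.
#'
#' @param query,subject Haploid character vectors aligned to `positions`.
#' @param positions Site positions (1-based, ascending).
#' @param region A [genomic_region()] bounding the tract.
#' @param anchor A position, or a length-2 interval `c(lo, hi)`, inside
#'   `region`.
#' @return Tibble (`tract_hit`): `start`, `end`, `length_bp`,
#'   `compared_sites` (inside the tract), `anchor_mismatch` (TRUE when a
#'   mismatch falls within the anchor itself, in which case length is 0).
#' @export
longest_identical_tract <- function(query, subject, positions, region,
                                    anchor) {
  anchor <- as.integer(anchor)
  if (length(anchor) == 1L) anchor <- c(anchor, anchor)
  if (anchor[1] < region$start || anchor[2] > region$end) {
    stop("anchor outside region", call. = FALSE)
  }
  ok <- query != "N" & subject != "N"
  mm_pos <- positions[ok & query != subject]
  inside <- any(mm_pos >= anchor[1] & mm_pos <= anchor[2])
  if (inside) {
    return(tibble::tibble(start = NA_integer_, end = NA_integer_,
                          length_bp = 0L, compared_sites = 0L,
                          anchor_mismatch = TRUE))
  }
  left_mm <- mm_pos[mm_pos < anchor[1]]
  right_mm <- mm_pos[mm_pos > anchor[2]]
  start <- if (length(left_mm)) max(left_mm) + 1L else region$start
  end <- if (length(right_mm)) min(right_mm) - 1L else region$end
  tibble::tibble(start = start, end = end,
                 length_bp = end - start + 1L,
                 compared_sites = sum(ok & positions >= start &
                                        positions <= end),
                 anchor_mismatch = FALSE)
}

#' Rank panel haplotypes by shared-tract length with a query
#'
#' Computes [longest_identical_tract()] of the query against every panel
#' haplotype and ranks partners by tract length (ties broken by label).
#'
#' @param query Haploid character vector aligned to the panel's sites.
#' @param panel A [hap_panel()] of subject haplotypes (non-empty).
#' @param anchor Anchor position or interval (see
#'   [longest_identical_tract()]).
#' @param types Optional [panel_promoter_types()] tibble to annotate
#'   partners.
#' @return Tibble sorted by `length_bp` descending: `partner`,
#'   (`promoter_type`,) tract fields.
#' @export
rank_tract_partners <- function(query, panel, anchor, types = NULL) {
  if (nrow(panel$alleles) == 0L) stop("empty subject set", call. = FALSE)
  hits <- purrr::map_dfr(rownames(panel$alleles), function(h) {
    dplyr::mutate(
      longest_identical_tract(query, panel$alleles[h, ], panel$positions,
                              panel$region, anchor),
      partner = h, .before = 1)
  })
  if (!is.null(types)) {
    hits <- dplyr::left_join(hits,
      stats::setNames(types[, c("haplotype", "promoter_type")],
                      c("partner", "promoter_type")), by = "partner")
  }
  dplyr::arrange(hits, dplyr::desc(.data$length_bp), .data$partner)
}

#' Label the mosaic donor structure of a recombinant sequence
#'
#' Each compared site is assigned to the donor type whose identical tract
#' through that site is locally longest; adjacent same-type assignments
#' are merged into segments with breakpoints at the midpoints between
#' differently-assigned neighbouring sites. A `TGT-CGT-TGT` label series,
#' for instance, indicates a central donor segment swapped into a TGT
#' background by two crossovers.
#'
#' @param query Haploid character vector.
#' @param donors Named list of haploid representative sequences, one per
#'   donor promoter type (>= 2).
#' @param positions Site positions.
#' @param region A [genomic_region()].
#' @return Tibble: `segment`, `type`, `start`, `end`.
#' @export
infer_mosaic_structure <- function(query, donors, positions, region) {
  if (length(donors) < 2L) stop("need >= 2 donor types", call. = FALSE)
  run_span <- function(donor) {
    ok <- query != "N" & donor != "N"
    mm <- positions[ok & query != donor]
    vapply(positions, function(p) {
      if (any(mm == p)) return(0)
      left <- mm[mm < p]; right <- mm[mm > p]
      lo <- if (length(left)) max(left) + 1L else region$start
      hi <- if (length(right)) min(right) - 1L else region$end
      as.numeric(hi - lo + 1L)
    }, numeric(1))
  }
  spans <- vapply(donors, run_span, numeric(length(positions)))
  if (is.null(dim(spans))) spans <- matrix(spans, nrow = 1)
  lab <- names(donors)[apply(spans, 1, which.max)]
  # collapse consecutive identical labels into segments
  runs <- rle(lab)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  seg_start <- vapply(seq_along(runs$values), function(k) {
    if (k == 1L) region$start
    else as.integer(floor((positions[starts_idx[k]] +
                             positions[ends_idx[k - 1]]) / 2)) + 1L
  }, integer(1))
  seg_end <- c(seg_start[-1] - 1L, region$end)
  tibble::tibble(segment = seq_along(runs$values), type = runs$values,
                 start = seg_start, end = seg_end)
}

#' Posterior lower bound on an allele frequency
#'
#' One-sided credible bound from the Beta posterior under a uniform prior:
#' with `n_type` observed alleles of the focal type and `n_other` others,
#' the posterior is `Beta(n_type + 1, n_other + 1)` and the bound `f0`
#' satisfies `P(f > f0 | data) = level`. With four archaic individuals all
#' homozygous for one promoter type (8 alleles, 0 others) the 95% bound is
#' 71.7%.
#'
#' @param n_type,n_other Observed allele counts.
#' @param level Credibility level in (0, 1), default 0.95.
#' @return The lower bound `f0` (a frequency).
#' @export
#' @examples
#' beta_frequency_lower_bound(8, 0)  # 0.717
beta_frequency_lower_bound <- function(n_type, n_other, level = 0.95) {
  stopifnot(n_type >= 0, n_other >= 0, level > 0, level < 1)
  stats::qbeta(1 - level, n_type + 1, n_other + 1)
}

#' Probability that a tract survives unrecombined
#'
#' `exp(-m * r * t_total / g)`: the chance that no crossover falls in a
#' tract of `m` bp over `t_total` years of lineage time. A small value for
#' an observed shared tract rejects the shared-ancestral (incomplete
#' lineage sorting) explanation in favour of recent introgression.
#'
#' @param m Tract length in bp.
#' @param params An [evo_params()].
#' @param t_total Total lineage time in years over which the tract must
#'   survive (scenario-dependent; always passed explicitly).
#' @return Survival probability.
#' @export
tract_survival_probability <- function(m, params, t_total) {
  stopifnot(m >= 0, t_total > 0)
  exp(-m * params$r * t_total / params$g)
}

#' Range of raw site differences between two haplotype sets
#'
#' Used to calibrate the modern-archaic divergence band from a known
#' introgressed lineage: the min and max pairwise raw differences across
#' the two sets, after excluding known recombinant haplotypes.
#'
#' @param alleles_a,alleles_b Character matrices (haplotypes x sites) over
#'   the same sites; row names are haplotype ids.
#' @param exclusions Haplotype ids to drop from either set.
#' @return Tibble: `min`, `max`, `n_pairs`.
#' @export
amh_ah_difference_range <- function(alleles_a, alleles_b,
                                    exclusions = character()) {
  keep <- function(m) m[!rownames(m) %in% exclusions, , drop = FALSE]
  a <- keep(alleles_a); b <- keep(alleles_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("empty set after exclusion", call. = FALSE)
  }
  d <- vapply(seq_len(nrow(a)), function(i) {
    vapply(seq_len(nrow(b)), function(j) {
      ok <- a[i, ] != "N" & b[j, ] != "N"
      sum(a[i, ok] != b[j, ok])
    }, numeric(1))
  }, numeric(nrow(b)))
  tibble::tibble(min = min(d), max = max(d), n_pairs = length(d))
}
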