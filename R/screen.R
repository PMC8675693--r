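#' Five-step screen for archaic-ancestry candidate haplotypes
#'
#' Hunts for haplotypes of modern populations that descend from archaic
#' introgression even though no archaic sample carries their promoter
#' type. The divergence band (`amh_ah_range`) is calibrated beforehand —
#' from a known introgressed lineage via [amh_ah_difference_range()] or
#' from split-time expectations via [expected_pairwise_differences()] —
#' and the screen then proceeds:
#'
#' 1. (input) the modern-archaic site-difference range;
#' 2. select haplotype groups showing at least one pairwise difference
#'    inside that range;
#' 3. build an NJ tree of the selected groups and record its two-cluster
#'    partition (split at the longest internal edge);
#' 4. reject groups distributed widely in Africa (present in
#'    `min_afr_subpops` or more African subpopulations) together with
#'    their close relatives at fewer than `min(range)` differences;
#' 5. examine the ages of variants shared only by (else unique to) the
#'    remaining groups: groups whose examined ages all fall outside the
#'    introgression window are rejected; groups with no age information
#'    are flagged `age_unknown`, not silently rejected.
#'
#' @param panel A [hap_panel()], typically MAF-filtered at 0.5%.
#' @param amh_ah_range Numeric length-2: `c(min, max)` site differences,
#'   or the tibble from [amh_ah_difference_range()].
#' @param african_subpops Character vector of subpopulation codes counted
#'   as African for step 4.
#' @param age_table Tibble with columns `variant_id` (matching panel site
#'   ids) and `age_years`; `NULL` disables step 5 (all step-4 survivors
#'   flagged `age_unknown`).
#' @param introgression_window Length-2 years, default `c(30000, 80000)`.
#' @param min_afr_subpops Step-4 "widely distributed" threshold, default 2.
#' @param haplotypes Optional haplotype ids delimiting the focal set
#'   (e.g. one promoter type in one meta-population); groups touching the
#'   set are screened against the whole panel.
#' @return Object of class `screen_result`: `survivors`, `audit` (one row
#'   per screened group with per-step outcomes), `tree`, `clusters`,
#'   `params`.
#' @export
archaic_candidate_screen <- function(panel, amh_ah_range, african_subpops,
                                     age_table = NULL,
                                     introgression_window = c(30000, 80000),
                                     min_afr_subpops = 2,
                                     haplotypes = NULL) {
  if (is.data.frame(amh_ah_range)) {
    amh_ah_range <- c(amh_ah_range$min[1], amh_ah_range$max[1])
  }
  lo <- amh_ah_range[1]; hi <- amh_ah_range[2]
  stopifnot(lo <= hi, length(introgression_window) == 2L)

  groups <- enumerate_haplotypes(panel)
  reps <- unique(groups$group)
  if (!is.null(haplotypes)) {
    focal <- unique(groups$group[groups$haplotype %in% haplotypes])
  } else {
    focal <- reps
  }
  rep_alleles <- panel$alleles[reps, , drop = FALSE]
  dm <- pairwise_difference_matrix(rep_alleles)
  d <- dm$differences

  # Step 2: any pairwise difference inside the calibrated range
  in_range <- d >= lo & d <= hi
  diag(in_range) <- FALSE
  selected <- reps[reps %in% focal & rowSums(in_range[reps, , drop = FALSE]) > 0]

  # Step 3: NJ tree of selected groups, two-cluster partition
  tree <- NULL
  clusters <- tibble::tibble(group = selected,
                             cluster = rep(1L, length(selected)))
  if (length(selected) >= 3L) {
    sub_dm <- structure(list(
      differences = d[selected, selected],
      compared = dm$compared[selected, selected]), class = "diff_matrix")
    tree <- nj_tree(sub_dm)
    clusters <- two_cluster_partition(tree)
  }

  # Step 4: African-widespread groups and their close relatives
  afr_width <- vapply(reps, function(g) {
    members <- groups$haplotype[groups$group == g]
    length(unique(groups$subpop[groups$haplotype %in% members &
                                  groups$subpop %in% african_subpops]))
  }, integer(1))
  widespread <- reps[afr_width >= min_afr_subpops]
  wide_sel <- intersect(selected, widespread)
  relatives <- character()
  if (length(widespread)) {
    rel_d <- d[selected, widespread, drop = FALSE]
    relatives <- selected[apply(rel_d, 1, function(x) any(x < lo))]
  }
  rejected4 <- union(wide_sel, setdiff(relatives, wide_sel))
  remaining <- setdiff(selected, rejected4)

  # Step 5: ages of variants shared only by (else unique to) the remaining
  step5 <- tibble::tibble(group = remaining,
                          status = rep("retained", length(remaining)),
                          ages_examined = rep(list(numeric()), length(remaining)))
  if (length(remaining)) {
    priv <- private_variants(panel, groups, remaining)
    for (k in seq_along(remaining)) {
      g <- remaining[k]
      vids <- priv$variant_id[vapply(priv$carrier_groups,
                                     function(cg) g %in% cg, logical(1))]
      if (!length(vids) || is.null(age_table)) {
        step5$status[k] <- "age_unknown"
        next
      }
      ages <- age_table$age_years[match(vids, age_table$variant_id)]
      known <- ages[!is.na(ages)]
      step5$ages_examined[[k]] <- known
      if (!length(known)) {
        step5$status[k] <- "age_unknown"
      } else if (!any(known >= introgression_window[1] &
                      known <= introgression_window[2])) {
        step5$status[k] <- "rejected_age"
      }
    }
  }
  survivors <- step5$group[step5$status != "rejected_age"]

  audit <- tibble::tibble(
    group = reps,
    focal = reps %in% focal,
    selected_step2 = reps %in% selected,
    afr_subpop_count = afr_width,
    rejected_step4 = reps %in% rejected4,
    step4_reason = dplyr::case_when(
      reps %in% wide_sel ~ "afr_widespread",
      reps %in% relatives & reps %in% selected ~ "relative_of_widespread",
      TRUE ~ NA_character_),
    step5_status = step5$status[match(reps, step5$group)],
    survivor = reps %in% survivors
  )
  structure(list(
    survivors = survivors,
    audit = audit,
    step5 = step5,
    tree = tree,
    clusters = clusters,
    difference_matrix = dm,
    groups = groups,
    params = list(amh_ah_range = c(lo, hi),
                  african_subpops = african_subpops,
                  introgression_window = introgression_window,
                  min_afr_subpops = min_afr_subpops)),
    class = "screen_result")
}

# Split an unrooted tree into the two leaf clusters flanking its longest
# internal edge (the expected modern/archaic partition in step 3).
two_cluster_partition <- function(tree) {
  n_tip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > n_tip)
  if (!length(internal)) {
    return(tibble::tibble(group = tree$tip.label, cluster = 1L))
  }
  e <- internal[which.max(tree$edge.length[internal])]
  below <- tree$tip.label[phangorn_descendants(tree, tree$edge[e, 2])]
  tibble::tibble(group = tree$tip.label,
                 cluster = ifelse(tree$tip.label %in% below, 2L, 1L))
}

# Variants (site, non-major allele) whose panel carriers all belong to the
# given groups. shared = carried by >=2 of them, unique = confined to one;
# unique variants are reported only for groups with no shared variant.
private_variants <- function(panel, groups, remaining) {
  members <- split(groups$haplotype, groups$group)[remaining]
  out <- list()
  for (j in seq_len(ncol(panel$alleles))) {
    col <- panel$alleles[, j]
    obs <- col[col != "N"]
    if (!length(obs)) next
    major <- names(which.max(table(obs)))
    for (al in setdiff(unique(obs), major)) {
      carriers <- rownames(panel$alleles)[col == al]
      carrier_groups <- remaining[vapply(members, function(m)
        any(carriers %in% m), logical(1))]
      in_groups <- unlist(members[carrier_groups], use.names = FALSE)
      if (length(carrier_groups) && all(carriers %in% in_groups)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          variant_id = panel$site_ids[j], allele = al,
          n_carriers = length(carriers),
          sharing = if (length(carrier_groups) > 1L) "shared" else "unique",
          carrier_groups = list(carrier_groups))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(variant_id = character(), allele = character(),
                          n_carriers = integer(), sharing = character(),
                          carrier_groups = list()))
  }
  res <- dplyr::bind_rows(out)
  if (any(res$sharing == "shared")) res[res$sharing == "shared", ] else res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d group(s) screened, %d selected, %d survivor(s)\n",
              nrow(x$audit), sum(x$audit$selected_step2),
              length(x$survivors)))
  if (length(x$survivors)) {
    cat("  survivors:", paste(x$survivors, collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy a screen result into its per-group audit table
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return The audit tibble (one row per haplotype group).
#' @export
tidy.screen_result <- function(x, ...) x$audit

#' One-row summary of a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return Tibble with group/selection/survivor counts and the range used.
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$audit),
    n_selected = sum(x$audit$selected_step2),
    n_rejected_afr = sum(x$audit$rejected_step4, na.rm = TRUE),
    n_survivors = length(x$survivors),
    range_min = x$params$amh_ah_range[1],
    range_max = x$params$amh_ah_range[2])
}

#' Write the screen audit as a structured JSON report
#'
#' @param x A `screen_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(x, path) {
  report <- list(
    params = x$params,
    survivors = x$survivors,
    audit = x$audit,
    clusters = x$clusters)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
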