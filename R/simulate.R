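#' Configuration for the synthetic study-design generator
#'
#' Describes the simulated locus the way the real one is structured: a
#' 40-kb window whose central 18-kb core (flanked by recombination
#' hotspots) carries the three promoter SNPs; meta-populations with
#' planted promoter-type compositions; a star-shaped haplotype genealogy
#' (type stems, templates within types, private tip branches); and an
#' optional archaic donor lineage introgressed at low frequency.
#'
#' @param seed Integer seed; every stochastic step derives from it.
#' @param window A [genomic_region()]: the simulated window (default
#'   40 kb on chr15).
#' @param core A [genomic_region()]: the 18-kb low-recombination core.
#' @param promoter_positions Positions of the three promoter SNPs
#'   (rs3759916, rs3759915, rs3759914), inside `core`.
#' @param pops Tibble with `subpop`, `metapop`, `n_samples` (diploid
#'   samples per subpopulation).
#' @param type_freqs Named list: per metapop, a named numeric vector of
#'   promoter-type frequencies summing to <= 1 (remainder drawn as the
#'   listed types' renormalisation; defaults follow the study's global
#'   compositions).
#' @param params An [evo_params()].
#' @param n_templates Templates per promoter type.
#' @param t_root,t_type,t_tip Depths (years) of the type stems' common
#'   root, the template radiation within each type, and the private tip
#'   branches.
#' @param recomb_expected Expected template-switch crossovers per sampled
#'   haplotype (an effective sample-survival rate; the raw map rate would
#'   apply to the full coalescent, not this star approximation).
#' @param introgression `NULL`, or a list with `donor_type`,
#'   `recipient_metapop`, `recipient_freq`, and optionally `t_split`
#'   (donor split, years; default `mean(params$t_split_amh_ah)`).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       window = genomic_region("chr15", 92901001, 92941000,
                                               "simulated window"),
                       core = genomic_region("chr15", 92912001, 92930000,
                                             "promoter core"),
                       promoter_positions = c(92919500, 92920500, 92921500),
                       pops = default_sim_pops(),
                       type_freqs = default_type_freqs(),
                       params = evo_params(),
                       n_templates = 3,
                       t_root = 400000, t_type = 250000, t_tip = 100000,
                       recomb_expected = 0.05,
                       introgression = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stopifnot(core$start >= window$start, core$end <= window$end)
  stopifnot(all(promoter_positions > core$start &
                  promoter_positions < core$end),
            length(promoter_positions) == 3L)
  stopifnot(all(c("subpop", "metapop", "n_samples") %in% names(pops)))
  for (f in type_freqs) {
    stopifnot(all(names(f) %in% PROMOTER_TYPES), sum(f) <= 1 + 1e-9,
              all(f >= 0))
  }
  stopifnot(t_root > t_type, t_type > t_tip, t_tip > 0)
  if (!is.null(introgression)) {
    introgression$t_split <- introgression$t_split %||%
      mean(params$t_split_amh_ah)
    stopifnot(introgression$t_split > params$t_introgression)
  }
  structure(list(seed = as.integer(seed), window = window, core = core,
                 promoter_positions = as.integer(promoter_positions),
                 pops = tibble::as_tibble(pops), type_freqs = type_freqs,
                 params = params, n_templates = n_templates,
                 t_root = t_root, t_type = t_type, t_tip = t_tip,
                 recomb_expected = recomb_expected,
                 introgression = introgression),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname sim_config
#' @export
default_sim_pops <- function() {
  tibble::tibble(
    subpop = c("YRI", "LWK", "ESN", "CEU", "GBR", "GIH", "PJL",
               "CHB", "JPT", "MXL"),
    metapop = c("AFR", "AFR", "AFR", "EUR", "EUR", "SAS", "SAS",
                "EAS", "EAS", "AMR"),
    n_samples = rep(25L, 10))
}

#' @rdname sim_config
#' @export
default_type_freqs <- function() {
  # meta-population compositions = the study's allele counts / totals
  list(AFR = c(TGT = 612, TCT = 625, CGT = 46, CGC = 11) / 1322,
       EUR = c(TGT = 33, TCT = 969, CGT = 1, CGC = 2) / 1006,
       SAS = c(TGT = 109, TCT = 782, CGT = 11, CGC = 76) / 978,
       EAS = c(TGT = 133, TCT = 515, CGT = 8, CGC = 349) / 1008,
       AMR = c(TGT = 126, TCT = 478, CGT = 8, CGC = 82) / 694)
}

# Promoter-SNP alleles per type, in rs3759916/rs3759915/rs3759914 order.
type_triplet <- function(type) strsplit(type, "")[[1]]

# Draw k distinct positions not yet used (infinite-sites approximation).
draw_positions <- function(k, window, used) {
  if (k == 0L) return(integer())
  avail <- setdiff(seq(window$start, window$end), used)
  sort(sample(avail, k))
}

#' Simulate a phased haplotype panel with planted promoter types
#'
#' Haplotypes evolve on a star genealogy: a common root at `t_root`, one
#' stem per promoter type, `n_templates` template lineages radiating at
#' `t_type`, and private tip branches below `t_tip`. Mutations fall as
#' Poisson counts (`mu * L * branch_years`) at unique uniform positions;
#' the three promoter SNP sites are set by each haplotype's assigned
#' type. Rare template-switch crossovers outside the promoter triplet
#' emulate surviving recombinants.
#'
#' @param config A [sim_config()].
#' @return List of class `hap_sim`: `panel` (a [hap_panel()] over the
#'   window), `truth` (list: `assignments`, `events`, `templates`,
#'   `config`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$params
  Lw <- region_length(config$window)
  types <- sort(unique(unlist(lapply(config$type_freqs, names))))

  # --- mutation events per branch of the star genealogy ---------------
  used <- config$promoter_positions
  events <- list()
  add_events <- function(branch, n, t_lo, t_hi) {
    if (n == 0L) return(invisible())
    pos <- draw_positions(n, config$window, used)
    used <<- c(used, pos)
    events[[length(events) + 1L]] <<- tibble::tibble(
      position = pos, branch = branch,
      age_years = stats::runif(n, t_lo, t_hi))
    invisible()
  }
  for (ty in types) {
    add_events(paste0("type:", ty),
               stats::rpois(1, p$mu * Lw * (config$t_root - config$t_type)),
               config$t_type, config$t_root)
    for (m in seq_len(config$n_templates)) {
      add_events(paste0("template:", ty, ":", m),
                 stats::rpois(1, p$mu * Lw * (config$t_type - config$t_tip)),
                 config$t_tip, config$t_type)
    }
  }

  # --- sample assignment ----------------------------------------------
  assign_rows <- list()
  for (i in seq_len(nrow(config$pops))) {
    sp <- config$pops$subpop[i]
    mp <- config$pops$metapop[i]
    f <- config$type_freqs[[mp]]
    n_hap <- 2L * config$pops$n_samples[i]
    hap_types <- sample(names(f), n_hap, replace = TRUE, prob = f / sum(f))
    samples <- sprintf("%s%04d", sp, seq_len(config$pops$n_samples[i]))
    assign_rows[[i]] <- tibble::tibble(
      haplotype = as.vector(rbind(paste0(samples, ".0"),
                                  paste0(samples, ".1"))),
      sample = rep(samples, each = 2), subpop = sp, metapop = mp,
      promoter_type = hap_types,
      template = sample.int(config$n_templates, n_hap, replace = TRUE))
  }
  assignments <- dplyr::bind_rows(assign_rows)

  # tip mutations, private per haplotype
  for (h in assignments$haplotype) {
    add_events(paste0("tip:", h),
               stats::rpois(1, p$mu * Lw * config$t_tip), 0, config$t_tip)
  }
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(position = integer(), branch = character(),
                   age_years = numeric())

  # --- site registry ---------------------------------------------------
  positions <- sort(c(config$promoter_positions, events$position))
  n_sites <- length(positions)
  anc <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  der <- vapply(anc, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
  prom_idx <- match(config$promoter_positions, positions)
  events$site <- match(events$position, positions)
  events$ancestral <- anc[events$site]
  events$derived <- der[events$site]

  # --- build haplotype sequences --------------------------------------
  branch_sets <- split(events$site, events$branch)
  template_seq <- function(ty, m) {
    s <- anc
    for (b in c(paste0("type:", ty), paste0("template:", ty, ":", m))) {
      s[branch_sets[[b]]] <- der[branch_sets[[b]]]
    }
    s
  }
  templates <- list()
  for (ty in types) for (m in seq_len(config$n_templates)) {
    templates[[paste0(ty, ":", m)]] <- template_seq(ty, m)
  }
  site_ids <- paste0("pos", positions)
  prom_idx2 <- match(config$promoter_positions, positions)
  site_ids[prom_idx2] <- c("rs3759916", "rs3759915", "rs3759914")
  attr(templates, "site_ids") <- site_ids

  n_hap <- nrow(assignments)
  alleles <- matrix("N", n_hap, n_sites,
                    dimnames = list(assignments$haplotype, NULL))
  crossovers <- vector("list", n_hap)
  template_keys <- names(templates)
  for (k in seq_len(n_hap)) {
    ty <- assignments$promoter_type[k]
    key <- paste0(ty, ":", assignments$template[k])
    s <- templates[[key]]
    # template-switch crossovers in the flanks (promoter span untouched)
    n_x <- stats::rpois(1, config$recomb_expected)
    if (n_x > 0) {
      span <- range(config$promoter_positions)
      bp <- sample(setdiff(seq(config$window$start, config$window$end),
                           seq(span[1], span[2])), n_x)
      donor_key <- sample(setdiff(template_keys, key), 1)
      dseq <- templates[[donor_key]]
      # alternate segments between own template and the partner template
      cuts <- sort(bp)
      seg_of <- findInterval(positions, cuts)
      own_seg <- findInterval(span[1], cuts)  # segment holding the promoter
      swap <- seg_of %% 2 != own_seg %% 2
      s[swap] <- dseq[swap]
      crossovers[[k]] <- list(positions = cuts, partner = donor_key)
    }
    tips <- branch_sets[[paste0("tip:", assignments$haplotype[k])]]
    s[tips] <- der[tips]
    s[prom_idx] <- type_triplet(ty)
    alleles[k, ] <- s
  }

  pop_map <- dplyr::distinct(assignments[, c("sample", "subpop", "metapop")])
  panel <- hap_panel(alleles, positions, config$window, pop_map,
                     site_ids = site_ids)
  assignments$crossovers <- crossovers
  events$site_id <- site_ids[events$site]
  structure(list(panel = panel,
                 truth = list(assignments = assignments, events = events,
                              templates = templates,
                              site_table = tibble::tibble(
                                site_id = site_ids, position = positions,
                                ancestral = anc, derived = der),
                              config = config)),
            class = "hap_sim")
}

#' @export
print.hap_sim <- function(x, ...) {
  cat("<hap_sim>\n")
  print(x$panel)
  if (!is.null(x$truth$carriers)) {
    cat("  planted introgression carriers:",
        length(x$truth$carriers), "\n")
  }
  invisible(x)
}

#' Plant an archaic introgressed lineage into a simulated panel
#'
#' A donor lineage is simulated at `2 * t_split * mu * L` expected
#' divergence from the panel (donor-stem mutations make up the difference
#' between the donor split and the depth already present in the panel's
#' genealogy). Recipient haplotypes drawn at the configured frequency
#' receive donor tracts of Exponential(`g / (r * t_introgression)`) mean
#' length, clipped to the window and centred on the promoter SNPs, plus
#' private post-introgression mutations inside the tract.
#'
#' @param sim A `hap_sim` from [simulate_panel()] whose config carries an
#'   `introgression` block.
#' @return The modified `hap_sim`; `truth` gains `carriers`, `tracts`,
#'   `donor_sequence`, and donor/post-introgression event rows.
#' @export
plant_introgression <- function(sim) {
  config <- sim$truth$config
  intro <- config$introgression
  if (is.null(intro)) stop("config has no introgression block", call. = FALSE)
  set.seed(config$seed + 1000003L)
  p <- config$params
  Lw <- region_length(config$window)
  panel <- sim$panel
  assignments <- sim$truth$assignments

  recipients <- assignments$haplotype[assignments$metapop ==
                                        intro$recipient_metapop]
  n_carriers <- stats::rbinom(1, length(recipients), intro$recipient_freq)
  if (n_carriers == 0L && intro$recipient_freq > 0) n_carriers <- 1L
  carriers <- if (n_carriers > 0) sample(recipients, n_carriers) else
    character()

  # donor stem: make total modern-vs-donor divergence ~ 2 * t_split * mu * L
  stem_years <- 2 * intro$t_split - config$t_root
  n_stem <- stats::rpois(1, p$mu * Lw * stem_years)
  used <- panel$positions
  stem_pos <- draw_positions(n_stem, config$window, used)
  anc_new <- sample(c("A", "C", "G", "T"), n_stem, replace = TRUE)
  der_new <- vapply(anc_new, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))

  # splice the new sites into the panel (everyone ancestral there)
  all_pos <- sort(c(panel$positions, stem_pos))
  old_idx <- match(panel$positions, all_pos)
  new_idx <- match(stem_pos, all_pos)
  alleles <- matrix("", nrow(panel$alleles), length(all_pos),
                    dimnames = list(rownames(panel$alleles), NULL))
  alleles[, old_idx] <- panel$alleles
  alleles[, new_idx] <- matrix(rep(anc_new, each = nrow(alleles)),
                               nrow(alleles))
  site_ids <- character(length(all_pos))
  site_ids[old_idx] <- panel$site_ids
  site_ids[new_idx] <- paste0("pos", stem_pos)
  site_tab <- tibble::tibble(
    site_id = site_ids, position = all_pos,
    ancestral = { a <- character(length(all_pos))
      a[old_idx] <- sim$truth$site_table$ancestral; a[new_idx] <- anc_new; a },
    derived = { d <- character(length(all_pos))
      d[old_idx] <- sim$truth$site_table$derived; d[new_idx] <- der_new; d })

  # donor haplotype: root state + stem mutations + donor promoter type
  donor <- site_tab$ancestral
  donor[new_idx] <- der_new
  prom_idx <- match(config$promoter_positions, all_pos)
  donor[prom_idx] <- type_triplet(intro$donor_type)

  events_new <- tibble::tibble(
    position = stem_pos, branch = "donor_stem",
    age_years = stats::runif(n_stem, p$t_introgression, intro$t_split),
    site = new_idx, ancestral = anc_new, derived = der_new,
    site_id = site_ids[new_idx])

  # plant tracts
  span <- range(config$promoter_positions)
  mean_len <- p$g / (p$r * p$t_introgression)
  tracts <- list()
  for (h in carriers) {
    len <- stats::rexp(1, 1 / mean_len)
    centre <- mean(span)
    lo <- max(config$window$start, round(centre - len / 2))
    hi <- min(config$window$end, round(centre + len / 2))
    lo <- min(lo, span[1]); hi <- max(hi, span[2])  # always cover the SNPs
    inside <- all_pos >= lo & all_pos <= hi
    alleles[h, inside] <- donor[inside]
    # post-introgression private mutations on the introgressed segment
    n_post <- stats::rpois(1, p$mu * (hi - lo + 1) * p$t_introgression)
    if (n_post > 0) {
      avail <- setdiff(seq(lo, hi), all_pos)
      post_pos <- sort(sample(avail, min(n_post, length(avail))))
      # splice again
      all_pos2 <- sort(c(all_pos, post_pos))
      idx_old <- match(all_pos, all_pos2)
      idx_new <- match(post_pos, all_pos2)
      a2 <- matrix("", nrow(alleles), length(all_pos2),
                   dimnames = list(rownames(alleles), NULL))
      a2[, idx_old] <- alleles
      anc2 <- sample(c("A", "C", "G", "T"), length(post_pos), TRUE)
      der2 <- vapply(anc2, function(a)
        sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
      a2[, idx_new] <- matrix(rep(anc2, each = nrow(a2)), nrow(a2))
      a2[h, idx_new] <- der2
      sid2 <- character(length(all_pos2))
      sid2[idx_old] <- site_tab$site_id
      sid2[idx_new] <- paste0("pos", post_pos)
      site_tab <- tibble::tibble(
        site_id = sid2, position = all_pos2,
        ancestral = { x <- character(length(all_pos2))
          x[idx_old] <- site_tab$ancestral; x[idx_new] <- anc2; x },
        derived = { x <- character(length(all_pos2))
          x[idx_old] <- site_tab$derived; x[idx_new] <- der2; x })
      donor2 <- character(length(all_pos2))
      donor2[idx_old] <- donor
      donor2[idx_new] <- anc2
      donor <- donor2
      events_new <- dplyr::bind_rows(events_new, tibble::tibble(
        position = post_pos, branch = paste0("postintro:", h),
        age_years = stats::runif(length(post_pos), 0, p$t_introgression),
        site = NA_integer_, ancestral = anc2, derived = der2,
        site_id = sid2[idx_new]))
      alleles <- a2
      all_pos <- all_pos2
      prom_idx <- match(config$promoter_positions, all_pos)
    }
    tracts[[h]] <- tibble::tibble(haplotype = h, start = lo, end = hi,
                                  length_bp = hi - lo + 1)
  }

  assignments$promoter_type[assignments$haplotype %in% carriers] <-
    intro$donor_type
  panel <- hap_panel(alleles, all_pos, config$window, panel$pop_map,
                     site_ids = site_tab$site_id)
  sim$panel <- panel
  sim$truth$assignments <- assignments
  sim$truth$site_table <- site_tab
  sim$truth$events <- dplyr::bind_rows(
    sim$truth$events[, names(events_new)], events_new)
  sim$truth$carriers <- carriers
  sim$truth$tracts <- if (length(tracts)) dplyr::bind_rows(tracts) else
    tibble::tibble(haplotype = character(), start = integer(),
                   end = integer(), length_bp = integer())
  sim$truth$donor_sequence <- stats::setNames(donor, site_tab$site_id)
  sim
}

#' Emulated variant-age table for a simulated panel
#'
#' Stands in for the external variant-age resource the analysis consumes:
#' variants found exclusively on planted introgression carriers are dated
#' around the introgression time (lognormal noise, sd 0.15 on the log
#' scale — a dating method sees such variants enter the modern population
#' at introgression), while all other variants report their true
#' branch-origin times.
#'
#' @param sim A `hap_sim` (after [plant_introgression()] if applicable).
#' @param sd_log Lognormal age noise for carrier-exclusive variants.
#' @return Tibble: `variant_id`, `age_years`, `estimator`.
#' @export
synthetic_age_table <- function(sim, sd_log = 0.15) {
  config <- sim$truth$config
  set.seed(config$seed + 2000003L)
  panel <- sim$panel
  carriers <- sim$truth$carriers %||% character()
  events <- sim$truth$events
  rows <- list()
  for (j in seq_len(ncol(panel$alleles))) {
    col <- panel$alleles[, j]
    obs <- col[col != "N"]
    if (length(unique(obs)) < 2L) next
    major <- names(which.max(table(obs)))
    for (al in setdiff(unique(obs), major)) {
      carrier_ids <- rownames(panel$alleles)[col == al]
      exclusive <- length(carriers) > 0 && all(carrier_ids %in% carriers)
      if (exclusive) {
        age <- config$params$t_introgression *
          exp(stats::rnorm(1, 0, sd_log))
        est <- "introgression_dated"
      } else {
        hit <- events$age_years[events$site_id == panel$site_ids[j]]
        if (!length(hit)) next  # promoter/type-defining site: no event age
        age <- hit[1]
        est <- "branch_truth"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant_id = panel$site_ids[j], age_years = age, estimator = est)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(variant_id = character(), age_years = numeric(),
                          estimator = character()))
  }
  dplyr::distinct(dplyr::bind_rows(rows), .data$variant_id,
                  .keep_all = TRUE)
}

#' Simulate unphased archaic diploids over a panel's sites
#'
#' Builds a small set of archaic individuals from a donor lineage defined
#' over the panel's site set: each individual pairs two donor-lineage
#' haplotypes carrying private branch mutations; one individual can be
#' forced fully homozygous (the reference used for linkage phasing); one
#' can be made a mosaic recombinant whose middle segment is swapped with
#' a modern template. Sites are masked to `N` at `n_mask_rate`.
#'
#' @param sim A `hap_sim`; if introgression was planted its donor
#'   sequence seeds the archaic lineage, otherwise a fresh donor stem is
#'   drawn at the configured split depth.
#' @param samples Character vector of individual labels.
#' @param n_mask_rate Per-site missing-call rate.
#' @param homozygous_reference Label of the individual forced homozygous
#'   (`NULL` for none).
#' @param mosaic Label of the individual whose first haplotype gets a
#'   modern-template middle segment (`NULL` for none).
#' @param t_branch Private branch depth (years) for individual
#'   haplotypes.
#' @return List of class `archaic_sim`: `diploids` (list of
#'   [archaic_diploid()]), `truth` (underlying phased haplotypes and the
#'   mask).
#' @export
simulate_archaic_diploids <- function(sim,
                                      samples = c("Altai", "Vindija",
                                                  "Chagyrskaya",
                                                  "Denisovan"),
                                      n_mask_rate = 0.02,
                                      homozygous_reference = "Altai",
                                      mosaic = "Vindija",
                                      t_branch = 120000) {
  config <- sim$truth$config
  set.seed(config$seed + 3000003L)
  stopifnot(length(samples) >= 1)
  panel <- sim$panel
  p <- config$params
  n_sites <- ncol(panel$alleles)
  site_tab <- sim$truth$site_table

  donor <- if (!is.null(sim$truth$donor_sequence)) {
    unname(sim$truth$donor_sequence)
  } else {
    # fresh donor: flip panel sites at stem depth (over existing sites)
    d <- site_tab$ancestral
    t_split <- mean(p$t_split_amh_ah)
    k <- stats::rpois(1, p$mu * region_length(config$window) *
                        (2 * t_split - config$t_root))
    flip <- sample.int(n_sites, min(k, n_sites))
    d[flip] <- site_tab$derived[flip]
    prom <- match(config$promoter_positions, panel$positions)
    d[prom] <- type_triplet(config$introgression$donor_type %||% "CGT")
    d
  }

  branch_hap <- function() {
    h <- donor
    k <- stats::rpois(1, p$mu * region_length(config$window) * t_branch)
    if (k > 0) {
      flip <- sample.int(n_sites, min(k, n_sites))
      h[flip] <- ifelse(h[flip] == site_tab$derived[flip],
                        site_tab$ancestral[flip], site_tab$derived[flip])
    }
    h
  }
  truth_haps <- list()
  diploids <- list()
  masks <- list()
  for (s in samples) {
    if (!is.null(homozygous_reference) && s == homozygous_reference) {
      h1 <- h2 <- branch_hap()
    } else {
      h1 <- branch_hap()
      h2 <- branch_hap()
    }
    if (!is.null(mosaic) && s == mosaic) {
      # swap a middle segment of h1 with a modern template (type mosaic)
      key <- sample(names(sim$truth$templates), 1)
      tm <- template_on_sites(sim, key)
      span <- range(config$promoter_positions)
      mid <- panel$positions > span[1] - 3000 &
        panel$positions < span[2] + 3000
      h1[mid] <- tm[mid]
    }
    mask <- stats::runif(n_sites) < n_mask_rate
    g <- rbind(h1, h2)
    g[, mask] <- "N"
    diploids[[s]] <- archaic_diploid(s, panel$positions, g)
    truth_haps[[paste0(s, "-1")]] <- h1
    truth_haps[[paste0(s, "-2")]] <- h2
    masks[[s]] <- mask
  }
  structure(list(diploids = diploids,
                 truth = list(haplotypes = truth_haps, masks = masks,
                              donor = donor)),
            class = "archaic_sim")
}

# A stored template re-expressed on the current (possibly introgression-
# extended) site set: ancestral at sites the template never saw.
template_on_sites <- function(sim, key) {
  site_tab <- sim$truth$site_table
  tmpl <- sim$truth$templates[[key]]
  out <- site_tab$ancestral
  idx <- match(attr(sim$truth$templates, "site_ids"), site_tab$site_id)
  ok <- !is.na(idx)
  out[idx[ok]] <- tmpl[ok]
  out
}

#' Simulate an index-SNP frequency panel with a planted fold structure
#'
#' Focal-population frequencies are uniform in `bin`; comparison
#' frequencies are `focal * fold` with `fold ~ Normal(mean, sd)`,
#' redrawn as needed to keep frequencies in (0, 1).
#'
#' @param n_snps Number of SNPs.
#' @param bin Length-2 focal frequency window.
#' @param fold_mean,fold_sd Normal fold distribution parameters.
#' @param seed Integer seed.
#' @param pop_a,pop_b Column names for the two populations.
#' @return Tibble: `snp_id`, `pop_a`, `pop_b` frequency columns.
#' @export
simulate_snp_panel_table <- function(n_snps, bin = c(0.401, 0.492),
                                     fold_mean = 1.20, fold_sd = 0.07,
                                     seed = 1, pop_a = "AFR",
                                     pop_b = "EUR") {
  stopifnot(n_snps >= 1)
  set.seed(seed)
  fa <- stats::runif(n_snps, bin[1], bin[2])
  fold <- stats::rnorm(n_snps, fold_mean, fold_sd)
  bad <- fa * fold >= 1 | fa * fold <= 0
  while (any(bad)) {
    fold[bad] <- stats::rnorm(sum(bad), fold_mean, fold_sd)
    bad <- fa * fold >= 1 | fa * fold <= 0
  }
  out <- tibble::tibble(snp_id = sprintf("snp%04d", seq_len(n_snps)))
  out[[pop_a]] <- fa
  out[[pop_b]] <- fa * fold
  attr(out, "true_folds") <- fold
  out
}
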