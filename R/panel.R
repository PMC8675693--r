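#' Define a genomic region
#'
#' A 1-based, inclusive interval on a chromosome. Used to delimit the
#' low-recombination promoter window within which haplotypes are compared.
#'
#' @param chrom Chromosome label (e.g. `"chr15"`).
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param label Optional free-text label.
#' @return An object of class `genomic_region`.
#' @export
#' @examples
#' genomic_region("chr15", 92920000, 92938000, label = "promoter core")
genomic_region <- function(chrom, start, end, label = "") {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid region: require start <= end", call. = FALSE)
  }
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         label = as.character(label)),
    class = "genomic_region"
  )
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%d-%d (%s bp)%s\n", x$chrom, x$start, x$end,
              format(x$end - x$start + 1L, big.mark = ","),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

region_length <- function(region) region$end - region$start + 1L

#' Construct a haplotype panel
#'
#' The central container: a haplotype-by-site allele matrix over a genomic
#' region, together with a sample-to-population map. Each diploid sample
#' contributes exactly two rows named `"SAMPLE.0"` and `"SAMPLE.1"`.
#'
#' @param alleles Character matrix (haplotypes x sites) over `{A,C,G,T,N}`,
#'   with row names `"SAMPLE.k"` (`k` in 0/1).
#' @param positions Integer vector of strictly increasing 1-based site
#'   positions, all within `region`.
#' @param region A [genomic_region()].
#' @param pop_map Data frame with columns `sample`, `subpop`, `metapop`,
#'   one row per sample appearing in `alleles`.
#' @param site_ids Optional character vector of site identifiers (rs ids);
#'   defaults to `"pos<position>"`.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(alleles, positions, region, pop_map,
                      site_ids = NULL) {
  positions <- as.integer(positions)
  if (!is.matrix(alleles) || !is.character(alleles)) {
    stop("alleles must be a character matrix", call. = FALSE)
  }
  if (ncol(alleles) != length(positions)) {
    stop("alleles has ", ncol(alleles), " columns but ", length(positions),
         " positions given", call. = FALSE)
  }
  if (length(positions) && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (length(positions) &&
      (min(positions) < region$start || max(positions) > region$end)) {
    stop("positions fall outside region", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(alleles)), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("alleles outside {A,C,G,T,N}: ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  ids <- rownames(alleles)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("alleles must have unique row names 'SAMPLE.0'/'SAMPLE.1'",
         call. = FALSE)
  }
  samples <- hap_sample(ids)
  pop_map <- tibble::as_tibble(pop_map)
  stopifnot(all(c("sample", "subpop", "metapop") %in% names(pop_map)))
  if (anyDuplicated(pop_map$sample)) {
    stop("pop_map lists a sample more than once", call. = FALSE)
  }
  missing <- setdiff(unique(samples), pop_map$sample)
  if (length(missing)) {
    stop("samples absent from population map: ",
         paste(utils::head(missing, 5), collapse = ","), call. = FALSE)
  }
  tab <- table(samples)
  if (any(tab != 2L)) {
    stop("each sample must contribute exactly two haplotypes", call. = FALSE)
  }
  if (is.null(site_ids)) site_ids <- paste0("pos", positions)
  stopifnot(length(site_ids) == length(positions))
  colnames(alleles) <- site_ids
  structure(
    list(alleles = alleles, positions = positions, site_ids = site_ids,
         region = region, pop_map = pop_map),
    class = "hap_panel"
  )
}

hap_sample <- function(hap_ids) sub("\\.[01]$", "", hap_ids)

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes (%d samples) x %d sites, %s:%d-%d\n",
              nrow(x$alleles), nrow(x$pop_map), ncol(x$alleles),
              x$region$chrom, x$region$start, x$region$end))
  cat("  meta-populations: ",
      paste(sort(unique(x$pop_map$metapop)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) dim(x$alleles)

#' Tidy view of a haplotype panel
#'
#' One row per haplotype x site, joined with population metadata — the long
#' format that dplyr/tidyr pipelines consume.
#'
#' @param x A [hap_panel()].
#' @param ... Unused.
#' @return A tibble with columns `haplotype`, `sample`, `subpop`, `metapop`,
#'   `site_id`, `position`, `allele`.
#' @export
as_tibble.hap_panel <- function(x, ...) {
  long <- tibble::tibble(
    haplotype = rep(rownames(x$alleles), times = ncol(x$alleles)),
    site_id = rep(x$site_ids, each = nrow(x$alleles)),
    position = rep(x$positions, each = nrow(x$alleles)),
    allele = as.vector(x$alleles)
  )
  long$sample <- hap_sample(long$haplotype)
  dplyr::left_join(long, x$pop_map, by = "sample")[
    , c("haplotype", "sample", "subpop", "metapop",
        "site_id", "position", "allele")]
}

#' Population metadata per haplotype
#'
#' @param panel A [hap_panel()].
#' @return Tibble with one row per haplotype: `haplotype`, `sample`,
#'   `subpop`, `metapop`, in panel row order.
#' @export
haplotype_populations <- function(panel) {
  out <- tibble::tibble(haplotype = rownames(panel$alleles),
                        sample = hap_sample(rownames(panel$alleles)))
  dplyr::left_join(out, panel$pop_map, by = "sample")
}

#' Subset a panel to chosen sites
#'
#' Keeps metadata and haplotype order; preserves the input order of the
#' retained sites (which must be ascending, as panels require).
#'
#' @param panel A [hap_panel()].
#' @param sites Site ids (character) or positions (numeric) to keep.
#' @return A [hap_panel()] over the requested sites.
#' @export
extract_sites <- function(panel, sites) {
  if (is.character(sites)) {
    idx <- match(sites, panel$site_ids)
    if (anyNA(idx)) {
      stop("unknown site id(s): ",
           paste(sites[is.na(idx)], collapse = ","), call. = FALSE)
    }
  } else {
    idx <- match(as.integer(sites), panel$positions)
    if (anyNA(idx)) {
      stop("unknown position(s): ",
           paste(sites[is.na(idx)], collapse = ","), call. = FALSE)
    }
  }
  hap_panel(panel$alleles[, idx, drop = FALSE], panel$positions[idx],
            panel$region, panel$pop_map, site_ids = panel$site_ids[idx])
}

#' Subset a panel to a subregion
#'
#' Keeps the sites falling inside `region` and re-bounds the panel to it
#' (tract lengths are then measured against the new edges).
#'
#' @param panel A [hap_panel()].
#' @param region A [genomic_region()] inside the panel's region.
#' @return A [hap_panel()] over `region`.
#' @export
extract_region <- function(panel, region) {
  keep <- panel$positions >= region$start & panel$positions <= region$end
  out <- hap_panel(panel$alleles[, keep, drop = FALSE],
                   panel$positions[keep], region, panel$pop_map,
                   site_ids = panel$site_ids[keep])
  class(out) <- class(panel)
  out
}

#' Subset a panel to chosen haplotypes
#'
#' @param panel A [hap_panel()]. The two phases of a sample may be split
#'   across the kept/dropped sets; the population map is trimmed to samples
#'   still present. Used internally by grouping and screening code.
#' @param haplotypes Character vector of haplotype ids to keep.
#' @return A list with the same fields as a panel but possibly unpaired
#'   haplotypes; class `hap_subset`.
#' @keywords internal
extract_haplotypes <- function(panel, haplotypes) {
  idx <- match(haplotypes, rownames(panel$alleles))
  if (anyNA(idx)) {
    stop("unknown haplotype id(s): ",
         paste(haplotypes[is.na(idx)], collapse = ","), call. = FALSE)
  }
  out <- panel
  out$alleles <- panel$alleles[idx, , drop = FALSE]
  out$pop_map <- panel$pop_map[panel$pop_map$sample %in%
                                 hap_sample(haplotypes), ]
  class(out) <- c("hap_subset", "hap_panel")
  out
}
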