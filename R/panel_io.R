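#' Read a population map
#'
#' Three-column tab-separated file with header: `sample`, `subpop`,
#' `metapop`.
#'
#' @param path File path.
#' @return A tibble with those three character columns.
#' @export
read_population_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("sample", "subpop", "metapop") %in% names(df)))
  tibble::as_tibble(df[, c("sample", "subpop", "metapop")])
}

#' @rdname read_population_map
#' @param pop_map Tibble as returned by [read_population_map()].
#' @export
write_population_map <- function(pop_map, path) {
  utils::write.table(pop_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read phased genotypes from a VCF into a haplotype panel
#'
#' Every sample in `pop_map` must be present with fully phased GT (`|`)
#' inside `region`. Missing genotype calls become `N`; indels and symbolic
#' alleles are skipped with a warning. Multiallelic SNVs are retained.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzip).
#' @param region A [genomic_region()]; only records inside it are used.
#' @param pop_map Population map tibble (see [read_population_map()]).
#' @return A [hap_panel()] with two rows (`.0`, `.1`) per sample.
#' @export
read_vcf_panel <- function(path, region, pop_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  keep <- fix[, "CHROM"] == region$chrom & pos >= region$start &
    pos <= region$end
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  is_snv <- vapply(seq_along(pos), function(i) {
    alleles <- c(fix[i, "REF"], alt_list[[i]])
    all(nchar(alleles) == 1L) && all(alleles %in% c("A", "C", "G", "T"))
  }, logical(1))
  if (any(keep & !is_snv)) {
    warning(sum(keep & !is_snv),
            " non-SNV record(s) (indel/symbolic) skipped", call. = FALSE)
  }
  keep <- keep & is_snv
  if (!any(keep)) stop("no SNV records in region", call. = FALSE)
  gt <- vcf@gt[keep, -1, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  alt_list <- alt_list[keep]

  vcf_samples <- colnames(gt)
  extra <- setdiff(vcf_samples, pop_map$sample)
  if (length(extra)) {
    stop("VCF sample(s) absent from population map: ",
         paste(utils::head(extra, 5), collapse = ","), call. = FALSE)
  }
  missing <- setdiff(pop_map$sample, vcf_samples)
  if (length(missing)) {
    stop("map sample(s) absent from VCF: ",
         paste(utils::head(missing, 5), collapse = ","), call. = FALSE)
  }
  gt <- gt[, pop_map$sample, drop = FALSE]

  # GT is the first colon-separated field
  gt_only <- sub(":.*$", "", gt)
  unphased <- grepl("/", gt_only, fixed = TRUE) & gt_only != "./."
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype for sample ", pop_map$sample[w[2]],
         " at position ", pos[w[1]], call. = FALSE)
  }

  n_sites <- nrow(gt_only)
  n_samp <- ncol(gt_only)
  alleles <- matrix("N", nrow = 2L * n_samp, ncol = n_sites)
  rownames(alleles) <- as.vector(rbind(paste0(pop_map$sample, ".0"),
                                       paste0(pop_map$sample, ".1")))
  for (i in seq_len(n_sites)) {
    codes <- c(fix[i, "REF"], alt_list[[i]])
    split_gt <- strsplit(gt_only[i, ], "[|/]")
    a0 <- vapply(split_gt, `[`, "", 1L)
    a1 <- vapply(split_gt, `[`, "", 2L)
    decode <- function(a) {
      out <- rep("N", length(a))
      ok <- !is.na(a) & a != "."
      out[ok] <- codes[as.integer(a[ok]) + 1L]
      out
    }
    alleles[seq(1L, 2L * n_samp, by = 2L), i] <- decode(a0)
    alleles[seq(2L, 2L * n_samp, by = 2L), i] <- decode(a1)
  }
  ids <- fix[, "ID"]
  ids <- ifelse(is.na(ids) | ids == ".", paste0("pos", pos), ids)
  hap_panel(alleles, pos, region, pop_map, site_ids = ids)
}

#' Write a haplotype panel as a phased VCF
#'
#' Plain-text VCF 4.2 with phased GT. The reference allele at each site is
#' the majority allele; remaining observed alleles become ALT in frequency
#' order. Sites where a haplotype carries `N` are written as `.`.
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  samples <- panel$pop_map$sample
  h0 <- panel$alleles[paste0(samples, ".0"), , drop = FALSE]
  h1 <- panel$alleles[paste0(samples, ".1"), , drop = FALSE]
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", panel$region$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(panel$positions), function(i) {
    obs <- c(h0[, i], h1[, i])
    counts <- sort(table(obs[obs != "N"]), decreasing = TRUE)
    codes <- names(counts)
    if (!length(codes)) codes <- "A"  # all-missing column
    ref <- codes[1]
    alt <- if (length(codes) > 1) paste(codes[-1], collapse = ",") else "."
    code_of <- function(a) {
      ifelse(a == "N", ".", as.character(match(a, codes) - 1L))
    }
    gt <- paste(code_of(h0[, i]), code_of(h1[, i]), sep = "|")
    gt[gt == ".|."] <- "./."  # conventional missing diploid call
    paste(c(panel$region$chrom, panel$positions[i], panel$site_ids[i],
            ref, alt, ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write haplotype sequences to FASTA
#'
#' One record per haplotype; the sequence is the concatenation of the
#' panel's site alleles (so record length equals the site count, not the
#' bp length of the region).
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(panel, path) {
  if (ncol(panel$alleles) == 0L) stop("empty panel", call. = FALSE)
  seqs <- apply(panel$alleles, 1, paste0, collapse = "")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Read a FASTA alignment back into an allele matrix
#'
#' Round-trip companion of [write_haplotype_fasta()].
#'
#' @param path FASTA file path.
#' @return Character matrix (records x columns) with record names as rows.
#' @export
read_haplotype_fasta <- function(path) {
  aln <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  m <- toupper(unclass(aln))
  dimnames(m) <- list(rownames(aln), NULL)
  m
}
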