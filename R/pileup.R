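#' Prepare an alignment file for pileup
#'
#' Accepts SAM or BAM. SAM input is converted to coordinate-sorted BAM; BAM
#' input without an index gets one. Used internally by the counting functions,
#' exported because simulator output is SAM text.
#'
#' @param path Path to a SAM (`.sam`) or BAM (`.bam`) file.
#' @return Path to a coordinate-sorted, indexed BAM file.
#' @export
ensure_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- sub("\\.sam$", "", path, ignore.case = TRUE)
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) {
      Rsamtools::sortBam(bam, destination = sub("\\.bam$", ".sorted", bam))
      bam <- sub("\\.bam$", ".sorted.bam", bam)
      Rsamtools::indexBam(bam)
    }
  }
  bam
}

# strand-aware pileup over a set of catalogued sites; returns one row per site
pileup_sites <- function(bam, catalog, min_baseq, min_mapq) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_chrom <- setdiff(unique(catalog$chrom), names(hdr))
  if (length(missing_chrom) > 0) {
    stop("chrom(s) absent from alignment header: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  which <- GenomicRanges::GRanges(catalog$chrom,
                                  IRanges::IRanges(catalog$position,
                                                   catalog$position))
  pp <- Rsamtools::PileupParam(
    max_depth = 10000000L,
    min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq),
    min_nucleotide_depth = 0L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  sbp <- Rsamtools::ScanBamParam(which = which)
  pu <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  pu <- tibble::as_tibble(pu)

  tally <- function(chrom, pos, strand) {
    at <- pu[pu$seqnames == chrom & pu$pos == pos, ]
    n_of <- function(base) sum(at$count[at$nucleotide == base])
    if (strand == "+") {
      edited <- n_of("T"); unedited <- n_of("C")
    } else {
      edited <- n_of("A"); unedited <- n_of("G")
    }
    c(n_edited = edited, n_unedited = unedited,
      n_other = sum(at$count) - edited - unedited)
  }
  counts <- purrr::pmap(
    list(catalog$chrom, catalog$position, catalog$strand),
    tally
  )
  counts <- do.call(rbind, counts)
  tibble::tibble(
    site_id = catalog$site_id,
    n_edited = as.integer(counts[, "n_edited"]),
    n_unedited = as.integer(counts[, "n_unedited"]),
    n_other = as.integer(counts[, "n_other"]),
    depth = as.integer(rowSums(counts))
  )
}

#' Count edited and unedited bases at one catalogued site
#'
#' Tallies the pileup column over an editing site. Reads must cover the
#' position with an aligned base (deletions and reference skips contribute to
#' no category) and pass the base- and mapping-quality filters; each read
#' contributes once. At a `+` strand site the reference-forward base T is the
#' edited observation and C the unedited one; at a `-` strand site the sense
#' strand is the reverse complement, so reference-forward A counts as edited
#' and G as unedited. Any other base is tallied as `n_other`.
#'
#' @param alignments Path to a coordinate-sorted SAM/BAM file (indexed, or
#'   indexable via [ensure_bam()]).
#' @param site A one-row `site_catalog` (or a data frame with the same fields).
#' @param min_baseq Minimum base quality (phred) for a read base to count.
#'   0 reproduces unfiltered tallies.
#' @param min_mapq Minimum mapping quality. 0 reproduces unfiltered tallies.
#' @param sample_id Label recorded in the output.
#' @return A one-row tibble with `site_id`, `sample_id`, `n_edited`,
#'   `n_unedited`, `n_other`, `depth`.
#' @export
count_bases_at_site <- function(alignments, site, min_baseq = 20, min_mapq = 20,
                                sample_id = "sample") {
  site <- site_catalog(tibble::as_tibble(site))
  if (nrow(site) != 1) stop("site must be a single catalogue row", call. = FALSE)
  bam <- ensure_bam(alignments)
  out <- pileup_sites(bam, site, min_baseq, min_mapq)
  dplyr::mutate(out, sample_id = sample_id, .after = "site_id")
}

#' Editing efficiency from base counts
#'
#' The digital editing-efficiency estimator: the fraction of informative reads
#' (those showing the edited or the unedited base) that show the edited base,
#' `n_edited / (n_edited + n_unedited)`. Reads showing any other base are
#' excluded from the denominator. When no informative reads cover the site the
#' efficiency is `NA` — never coerced to zero.
#'
#' @param counts A tibble of base counts with columns `n_edited`, `n_unedited`
#'   (as from [count_bases_at_site()] or [quantify_all()]).
#' @return The input with `n_informative` and `efficiency` columns appended.
#' @examples
#' editing_efficiency(tibble::tibble(site_id = "ndhB-C277", n_edited = 30,
#'                                   n_unedited = 10, n_other = 0))
#' @export
editing_efficiency <- function(counts) {
  dplyr::mutate(
    tibble::as_tibble(counts),
    n_informative = .data$n_edited + .data$n_unedited,
    efficiency = dplyr::if_else(.data$n_informative > 0,
                                .data$n_edited / .data$n_informative,
                                NA_real_)
  )
}

#' Quantify editing at every catalogued site in one sample
#'
#' Runs the strand-aware pileup tally of [count_bases_at_site()] over a whole
#' catalogue and appends the efficiency estimate. The output has exactly one
#' row per catalogue site, in catalogue order; sites with no informative
#' coverage are retained with `NA` efficiency.
#'
#' @inheritParams count_bases_at_site
#' @param catalog A `site_catalog`.
#' @return A tibble with one row per site: `site_id`, `sample_id`, `n_edited`,
#'   `n_unedited`, `n_other`, `depth`, `n_informative`, `efficiency`.
#' @export
quantify_all <- function(alignments, catalog, sample_id = "sample",
                         min_baseq = 20, min_mapq = 20) {
  catalog <- site_catalog(tibble::as_tibble(catalog))
  if (nrow(catalog) == 0) stop("catalogue is empty", call. = FALSE)
  bam <- ensure_bam(alignments)
  out <- pileup_sites(bam, catalog, min_baseq, min_mapq)
  out <- dplyr::mutate(out, sample_id = sample_id, .after = "site_id")
  editing_efficiency(out)
}

#' Write per-site efficiency estimates to TSV
#'
#' @param estimates Output of [quantify_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_efficiency <- function(estimates, path) {
  readr::write_tsv(estimates, path)
  invisible(path)
}
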