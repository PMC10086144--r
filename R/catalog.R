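#' Construct an editing-site catalogue
#'
#' A site catalogue is the fixed list of known C-to-U editing positions that
#' all quantification in this package is anchored to. Each row is one edited
#' cytidine, identified by its gene and codon (`site_id` of the form
#' `<gene>-C<codon>`, e.g. `ndhB-C277`) and located by a 1-based plastome
#' coordinate plus the strand of the gene's sense relative to the reference.
#'
#' @param sites A data frame with columns `site_id`, `chrom`, `position`,
#'   `strand`, `gene`, `codon_number`, `codon_position`.
#' @param source Provenance string recorded as an attribute.
#' @return A tibble of class `site_catalog`, one row per site, input order
#'   preserved.
#' @examples
#' site_catalog(tibble::tibble(
#'   site_id = "ndhB-C277", chrom = "chrPt", position = 100L, strand = "+",
#'   gene = "ndhB", codon_number = 277L, codon_position = 2L
#' ))
#' @export
site_catalog <- function(sites, source = "user") {
  required <- c("site_id", "chrom", "position", "strand",
                "gene", "codon_number", "codon_position")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    stop("catalogue is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sites <- tibble::as_tibble(sites)
  sites$position <- as.integer(sites$position)
  sites$codon_number <- as.integer(sites$codon_number)
  sites$codon_position <- as.integer(sites$codon_position)
  # normalise the unicode minus some catalogue sources use
  sites$strand <- sub("−", "-", sites$strand)
  bad <- which(is.na(sites$position) | sites$position < 1L)
  if (length(bad) > 0) {
    stop("invalid position at catalogue row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!sites$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop("strand must be '+' or '-' at catalogue row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!sites$codon_position %in% 1:3)
  if (length(bad) > 0) {
    stop("codon_position must be 1, 2 or 3 at catalogue row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) {
    dups <- unique(sites$site_id[duplicated(sites$site_id)])
    stop("duplicate site_id in catalogue: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(sites$chrom, sites$position, sites$strand)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, position, strand) in catalogue", call. = FALSE)
  }
  attr(sites, "source") <- source
  class(sites) <- c("site_catalog", class(tibble::tibble()))
  sites
}

#' Read an editing-site catalogue from TSV
#'
#' The TSV must carry a header row naming the catalogue fields
#' (`site_id`, `chrom`, `position`, `strand`, `gene`, `codon_number`,
#' `codon_position`); extra columns (e.g. free-text aliases) are kept.
#'
#' @param path Path to a tab-separated catalogue file.
#' @return A `site_catalog` tibble; a header-only file yields an empty
#'   catalogue with a warning.
#' @seealso [write_catalog()], [default_catalog()]
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(
      site_id = readr::col_character(),
      chrom = readr::col_character(),
      position = readr::col_integer(),
      strand = readr::col_character(),
      gene = readr::col_character(),
      codon_number = readr::col_integer(),
      codon_position = readr::col_integer(),
      .default = readr::col_character()
    ), lazy = FALSE)
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed catalogue row at line ", probs$row[1], " of ", path,
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("catalogue ", path, " contains a header but no sites", call. = FALSE)
  }
  cat <- site_catalog(raw, source = path)
  message("loaded ", nrow(cat), " editing site(s) from ", path)
  cat
}

#' Write a catalogue back to TSV
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(cat, f))` preserves
#' all field values.
#'
#' @param catalog A `site_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(tibble::as_tibble(catalog), path)
  invisible(path)
}

#' The bundled 33-site chloroplast catalogue
#'
#' Returns the package's default catalogue of 33 plastid C-to-U editing sites.
#' Gene names and codon numbers follow the Arabidopsis chloroplast editing
#' literature, but the coordinates are synthetic: they place the sites on the
#' bundled 10-kb synthetic plastome (`toy_plastome_path()`), with genes on both
#' strands, so that strand handling is always exercised without requiring real
#' genome coordinates. Quantification of real data should use a user catalogue
#' with real coordinates.
#'
#' @return A `site_catalog` of 33 sites.
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "synthetic_plastome_sites33.tsv",
                      package = "plastedit", mustWork = TRUE)
  suppressMessages(load_catalog(path))
}

#' Path to the bundled synthetic plastome FASTA
#'
#' A 10-kb synthetic plastome-like reference carrying the genes of
#' [default_catalog()] on both strands. The sense-strand base at every
#' catalogued site is a C.
#'
#' @return Path to a FASTA file.
#' @export
toy_plastome_path <- function() {
  system.file("extdata", "synthetic_plastome.fa",
              package = "plastedit", mustWork = TRUE)
}

#' Validate a catalogue against a reference sequence
#'
#' Checks that the sense-strand base at every catalogued position is a C:
#' the reference-forward base must be C for `+` strand sites and G for `-`
#' strand sites (whose sense strand is the reverse complement).
#'
#' @param catalog A `site_catalog`.
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file
#'   containing every `chrom` the catalogue names.
#' @return A tibble of violations (columns `site_id`, `chrom`, `position`,
#'   `strand`, `ref_base`, `expected`), empty when the catalogue is clean.
#' @export
validate_catalog <- function(catalog, reference) {
  catalog <- site_catalog(catalog, source = attr(catalog, "source") %||% "user")
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  missing_chrom <- setdiff(unique(catalog$chrom), names(reference))
  if (length(missing_chrom) > 0) {
    stop("chrom(s) absent from reference: ", paste(missing_chrom, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(catalog) == 0) {
    return(tibble::tibble(site_id = character(), chrom = character(),
                          position = integer(), strand = character(),
                          ref_base = character(), expected = character()))
  }
  ref_base <- purrr::map2_chr(catalog$chrom, catalog$position, function(ch, pos) {
    if (pos > Biostrings::nchar(reference[[ch]])) return(NA_character_)
    as.character(Biostrings::subseq(reference[[ch]], pos, pos))
  })
  expected <- ifelse(catalog$strand == "+", "C", "G")
  bad <- is.na(ref_base) | ref_base != expected
  tibble::tibble(
    site_id = catalog$site_id[bad],
    chrom = catalog$chrom[bad],
    position = catalog$position[bad],
    strand = catalog$strand[bad],
    ref_base = ref_base[bad],
    expected = expected[bad]
  )
}

#' Export a catalogue as BED intervals
#'
#' Catalogue coordinates are 1-based inclusive; BED is 0-based half-open, so a
#' site at position `p` becomes the width-1 interval `[p - 1, p)`. Records are
#' sorted by (chrom, start) as BED consumers expect.
#'
#' @param catalog A `site_catalog`.
#' @return A tibble with BED6 columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @seealso [write_bed()]
#' @export
to_bed <- function(catalog) {
  catalog <- site_catalog(catalog, source = attr(catalog, "source") %||% "user")
  bed <- tibble::tibble(
    chrom = catalog$chrom,
    start = catalog$position - 1L,
    end = catalog$position,
    name = catalog$site_id,
    score = 0L,
    strand = catalog$strand
  )
  dplyr::arrange(bed, .data$chrom, .data$start)
}

#' Write BED6 records to file
#'
#' @param bed A tibble as returned by [to_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
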