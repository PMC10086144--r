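# All simulators are pure functions of (parameters, seed): the RNG state is
# scoped with withr::with_seed so global reproducibility is never disturbed.

#' Simulate aligned reads over one editing site
#'
#' Emits fully aligned 50-bp reads covering a catalogued site on the bundled
#' synthetic plastome (or any supplied reference). Each read is independently
#' edited with probability `true_eff`; the observed base is then miscalled
#' uniformly to one of the other three bases with probability `error_rate`.
#' The returned ledger records the sampled truth exactly, so downstream
#' pileup counts can be checked read-for-read.
#'
#' @param site A one-row `site_catalog`.
#' @param true_eff True per-read editing probability in \[0, 1\].
#' @param coverage Number of reads.
#' @param error_rate Per-base miscall probability in \[0, 0.25).
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @param reference Path to the reference FASTA (default the bundled synthetic
#'   plastome).
#' @param read_length Read length in bp (default 50).
#' @return A list with `reads` (a tibble of SAM fields), `ledger` (one-row
#'   tibble of true/observed counts) and `reference` (the path used).
#' @seealso [write_sam()] to serialise the reads for [quantify_all()].
#' @export
simulate_site_reads <- function(site, true_eff, coverage, error_rate = 0,
                                seed = 1, reference = toy_plastome_path(),
                                read_length = 50) {
  site <- site_catalog(tibble::as_tibble(site))
  stopifnot(nrow(site) == 1)
  if (coverage < 0) stop("coverage must be nonnegative", call. = FALSE)
  stopifnot(true_eff >= 0, true_eff <= 1, error_rate >= 0, error_rate < 0.25)
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (!site$chrom %in% names(ref)) {
    stop("site chrom absent from reference: ", site$chrom, call. = FALSE)
  }
  refseq <- ref[[site$chrom]]
  reflen <- Biostrings::nchar(refseq)
  pos <- site$position
  # forward-orientation base each biological state presents at the site
  base_edit <- if (site$strand == "+") "T" else "A"
  base_uned <- if (site$strand == "+") "C" else "G"

  withr::with_seed(seed, {
    start <- pmax(1L, pmin(as.integer(pos - read_length + 1L), reflen - read_length + 1L))
    starts <- sample(seq(start, min(pos, reflen - read_length + 1L)),
                     coverage, replace = TRUE)
    edited <- runif(coverage) < true_eff
    true_base <- ifelse(edited, base_edit, base_uned)
    obs_base <- true_base
    miscall <- runif(coverage) < error_rate
    if (any(miscall)) {
      obs_base[miscall] <- vapply(true_base[miscall], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, "")
    }
  })

  ref_str <- as.character(refseq)
  seqs <- substring(ref_str, starts, starts + read_length - 1L)
  at <- pos - starts + 1L
  substr(seqs, at, at) <- obs_base
  reads <- tibble::tibble(
    qname = sprintf("read%06d", seq_len(coverage)),
    flag = if (site$strand == "+") 0L else 16L,
    rname = site$chrom,
    pos = starts,
    mapq = 60L,
    cigar = paste0(read_length, "M"),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = seqs,
    qual = strrep("I", read_length)
  )
  n_edi <- sum(obs_base == base_edit)
  n_une <- sum(obs_base == base_uned)
  ledger <- tibble::tibble(
    site_id = site$site_id,
    true_eff = true_eff,
    n_reads = coverage,
    n_true_edited = sum(edited),
    n_miscalled = sum(miscall),
    n_obs_edited = n_edi,
    n_obs_unedited = n_une,
    n_obs_other = coverage - n_edi - n_une
  )
  list(reads = reads, ledger = ledger, reference = reference)
}

#' Write simulated reads as a SAM file
#'
#' Emits a valid header (`@HD`, one `@SQ` per reference sequence) followed by
#' the read records. The result feeds [ensure_bam()] / [quantify_all()].
#'
#' @param reads A read tibble from [simulate_site_reads()], or several
#'   row-bound together (same reference).
#' @param path Output path (`.sam`).
#' @param reference Path to the reference FASTA the reads were drawn from.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, reference = toy_plastome_path()) {
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref), Biostrings::width(ref)), con)
  if (nrow(reads) > 0) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                       reads$qname, reads$flag, reads$rname, reads$pos,
                       reads$mapq, reads$cigar, reads$rnext, reads$pnext,
                       reads$tlen, reads$seq, reads$qual), con)
  }
  invisible(path)
}

#' Define an editing-simulation scenario
#'
#' A scenario fixes everything the experiment-level simulator needs: the
#' catalogue, the true efficiency of every site under each condition, the
#' per-replicate coverage, the miscall rate and the replicate count. The
#' default design mirrors a two-condition, two-replicate knockdown study.
#'
#' @param catalog A `site_catalog`.
#' @param eff_a,eff_b Named numeric vectors (site_id -> true efficiency) or a
#'   single value recycled over all sites.
#' @param coverage Reads per site per replicate (default 2000).
#' @param error_rate Per-base miscall probability (default 0).
#' @param n_replicates Biological replicates per condition (default 2).
#' @return A list of class `editing_scenario`.
#' @export
editing_scenario <- function(catalog, eff_a, eff_b, coverage = 2000,
                             error_rate = 0, n_replicates = 2) {
  catalog <- site_catalog(tibble::as_tibble(catalog))
  expand <- function(eff) {
    if (length(eff) == 1 && is.null(names(eff))) {
      eff <- setNames(rep(eff, nrow(catalog)), catalog$site_id)
    }
    if (!all(catalog$site_id %in% names(eff))) {
      stop("efficiencies missing for some catalogue sites", call. = FALSE)
    }
    eff <- eff[catalog$site_id]
    stopifnot(all(eff >= 0 & eff <= 1))
    eff
  }
  stopifnot(coverage >= 0, error_rate >= 0, error_rate < 0.25, n_replicates >= 1)
  structure(list(catalog = catalog, eff_a = expand(eff_a), eff_b = expand(eff_b),
                 coverage = coverage, error_rate = error_rate,
                 n_replicates = n_replicates),
            class = "editing_scenario")
}

#' The knockdown and null scenario presets
#'
#' `scenario_knockdown33()` is the package's reference perturbation design:
#' the bundled 33-site catalogue with a baseline efficiency of 0.8 at every
#' site in both conditions, and eight fixed sites (in ndhB, ndhD, ndhF, psbZ
#' and rps14, the genes typically perturbed when an editing factor is
#' knocked down) shifted to 0.5 in condition B. Coverage is 2000 reads per
#' site per replicate with two replicates per condition, giving essentially
#' full power for the pooled Fisher test at every planted site.
#' `scenario_null33()` is the same design with no shifted sites.
#'
#' @return An `editing_scenario`; the knockdown scenario carries the planted
#'   site ids in `attr(, "planted")`.
#' @export
scenario_knockdown33 <- function() {
  cat33 <- default_catalog()
  planted <- c("ndhB-C50", "ndhB-C156", "ndhB-C277", "ndhD-C1",
               "ndhD-C128", "ndhF-C97", "psbZ-C50", "rps14-C27")
  eff_b <- setNames(rep(0.8, nrow(cat33)), cat33$site_id)
  eff_b[planted] <- 0.5
  sc <- editing_scenario(cat33, eff_a = 0.8, eff_b = eff_b,
                         coverage = 2000, n_replicates = 2)
  attr(sc, "planted") <- planted
  sc
}

#' @rdname scenario_knockdown33
#' @export
scenario_null33 <- function() {
  editing_scenario(default_catalog(), eff_a = 0.8, eff_b = 0.8,
                   coverage = 2000, n_replicates = 2)
}

# split `n` draws of a base among observed bases given a miscall rate:
# returns c(kept, to_partner, to_other)
miscall_split <- function(n, error_rate) {
  if (n == 0) return(c(n, 0L, 0L))
  probs <- c(1 - error_rate, error_rate / 3, 2 * error_rate / 3)
  drop(stats::rmultinom(1, n, probs))
}

#' Simulate a full editing experiment as base-count tables
#'
#' Draws, for every catalogued site and every replicate of both conditions,
#' the number of truly edited transcripts (binomial at the scenario's true
#' efficiency) and then the observed base of each read under the uniform
#' miscall model. Returns per-replicate base-count tables in the shape
#' [differential_editing()] consumes, plus a ledger of the sampled truth.
#'
#' @param scenario An [editing_scenario()].
#' @param seed Integer seed; output is bit-reproducible given it.
#' @return A list with `counts_a`, `counts_b` (tibbles: `site_id`,
#'   `condition`, `replicate`, `n_edited`, `n_unedited`, `n_other`) and
#'   `ledger` (adds `n_true_edited` and `true_eff`).
#' @export
simulate_experiment <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "editing_scenario"))
  cat <- scenario$catalog
  draw_condition <- function(cond, effs) {
    purrr::map_dfr(seq_len(scenario$n_replicates), function(rep_i) {
      n_true <- rbinom(nrow(cat), scenario$coverage, effs)
      obs <- vapply(seq_len(nrow(cat)), function(i) {
        ed <- miscall_split(n_true[i], scenario$error_rate)
        un <- miscall_split(scenario$coverage - n_true[i], scenario$error_rate)
        # edited base kept -> edited; miscall to partner base -> unedited; etc.
        c(n_edited = ed[1] + un[2], n_unedited = un[1] + ed[2],
          n_other = ed[3] + un[3])
      }, c(n_edited = 0, n_unedited = 0, n_other = 0))
      tibble::tibble(
        site_id = cat$site_id,
        condition = cond,
        replicate = rep_i,
        true_eff = unname(effs),
        n_true_edited = n_true,
        n_edited = as.integer(obs["n_edited", ]),
        n_unedited = as.integer(obs["n_unedited", ]),
        n_other = as.integer(obs["n_other", ])
      )
    })
  }
  ledger <- withr::with_seed(seed, {
    dplyr::bind_rows(draw_condition("A", scenario$eff_a),
                     draw_condition("B", scenario$eff_b))
  })
  strip <- function(cond) {
    dplyr::select(dplyr::filter(ledger, .data$condition == cond),
                  "site_id", "condition", "replicate",
                  "n_edited", "n_unedited", "n_other")
  }
  list(counts_a = strip("A"), counts_b = strip("B"), ledger = ledger)
}

#' Simulate a Sanger chromatogram with a known T/C mixture
#'
#' Builds a trace whose basecalls sit `peak_spacing` scans apart, each
#' carrying a Gaussian peak (sd = `peak_spacing / 4`) in a single channel,
#' except the central target position where the C and T channels carry peaks
#' with amplitudes proportional to `1 - true_mixture` and `true_mixture`.
#' Independent Gaussian noise with standard deviation `noise_sd * amplitude`
#' is added to every channel; intensities are rounded to integers and floored
#' at zero, as processed chromatogram data are.
#'
#' @param true_mixture Edited (T) fraction at the target position, in \[0, 1\].
#' @param peak_spacing Scans between consecutive basecalls (default 12).
#' @param amplitude Total peak amplitude at the target (default 1000).
#' @param noise_sd Noise standard deviation as a fraction of `amplitude`
#'   (default 0).
#' @param n_flank Basecalls on either side of the target (default 10).
#' @param seed Integer seed.
#' @return A [sanger_trace()] with attributes `site_index` (the basecall index
#'   of the mixed position) and `true_mixture`.
#' @export
simulate_trace <- function(true_mixture, peak_spacing = 12, amplitude = 1000,
                           noise_sd = 0, n_flank = 10, seed = 1) {
  stopifnot(true_mixture >= 0, true_mixture <= 1, peak_spacing >= 4)
  n_calls <- 2L * n_flank + 1L
  centers <- peak_spacing * seq_len(n_calls)
  len <- peak_spacing * (n_calls + 1L)
  sd <- peak_spacing / 4
  scan <- seq_len(len) - 1L
  gauss <- function(center, amp) amp * exp(-((scan - center)^2) / (2 * sd^2))

  withr::with_seed(seed, {
    flank_bases <- sample(c("A", "G"), n_calls, replace = TRUE)
    chan <- matrix(0, nrow = len, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
    target <- n_flank + 1L
    for (i in seq_len(n_calls)) {
      if (i == target) {
        chan[, "T"] <- chan[, "T"] + gauss(centers[i], amplitude * true_mixture)
        chan[, "C"] <- chan[, "C"] + gauss(centers[i], amplitude * (1 - true_mixture))
      } else {
        chan[, flank_bases[i]] <- chan[, flank_bases[i]] +
          gauss(centers[i], amplitude)
      }
    }
    if (noise_sd > 0) {
      chan <- chan + matrix(rnorm(length(chan), 0, noise_sd * amplitude),
                            nrow = len)
    }
  })
  chan <- pmax(round(chan), 0)
  called <- ifelse(seq_len(n_calls) == target,
                   ifelse(true_mixture >= 0.5, "T", "C"), flank_bases)
  tr <- sanger_trace(chan, tibble::tibble(scan = centers, base = called))
  attr(tr, "site_index") <- target
  attr(tr, "true_mixture") <- true_mixture
  tr
}

#' Simulate a count matrix with planted fold changes
#'
#' Negative-binomial counts for a two-group design. Per-gene baseline means
#' are drawn log-normally around `base_mean`; genes named in `planted` have
#' their group-B mean multiplied by the given fold change. An optional block
#' of near-silent genes (mean 0.05) is appended for testing expressed-gene
#' filters. `dispersion` is the NB dispersion (variance = mu + dispersion *
#' mu^2); 0 gives Poisson counts.
#'
#' @param n_genes Number of expressed genes.
#' @param samples_per_group Samples in each of groups A and B (default 2).
#' @param base_mean Median baseline mean count (default 500).
#' @param dispersion NB dispersion (default 0.01, the squared biological CV
#'   typical of genetically identical replicates).
#' @param planted Named numeric vector gene -> fold change applied in group B
#'   (names like `"gene0001"`), or `NULL`.
#' @param n_silent Number of near-silent genes appended (default 0).
#' @param seed Integer seed.
#' @return A list with `counts` (tibble, gene column + samples `A1..`,`B1..`)
#'   and `truth` (tibble: `gene`, `base_mean`, `fold_change`, `expressed`).
#' @export
simulate_count_matrix <- function(n_genes, samples_per_group = 2,
                                  base_mean = 500, dispersion = 0.01,
                                  planted = NULL, n_silent = 0, seed = 1) {
  stopifnot(n_genes > 0, samples_per_group >= 1, dispersion >= 0)
  genes <- sprintf("gene%04d", seq_len(n_genes + n_silent))
  if (!is.null(planted) && !all(names(planted) %in% genes[seq_len(n_genes)])) {
    stop("planted genes must name expressed genes", call. = FALSE)
  }
  fc <- setNames(rep(1, length(genes)), genes)
  if (!is.null(planted)) fc[names(planted)] <- planted
  withr::with_seed(seed, {
    mu0 <- c(exp(rnorm(n_genes, log(base_mean), 0.7)),
             rep(0.05, n_silent))
    draw <- function(mu) {
      if (dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    cols_a <- replicate(samples_per_group, draw(mu0))
    cols_b <- replicate(samples_per_group, draw(mu0 * fc))
  })
  m <- cbind(cols_a, cols_b)
  colnames(m) <- c(paste0("A", seq_len(samples_per_group)),
                   paste0("B", seq_len(samples_per_group)))
  rownames(m) <- genes
  truth <- tibble::tibble(
    gene = genes,
    base_mean = mu0,
    fold_change = unname(fc),
    expressed = c(rep(TRUE, n_genes), rep(FALSE, n_silent))
  )
  list(counts = matrix_to_tibble(m), truth = truth)
}
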