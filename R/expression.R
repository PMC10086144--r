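# counts come in either as a numeric matrix with gene rownames or as a tibble
# whose first column is the gene label; helpers convert between the two so
# every operation is tibble-in / tibble-out
as_count_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("count matrix needs gene rownames", call. = FALSE)
    return(x)
  }
  x <- tibble::as_tibble(x)
  gene_col <- names(x)[1]
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[gene_col]]
  if (anyDuplicated(rownames(m))) stop("gene labels must be unique", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("sample labels must be unique", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m, gene_col = "gene") {
  out <- tibble::as_tibble(m, rownames = gene_col)
  out
}

#' Counts-per-million normalisation
#'
#' Scales each sample's counts by its library total so every column sums to
#' one million: `cpm = count / sum(counts in sample) * 1e6`.
#'
#' @param counts A genes x samples count table: either a tibble whose first
#'   column holds gene labels or a numeric matrix with gene rownames. No
#'   negative entries.
#' @return A tibble (gene column plus one CPM column per sample).
#' @examples
#' cpm(tibble::tibble(gene = c("g1", "g2"), s1 = c(250, 750)))
#' @export
cpm <- function(counts) {
  m <- as_count_matrix(counts)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("zero library total for sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  }
  matrix_to_tibble(sweep(m, 2, lib, "/") * 1e6)
}

#' Expressed-gene filter
#'
#' A gene is considered expressed when its CPM is strictly above `threshold`
#' in at least `min_samples` samples. The three presets used in this package's
#' analyses are above 2 CPM in at least 9 of 10 samples, above 0.5 CPM in at
#' least 11 of 12, and above 0.5 CPM in at least 3 of 4; see
#' [expressed_preset()].
#'
#' @param cpm A CPM table as returned by [cpm()] (tibble or matrix).
#' @param threshold CPM threshold (strict by default).
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @param strict Use strict inequality (`>`; default) or `>=`.
#' @return Character vector of retained gene labels, in input order.
#' @export
expressed_filter <- function(cpm, threshold, min_samples, strict = TRUE) {
  m <- as_count_matrix(cpm)
  if (min_samples > ncol(m)) {
    stop("min_samples exceeds the number of samples", call. = FALSE)
  }
  hits <- if (strict) m > threshold else m >= threshold
  rownames(m)[rowSums(hits) >= min_samples]
}

#' Expressed-gene filter presets
#'
#' @param name One of `"cpm2_of10"` (above 2 CPM in >= 9 of 10 samples),
#'   `"cpm0.5_of12"` (above 0.5 CPM in >= 11 of 12) or `"cpm0.5_of4"`
#'   (above 0.5 CPM in >= 3 of 4).
#' @return A list with `threshold` and `min_samples` for [expressed_filter()].
#' @export
expressed_preset <- function(name = c("cpm2_of10", "cpm0.5_of12", "cpm0.5_of4")) {
  switch(match.arg(name),
    cpm2_of10 = list(threshold = 2, min_samples = 9L),
    cpm0.5_of12 = list(threshold = 0.5, min_samples = 11L),
    cpm0.5_of4 = list(threshold = 0.5, min_samples = 3L)
  )
}

#' Call significantly differentially expressed genes (SDEGs)
#'
#' A deliberately simple exact-test caller (this package does not fit a
#' negative-binomial model): per gene, the log2 fold change is computed from
#' group-mean CPM with a pseudocount, and the p-value from a two-sided exact
#' binomial test of the gene's pooled count split between the groups against
#' the library-size expectation. FDR is Benjamini-Hochberg. A gene is called
#' up (down) when `log2fc >= lfc_min` (`<= -lfc_min`) and `fdr < fdr_max`;
#' defaults implement the |log2FC| >= 1, FDR < 0.01% rule. Because pooling
#' ignores biological dispersion, p-values are anti-conservative for noisy
#' genes; the fold-change gate carries most of the specificity.
#'
#' @param counts Count table (tibble with gene column, or matrix).
#' @param group_a,group_b Character vectors of sample (column) names.
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param fdr_max FDR ceiling (default 1e-4, i.e. 0.01 percent).
#' @param pseudocount Added to group-mean CPM before the log ratio
#'   (default 0.5).
#' @return A tibble of class `sdeg_result`: `gene`, `mean_cpm_a`,
#'   `mean_cpm_b`, `log2fc` (b vs a), `p`, `fdr`, `direction`
#'   (`up`/`down`/`ns`).
#' @export
sdeg_call <- function(counts, group_a, group_b, lfc_min = 1, fdr_max = 1e-4,
                      pseudocount = 0.5) {
  m <- as_count_matrix(counts)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  missing_s <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing_s) > 0) {
    stop("sample(s) not in count table: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  cpm_m <- as_count_matrix(cpm(m))
  mean_a <- rowMeans(cpm_m[, group_a, drop = FALSE])
  mean_b <- rowMeans(cpm_m[, group_b, drop = FALSE])
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))

  pooled_a <- rowSums(m[, group_a, drop = FALSE])
  pooled_b <- rowSums(m[, group_b, drop = FALSE])
  lib_a <- sum(pooled_a)
  lib_b <- sum(pooled_b)
  expect_b <- lib_b / (lib_a + lib_b)
  p <- vapply(seq_len(nrow(m)), function(i) {
    tot <- pooled_a[i] + pooled_b[i]
    if (tot == 0) return(1)
    binom.test(round(pooled_b[i]), round(tot), p = expect_b)$p.value
  }, 1)
  fdr <- p.adjust(p, method = "BH")
  direction <- dplyr::case_when(
    log2fc >= lfc_min & fdr < fdr_max ~ "up",
    log2fc <= -lfc_min & fdr < fdr_max ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble::tibble(
    gene = rownames(m),
    mean_cpm_a = mean_a, mean_cpm_b = mean_b,
    log2fc = log2fc, p = p, fdr = fdr, direction = direction
  )
  attr(out, "lfc_min") <- lfc_min
  attr(out, "fdr_max") <- fdr_max
  class(out) <- c("sdeg_result", class(out))
  out
}

#' @rdname sdeg_call
#' @param x An `sdeg_result`.
#' @param ... Unused.
#' @method tidy sdeg_result
#' @export
tidy.sdeg_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sdeg_result")
  out
}

#' @rdname sdeg_call
#' @method glance sdeg_result
#' @export
glance.sdeg_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    lfc_min = attr(x, "lfc_min") %||% 1,
    fdr_max = attr(x, "fdr_max") %||% 1e-4
  )
}

# round half away from zero, as printed percentages are
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Overlap statistics between two gene sets
#'
#' Reports the intersection size and the percentage of set A contained in set
#' B, `100 * |A intersect B| / |A|`, rounded half-up to one decimal (the
#' convention of printed overlap percentages). `NA` when A is empty.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @return A one-row tibble: `n_intersect`, `n_a`, `n_b`, `pct_a_in_b`.
#' @examples
#' overlap_stats(letters[1:10], letters[6:15])  # 50%
#' @export
overlap_stats <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  n_int <- length(intersect(set_a, set_b))
  tibble::tibble(
    n_intersect = n_int,
    n_a = length(set_a),
    n_b = length(set_b),
    pct_a_in_b = if (length(set_a) == 0) NA_real_
                 else round_half_up(100 * n_int / length(set_a), 1)
  )
}

#' Overlap percentage from printed counts
#'
#' Convenience for recomputing a published overlap percentage directly from
#' its numerator and denominator, with the same half-up one-decimal rounding
#' as [overlap_stats()].
#'
#' @param n_overlap,n_total Counts.
#' @return Percentage rounded to one decimal.
#' @export
overlap_pct <- function(n_overlap, n_total) {
  if (n_total == 0) return(NA_real_)
  round_half_up(100 * n_overlap / n_total, 1)
}

#' Fisher set enrichment
#'
#' Tests whether a member set (e.g. a transcription-factor family) is
#' over-represented in a selected gene set (e.g. the upregulated SDEGs) drawn
#' from a universe, using the same two-sided Fisher's exact test as the
#' differential-editing module. The odds ratio is the cross-product, with a
#' Haldane correction of 0.5 added to every cell when any cell is zero.
#'
#' @param member_set,selected,universe Character vectors of gene identifiers;
#'   `member_set` and `selected` must be subsets of `universe`.
#' @return A one-row tibble: `k` (members among selected), `K` (selected
#'   size), `n` (members in universe), `N` (universe size), `odds_ratio`, `p`.
#' @export
set_enrichment <- function(member_set, selected, universe) {
  universe <- unique(universe)
  member_set <- unique(member_set)
  selected <- unique(selected)
  if (length(setdiff(selected, universe)) > 0) {
    stop("selected set is not a subset of the universe", call. = FALSE)
  }
  if (length(setdiff(member_set, universe)) > 0) {
    stop("member set is not a subset of the universe", call. = FALSE)
  }
  k <- length(intersect(member_set, selected))
  K <- length(selected)
  n <- length(member_set)
  N <- length(universe)
  cells <- c(k, K - k, n - k, N - K - (n - k))
  p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
  if (any(cells == 0)) cells <- cells + 0.5
  tibble::tibble(
    k = k, K = K, n = n, N = N,
    odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
    p = p
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are first averaged to a mean Ct per sample and gene;
#' then for each sample `dCt = Ct_target - Ct_reference`, `ddCt = dCt -
#' dCt_calibrator`, and relative expression is `2^-ddCt`. The calibrator
#' sample's relative expression is exactly 1 by construction.
#'
#' @param measurements Tibble with columns `sample`, `gene`, `ct` and
#'   optionally `replicate`.
#' @param target Target gene name.
#' @param reference Reference (internal control) gene name, e.g. `"PP2A"`.
#' @param calibrator_sample Sample the others are expressed relative to.
#' @return A tibble per sample: `sample`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expression`.
#' @export
delta_delta_ct <- function(measurements, target, reference, calibrator_sample) {
  x <- tibble::as_tibble(measurements)
  stopifnot(all(c("sample", "gene", "ct") %in% names(x)))
  if (any(!is.finite(x$ct) | x$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  mean_ct <- dplyr::summarise(dplyr::group_by(x, .data$sample, .data$gene),
                              ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(
    dplyr::filter(mean_ct, .data$gene %in% c(target, reference)),
    names_from = "gene", values_from = "ct"
  )
  if (!reference %in% names(wide) || anyNA(wide[[reference]])) {
    stop("reference gene '", reference, "' missing for some sample(s)",
         call. = FALSE)
  }
  if (!target %in% names(wide) || anyNA(wide[[target]])) {
    stop("target gene '", target, "' missing for some sample(s)", call. = FALSE)
  }
  if (!calibrator_sample %in% wide$sample) {
    stop("calibrator sample '", calibrator_sample, "' not measured", call. = FALSE)
  }
  dct <- wide[[target]] - wide[[reference]]
  ddct <- dct - dct[wide$sample == calibrator_sample]
  tibble::tibble(
    sample = wide$sample,
    delta_ct = dct,
    delta_delta_ct = ddct,
    rel_expression = 2^(-ddct)
  )
}

#' Row Z-scores
#'
#' Centers and scales each row (gene) of an expression matrix to mean 0 and
#' standard deviation 1 (sample standard deviation, denominator n - 1), the
#' transformation used for expression heatmaps. Constant rows become all
#' zeros, with a warning.
#'
#' @param mat Expression table (tibble with gene column, or matrix) with at
#'   least two samples.
#' @return A tibble of the same shape.
#' @export
row_zscore <- function(mat) {
  m <- as_count_matrix(mat)
  if (ncol(m) < 2) stop("row Z-scores need at least two samples", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant row(s) set to zero", call. = FALSE)
    s[s == 0] <- Inf
  }
  matrix_to_tibble((m - mu) / s)
}
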