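#' Pool replicate base counts
#'
#' Biological replicates of the same condition are combined by exact summation
#' of their edited and unedited counts before testing, mirroring how replicate
#' pileup counts are treated throughout the package. Pooling is per site (and
#' per condition when a `condition` column is present).
#'
#' @param counts A tibble of base counts with columns `site_id`, `n_edited`,
#'   `n_unedited` and optionally `n_other` and `condition`.
#' @return A tibble with one row per site (x condition): summed `n_edited`,
#'   `n_unedited` (and `n_other` if supplied) plus `n_replicates`.
#' @examples
#' pool_replicates(tibble::tibble(site_id = "ndhB-C277",
#'                                n_edited = c(10, 20), n_unedited = c(30, 40)))
#' @export
pool_replicates <- function(counts) {
  counts <- tibble::as_tibble(counts)
  keys <- intersect(c("site_id", "condition"), names(counts))
  sums <- intersect(c("n_edited", "n_unedited", "n_other"), names(counts))
  dplyr::summarise(
    dplyr::group_by(counts, dplyr::across(dplyr::all_of(keys))),
    dplyr::across(dplyr::all_of(sums), sum),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}

#' Two-sided Fisher's exact test for 2x2 tables, vectorised
#'
#' Computes the two-sided p-value for the table `[[a, b], [c, d]]` by the
#' minimum-likelihood rule: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (within relative tolerance 1e-7, the convention of
#' standard exact-test implementations). Inputs recycle and may be vectors;
#' tables sharing margins are computed once.
#'
#' @param a,b,c,d Nonnegative integer counts; `a`,`b` form the first row.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # 1
#' fisher_exact_2x2(12, 3, 5, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  x <- cbind(a, b, c, d)
  if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  m1 <- a + b          # row margins
  m2 <- c + d
  k <- a + c           # first column margin
  p <- numeric(n)
  key <- paste(m1, m2, k)
  for (grp in split(seq_len(n), key)) {
    i1 <- grp[1]
    lo <- max(0L, k[i1] - m2[i1])
    hi <- min(k[i1], m1[i1])
    probs <- dhyper(lo:hi, m1[i1], m2[i1], k[i1])
    ord <- order(probs)
    cum <- cumsum(probs[ord])
    # p(a) = total probability of tables no more likely than observed
    obs <- probs[a[grp] - lo + 1L]
    pos <- findInterval(obs * (1 + 1e-7), probs[ord])
    p_grp <- pmin(cum[pos], 1)
    p_grp[pos == length(probs)] <- 1  # every table included: exactly 1
    p[grp] <- p_grp
  }
  p
}

#' Bonferroni adjustment
#'
#' Family-wise error control by multiplying each p-value by the number of
#' tests `m` and capping at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1]; `NA`s pass through.
#' @param m Number of tests; must be at least `length(p_values)` (default).
#' @return Adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  ok <- is.na(p_values) | (p_values > 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in (0, 1]", call. = FALSE)
  if (m < sum(!is.na(p_values))) {
    stop("m must be at least the number of p-values", call. = FALSE)
  }
  pmin(1, m * p_values)
}

#' Differential editing between two conditions
#'
#' For each catalogued site, pools the replicate base counts within each
#' condition, then tests the 2x2 contingency table (edited/unedited x
#' condition) with the two-sided Fisher's exact test and applies a Bonferroni
#' correction over the testable sites. A site is testable when both pooled
#' conditions have at least one informative read; untestable sites are
#' reported with `NA` efficiencies and excluded from the Bonferroni family
#' size `m_tested`.
#'
#' @param samples_a,samples_b Base-count tibbles (columns `site_id`,
#'   `n_edited`, `n_unedited`; one row per replicate per site) for the two
#'   conditions, keyed by catalogue `site_id`s.
#' @param catalog A `site_catalog`; the output has one row per catalogue site
#'   in catalogue order.
#' @param alpha Family-wise significance level applied to the adjusted
#'   p-values (default 0.05).
#' @param m Bonferroni family size; defaults to the number of testable sites.
#' @return A tibble of class `diff_editing` with columns `site_id`, `eff_a`,
#'   `eff_b`, `delta` (`eff_b - eff_a`), `p_raw`, `p_adj`, `significant`,
#'   `m_tested`.
#' @export
differential_editing <- function(samples_a, samples_b, catalog, alpha = 0.05,
                                 m = NULL) {
  catalog <- site_catalog(tibble::as_tibble(catalog))
  if (nrow(catalog) == 0) stop("catalogue is empty", call. = FALSE)
  pool <- function(x, suffix) {
    x <- pool_replicates(dplyr::select(tibble::as_tibble(x),
                                       -dplyr::any_of("condition")))
    x <- dplyr::select(x, "site_id", "n_edited", "n_unedited")
    stats::setNames(x, c("site_id", paste0(c("e", "u"), suffix)))
  }
  tab <- dplyr::left_join(
    tibble::tibble(site_id = catalog$site_id),
    pool(samples_a, "_a"), by = "site_id"
  )
  tab <- dplyr::left_join(tab, pool(samples_b, "_b"), by = "site_id")
  tab <- dplyr::mutate(
    tab,
    dplyr::across(dplyr::all_of(c("e_a", "u_a", "e_b", "u_b")),
                  ~ dplyr::coalesce(.x, 0L)),
    testable = (.data$e_a + .data$u_a) > 0 & (.data$e_b + .data$u_b) > 0,
    eff_a = dplyr::if_else(.data$e_a + .data$u_a > 0,
                           .data$e_a / (.data$e_a + .data$u_a), NA_real_),
    eff_b = dplyr::if_else(.data$e_b + .data$u_b > 0,
                           .data$e_b / (.data$e_b + .data$u_b), NA_real_),
    delta = .data$eff_b - .data$eff_a
  )
  m_tested <- if (is.null(m)) sum(tab$testable) else as.integer(m)
  p_raw <- rep(NA_real_, nrow(tab))
  if (any(tab$testable)) {
    t_i <- which(tab$testable)
    p_raw[t_i] <- fisher_exact_2x2(tab$e_a[t_i], tab$u_a[t_i],
                                   tab$e_b[t_i], tab$u_b[t_i])
  }
  out <- tibble::tibble(
    site_id = tab$site_id,
    eff_a = tab$eff_a,
    eff_b = tab$eff_b,
    delta = tab$delta,
    p_raw = p_raw,
    p_adj = pmin(1, m_tested * p_raw),
    significant = !is.na(p_raw) & pmin(1, m_tested * p_raw) < alpha,
    m_tested = m_tested
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("diff_editing", class(out))
  out
}

#' @rdname differential_editing
#' @param x A `diff_editing` result.
#' @param ... Unused.
#' @method tidy diff_editing
#' @export
tidy.diff_editing <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diff_editing")
  out
}

#' @rdname differential_editing
#' @method glance diff_editing
#' @export
glance.diff_editing <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_testable = sum(!is.na(x$p_raw)),
    n_significant = sum(x$significant, na.rm = TRUE),
    m_tested = x$m_tested[1],
    alpha = attr(x, "alpha") %||% 0.05
  )
}
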