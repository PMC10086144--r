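test_that("cpm rescales every library to one million", {
  x <- tibble::tibble(gene = c("g1", "g2"), s1 = c(250, 750))
  expect_equal(cpm(x)$s1, c(250000, 750000))
  sim <- simulate_count_matrix(200, samples_per_group = 3, seed = 2)
  cp <- cpm(sim$counts)
  sums <- colSums(as.matrix(cp[, -1]))
  expect_equal(unname(sums), rep(1e6, 6), tolerance = 1e-9)
  # scale invariance: multiplying one sample's counts leaves its CPM unchanged
  m <- as.matrix(sim$counts[, -1]); rownames(m) <- sim$counts$gene
  m2 <- m; m2[, 1] <- m2[, 1] * 7L
  expect_equal(cpm(m2)[[2]], cpm(m)[[2]])
  # all-equal counts give all-equal CPM
  eq <- tibble::tibble(gene = paste0("g", 1:4), s1 = rep(5, 4), s2 = rep(9, 4))
  expect_true(all(as.matrix(cpm(eq)[, -1]) == 250000))
  bad <- tibble::tibble(gene = "g1", s1 = 0)
  expect_error(cpm(bad), "s1")
})

test_that("expressed filter applies strict thresholds and presets", {
  # 2.5 CPM in 9 of 10 samples passes preset (2, 9); exactly 2.0 fails
  m <- rbind(passes = c(rep(2.5, 9), 0), boundary = rep(2, 10))
  colnames(m) <- paste0("s", 1:10)
  p <- expressed_preset("cpm2_of10")
  kept <- expressed_filter(m, p$threshold, p$min_samples)
  expect_equal(kept, "passes")
  expect_true("boundary" %in% expressed_filter(m, 2, 9, strict = FALSE))
  # monotone: raising the threshold never grows the set
  set.seed(1)
  r <- matrix(runif(400, 0, 5), 40, dimnames = list(paste0("g", 1:40), NULL))
  colnames(r) <- paste0("s", 1:10)
  k1 <- expressed_filter(r, 1, 5)
  k2 <- expressed_filter(r, 2, 5)
  expect_true(all(k2 %in% k1))
  expect_error(expressed_filter(r, 1, 11), "min_samples")
})

test_that("the three filter presets recover planted expressed genes", {
  presets <- list(
    list(name = "cpm2_of10", n_samp = 10),
    list(name = "cpm0.5_of12", n_samp = 12),
    list(name = "cpm0.5_of4", n_samp = 4)
  )
  for (ps in presets) {
    sim <- simulate_count_matrix(300, samples_per_group = ps$n_samp / 2,
                                 base_mean = 400, n_silent = 100, seed = 8)
    p <- expressed_preset(ps$name)
    kept <- expressed_filter(cpm(sim$counts), p$threshold, p$min_samples)
    expect_setequal(kept, sim$truth$gene[sim$truth$expressed])
  }
})

test_that("sdeg thresholds gate on both fold change and FDR", {
  sim <- simulate_count_matrix(400, seed = 3)
  counts <- sim$counts
  res0 <- sdeg_call(counts, c("A1", "A2"), c("B1", "B2"))
  # a gene with tiny p but sub-threshold fold change stays ns
  expect_true(all(res0$direction[abs(res0$log2fc) < 1] == "ns"))
  # identical groups -> nothing called
  same <- sdeg_call(counts, c("A1", "A2"), c("A1", "A2"))
  expect_equal(sum(same$direction != "ns"), 0)
  expect_error(sdeg_call(counts, character(0), "B1"), "at least one")
})

test_that("sdeg_call recovers planted 4-fold genes with few false calls", {
  planted <- setNames(rep(4, 50), sprintf("gene%04d", 1:50))
  sim <- simulate_count_matrix(1050, base_mean = 800, planted = planted,
                               seed = 12)
  res <- sdeg_call(sim$counts, c("A1", "A2"), c("B1", "B2"))
  up <- res$gene[res$direction == "up"]
  down <- res$gene[res$direction == "down"]
  expect_gte(sum(names(planted) %in% up), 48)
  false_pos <- setdiff(c(up, down), names(planted))
  expect_lte(length(false_pos), 2)
  # direction flags antisymmetric under group swap
  swapped <- sdeg_call(sim$counts, c("B1", "B2"), c("A1", "A2"))
  expect_equal(swapped$log2fc, -res$log2fc)
  map <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(map[res$direction]), swapped$direction)
})

test_that("overlap percentages reproduce printed arithmetic", {
  expect_equal(overlap_pct(145, 161), 90.1)
  expect_equal(overlap_pct(22, 27), 81.5)
  a <- sprintf("u%03d", 1:161)
  b <- c(a[1:145], sprintf("v%03d", 1:300))
  os <- overlap_stats(a, b)
  expect_equal(os$n_intersect, 145)
  expect_equal(os$pct_a_in_b, 90.1)
  expect_equal(overlap_stats(letters[1:3], LETTERS[1:3])$pct_a_in_b, 0)
  expect_equal(overlap_stats(letters[1:3], letters)$pct_a_in_b, 100)
  expect_true(is.na(overlap_stats(character(0), letters)$pct_a_in_b))
})

test_that("set enrichment matches hypergeometric enumeration", {
  universe <- sprintf("g%04d", 1:1000)
  selected <- universe[1:100]
  members <- universe[1:20]  # all 20 inside the selection
  res <- set_enrichment(members, selected, universe)
  expect_equal(res$k, 20)
  # frozen value from exhaustive enumeration over margins (20, 980, 100)
  expect_equal(res$p, 1.578823e-21, tolerance = 1e-6)
  expect_equal(res$p, oracle_fisher(20, 80, 0, 900), tolerance = 1e-10)
  expect_true(res$odds_ratio > 1)
  # degenerate: member set = selection = universe
  expect_equal(set_enrichment(universe, universe, universe)$p, 1)
  expect_error(set_enrichment(members, c(selected, "zzz"), universe), "subset")
})

test_that("planted TF-family enrichment is detected in most seeds", {
  # a TF-family-sized member set (100 genes of a 2000-gene universe) whose
  # members enter the upregulated selection at 5x the background rate
  universe <- sprintf("g%04d", 1:2000)
  family <- universe[1:100]
  hits <- 0
  for (s in 1:60) {
    withr::with_seed(s, {
      p_sel <- ifelse(universe %in% family, 0.25, 0.05)
      selected <- universe[runif(2000) < p_sel]
    })
    if (set_enrichment(family, selected, universe)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.95)
})

test_that("2^-ddCt relative expression behaves as the textbook method", {
  meas <- tibble::tibble(
    sample = rep(c("cal", "s2", "s3"), each = 2),
    gene = rep(c("TGT", "PP2A"), 3),
    ct = c(25, 20, 24, 20, 26, 21)
  )
  res <- delta_delta_ct(meas, "TGT", "PP2A", "cal")
  expect_equal(res$rel_expression[res$sample == "cal"], 1)
  expect_equal(res$rel_expression[res$sample == "s2"], 2)   # ddCt -1
  expect_equal(res$rel_expression[res$sample == "s3"], 1)   # ddCt 0
  # technical replicates average before the subtraction
  reps <- tibble::tibble(
    sample = c(rep("cal", 4), rep("s2", 2)),
    gene = c(rep("TGT", 3), "PP2A", "TGT", "PP2A"),
    ct = c(25.1, 24.9, 25.0, 20, 24, 20),
    replicate = c(1, 2, 3, 1, 1, 1)
  )
  single <- tibble::tibble(sample = c("cal", "cal", "s2", "s2"),
                           gene = c("TGT", "PP2A", "TGT", "PP2A"),
                           ct = c(25, 20, 24, 20))
  expect_equal(delta_delta_ct(reps, "TGT", "PP2A", "cal")$rel_expression,
               delta_delta_ct(single, "TGT", "PP2A", "cal")$rel_expression)
  expect_error(delta_delta_ct(single[-2, ], "TGT", "PP2A", "cal"), "PP2A")
})

test_that("row z-scores have zero mean and unit sd, constants to zero", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(z <- row_zscore(m), "constant")
  zm <- as.matrix(z[, -1])
  expect_equal(unname(zm[1, ]), c(-1, 0, 1))
  expect_equal(unname(zm[2, ]), c(0, 0, 0))
  set.seed(5)
  r <- matrix(rnorm(500), 50, dimnames = list(paste0("g", 1:50), NULL))
  colnames(r) <- paste0("s", 1:10)
  zr <- as.matrix(row_zscore(r)[, -1])
  expect_lt(max(abs(rowMeans(zr))), 1e-9)
  expect_lt(max(abs(apply(zr, 1, sd) - 1)), 1e-9)
  expect_error(row_zscore(r[, 1, drop = FALSE]), "two samples")
})
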