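test_that("base tallies are strand-aware with other bases set aside", {
  sam <- withr::local_tempfile(fileext = ".sam")
  # + site: 30 T (edited), 10 C (unedited)
  tiny_sam(sam, c(rep("T", 30), rep("C", 10)), position = 30)
  bc <- count_bases_at_site(sam, tiny_site("+"), min_baseq = 0, min_mapq = 0)
  expect_equal(bc$n_edited, 30L)
  expect_equal(bc$n_unedited, 10L)
  expect_equal(bc$n_other, 0L)
  expect_equal(bc$depth, 40L)

  # - site: all reads show reference-forward G -> all unedited
  sam2 <- withr::local_tempfile(fileext = ".sam")
  tiny_sam(sam2, rep("G", 50), position = 40)
  bc2 <- count_bases_at_site(sam2, tiny_site("-"), min_baseq = 0, min_mapq = 0)
  expect_equal(bc2$n_edited, 0L)
  expect_equal(bc2$n_unedited, 50L)

  # - site: forward A is the edited observation; forward T is neither
  sam3 <- withr::local_tempfile(fileext = ".sam")
  tiny_sam(sam3, c(rep("A", 7), rep("G", 2), "T"), position = 40)
  bc3 <- count_bases_at_site(sam3, tiny_site("-"), min_baseq = 0, min_mapq = 0)
  expect_equal(c(bc3$n_edited, bc3$n_unedited, bc3$n_other), c(7L, 2L, 1L))
})

test_that("a + site and its reverse-complement mirror give identical counts", {
  bases_plus <- c(rep("T", 5), rep("C", 3), "A", "G")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sam_p <- withr::local_tempfile(fileext = ".sam")
  sam_m <- withr::local_tempfile(fileext = ".sam")
  tiny_sam(sam_p, bases_plus, position = 30)
  tiny_sam(sam_m, unname(comp[bases_plus]), position = 40)
  bc_p <- count_bases_at_site(sam_p, tiny_site("+"), 0, 0)
  bc_m <- count_bases_at_site(sam_m, tiny_site("-"), 0, 0)
  cols <- c("n_edited", "n_unedited", "n_other", "depth")
  expect_equal(bc_p[cols], bc_m[cols])
})

test_that("quality filters are monotone and deletions contribute nothing", {
  sam <- withr::local_tempfile(fileext = ".sam")
  # 5 high-quality and 5 low-quality (Q10 = '+') bases at the site
  tiny_sam(sam, rep("T", 10), position = 30,
           quals = c(rep("I", 5), rep("+", 5)))
  site <- tiny_site("+")
  d0 <- count_bases_at_site(sam, site, min_baseq = 0, min_mapq = 0)$depth
  d20 <- count_bases_at_site(sam, site, min_baseq = 20, min_mapq = 0)$depth
  d50 <- count_bases_at_site(sam, site, min_baseq = 50, min_mapq = 0)$depth
  expect_equal(d0, 10L)
  expect_equal(d20, 5L)
  expect_true(d50 <= d20 && d20 <= d0)

  # mapq filter
  sam_lo <- withr::local_tempfile(fileext = ".sam")
  tiny_sam(sam_lo, rep("T", 4), position = 30, mapq = 5L)
  expect_equal(count_bases_at_site(sam_lo, site, 0, 0)$depth, 4L)
  expect_equal(count_bases_at_site(sam_lo, site, 0, 20)$depth, 0L)

  # read whose deletion spans the site counts in no category
  sam_del <- withr::local_tempfile(fileext = ".sam")
  tiny_sam(sam_del, c("T", "T"), position = 30,
           starts = c(10L, 10L), cigars = c("25M", "15M6D10M"))
  bc <- count_bases_at_site(sam_del, site, 0, 0)
  expect_equal(bc$depth, 1L)
})

test_that("efficiency is edited over informative, NA when uninformative", {
  x <- editing_efficiency(tibble::tibble(
    site_id = c("a", "b"), n_edited = c(30L, 0L),
    n_unedited = c(10L, 0L), n_other = c(0L, 5L)
  ))
  expect_equal(x$efficiency, c(0.75, NA_real_))
  expect_equal(x$n_informative, c(40L, 0L))
})

test_that("simulated reads are recovered count-for-count from the ledger", {
  cat33 <- default_catalog()
  site <- cat33[cat33$site_id == "ndhD-C128", ]  # a - strand site
  sim <- simulate_site_reads(site, true_eff = 0.75, coverage = 200,
                             error_rate = 0, seed = 11)
  expect_equal(sim$ledger$n_obs_edited + sim$ledger$n_obs_unedited, 200)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$reads, sam)
  q <- quantify_all(sam, site, "s1", min_baseq = 0, min_mapq = 0)
  expect_equal(q$n_edited, sim$ledger$n_obs_edited)
  expect_equal(q$n_unedited, sim$ledger$n_obs_unedited)
  expect_equal(q$n_other, sim$ledger$n_obs_other)

  # with miscalls the partition stays exhaustive
  sim_e <- simulate_site_reads(site, 0.5, 300, error_rate = 0.01, seed = 3)
  sam_e <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim_e$reads, sam_e)
  q_e <- quantify_all(sam_e, site, "s1", min_baseq = 0, min_mapq = 0)
  expect_equal(q_e$depth, 300L)
  expect_equal(q_e$n_edited, sim_e$ledger$n_obs_edited)
  expect_equal(q_e$n_other, sim_e$ledger$n_obs_other)
})

test_that("quantify_all returns one row per catalogue site in order", {
  cat33 <- default_catalog()
  # well-separated ndhB sites (no 50-bp read can span two of them)
  five <- cat33[cat33$site_id %in% c("ndhB-C50", "ndhB-C156", "ndhB-C277",
                                     "ndhB-C419", "ndhB-C494"), ]
  sims <- lapply(seq_len(nrow(five)), function(i) {
    simulate_site_reads(five[i, ], true_eff = 0.6, coverage = 100, seed = i)
  })
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(dplyr::bind_rows(lapply(sims, `[[`, "reads")), sam)
  q <- quantify_all(sam, five, "s1", min_baseq = 0, min_mapq = 0)
  expect_equal(q$site_id, five$site_id)
  truth <- vapply(sims, function(s) {
    s$ledger$n_obs_edited / (s$ledger$n_obs_edited + s$ledger$n_obs_unedited)
  }, 1)
  expect_equal(q$efficiency, truth)

  # empty alignment -> all sites NA but present
  empty <- withr::local_tempfile(fileext = ".sam")
  write_sam(sims[[1]]$reads[0, ], empty)
  q0 <- quantify_all(empty, cat33, "s0")
  expect_equal(nrow(q0), 33)
  expect_true(all(is.na(q0$efficiency)))

  # unknown chromosome is reported by name
  bad <- site_catalog(dplyr::mutate(five[1, ], chrom = "nosuch"))
  expect_error(quantify_all(sam, bad, "s1"), "nosuch")
})

test_that("the mean pileup estimate is unbiased at binomial scale", {
  site <- default_catalog()[1, ]
  sc <- editing_scenario(site, eff_a = 0.3, eff_b = 0.3, coverage = 50,
                         n_replicates = 1)
  est <- vapply(1:1000, function(s) {
    cnt <- simulate_experiment(sc, seed = s)$counts_a
    cnt$n_edited / (cnt$n_edited + cnt$n_unedited)
  }, 1)
  tol <- 3 * sqrt(0.3 * 0.7 / 50) / sqrt(1000)
  expect_lt(abs(mean(est) - 0.3), tol)
})
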