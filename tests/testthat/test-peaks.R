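panel <- default_hexb_panel()
noiseless <- noise_model(cv = 0, sample_scale_cv = 0)

test_that("peak CSVs round-trip and invalid rows are rejected by row number", {
  pt <- simulate_sample(panel, preset_genotype("normal", panel), noiseless, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(pt, path)
  back <- read_peak_table(path, sample_id = pt$sample_id)
  expect_equal(back$peaks$size_nt, pt$peaks$size_nt, tolerance = 1e-6)
  expect_equal(nrow(back$peaks), 17L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("size_nt,height", "100,5000", "108,6000", "116,-5"), bad)
  expect_error(read_peak_table(bad), "row\\(s\\) 3")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("size_nt,height", empty)
  et <- read_peak_table(empty)
  expect_equal(nrow(et$peaks), 0L)

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("size,height", "100,5000"), nocol)
  expect_error(read_peak_table(nocol), "lacks column")
})

test_that("binning matches every probe of a diploid sample and respects tolerance", {
  pt <- simulate_sample(panel, preset_genotype("normal", panel), noiseless, seed = 4)
  sm <- bin_peaks(pt, panel)
  expect_setequal(names(sm$signals), panel$probes$probe_id)
  expect_equal(nrow(sm$unassigned_peaks), 0L)

  hom <- simulate_sample(panel, preset_genotype("del1_hom", panel), noiseless, seed = 4)
  smh <- bin_peaks(hom, panel)
  expect_length(smh$signals, 16L)
  expect_false("HEXB_ex02" %in% names(smh$signals))

  # a peak 3 tolerances away from its probe stays unassigned
  far <- peak_table("far", data.frame(
    size_nt = panel$probes$product_size[1] + 3 * panel$size_tolerance,
    height = 1000))
  smf <- bin_peaks(far, panel)
  expect_length(smf$signals, 0L)
  expect_equal(nrow(smf$unassigned_peaks), 1L)
})

test_that("binning is invariant to input peak order and injective", {
  pt <- simulate_sample(panel, preset_genotype("normal", panel), noise_model(), seed = 6)
  extra <- rbind(pt$peaks,
                 data.frame(size_nt = c(150.2, 300), height = c(500, 700), area = NA_real_))
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(nrow(extra)))
    sm <- bin_peaks(peak_table("perm", extra[perm, ]), panel)
    smo <- bin_peaks(peak_table("perm", extra), panel)
    expect_equal(sm$signals[sort(names(sm$signals))],
                 smo$signals[sort(names(smo$signals))])
    # injectivity: assigned heights are distinct rows of the input
    expect_true(all(table(names(sm$signals)) == 1L))
  }
})

test_that("greedy binning equals the brute-force optimal assignment", {
  sizes <- c(100, 106, 112, 118, 124, 130)
  probes <- data.frame(
    probe_id = paste0("p", seq_along(sizes)),
    role = c(rep("target", 4), "reference", "reference"),
    gene = c(rep("G", 4), "R1", "R2"),
    exon = c(1:4, NA, NA),
    product_size = sizes)
  small <- probe_panel("small", probes, size_tolerance = 1.5)
  for (s in 1:25) {
    obs <- withr::with_seed(s, {
      keep <- sample(c(TRUE, FALSE), length(sizes), replace = TRUE, prob = c(.8, .2))
      jit <- stats::runif(length(sizes), -2, 2)  # some beyond tolerance
      (sizes + jit)[keep]
    })
    if (length(obs) == 0) next
    pt <- peak_table("rand", data.frame(size_nt = obs,
                                        height = seq_along(obs) * 100))
    sm <- bin_peaks(pt, small)
    oracle <- oracle_assignment(obs, sizes, small$size_tolerance)
    matched <- !is.na(oracle)
    expect_setequal(names(sm$signals), probes$probe_id[matched])
    expect_equal(unname(sm$signals[probes$probe_id[matched]]),
                 (seq_along(obs) * 100)[oracle[matched]])
  }
})

test_that("QC fails on missing or weak references but not on missing targets", {
  pt <- simulate_sample(panel, preset_genotype("normal", panel), noiseless, seed = 8)
  sm <- bin_peaks(pt, panel)
  expect_true(qc_sample(sm, panel)$pass)

  no_alb <- sm
  no_alb$signals <- sm$signals[names(sm$signals) != "REF_ALB"]
  qc <- qc_sample(no_alb, panel)
  expect_false(qc$pass)
  expect_match(qc$findings, "reference probe ALB missing", all = FALSE)

  hom <- bin_peaks(simulate_sample(panel, preset_genotype("del1_hom", panel),
                                   noiseless, seed = 8), panel)
  expect_true(qc_sample(hom, panel)$pass)

  weak <- sm
  weak$signals[c("REF_ACTR1a", "REF_AFAP", "REF_ALB")] <- 1
  qcw <- qc_sample(weak, panel, min_ref_height = 100)
  expect_false(qcw$pass)
  expect_match(qcw$findings, "below floor", all = FALSE)
})
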