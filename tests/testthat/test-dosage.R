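panel <- default_hexb_panel()
noiseless <- noise_model(cv = 0, sample_scale_cv = 0)

make_map <- function(signals, sample_id = "s") {
  structure(list(sample_id = sample_id, signals = signals,
                 unassigned_peaks = data.frame()),
            class = "probe_signal_map")
}

# hand-built panel with one target and three references, for arithmetic checks
mini_panel <- probe_panel("mini", data.frame(
  probe_id = c("T1", "R1", "R2", "R3"),
  role = c("target", "reference", "reference", "reference"),
  gene = c("G", "Ra", "Rb", "Rc"),
  exon = c(1L, NA, NA, NA),
  product_size = c(100, 110, 120, 130)))

test_that("raw ratio is height over the reference sum and scale-free", {
  sm <- make_map(c(T1 = 5000, R1 = 4000, R2 = 3000, R3 = 3000))
  r <- raw_ratios(sm, mini_panel)
  expect_equal(r$raw[["T1"]], 0.5)
  doubled <- make_map(c(T1 = 10000, R1 = 8000, R2 = 6000, R3 = 6000))
  expect_equal(raw_ratios(doubled, mini_panel)$raw, r$raw)

  # absent target -> raw 0; absent reference -> error
  no_t <- make_map(c(R1 = 4000, R2 = 3000, R3 = 3000))
  expect_equal(raw_ratios(no_t, mini_panel)$raw[["T1"]], 0)
  no_r <- make_map(c(T1 = 5000, R1 = 4000, R2 = 3000))
  expect_error(raw_ratios(no_r, mini_panel), "reference signal\\(s\\) missing")
})

test_that("control reference averages raw ratios and screens dispersion", {
  pt <- simulate_sample(panel, preset_genotype("normal", panel), noiseless, seed = 1)
  rr <- raw_ratios(bin_peaks(pt, panel), panel)
  ref <- build_control_reference(list(rr, rr, rr))
  expect_equal(ref$n_samples, 3L)
  expect_equal(ref$mean_raw, rr$raw)
  expect_true(all(ref$cv_raw == 0))
  expect_length(ref$warnings, 0L)

  expect_error(build_control_reference(list(rr)), "at least 2")

  zero <- rr
  zero$raw[["HEXB_ex03"]] <- 0
  expect_error(build_control_reference(list(rr, zero)), "diploid-complete")
})

test_that("8 simulated controls at cv 0.05 stay under the 10% dispersion warning", {
  set <- simulate_set(panel, n_controls = 8, noise = noise_model(), seed = 1)
  ratios <- lapply(set$controls, function(pt) raw_ratios(bin_peaks(pt, panel), panel))
  ref <- build_control_reference(ratios)
  expect_true(all(ref$cv_raw < 0.10))
  expect_length(ref$warnings, 0L)
  # direct recomputation of the mean for one probe
  manual <- mean(vapply(ratios, function(r) r$raw[["HEXB_ex07"]], numeric(1)))
  expect_equal(ref$mean_raw[["HEXB_ex07"]], manual)
})

test_that("normalization gives 1 for controls, 0.5 for het and 0 for hom deletions", {
  ctrl <- raw_ratios(bin_peaks(
    simulate_sample(panel, preset_genotype("normal", panel), noiseless, seed = 2),
    panel), panel)
  ref <- build_control_reference(list(ctrl, ctrl))
  expect_true(all(abs(normalized_ratios(ctrl, ref)$normalized - 1) < 1e-12))

  het <- raw_ratios(bin_peaks(
    simulate_sample(panel, preset_genotype("del1_het", panel), noiseless, seed = 2),
    panel), panel)
  n_het <- normalized_ratios(het, ref)$normalized
  expect_equal(n_het[["HEXB_ex02"]], 0.5)

  hom <- raw_ratios(bin_peaks(
    simulate_sample(panel, preset_genotype("del1_hom", panel), noiseless, seed = 2),
    panel), panel)
  expect_equal(normalized_ratios(hom, ref)$normalized[["HEXB_ex02"]], 0)

  incomplete <- ref
  incomplete$mean_raw <- ref$mean_raw[-1]
  expect_error(normalized_ratios(ctrl, incomplete), "lacks probe")
})

test_that("band calling follows the 0.25/0.75/1.25 thresholds", {
  ratios <- c(1.0, 0.5, 0.10, 1.6, 0.25, 0.75, 1.25, 0.7499, 1.2501, 0)
  s <- structure(list(sample_id = "b",
                      raw = stats::setNames(ratios, paste0("p", seq_along(ratios))),
                      normalized = stats::setNames(ratios, paste0("p", seq_along(ratios)))),
                 class = "sample_ratios")
  calls <- call_copy_number(s)
  expect_equal(calls$copy_state,
               c("2", "1", "0", "gain", "1", "2", "2", "1", "gain", "0"))
  expect_equal(calls$copy_state,
               vapply(ratios, oracle_band, character(1)))
  expect_error(call_copy_number(structure(list(sample_id = "x", raw = 1,
                                               normalized = NULL),
                                          class = "sample_ratios")),
               "no normalized ratios")
  expect_error(calling_bands(0.8, 0.75, 1.25), "lo_del < hi_del")
})

test_that("copy state is monotone in the normalized ratio", {
  grid <- seq(0, 2, by = 0.01)
  s <- structure(list(sample_id = "m",
                      raw = stats::setNames(grid, paste0("p", seq_along(grid))),
                      normalized = stats::setNames(grid, paste0("p", seq_along(grid)))),
                 class = "sample_ratios")
  states <- call_copy_number(s)$copy_state
  rank <- match(states, c("0", "1", "2", "gain"))
  expect_true(all(diff(rank) >= 0))
})

test_that("segmentation reports maximal runs with correct zygosity", {
  res2 <- run_pipeline(panel, preset_genotype("del2_het", panel), noiseless, seed = 10)
  expect_equal(nrow(res2$segments), 1L)
  expect_equal(res2$segments$exon_start, 1L)
  expect_equal(res2$segments$exon_end, 5L)
  expect_equal(res2$segments$zygosity, "heterozygous")

  res1 <- run_pipeline(panel, preset_genotype("del1_het", panel), noiseless, seed = 10)
  expect_equal(res1$segments[, c("exon_start", "exon_end", "zygosity")],
               data.frame(exon_start = 2L, exon_end = 2L, zygosity = "heterozygous"))

  resn <- run_pipeline(panel, preset_genotype("normal", panel), noiseless, seed = 10)
  expect_equal(nrow(resn$segments), 0L)

  # mixed zygosity and indeterminate exclusion on hand-made calls
  calls <- data.frame(
    probe_id = c(sprintf("HEXB_ex%02d", 1:14), "REF_ACTR1a", "REF_AFAP", "REF_ALB"),
    normalized_ratio = 1,
    copy_state = c("1", "0", "1", rep("2", 3), "indeterminate", rep("2", 7), "2", "2", "2"),
    stringsAsFactors = FALSE)
  segs <- segment_deletions(calls, panel)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$exon_end, 3L)
  expect_equal(segs$zygosity, "mixed")
})

test_that("noiseless end-to-end calls equal the simulated copy numbers", {
  state_of_cn <- c(`0` = "0", `1` = "1", `2` = "2", `3` = "gain")
  tg <- panel$probes$probe_id[panel$probes$role == "target"]
  for (s in 1:20) {
    cn <- withr::with_seed(s, stats::setNames(sample(0:3, length(tg), replace = TRUE,
                                                     prob = c(.15, .25, .45, .15)), tg))
    g <- genotype_spec(paste0("rand", s), cn)
    res <- run_pipeline(panel, g, noiseless, seed = s, n_controls = 2)
    called <- res$calls$copy_state[match(tg, res$calls$probe_id)]
    expect_equal(called, unname(state_of_cn[as.character(cn)]))
  }
})

test_that("a per-sample multiplicative scale cancels out of the pipeline", {
  set <- simulate_set(panel, n_controls = 4,
                      cases = list(preset_genotype("del2_het", panel)),
                      noise = noise_model(), seed = 31)
  case <- set$cases[[1]]$peaks
  res <- mlpa_call_sample(panel, set$controls, case)
  scaled <- case
  scaled$peaks$height <- scaled$peaks$height * 7.3
  res_scaled <- mlpa_call_sample(panel, set$controls, scaled)
  expect_equal(res_scaled$ratios$normalized, res$ratios$normalized)
  expect_equal(res_scaled$segments, res$segments)
})
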