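# Synthetic fragment-analysis data with the statistical structure MLPA
# dosage analysis assumes: peak height proportional to target copy number,
# times a per-probe amplification efficiency, times a per-sample global
# scale, times multiplicative lognormal noise.

#' Noise model for simulated MLPA peaks
#'
#' @param cv Coefficient of variation of the multiplicative lognormal noise
#'   applied independently to each peak height (default 0.05; typical
#'   well-optimized MLPA runs show per-probe CVs of a few percent, which
#'   keeps an 8-sample control cohort comfortably inside the 0.75-1.25
#'   diploid band).
#' @param sample_scale_cv CV of the per-sample global scale factor (default
#'   0.15) emulating differences in DNA input and PCR yield between samples;
#'   the dosage-ratio formula cancels it exactly.
#' @param baseline_height Expected peak height of a diploid probe with unit
#'   efficiency at scale 1, in arbitrary fluorescence units (default 10000).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, sample_scale_cv = 0.15, baseline_height = 10000) {
  stopifnot(cv >= 0, sample_scale_cv >= 0, baseline_height > 0)
  structure(list(cv = cv, sample_scale_cv = sample_scale_cv,
                 baseline_height = baseline_height),
            class = "noise_model")
}

#' Genotype specification for simulation
#'
#' Maps probe ids to integer copy numbers in 0..3; probes not named default
#' to 2 (diploid). Reference probes may not deviate from copy 2: the dosage
#' formula normalizes by the reference-peak sum, so a reference CNV is
#' unidentifiable and the simulator refuses to encode one silently.
#'
#' @param label Genotype label (e.g. `"del1_het"`).
#' @param copy_number Named integer vector, `probe_id -> copy number`.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(label, copy_number = integer(0)) {
  copy_number <- vapply(copy_number, as.integer, integer(1))
  if (length(copy_number) > 0 &&
      (is.null(names(copy_number)) || any(names(copy_number) == ""))) {
    stop("copy_number must be a named vector of probe ids")
  }
  if (any(!copy_number %in% 0:3)) stop("copy numbers must be integers in 0..3")
  structure(list(label = label, copy_number = copy_number),
            class = "genotype_spec")
}

#' Preset genotypes for the deletion controls and normals
#'
#' `del1_het`: heterozygous carrier of the 2.4-kb deletion removing exon 2
#' (copy 1 at exon 2). `del2_het`: heterozygous carrier of the 16-kb 5'-end
#' deletion spanning the promoter and exons 1-5 (copy 1 at exons 1-5).
#' `del1_hom`: both alleles carrying the exon-2 deletion (copy 0 at exon 2,
#' no peak). `normal`: all diploid.
#'
#' @param name One of `"normal"`, `"del1_het"`, `"del2_het"`, `"del1_hom"`.
#' @param panel Panel supplying the probe ids (default HEXB panel).
#' @return A `genotype_spec`.
#' @export
preset_genotype <- function(name = c("normal", "del1_het", "del2_het", "del1_hom"),
                            panel = default_hexb_panel()) {
  name <- match.arg(name)
  tg <- target_probes(panel, gene = "HEXB")
  id_of_exon <- function(e) tg$probe_id[match(e, tg$exon)]
  cn <- switch(name,
    normal   = integer(0),
    del1_het = stats::setNames(1L, id_of_exon(2L)),
    del1_hom = stats::setNames(0L, id_of_exon(2L)),
    del2_het = stats::setNames(rep(1L, 5L), id_of_exon(1:5))
  )
  genotype_spec(name, cn)
}

# Per-probe amplification efficiencies: a fixed panel property, drawn once
# from a lognormal with mean 1 and sdlog 0.3 under an internal constant
# seed, so a given panel always amplifies with the same profile (and panels
# round-trip through files without carrying efficiencies).
probe_efficiencies <- function(panel, sdlog = 0.3) {
  n <- nrow(panel$probes)
  eff <- with_local_seed(392699L, stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  stats::setNames(eff, panel$probes$probe_id)
}

# Run code under a temporary RNG state, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Multiplicative lognormal factors with mean 1 and the requested CV.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate one sample's peak table
#'
#' Each probe with copy number > 0 emits one peak with
#' `height = baseline_height * efficiency * (copy_number / 2) * sample_scale
#' * lognormal(1, cv)` and observed size jittered uniformly within +/- 0.5 nt
#' of the expected amplicon size. Probes at copy 0 emit no peak. The result
#' is deterministic for a fixed seed.
#'
#' @param panel A `probe_panel`.
#' @param genotype A `genotype_spec`; probe ids must exist in the panel.
#' @param noise A `noise_model`.
#' @param seed Integer seed.
#' @param sample_id Sample label (default derived from the genotype label).
#' @return A `peak_table`.
#' @export
simulate_sample <- function(panel, genotype = preset_genotype("normal", panel),
                            noise = noise_model(), seed,
                            sample_id = genotype$label) {
  stopifnot(inherits(panel, "probe_panel"), inherits(genotype, "genotype_spec"),
            inherits(noise, "noise_model"))
  unknown <- setdiff(names(genotype$copy_number), panel$probes$probe_id)
  if (length(unknown) > 0L) {
    stop("genotype names probe id(s) not in panel: ", paste(unknown, collapse = ", "))
  }
  refs <- reference_probes(panel)$probe_id
  bad_ref <- intersect(names(genotype$copy_number)[genotype$copy_number != 2L], refs)
  if (length(bad_ref) > 0L) {
    stop("reference probes must stay at copy number 2 (normalization assumes diploid references): ",
         paste(bad_ref, collapse = ", "))
  }

  p <- panel$probes
  cn <- rep(2L, nrow(p))
  names(cn) <- p$probe_id
  cn[names(genotype$copy_number)] <- genotype$copy_number

  with_local_seed(as.integer(seed), {
    scale <- rlnorm_cv(1L, noise$sample_scale_cv)
    noise_fac <- rlnorm_cv(nrow(p), noise$cv)
    jitter <- stats::runif(nrow(p), -0.5, 0.5)
    eff <- probe_efficiencies(panel)
    keep <- cn > 0L
    peaks <- data.frame(
      size_nt = p$product_size[keep] + jitter[keep],
      height = noise$baseline_height * eff[p$probe_id[keep]] *
        (cn[keep] / 2) * scale * noise_fac[keep],
      stringsAsFactors = FALSE
    )
    rownames(peaks) <- NULL
    peak_table(sample_id, peaks)
  })
}

#' Simulate a control cohort plus deletion cases
#'
#' Controls are all-diploid samples with independent noise draws; per-sample
#' seeds are derived deterministically from the master seed, so the whole
#' set is reproducible.
#'
#' @param panel A `probe_panel`.
#' @param n_controls Number of diploid controls (>= 2; default 8, the cohort
#'   size the dosage normalization was designed around).
#' @param cases List of `genotype_spec` objects to simulate as cases.
#' @param noise A `noise_model`.
#' @param seed Master integer seed.
#' @return An object of class `simulated_set` with elements `controls` (list
#'   of `peak_table`), `cases` (list of `list(genotype, peaks)`), and `seed`.
#' @export
simulate_set <- function(panel, n_controls = 8L, cases = list(),
                         noise = noise_model(), seed) {
  if (n_controls < 2L) stop("n_controls must be >= 2: the control mean is undefined robustly otherwise")
  n <- n_controls + length(cases)
  seeds <- with_local_seed(as.integer(seed),
                           sample.int(.Machine$integer.max, n))
  controls <- lapply(seq_len(n_controls), function(i) {
    simulate_sample(panel, preset_genotype("normal", panel), noise,
                    seed = seeds[i], sample_id = sprintf("control_%02d", i))
  })
  case_out <- lapply(seq_along(cases), function(j) {
    g <- cases[[j]]
    list(genotype = g,
         peaks = simulate_sample(panel, g, noise, seed = seeds[n_controls + j],
                                 sample_id = sprintf("case_%02d_%s", j, g$label)))
  })
  structure(list(controls = controls, cases = case_out, seed = as.integer(seed)),
            class = "simulated_set")
}

#' Write a simulated set to per-sample CSVs plus a manifest
#'
#' One `<sample_id>.csv` per sample (columns `size_nt,height`) and a
#' `manifest.yaml` recording sample ids, roles, genotype labels and the
#' master seed.
#'
#' @param set A `simulated_set`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_simulated_set <- function(set, dir) {
  stopifnot(inherits(set, "simulated_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  dump <- function(pt, role, label) {
    f <- file.path(dir, paste0(pt$sample_id, ".csv"))
    write_peak_table(pt, f)
    entries[[length(entries) + 1L]] <<- list(
      sample_id = pt$sample_id, file = basename(f), role = role, genotype = label)
  }
  for (pt in set$controls) dump(pt, "control", "normal")
  for (cs in set$cases) dump(cs$peaks, "case", cs$genotype$label)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(seed = set$seed, samples = entries), manifest)
  invisible(manifest)
}
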