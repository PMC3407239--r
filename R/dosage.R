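# Dosage-quotient quantification: raw ratios against the reference-probe
# sum, normalization against a diploid control cohort, band-based copy
# calling, and deletion segmentation.

#' Raw dosage ratios for one sample
#'
#' Each probe's signal height divided by the sum of the reference-probe
#' heights. A target probe without a matched peak gets raw ratio 0 (the
#' homozygous-deletion convention); a missing reference signal is an error
#' because the denominator is incomplete — run [qc_sample()] first.
#' Reference probes are included in the map: their own ratios serve as an
#' internal sanity check after normalization (they should sit near 1).
#'
#' @param signals A `probe_signal_map` from [bin_peaks()].
#' @param panel The `probe_panel`.
#' @return An object of class `sample_ratios` with elements `sample_id`,
#'   `raw` (named numeric over all panel probes) and `normalized` (NULL until
#'   [normalized_ratios()] is applied).
#' @export
raw_ratios <- function(signals, panel) {
  stopifnot(inherits(signals, "probe_signal_map"), inherits(panel, "probe_panel"))
  refs <- reference_probes(panel)$probe_id
  missing_ref <- setdiff(refs, names(signals$signals))
  if (length(missing_ref) > 0L) {
    stop("cannot normalize: reference signal(s) missing for ",
         paste(missing_ref, collapse = ", "))
  }
  denom <- sum(signals$signals[refs])
  all_ids <- panel$probes$probe_id
  h <- stats::setNames(rep(0, length(all_ids)), all_ids)
  h[names(signals$signals)] <- signals$signals
  structure(list(sample_id = signals$sample_id,
                 raw = h / denom,
                 normalized = NULL),
            class = "sample_ratios")
}

#' Aggregate a diploid control cohort into a reference
#'
#' Per-probe arithmetic mean of the raw ratios over the controls (the
#' aggregation the dosage method defines; set `aggregate = "median"` for a
#' robust variant) plus the per-probe coefficient of variation as a
#' dispersion QC. Probes with CV above `cv_warn` are flagged in `warnings` —
#' a noisy control cohort makes the 0.75/1.25 bands unreliable.
#'
#' @param controls List of `sample_ratios` from diploid control samples; at
#'   least 2, each with a complete positive raw map (a control with a raw
#'   ratio of 0 cannot be diploid-complete and is an error).
#' @param aggregate `"mean"` (default) or `"median"`.
#' @param cv_warn CV threshold for the dispersion warning (default 0.10).
#' @return An object of class `control_reference`: `n_samples`, `mean_raw`,
#'   `cv_raw`, `warnings`.
#' @export
build_control_reference <- function(controls, aggregate = c("mean", "median"),
                                    cv_warn = 0.10) {
  aggregate <- match.arg(aggregate)
  if (!is.list(controls) || length(controls) < 2L) {
    stop("need at least 2 control samples to build a reference")
  }
  for (s in controls) stopifnot(inherits(s, "sample_ratios"))
  ids <- names(controls[[1L]]$raw)
  for (s in controls) {
    if (!identical(sort(names(s$raw)), sort(ids))) {
      stop("control samples cover different probe sets")
    }
    zero <- names(s$raw)[s$raw <= 0]
    if (length(zero) > 0L) {
      stop("control ", s$sample_id, " has zero raw ratio at ",
           paste(zero, collapse = ", "), ": controls must be diploid-complete")
    }
  }
  mat <- do.call(rbind, lapply(controls, function(s) s$raw[ids]))
  center <- if (aggregate == "mean") colMeans(mat) else apply(mat, 2L, stats::median)
  cv <- apply(mat, 2L, stats::sd) / colMeans(mat)
  warn <- names(cv)[cv > cv_warn]
  warnings <- if (length(warn) > 0L) {
    sprintf("probe %s: control CV %.3f exceeds %.2f", warn, cv[warn], cv_warn)
  } else character(0)
  structure(list(n_samples = length(controls),
                 mean_raw = center, cv_raw = cv, warnings = warnings),
            class = "control_reference")
}

#' Normalize a sample's raw ratios against the control reference
#'
#' `normalized[p] = raw[p] / mean_raw[p]`; for a true diploid probe the
#' result is ~1, for a heterozygous deletion ~0.5, for a homozygous deletion
#' 0.
#'
#' @param sample A `sample_ratios`.
#' @param ref A `control_reference` covering every probe in the sample.
#' @return The `sample_ratios` with `normalized` filled in.
#' @export
normalized_ratios <- function(sample, ref) {
  stopifnot(inherits(sample, "sample_ratios"), inherits(ref, "control_reference"))
  missing_probe <- setdiff(names(sample$raw), names(ref$mean_raw))
  if (length(missing_probe) > 0L) {
    stop("control reference lacks probe(s): ", paste(missing_probe, collapse = ", "))
  }
  sample$normalized <- sample$raw / ref$mean_raw[names(sample$raw)]
  sample
}

#' Copy-number calling bands
#'
#' The dosage-quotient bands: a normalized ratio between `hi_del` (0.75) and
#' `hi_norm` (1.25) corresponds to 2 copies, between `lo_del` (0.25) and
#' `hi_del` to 1 copy. Below `lo_del` is called 0 copies and above `hi_norm`
#' a gain — both extrapolations beyond the defined 1- and 2-copy bands,
#' needed for a total calling function. Boundary convention (the published
#' bands leave inclusivity unstated): `r < lo_del -> 0`;
#' `lo_del <= r < hi_del -> 1`; `hi_del <= r <= hi_norm -> 2`;
#' `r > hi_norm -> gain`, so 0.75 is never double-assigned.
#'
#' @param lo_del,hi_del,hi_norm Band edges; must satisfy
#'   `0 < lo_del < hi_del < hi_norm`.
#' @return An object of class `calling_bands`.
#' @export
calling_bands <- function(lo_del = 0.25, hi_del = 0.75, hi_norm = 1.25) {
  if (!(0 < lo_del && lo_del < hi_del && hi_del < hi_norm)) {
    stop("bands must satisfy 0 < lo_del < hi_del < hi_norm")
  }
  structure(list(lo_del = lo_del, hi_del = hi_del, hi_norm = hi_norm),
            class = "calling_bands")
}

#' Call per-probe copy states from normalized ratios
#'
#' @param sample A `sample_ratios` with normalized ratios present.
#' @param bands A `calling_bands`.
#' @return A data.frame (class `copy_number_calls`) with columns `probe_id`,
#'   `normalized_ratio`, `copy_state` (character: `"0"`, `"1"`, `"2"`,
#'   `"gain"`, or `"indeterminate"` for a probe whose ratio is undefined,
#'   e.g. absent from the control reference).
#' @export
call_copy_number <- function(sample, bands = calling_bands()) {
  stopifnot(inherits(sample, "sample_ratios"), inherits(bands, "calling_bands"))
  if (is.null(sample$normalized)) {
    stop("sample has no normalized ratios: apply normalized_ratios() first")
  }
  r <- sample$normalized
  state <- ifelse(is.na(r), "indeterminate",
           ifelse(r < bands$lo_del, "0",
           ifelse(r < bands$hi_del, "1",
           ifelse(r <= bands$hi_norm, "2", "gain"))))
  out <- data.frame(probe_id = names(r),
                    normalized_ratio = unname(r),
                    copy_state = unname(state),
                    stringsAsFactors = FALSE)
  class(out) <- c("copy_number_calls", "data.frame")
  out
}

#' Segment reduced-copy exons into deletion calls
#'
#' Scans the target probes of one gene in exon order and reports maximal
#' runs of consecutive exons called at copy state 0 or 1. Zygosity is
#' `"heterozygous"` if every exon in the run is at state 1, `"homozygous"`
#' if all at 0, `"mixed"` otherwise. Reference probes and indeterminate
#' calls never enter segments.
#'
#' @param calls A `copy_number_calls` data.frame.
#' @param panel The `probe_panel`.
#' @param gene Gene whose target probes are segmented (default the panel's
#'   first target gene).
#' @return A data.frame with columns `gene`, `exon_start`, `exon_end`
#'   (inclusive, 1-based), `zygosity`; zero rows when no exon is reduced.
#' @export
segment_deletions <- function(calls, panel, gene = NULL) {
  stopifnot(inherits(calls, "data.frame"), inherits(panel, "probe_panel"))
  if (is.null(gene)) gene <- target_probes(panel)$gene[1L]
  tg <- target_probes(panel, gene = gene)
  state <- calls$copy_state[match(tg$probe_id, calls$probe_id)]
  if (anyNA(state)) {
    stop("calls do not cover every target probe of gene ", gene)
  }
  reduced <- state %in% c("0", "1")
  segs <- data.frame(gene = character(0), exon_start = integer(0),
                     exon_end = integer(0), zygosity = character(0),
                     stringsAsFactors = FALSE)
  if (!any(reduced)) return(segs)
  r <- rle(reduced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    st <- state[idx]
    zyg <- if (all(st == "1")) "heterozygous"
           else if (all(st == "0")) "homozygous"
           else "mixed"
    segs <- rbind(segs, data.frame(
      gene = gene, exon_start = tg$exon[idx[1L]], exon_end = tg$exon[idx[length(idx)]],
      zygosity = zyg, stringsAsFactors = FALSE))
  }
  segs
}

#' Run the full dosage pipeline on one sample
#'
#' Convenience wrapper: bins the control and test peak tables against the
#' panel, checks QC, builds the control reference, normalizes the test
#' sample, calls copy states and segments deletions.
#'
#' @param panel A `probe_panel`.
#' @param controls List of `peak_table` objects from diploid controls.
#' @param sample A `peak_table` for the test sample.
#' @param bands A `calling_bands`.
#' @return A list with `qc`, `reference`, `ratios` (the normalized
#'   `sample_ratios`), `calls` and `segments`.
#' @export
mlpa_call_sample <- function(panel, controls, sample, bands = calling_bands()) {
  ctrl_maps <- lapply(controls, bin_peaks, panel = panel)
  for (m in ctrl_maps) {
    qc <- qc_sample(m, panel)
    if (!qc$pass) stop("control ", m$sample_id, " fails QC: ",
                       paste(qc$findings, collapse = "; "))
  }
  smap <- bin_peaks(sample, panel)
  qc <- qc_sample(smap, panel)
  if (!qc$pass) stop("sample ", smap$sample_id, " fails QC: ",
                     paste(qc$findings, collapse = "; "))
  ref <- build_control_reference(lapply(ctrl_maps, raw_ratios, panel = panel))
  ratios <- normalized_ratios(raw_ratios(smap, panel), ref)
  calls <- call_copy_number(ratios, bands)
  list(qc = qc, reference = ref, ratios = ratios, calls = calls,
       segments = segment_deletions(calls, panel))
}

#' Plot normalized dosage ratios
#'
#' Bar chart of per-probe normalized ratios with the calling bands drawn as
#' horizontal lines — the standard per-sample MLPA report figure. Requires
#' ggplot2.
#'
#' @param calls A `copy_number_calls` data.frame.
#' @param bands The `calling_bands` used for calling.
#' @return A ggplot object.
#' @export
plot_ratios <- function(calls, bands = calling_bands()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ratios requires the ggplot2 package")
  }
  calls$probe_id <- factor(calls$probe_id, levels = calls$probe_id)
  ggplot2::ggplot(calls, ggplot2::aes(x = probe_id, y = normalized_ratio,
                                      fill = copy_state)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(bands$lo_del, bands$hi_del, bands$hi_norm),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "normalized dosage ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
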