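# Reading fragment-analysis peak tables and assigning observed peaks to
# panel probes by expected amplicon size.

#' Construct a peak table
#'
#' One sample's fragment-analysis readout: observed fragment sizes (nt) and
#' peak heights (arbitrary fluorescence units), with optional peak areas.
#' Height, not area, is the quantity the dosage analysis consumes; area is
#' carried through untouched.
#'
#' @param sample_id Sample label.
#' @param peaks A data.frame with columns `size_nt` (> 0), `height` (> 0) and
#'   optionally `area` (> 0).
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(sample_id, peaks) {
  stopifnot(is.data.frame(peaks))
  if (!all(c("size_nt", "height") %in% names(peaks))) {
    stop("peak table needs columns size_nt and height")
  }
  if (!"area" %in% names(peaks)) peaks$area <- rep(NA_real_, nrow(peaks))
  peaks <- peaks[, c("size_nt", "height", "area"), drop = FALSE]
  bad <- which(!is.finite(peaks$size_nt) | peaks$size_nt <= 0 |
               !is.finite(peaks$height) | peaks$height <= 0)
  if (length(bad) > 0L) {
    stop("invalid peak row(s) ", paste(bad, collapse = ", "),
         ": sizes and heights must be positive")
  }
  structure(list(sample_id = as.character(sample_id), peaks = peaks),
            class = "peak_table")
}

#' Read a peak table from CSV
#'
#' Expects a header with columns `size_nt,height` and optionally `area`.
#' Rows violating positivity are rejected with their row numbers. An empty
#' file with a header parses to a zero-peak table (downstream QC fails it).
#'
#' @param path CSV path.
#' @param sample_id Sample label; default the file name without extension.
#' @return A `peak_table`.
#' @export
read_peak_table <- function(path, sample_id = sub("\\.[Cc][Ss][Vv]$", "", basename(path))) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("peak CSV parse failure in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(c("size_nt", "height"), names(df))
  if (length(missing_cols) > 0L) {
    stop("peak CSV ", path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 0L) {
    bad <- which(!is.finite(df$size_nt) | df$size_nt <= 0 |
                 !is.finite(df$height) | df$height <= 0)
    if (length(bad) > 0L) {
      stop("peak CSV ", path, ": invalid value(s) at data row(s) ",
           paste(bad, collapse = ", "), " (sizes and heights must be positive)")
    }
  }
  peak_table(sample_id, df)
}

#' Write a peak table to CSV
#'
#' @param pt A `peak_table`.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pt, path) {
  stopifnot(inherits(pt, "peak_table"))
  out <- pt$peaks
  if (all(is.na(out$area))) out$area <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign observed peaks to panel probes
#'
#' Greedy nearest-match assignment: probe-peak pairs within the panel's size
#' tolerance are taken in order of increasing absolute size difference (ties
#' broken by smaller expected size, then input position), each probe and
#' each peak used at most once. With inter-probe spacing greater than twice
#' the tolerance — which [validate_panel()] enforces — this equals the
#' globally optimal assignment. A probe with no peak inside the tolerance is
#' simply absent from the signal map (a candidate homozygous-deletion call,
#' not an error); peaks matched to no probe are listed in
#' `unassigned_peaks`.
#'
#' @param pt A `peak_table`.
#' @param panel A valid `probe_panel`.
#' @return An object of class `probe_signal_map`: `sample_id`, `signals`
#'   (named numeric vector, probe_id -> height, matched probes only), and
#'   `unassigned_peaks` (data.frame of unmatched peaks).
#' @export
bin_peaks <- function(pt, panel) {
  stopifnot(inherits(pt, "peak_table"), inherits(panel, "probe_panel"))
  probes <- panel$probes
  peaks <- pt$peaks
  tol <- panel$size_tolerance

  cand <- NULL
  if (nrow(peaks) > 0L) {
    d <- abs(outer(peaks$size_nt, probes$product_size, "-"))
    hit <- which(d <= tol, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      cand <- data.frame(peak = hit[, 1L], probe = hit[, 2L],
                         dist = d[hit],
                         expected = probes$product_size[hit[, 2L]])
      cand <- cand[order(cand$dist, cand$expected, cand$peak), , drop = FALSE]
    }
  }

  signals <- stats::setNames(numeric(0), character(0))
  peak_used <- rep(FALSE, nrow(peaks))
  probe_used <- rep(FALSE, nrow(probes))
  if (!is.null(cand)) {
    for (i in seq_len(nrow(cand))) {
      pk <- cand$peak[i]; pr <- cand$probe[i]
      if (peak_used[pk] || probe_used[pr]) next
      peak_used[pk] <- TRUE
      probe_used[pr] <- TRUE
      signals[probes$probe_id[pr]] <- peaks$height[pk]
    }
  }
  structure(list(
    sample_id = pt$sample_id,
    signals = signals,
    unassigned_peaks = peaks[!peak_used, , drop = FALSE]
  ), class = "probe_signal_map")
}

#' QC a binned sample
#'
#' A sample fails QC when any reference probe produced no signal (the
#' normalization denominator would be undefined) or when the summed
#' reference height falls below `min_ref_height`. A missing target probe is
#' NOT a failure: it is a candidate zero-copy call and is left to the dosage
#' stage.
#'
#' @param signal_map A `probe_signal_map`.
#' @param panel The `probe_panel` the sample was binned against.
#' @param min_ref_height Floor on the summed reference-peak height, in the
#'   same arbitrary units as the peak heights (default 100).
#' @return A list with elements `pass` (logical) and `findings` (character).
#' @export
qc_sample <- function(signal_map, panel, min_ref_height = 100) {
  stopifnot(inherits(signal_map, "probe_signal_map"), inherits(panel, "probe_panel"))
  findings <- character(0)
  refs <- reference_probes(panel)
  missing_ref <- setdiff(refs$probe_id, names(signal_map$signals))
  for (id in missing_ref) {
    gene <- refs$gene[match(id, refs$probe_id)]
    findings <- c(findings, paste0("reference probe ", gene, " missing"))
  }
  present <- intersect(refs$probe_id, names(signal_map$signals))
  total_ref <- sum(signal_map$signals[present])
  if (length(missing_ref) == 0L && total_ref < min_ref_height) {
    findings <- c(findings, sprintf(
      "total reference height %.1f below floor %.1f", total_ref, min_ref_height))
  }
  list(pass = length(findings) == 0L, findings = findings)
}
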