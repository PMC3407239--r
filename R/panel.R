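#' Construct an MLPA probe panel
#'
#' A probe panel is the assay definition: a set of target probes (one per
#' exon of the gene under study) and reference probes (loci assumed diploid
#' in every sample, used as the normalization denominator), each with an
#' expected amplicon size in nucleotides. Probes must be separated in size by
#' more than twice `size_tolerance` so that peak-to-probe binning is
#' unambiguous.
#'
#' @param name Panel name.
#' @param probes A data.frame with columns `probe_id` (character, unique),
#'   `role` (`"target"` or `"reference"`), `gene` (character), `exon`
#'   (integer, `NA` for reference probes), `product_size` (expected amplicon
#'   length, nt).
#' @param size_tolerance Maximum |observed - expected| size (nt) for a peak
#'   to be assigned to a probe. Default 1.5 nt: capillary sizing is
#'   sub-nucleotide accurate in this size range, and the tolerance must stay
#'   below half the minimum inter-probe spacing.
#' @return An object of class `probe_panel`.
#' @seealso [default_hexb_panel()], [validate_panel()], [load_panel()]
#' @export
probe_panel <- function(name, probes, size_tolerance = 1.5) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(probes))
  required <- c("probe_id", "role", "gene", "exon", "product_size")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols) > 0L) {
    stop("probe table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  probes <- data.frame(
    probe_id = as.character(probes$probe_id),
    role = as.character(probes$role),
    gene = as.character(probes$gene),
    exon = suppressWarnings(as.integer(probes$exon)),
    product_size = as.numeric(probes$product_size),
    stringsAsFactors = FALSE
  )
  panel <- structure(
    list(name = name, size_tolerance = as.numeric(size_tolerance), probes = probes),
    class = "probe_panel"
  )
  findings <- validate_panel(panel)
  if (length(findings) > 0L) {
    stop("invalid probe panel:\n  - ", paste(findings, collapse = "\n  - "))
  }
  panel
}

#' Validate a probe panel
#'
#' Checks every structural rule a usable panel must satisfy and returns the
#' violations as QC findings rather than raising them, so callers can report
#' all problems at once.
#'
#' Rules: probe ids unique; product sizes unique and pairwise separated by
#' more than `2 * size_tolerance`; `exon` present exactly for target probes;
#' at least one target and at least two reference probes; target probes of
#' one gene carry unique exon numbers; product sizes at least 60 nt.
#'
#' @param panel A `probe_panel` (or a structurally similar list, so that
#'   broken candidates can be inspected).
#' @return Character vector of findings; `character(0)` iff the panel is
#'   valid.
#' @export
validate_panel <- function(panel) {
  p <- panel$probes
  tol <- panel$size_tolerance
  findings <- character(0)
  note <- function(...) findings <<- c(findings, paste0(...))

  if (!is.data.frame(p) || nrow(p) == 0L) {
    return("panel has no probes")
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    note("size_tolerance must be a single positive number")
    tol <- NA_real_
  }

  dup_id <- unique(p$probe_id[duplicated(p$probe_id)])
  for (id in dup_id) note("duplicate id: ", id)

  bad_role <- unique(p$probe_id[!p$role %in% c("target", "reference")])
  for (id in bad_role) note("probe ", id, ": role must be 'target' or 'reference'")

  small <- p$probe_id[!is.na(p$product_size) & p$product_size < 60]
  for (id in small) note("probe ", id, ": product_size below 60 nt")

  no_exon <- p$probe_id[p$role == "target" & is.na(p$exon)]
  for (id in no_exon) note("probe ", id, ": target probe lacks exon number")
  has_exon <- p$probe_id[p$role == "reference" & !is.na(p$exon)]
  for (id in has_exon) note("probe ", id, ": reference probe must not carry an exon number")
  nonpos <- p$probe_id[p$role == "target" & !is.na(p$exon) & p$exon < 1L]
  for (id in nonpos) note("probe ", id, ": exon numbers are 1-based positive integers")

  if (sum(p$role == "reference") < 2L) note("fewer than 2 reference probes")
  if (sum(p$role == "target") < 1L) note("no target probes")

  tg <- p[p$role == "target" & !is.na(p$exon), , drop = FALSE]
  if (nrow(tg) > 0L) {
    key <- paste(tg$gene, tg$exon)
    dup <- unique(key[duplicated(key)])
    for (k in dup) note("duplicate target exon: ", k)
  }

  sizes <- sort(p$product_size)
  if (anyDuplicated(p$product_size)) {
    note("sizes not separated: duplicate product_size ",
         paste(unique(p$product_size[duplicated(p$product_size)]), collapse = ", "))
  }
  if (!is.na(tol) && length(sizes) > 1L) {
    gaps <- diff(sizes)
    close_pairs <- which(gaps <= 2 * tol & gaps > 0)
    for (i in close_pairs) {
      note("sizes not separated: ", sizes[i], " and ", sizes[i + 1L],
           " nt differ by <= 2 x size_tolerance")
    }
  }
  findings
}

#' The default HEXB MLPA panel
#'
#' Seventeen probes: targets for HEXB exons 1 to 14 plus reference probes in
#' ACTR1a (alpha-centractin), AFAP (actin filament-associated protein) and
#' ALB (albumin). The amplicon sizes are synthetic fixture constants on an
#' 8-nt grid (94 + 8(k-1) nt for exon k, references at 210/218/226 nt): the
#' real assay's per-probe product sizes are a property of its oligo design
#' and are not modeled here. The grid keeps every pair of probes separated
#' by well over twice the 1.5-nt binning tolerance.
#'
#' @return A `probe_panel` with 17 probes (14 target, 3 reference).
#' @examples
#' panel <- default_hexb_panel()
#' table(panel$probes$role)
#' @export
default_hexb_panel <- function() {
  exons <- 1:14
  probes <- data.frame(
    probe_id = c(sprintf("HEXB_ex%02d", exons), "REF_ACTR1a", "REF_AFAP", "REF_ALB"),
    role = c(rep("target", 14L), rep("reference", 3L)),
    gene = c(rep("HEXB", 14L), "ACTR1a", "AFAP", "ALB"),
    exon = c(exons, NA_integer_, NA_integer_, NA_integer_),
    product_size = c(94 + 8 * (exons - 1L), 210, 218, 226),
    stringsAsFactors = FALSE
  )
  probe_panel("HEXB_MLPA_v1", probes, size_tolerance = 1.5)
}

#' Load a probe panel from JSON or TSV
#'
#' JSON layout: `{"name", "size_tolerance", "probes": [{"probe_id", "role",
#' "gene", "exon", "product_size"}, ...]}` with `exon` absent or null for
#' reference probes. TSV layout: the same five columns with a header row;
#' empty or `NA` exon for reference probes. Probe order is preserved.
#'
#' @param path File path.
#' @param format `"json"` or `"tsv"`; inferred from the file extension when
#'   omitted.
#' @return A validated `probe_panel`.
#' @export
load_panel <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- tryCatch(
      jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) stop("panel JSON parse failure in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    for (field in c("name", "probes")) {
      if (is.null(obj[[field]])) stop("panel JSON lacks field '", field, "'")
    }
    probes <- as.data.frame(obj$probes, stringsAsFactors = FALSE)
    if (is.null(probes$exon)) probes$exon <- NA_integer_
    tol <- if (is.null(obj$size_tolerance)) 1.5 else obj$size_tolerance
    probe_panel(obj$name, probes, size_tolerance = tol)
  } else {
    probes <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
      error = function(e) stop("panel TSV parse failure in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    required <- c("probe_id", "role", "gene", "exon", "product_size")
    missing_cols <- setdiff(required, names(probes))
    if (length(missing_cols) > 0L) {
      stop("panel TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    name <- attr(probes, "panel_name")
    meta <- grep("^#", readLines(path, n = 1L), value = TRUE)
    name <- if (length(meta) == 1L) sub("^#\\s*", "", meta) else
      sub("\\.(tsv|txt)$", "", basename(path), ignore.case = TRUE)
    probe_panel(name, probes, size_tolerance = 1.5)
  }
}

#' Write a probe panel to JSON or TSV
#'
#' `load_panel(write_panel(panel, path))` is the identity on valid panels in
#' both formats (for TSV the panel name is stored in a leading `#` comment
#' line).
#'
#' @param panel A `probe_panel`.
#' @param path Destination file.
#' @param format `"json"` or `"tsv"`; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("auto", "json", "tsv")) {
  stopifnot(inherits(panel, "probe_panel"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- list(
      name = panel$name,
      size_tolerance = panel$size_tolerance,
      probes = panel$probes
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", panel$name), con)
    utils::write.table(panel$probes, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' @export
print.probe_panel <- function(x, ...) {
  n_t <- sum(x$probes$role == "target")
  n_r <- sum(x$probes$role == "reference")
  cat(sprintf("MLPA probe panel '%s': %d probes (%d target, %d reference), size tolerance %.1f nt\n",
              x$name, nrow(x$probes), n_t, n_r, x$size_tolerance))
  invisible(x)
}

# Target probes of one gene, ordered by exon number.
target_probes <- function(panel, gene = NULL) {
  tg <- panel$probes[panel$probes$role == "target", , drop = FALSE]
  if (!is.null(gene)) tg <- tg[tg$gene == gene, , drop = FALSE]
  tg[order(tg$exon), , drop = FALSE]
}

reference_probes <- function(panel) {
  panel$probes[panel$probes$role == "reference", , drop = FALSE]
}
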