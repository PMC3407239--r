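# Frame arithmetic for splice-event transcript consequences: how many
# nucleotides an exon skip, partial skip or cryptic-acceptor usage removes
# from the mature transcript, and whether the loss preserves the reading
# frame. Consequences are purely arithmetic; premature-stop positions need
# the actual cDNA sequence and are carried only as annotations.

#' Exon-length model
#'
#' @param gene Gene name.
#' @param exon_lengths Named numeric vector: names are 1-based exon numbers,
#'   values exon lengths in nt (all > 0). Models may cover any contiguous or
#'   non-contiguous subset of a gene's exons (e.g. the exons present in a
#'   minigene construct).
#' @return An object of class `exon_model`.
#' @export
exon_model <- function(gene, exon_lengths) {
  if (is.null(names(exon_lengths)) || any(!grepl("^[0-9]+$", names(exon_lengths)))) {
    stop("exon_lengths must be named by 1-based exon numbers")
  }
  len <- as.numeric(exon_lengths)
  if (any(!is.finite(len) | len <= 0)) stop("exon lengths must be positive")
  structure(list(gene = gene,
                 exon_lengths = stats::setNames(len, names(exon_lengths))),
            class = "exon_model")
}

#' A single splice event
#'
#' @param kind `"exon_skip"` (the whole exon is excluded), `"partial_skip"`
#'   (a boundary portion of the exon is excluded) or `"cryptic_acceptor"`
#'   (splicing to an acceptor inside the exon, excluding the first
#'   `nt_affected` nt downstream of the normal acceptor).
#' @param exon 1-based exon number.
#' @param nt_affected Nucleotides excluded, for partial events; ignored (and
#'   taken from the model) for `exon_skip`.
#' @return An object of class `splice_event`.
#' @export
splice_event <- function(kind = c("exon_skip", "partial_skip", "cryptic_acceptor"),
                         exon, nt_affected = NA_integer_) {
  kind <- match.arg(kind)
  exon <- as.integer(exon)
  if (kind != "exon_skip") {
    if (is.na(nt_affected) || nt_affected <= 0) {
      stop(kind, " events need a positive nt_affected")
    }
  }
  structure(list(kind = kind, exon = exon, nt_affected = as.integer(nt_affected)),
            class = "splice_event")
}

#' Reading-frame effect of removing nucleotides
#'
#' @param nt_removed Non-negative nucleotide count.
#' @return `"in_frame"` iff `nt_removed` is a multiple of 3, else
#'   `"frameshift"`.
#' @export
frame_effect <- function(nt_removed) {
  if (length(nt_removed) != 1L || !is.finite(nt_removed) || nt_removed < 0 ||
      nt_removed != as.integer(nt_removed)) {
    stop("nt_removed must be a single non-negative integer")
  }
  if (nt_removed %% 3 == 0) "in_frame" else "frameshift"
}

#' Transcript consequence of a set of splice events
#'
#' Sums the nucleotides each event excludes from the mature transcript
#' (`exon_skip`: the full exon length from the model; `partial_skip` and
#' `cryptic_acceptor`: the event's `nt_affected`) and derives the frame
#' effect. When the total loss is a multiple of 3 the codon count removed is
#' `nt_removed / 3`.
#'
#' @param model An `exon_model`.
#' @param events A list of `splice_event`s (or a single event); at most one
#'   event per exon, every exon present in the model, and partial losses not
#'   exceeding the exon length.
#' @return A list of class `transcript_consequence`: `nt_removed`, `frame`,
#'   `codons_removed` (`NA` for frameshifts), `events`.
#' @export
apply_events <- function(model, events) {
  stopifnot(inherits(model, "exon_model"))
  if (inherits(events, "splice_event")) events <- list(events)
  for (e in events) stopifnot(inherits(e, "splice_event"))
  exons <- vapply(events, function(e) e$exon, integer(1))
  if (anyDuplicated(exons)) stop("at most one splice event per exon")
  known <- as.integer(names(model$exon_lengths))
  outside <- setdiff(exons, known)
  if (length(outside) > 0L) {
    stop("event exon(s) outside the model: ", paste(outside, collapse = ", "))
  }
  losses <- vapply(events, function(e) {
    len <- model$exon_lengths[[as.character(e$exon)]]
    if (e$kind == "exon_skip") {
      len
    } else {
      if (e$nt_affected > len) {
        stop("event on exon ", e$exon, " removes ", e$nt_affected,
             " nt but the exon is only ", len, " nt")
      }
      as.numeric(e$nt_affected)
    }
  }, numeric(1))
  nt <- as.integer(sum(losses))
  frame <- frame_effect(nt)
  structure(list(
    nt_removed = nt,
    frame = frame,
    codons_removed = if (frame == "in_frame") nt %/% 3L else NA_integer_,
    events = events
  ), class = "transcript_consequence")
}

#' @export
print.transcript_consequence <- function(x, ...) {
  cat(sprintf("splice consequence: %d nt removed, %s%s\n",
              x$nt_removed, x$frame,
              if (x$frame == "in_frame") sprintf(" (%d codons)", x$codons_removed) else ""))
  invisible(x)
}

# Exon-length model used by the minigene presets. Exon 8 (181 nt) and exon
# 10 (73 nt) lengths come from the characterized skip products; exons 7, 9
# and 11 only need to be long enough to host their partial events, and
# their lengths here are synthetic placeholders (they never enter a
# computed consequence).
minigene_exon_model <- function() {
  exon_model("HEXB", c(`7` = 132, `8` = 181, `9` = 150, `10` = 73, `11` = 210))
}

#' Minigene splice-outcome presets
#'
#' The characterized outcomes of the three intronic mutations studied by
#' minigene assay, plus the alternative isoform seen with the normal
#' construct:
#' \describe{
#'   \item{`c.1082+5G>A`}{skip of exon 8 (181 nt; the accompanying figure
#'     legend states 178 nt — recorded in `notes`, the main-text value is
#'     used), frameshift, annotated p.G301_W361delfsX10.}
#'   \item{`c.1169+5G>A`}{partial skip of 87 nt of exon 9, in frame.}
#'   \item{`c.1242+1G>A`}{two isoforms: full skip of exon 10 (73 nt), and
#'     exon-10 skip combined with a cryptic acceptor 112 nt inside exon 11
#'     (185 nt total); both frameshifts.}
#'   \item{`normal`}{the cryptic acceptor 112 nt downstream of the exon-11
#'     acceptor is also used by the normal construct (and in normal
#'     fibroblasts), excluding 112 nt.}
#' }
#'
#' @return A named list; each preset has `model` (an `exon_model`),
#'   `isoforms` (named list of `splice_event` lists), `protein_annotation`
#'   and `notes`.
#' @export
minigene_presets <- function() {
  model <- minigene_exon_model()
  list(
    `c.1082+5G>A` = list(
      model = model,
      isoforms = list(exon8_skip = list(splice_event("exon_skip", 8L))),
      protein_annotation = "p.G301_W361delfsX10",
      notes = paste("exon-8 length 181 nt per the transcript-size result;",
                    "the figure legend's 178 nt is inconsistent with it and not used")
    ),
    `c.1169+5G>A` = list(
      model = model,
      isoforms = list(exon9_partial = list(splice_event("partial_skip", 9L, 87L))),
      protein_annotation = "p.E362_K390del",
      notes = "87/3 = 29 codons removed (the annotation p.E362_K390del spans 29 residues)"
    ),
    `c.1242+1G>A` = list(
      model = model,
      isoforms = list(
        exon10_skip = list(splice_event("exon_skip", 10L)),
        exon10_skip_plus_cryptic = list(splice_event("exon_skip", 10L),
                                        splice_event("cryptic_acceptor", 11L, 112L))
      ),
      protein_annotation = "p.K390_K414delfsX7",
      notes = "both isoforms shift the reading frame"
    ),
    normal = list(
      model = model,
      isoforms = list(exon11_cryptic = list(splice_event("cryptic_acceptor", 11L, 112L))),
      protein_annotation = NA_character_,
      notes = "alternative isoform via the intra-exon-11 acceptor, present in normal cells"
    )
  )
}

#' Consequences of every isoform of a minigene preset
#'
#' @param name A preset name from [minigene_presets()].
#' @return Named list of `transcript_consequence` objects, one per isoform.
#' @export
minigene_consequences <- function(name) {
  presets <- minigene_presets()
  if (!name %in% names(presets)) {
    stop("unknown minigene preset \"", name, "\"; available: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  lapply(p$isoforms, function(ev) apply_events(p$model, ev))
}
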