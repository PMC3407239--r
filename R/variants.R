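# Parser and catalog for the HGVS-style Sandhoff-disease genotype dialect:
# cDNA substitutions (c.NX>Y, with optional intronic +n/-n offsets), small
# deletions (c.N_MdelSEQ), named large deletions, and the unknown allele
# "?". Deliberately restricted to the patterns occurring in the packaged
# patient catalog; full HGVS validation against the reference transcript is
# out of scope.

POS_RE <- "[0-9]+(?:[+-][0-9]+)?"

#' Parse one allele token
#'
#' Accepts the bracket contents of a genotype string: a substitution
#' (`c.626C>T(p.T209I)`, `c.445+1G>A (r.0)`), a small deletion
#' (`c.1260_1265delAGTTGA(p.V421_E422del)`), a large deletion named by span
#' (`c.299+1471_408del2406`) or by size (`16Kbdel`), or `?` for an
#' uncharacterized allele. Parenthesized protein (`p.`) and RNA (`r.`)
#' annotations are captured but do not enter the allele identity key.
#'
#' Mutation classes: an intronic offset (`+n`/`-n`) in a substitution makes
#' it `splice_site`; a protein annotation ending in a stop (`X` or `*`)
#' makes a substitution `nonsense`, otherwise `missense`; deletions longer
#' than 50 nt (or named at kb scale) are `large_deletion`; shorter deletions
#' are `small_deletion_inframe` when the deleted length is a multiple of 3
#' and the protein annotation carries no frameshift, else
#' `small_deletion_frameshift`.
#'
#' @param text One allele token (brackets already stripped).
#' @param novel_keys Character vector of cDNA keys annotated as previously
#'   unpublished; sets the `novel` flag.
#' @return An object of class `allele_record` with fields `cdna`, `protein`,
#'   `rna`, `mut_class`, `novel`, and `key` (the whitespace-stripped cDNA
#'   identity key, `NA` for the unknown allele).
#' @export
parse_allele <- function(text, novel_keys = character(0)) {
  raw <- text
  s <- trimws(text)

  protein <- NA_character_
  rna <- NA_character_
  m <- regmatches(s, regexec("\\((p\\.[^)]*)\\)", s))[[1]]
  if (length(m) == 2L) protein <- m[2]
  m <- regmatches(s, regexec("\\((r\\.[^)]*)\\)", s))[[1]]
  if (length(m) == 2L) rna <- m[2]
  core <- trimws(gsub("\\((p|r)\\.[^)]*\\)", "", s))

  rec <- function(cdna, mut_class) {
    key <- if (is.na(cdna)) NA_character_ else gsub("\\s", "", cdna)
    structure(list(cdna = cdna, protein = protein, rna = rna,
                   mut_class = mut_class,
                   novel = !is.na(key) && key %in% gsub("\\s", "", novel_keys),
                   key = key, raw = raw),
              class = "allele_record")
  }

  if (core == "?") {
    return(rec(NA_character_, "unknown"))
  }
  if (grepl("^16\\s*[Kk]b\\s*del$", core)) {
    return(rec("16Kbdel", "large_deletion"))
  }

  sub_re <- paste0("^c\\.(", POS_RE, ")([ACGT])>([ACGT])$")
  if (grepl(sub_re, core)) {
    pos <- sub(sub_re, "\\1", core)
    intronic <- grepl("[+-]", pos)
    cls <- if (intronic) "splice_site"
           else if (!is.na(protein) && grepl("(X|\\*)[0-9]*$", protein)) "nonsense"
           else "missense"
    return(rec(core, cls))
  }

  del_re <- paste0("^c\\.(", POS_RE, ")(?:_(", POS_RE, "))?del([ACGT]+|[0-9]+)?$")
  if (grepl(del_re, core, perl = TRUE)) {
    g <- regmatches(core, regexec(del_re, core, perl = TRUE))[[1]]
    start <- g[2]; end <- g[3]; suffix <- g[4]
    len <- if (nzchar(suffix) && grepl("^[0-9]+$", suffix)) {
      as.integer(suffix)
    } else if (nzchar(suffix)) {
      nchar(suffix)
    } else if (nzchar(end) && !grepl("[+-]", start) && !grepl("[+-]", end)) {
      as.integer(end) - as.integer(start) + 1L
    } else {
      NA_integer_
    }
    cls <- if (is.na(len)) "unknown"
           else if (len > 50L) "large_deletion"
           else if (len %% 3L == 0L && !(!is.na(protein) && grepl("fs", protein)))
             "small_deletion_inframe"
           else "small_deletion_frameshift"
    return(rec(core, cls))
  }

  stop("unrecognized allele token: \"", raw, "\"")
}

#' Format an allele record back to its token form
#'
#' `parse_allele(format_allele(parse_allele(x)))` yields a record identical
#' to `parse_allele(x)` for every token in the packaged catalog.
#'
#' @param rec An `allele_record`.
#' @return A single string.
#' @export
format_allele <- function(rec) {
  stopifnot(inherits(rec, "allele_record"))
  if (is.na(rec$cdna)) return("?")
  out <- rec$cdna
  if (!is.na(rec$rna)) out <- paste0(out, " (", rec$rna, ")")
  if (!is.na(rec$protein)) out <- paste0(out, "(", rec$protein, ")")
  out
}

#' Parse a two-allele genotype string
#'
#' Expects exactly two bracketed allele tokens, e.g.
#' `"[c.146C>A(p.S49X)]+ [c.146C>A(p.S49X)]"`. The genotype is an unordered
#' pair: swapping the tokens yields an equal genotype key. `homozygous` is
#' true iff the two normalized allele keys are equal (and known).
#'
#' @param patient_id Patient label.
#' @param text Genotype string.
#' @param novel_keys Passed to [parse_allele()].
#' @return An object of class `genotype` with fields `patient_id`,
#'   `allele1`, `allele2`, `homozygous`, `key`.
#' @export
parse_genotype <- function(patient_id, text, novel_keys = character(0)) {
  tokens <- regmatches(text, gregexpr("\\[([^][]*)\\]", text))[[1]]
  if (length(tokens) != 2L) {
    stop("genotype for ", patient_id, " must contain exactly 2 bracketed alleles, found ",
         length(tokens), ": \"", text, "\"")
  }
  tokens <- sub("^\\[", "", sub("\\]$", "", tokens))
  a1 <- parse_allele(tokens[1], novel_keys)
  a2 <- parse_allele(tokens[2], novel_keys)
  k1 <- if (is.na(a1$key)) "?" else a1$key
  k2 <- if (is.na(a2$key)) "?" else a2$key
  structure(list(patient_id = patient_id, allele1 = a1, allele2 = a2,
                 homozygous = !is.na(a1$key) && !is.na(a2$key) && a1$key == a2$key,
                 key = paste(sort(c(k1, k2)), collapse = " | ")),
            class = "genotype")
}

#' Summarize a genotype catalog
#'
#' Distinct alleles are counted by their normalized cDNA keys, excluding the
#' unknown `?` allele; distinct genotypes by unordered allele-pair keys
#' (unknown alleles kept, so a genotype with one uncharacterized allele is
#' still one genotype); mutation classes are tallied over distinct alleles.
#'
#' @param genotypes List of `genotype` objects.
#' @param novel_keys Character vector of cDNA keys annotated as novel.
#' @return A list: `n_patients`, `n_distinct_genotypes`,
#'   `n_distinct_alleles`, `n_novel_alleles`, `class_counts` (named integer
#'   vector over mutation classes present).
#' @export
catalog_stats <- function(genotypes, novel_keys = character(0)) {
  for (g in genotypes) stopifnot(inherits(g, "genotype"))
  alleles <- unlist(lapply(genotypes, function(g) list(g$allele1, g$allele2)),
                    recursive = FALSE)
  keys <- vapply(alleles, function(a) if (is.na(a$key)) NA_character_ else a$key,
                 character(1))
  known <- !is.na(keys)
  first_idx <- match(unique(keys[known]), keys)
  distinct <- unique(keys[known])
  novel_norm <- gsub("\\s", "", novel_keys)
  classes <- vapply(alleles[first_idx], function(a) a$mut_class, character(1))
  list(
    n_patients = length(genotypes),
    n_distinct_genotypes = length(unique(vapply(genotypes, function(g) g$key, character(1)))),
    n_distinct_alleles = length(distinct),
    n_novel_alleles = sum(distinct %in% novel_norm),
    class_counts = if (length(classes) > 0L) table(classes) else table(character(0))
  )
}

#' Load the packaged Sandhoff-disease patient catalog
#'
#' Fourteen patient records (SD1..SD14) with their published genotype
#' strings, plus the set of cDNA keys annotated as previously unpublished
#' alleles. Shipped as plain-text fixtures under `extdata/`.
#'
#' @return A list with `genotypes` (data.frame: `patient_id`, `genotype`)
#'   and `novel_keys` (character vector).
#' @export
load_table1_fixture <- function() {
  gpath <- system.file("extdata", "hexb_sd_genotypes.tsv", package = "mlpadose",
                       mustWork = TRUE)
  npath <- system.file("extdata", "hexb_sd_novel_alleles.txt", package = "mlpadose",
                       mustWork = TRUE)
  genotypes <- utils::read.delim(gpath, stringsAsFactors = FALSE)
  novel <- readLines(npath)
  novel <- trimws(novel[nzchar(trimws(novel)) & !grepl("^#", novel)])
  list(genotypes = genotypes, novel_keys = novel)
}

#' Parse and summarize the packaged catalog in one step
#'
#' @return The [catalog_stats()] summary of the packaged 14-patient catalog.
#' @export
sd_catalog_summary <- function() {
  fx <- load_table1_fixture()
  gts <- Map(parse_genotype, fx$genotypes$patient_id, fx$genotypes$genotype,
             MoreArgs = list(novel_keys = fx$novel_keys))
  catalog_stats(unname(gts), fx$novel_keys)
}
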