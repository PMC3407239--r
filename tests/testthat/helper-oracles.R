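# Independent oracles used to cross-check the implementation.

# Brute-force optimal peak->probe assignment: enumerate every injective
# assignment of probes to in-tolerance peaks, preferring more matches, then
# smaller total |size difference|. Exponential; only for small cases.
oracle_assignment <- function(peak_sizes, expected_sizes, tol) {
  np <- length(expected_sizes)
  cand <- lapply(seq_len(np), function(i) {
    which(abs(peak_sizes - expected_sizes[i]) <= tol)
  })
  best <- list(n = -1L, dist = Inf, assign = rep(NA_integer_, np))
  recurse <- function(i, used, assign, n, dist) {
    if (i > np) {
      if (n > best$n || (n == best$n && dist < best$dist)) {
        best <<- list(n = n, dist = dist, assign = assign)
      }
      return(invisible())
    }
    recurse(i + 1L, used, assign, n, dist)  # probe i unmatched
    for (pk in cand[[i]]) {
      if (pk %in% used) next
      a <- assign; a[i] <- pk
      recurse(i + 1L, c(used, pk), a, n + 1L,
              dist + abs(peak_sizes[pk] - expected_sizes[i]))
    }
  }
  recurse(1L, integer(0), rep(NA_integer_, np), 0L, 0)
  best$assign
}

# Codon re-partitioning oracle for the frame effect: model the transcript as
# integer positions, cut n positions out of the middle, re-split into
# triples and check whether the final codon still groups the original last
# three positions.
oracle_frame <- function(n) {
  L <- 3L * (ceiling(n / 3) + 20L)  # always leaves sequence downstream of the cut
  keep <- c(seq_len(30L), seq.int(31L + n, L))
  codons <- split(keep, ceiling(seq_along(keep) / 3))
  last <- as.numeric(codons[[length(codons)]])
  if (length(last) == 3L && all(last == c(L - 2, L - 1, L))) "in_frame" else "frameshift"
}

# Set-based catalog oracle operating on the raw genotype strings, never on
# the package's parser.
oracle_catalog <- function(genotype_strings, novel_keys) {
  tokens <- lapply(genotype_strings, function(s) {
    tk <- regmatches(s, gregexpr("\\[([^][]*)\\]", s))[[1]]
    tk <- sub("^\\[", "", sub("\\]$", "", tk))
    tk <- gsub("\\((p|r)\\.[^)]*\\)", "", tk)
    gsub("\\s", "", tk)
  })
  all_alleles <- unlist(tokens)
  known <- setdiff(unique(all_alleles), "?")
  pair_keys <- vapply(tokens, function(tk) paste(sort(tk), collapse = "|"),
                      character(1))
  list(
    n_distinct_alleles = length(known),
    n_novel_alleles = length(intersect(known, gsub("\\s", "", novel_keys))),
    n_distinct_genotypes = length(unique(pair_keys))
  )
}

# Band lookup by interval enumeration, independent of the vectorized caller.
oracle_band <- function(r, lo = 0.25, hi = 0.75, top = 1.25) {
  bands <- list(
    list(test = function(x) x < lo, state = "0"),
    list(test = function(x) x >= lo && x < hi, state = "1"),
    list(test = function(x) x >= hi && x <= top, state = "2"),
    list(test = function(x) x > top, state = "gain")
  )
  for (b in bands) if (b$test(r)) return(b$state)
  stop("no band matched")
}

# Full simulate -> bin -> normalize -> call run for one case genotype.
run_pipeline <- function(panel, genotype, noise, seed, n_controls = 8L) {
  set <- simulate_set(panel, n_controls = n_controls, cases = list(genotype),
                      noise = noise, seed = seed)
  mlpa_call_sample(panel, set$controls, set$cases[[1]]$peaks)
}
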