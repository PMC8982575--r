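# standard genetic code (translation table 1), shared by translate and the
# synonymous-codon index
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = names(gc), aa = unname(gc))
}

#' Translate a coding sequence
#'
#' Standard genetic code, one-letter amino acids, terminal stop reported as
#' `"*"`. An internal stop codon is a warning (the recoder refuses to touch
#' stop codons anyway).
#'
#' @param cds In-frame coding sequence ([dna()] or string), length
#'   divisible by 3.
#' @return Protein string.
#' @examples
#' translate_cds("ATGGGATCC")
#' @export
translate_cds <- function(cds) {
  s <- as.character(as_dna(cds))
  if (nchar(s) == 0L) return("")
  if (nchar(s) %% 3L != 0L)
    abort(sprintf("CDS length %d is not divisible by 3", nchar(s)))
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (any(aa[-length(aa)] == "*"))
    warn("internal stop codon in CDS")
  paste(aa, collapse = "")
}

# forbidden-motif hits on both strands, as 1-based start positions on the
# forward strand, over all motifs
forbidden_hits <- function(s, forbidden) {
  hits <- lapply(forbidden, function(m) {
    h <- find_motif(dna(s), m, both_strands = TRUE)
    if (!nrow(h)) return(NULL)
    tibble::tibble(motif = m, start = h$offset + 1L,
                   end = h$offset + nchar(m))
  })
  empty <- tibble::tibble(motif = character(), start = integer(),
                          end = integer())
  out <- dplyr::bind_rows(c(list(empty), hits))
  dplyr::arrange(out, .data$start)
}

#' Remove forbidden restriction sites by synonymous recoding
#'
#' Rewrites a protein-coding sequence so that no forbidden recognition motif
#' occurs on either strand, changing only synonymous codons — the procedure
#' used on the toolkit's fluorescent-reporter and puromycin coding
#' sequences so they do not conflict with the vectors' cloning sites.
#'
#' Resolution is greedy and deterministic: hits are taken left to right;
#' for each hit the overlapping codons are tried left to right and, within
#' a codon, synonymous codons in lexicographic order; the first
#' substitution that removes the hit without creating a new forbidden hit
#' within +/-6 codons is accepted, and the whole sequence is re-scanned to a
#' fixpoint (junction-created hits included). A hit overlapping only
#' single-codon amino acids (Met/Trp) or stop codons is an
#' unresolvable-site error.
#'
#' @param cds In-frame coding sequence, length divisible by 3.
#' @param forbidden Character vector of recognition motifs (default: the
#'   recognition sites of the full [enzymes()] registry).
#' @return A list of class `recode_result`: `cds` (recoded [dna()]),
#'   `log` (tibble: `codon_index`, `old_codon`, `new_codon`,
#'   `removed_site`, `site_offset` 0-based).
#' @examples
#' recode("GGGGGATCCTAA", forbidden = "GGATCC")
#' @export
recode <- function(cds, forbidden = enzymes()$recognition) {
  s <- as.character(as_dna(cds))
  if (nchar(s) %% 3L != 0L)
    abort(sprintf("CDS length %d is not divisible by 3", nchar(s)))
  forbidden <- toupper(forbidden)
  tab <- codon_table()
  syn <- split(tab$codon, tab$aa)
  log <- tibble::tibble(codon_index = integer(), old_codon = character(),
                        new_codon = character(), removed_site = character(),
                        site_offset = integer())
  n_codons <- nchar(s) %/% 3L
  get_codon <- function(seq, i) substr(seq, 3L * i - 2L, 3L * i)
  set_codon <- function(seq, i, codon) {
    paste0(substr(seq, 1, 3L * i - 3L), codon, substr(seq, 3L * i + 1L,
                                                      nchar(seq)))
  }
  max_rounds <- 10L * max(1L, n_codons)
  for (round in seq_len(max_rounds)) {
    hits <- forbidden_hits(s, forbidden)
    if (!nrow(hits)) break
    hit <- hits[1, ]
    codon_from <- (hit$start - 1L) %/% 3L + 1L
    codon_to <- min((hit$end - 1L) %/% 3L + 1L, n_codons)
    resolved <- FALSE
    for (ci in codon_from:codon_to) {
      old <- get_codon(s, ci)
      aa <- Biostrings::GENETIC_CODE[[old]]
      if (aa == "*") next   # never rewrite stop codons
      for (cand in setdiff(sort(syn[[aa]]), old)) {
        trial <- set_codon(s, ci, cand)
        # the hit itself must be gone ...
        span <- substr(trial, hit$start, hit$end)
        if (span == hit$motif || span == revcomp_chr(hit$motif)) next
        # ... and no new hit may appear within +/-6 codons of the change
        local_from <- max(1L, (ci - 7L) * 3L + 1L)
        local_to <- min(nchar(s), (ci + 6L) * 3L)
        before <- forbidden_hits(substr(s, local_from, local_to), forbidden)
        after <- forbidden_hits(substr(trial, local_from, local_to),
                                forbidden)
        new_hits <- dplyr::anti_join(after, before,
                                     by = c("motif", "start", "end"))
        if (nrow(new_hits)) next
        log <- dplyr::bind_rows(log, tibble::tibble(
          codon_index = ci, old_codon = old, new_codon = cand,
          removed_site = hit$motif, site_offset = hit$start - 1L))
        s <- trial
        resolved <- TRUE
        break
      }
      if (resolved) break
    }
    if (!resolved) {
      abort(sprintf(
        "forbidden site %s at offset %d cannot be removed by synonymous substitution",
        hit$motif, hit$start - 1L), class = "mirab_unresolvable_site")
    }
  }
  if (nrow(forbidden_hits(s, forbidden)))
    abort("recoding did not converge")   # defensive; bounded by max_rounds
  structure(list(cds = dna(s), log = log), class = "recode_result")
}

#' @export
print.recode_result <- function(x, ...) {
  cat(sprintf("<recode_result> %d codon substitution(s)\n", nrow(x$log)))
  if (nrow(x$log)) print(x$log)
  invisible(x)
}

#' @exportS3Method
tidy.recode_result <- function(x, ...) x$log

#' @exportS3Method
glance.recode_result <- function(x, ...) {
  tibble::tibble(n_substitutions = nrow(x$log),
                 cds_length = nchar(x$cds))
}
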