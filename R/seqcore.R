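#' DNA sequence with topology
#'
#' Constructs a normalized DNA string. Input is uppercased, `U` is converted
#' to `T` with a warning (predicted shRNAmir sequences are sometimes pasted
#' as RNA), and any character outside `ACGT` is an error naming the first
#' offending position. Circular sequences have no distinguished endpoint for
#' motif search.
#'
#' @param bases Single character string over A/C/G/T (case-insensitive;
#'   U accepted with a warning).
#' @param topology `"linear"` (default) or `"circular"`.
#' @return A character scalar of class `dna_seq` with a `topology` attribute.
#' @examples
#' dna("ggatcc")
#' dna("GGGCCC", topology = "circular")
#' @export
dna <- function(bases, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  x <- toupper(bases)
  if (grepl("U", x, fixed = TRUE)) {
    warn("'U' found in input; converting RNA-style 'U' to 'T'.")
    x <- gsub("U", "T", x, fixed = TRUE)
  }
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0L) {
    abort(sprintf(
      "invalid character '%s' at position %d (alphabet is ACGT)",
      substr(x, bad, bad), bad
    ), class = "mirab_alphabet_error")
  }
  structure(x, class = "dna_seq", topology = topology)
}

#' @export
print.dna_seq <- function(x, ...) {
  cat(sprintf("<dna_seq> %s, %d nt\n", attr(x, "topology"), nchar(x)))
  cat(if (nchar(x) > 70) paste0(substr(x, 1, 67), "...") else unclass(x), "\n")
  invisible(x)
}

#' @rdname dna
#' @param x Object to test or coerce.
#' @export
is_dna <- function(x) inherits(x, "dna_seq")

as_dna <- function(x, topology = "linear") {
  if (is_dna(x)) return(x)
  if (inherits(x, "mirab_fragment"))
    return(dna(x$seq, topology = x$topology %||% "linear"))
  dna(as.character(x), topology = topology)
}

#' Topology of a DNA sequence
#' @param x A [dna()] object.
#' @return `"linear"` or `"circular"`.
#' @export
topology <- function(x) attr(x, "topology") %||% "linear"

#' Reverse complement
#'
#' @param seq A [dna()] object or plain string.
#' @return A `dna_seq` with the same topology.
#' @examples
#' revcomp("GGATCC")  # palindromic site
#' @export
revcomp <- function(seq) {
  s <- as_dna(seq)
  rc <- revcomp_chr(unclass(s))
  structure(rc, class = "dna_seq", topology = topology(s))
}

# bare-string reverse complement used throughout internals
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Find all occurrences of a motif
#'
#' Exact motif search on the forward strand and, optionally, the reverse
#' strand (minus-strand hits are reported at forward-strand coordinates of
#' the site they occupy). On circular sequences hits may wrap the origin and
#' are reported with a start offset in `[0, length)`.
#'
#' @param seq A [dna()] object or string.
#' @param motif Motif over ACGT, length >= 4.
#' @param both_strands Also search the minus strand (default `TRUE`).
#' @return A tibble with columns `offset` (0-based forward-strand start),
#'   `strand` (`"+"`/`"-"`) and `motif`.
#' @examples
#' find_motif("AAGGATCCAA", "GGATCC")
#' @export
find_motif <- function(seq, motif, both_strands = TRUE) {
  s <- as_dna(seq)
  motif <- as.character(as_dna(motif))
  if (nchar(motif) < 4) abort("motif must be at least 4 nt")
  fwd <- scan_offsets(s, motif)
  hits <- tibble::tibble(offset = fwd, strand = rep("+", length(fwd)),
                         motif = rep(motif, length(fwd)))
  if (both_strands) {
    rc <- revcomp_chr(motif)
    if (!identical(rc, motif)) {   # palindromes already covered by + scan
      rev <- scan_offsets(s, rc)
      hits <- dplyr::bind_rows(hits, tibble::tibble(
        offset = rev, strand = rep("-", length(rev)),
        motif = rep(motif, length(rev))
      ))
    }
  }
  dplyr::arrange(hits, .data$offset, .data$strand)
}

# 0-based start offsets of exact matches, wrap-aware for circular topology
scan_offsets <- function(s, motif) {
  n <- nchar(s)
  m <- nchar(motif)
  if (m > n && topology(s) == "linear") return(integer(0))
  subject <- unclass(s)
  if (topology(s) == "circular") {
    if (m > n) return(integer(0))
    subject <- paste0(subject, substr(subject, 1, m - 1L))
  }
  res <- gregexpr(motif, subject, fixed = TRUE)[[1]]
  if (res[1] == -1L) return(integer(0))
  starts <- as.integer(res) - 1L
  sort(unique(starts %% n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read named sequence records
#'
#' Reads multi-record FASTA (any wrap width) or a tab-separated table with
#' optional header and columns `name`/`sequence`, or `name`/`top`/`bottom`
#' for oligo pairs. Duplicate names are de-duplicated with a numeric suffix
#' and a warning; empty sequences are an error. CRLF and LF input parse
#' identically.
#'
#' @param path File path.
#' @param format `"fasta"` or `"tsv"`; guessed from the extension when `NULL`.
#' @return A tibble with a `name` column and either `sequence`, or
#'   `top` + `bottom` for the two-oligo TSV dialect.
#' @export
read_records <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  format <- match.arg(format, c("fasta", "tsv"))
  out <- if (format == "fasta") {
    xs <- Biostrings::readDNAStringSet(path)
    tibble::tibble(name = names(xs) %||% as.character(seq_along(xs)),
                   sequence = unname(as.character(xs)))
  } else {
    read_tsv_records(path)
  }
  seq_cols <- intersect(c("sequence", "top", "bottom"), names(out))
  for (col in seq_cols) {
    bad <- is.na(out[[col]]) | !nzchar(out[[col]])
    if (any(bad))
      abort(sprintf("empty sequence in record %d", which(bad)[1]))
  }
  if (anyDuplicated(out$name)) {
    warn("duplicate record names; de-duplicating with numeric suffixes")
    out$name <- make.unique(out$name, sep = "_")
  }
  out
}

read_tsv_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) abort("no records in TSV input")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(cells[[1]])
  first <- toupper(trimws(cells[[1]][[min(2L, ncol)]]))
  has_header <- !grepl("^[ACGTUacgtu]+$", first)
  header <- if (has_header) tolower(trimws(cells[[1]])) else NULL
  if (has_header) cells <- cells[-1]
  mat <- do.call(rbind, lapply(cells, function(x) {
    length(x) <- ncol
    trimws(x)
  }))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header %||% switch(as.character(ncol),
    "2" = c("name", "sequence"),
    "3" = c("name", "top", "bottom"),
    abort("TSV must have 2 (name, sequence) or 3 (name, top, bottom) columns"))
  tibble::as_tibble(df)
}

#' Write named sequence records
#'
#' Inverse of [read_records()]: writes FASTA (wrapped at 70 columns) or the
#' TSV dialect, preserving record order.
#'
#' @param records Tibble as returned by [read_records()].
#' @param path Output path.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- records[[if ("sequence" %in% names(records)) "sequence" else "top"]]
    xs <- Biostrings::DNAStringSet(seqs)
    names(xs) <- records$name
    Biostrings::writeXStringSet(xs, path, width = 70)
  } else {
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
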