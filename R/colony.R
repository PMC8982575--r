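#' Simulate a Sanger colony-sequencing read
#'
#' Draws a read of `read_len` bases from a construct starting at
#' `primer_offset` (0-based; circular constructs wrap), with independent
#' uniform substitution errors at rate `sub_rate`. Deterministic given
#' `seed`; error positions are recorded. Substitution-only: chromatogram
#' artefacts and indels are not modeled.
#'
#' @param construct Construct sequence ([dna()] or fragment from
#'   [ligate()]).
#' @param primer_offset 0-based read start on the forward strand.
#' @param read_len Read length (default 700, a typical Sanger read).
#' @param sub_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @return A list of class `sanger_read`: `bases`, `origin`,
#'   `primer_offset`, `error_positions` (1-based within the read).
#' @export
simulate_read <- function(construct, primer_offset, read_len = 700L,
                          sub_rate = 0, seed = 1L) {
  if (inherits(construct, "mirab_fragment")) {
    origin <- construct$provenance
    construct <- dna(construct$seq,
                     topology = construct$topology %||% "linear")
  } else origin <- NA_character_
  s <- as_dna(construct)
  n <- nchar(s)
  if (read_len <= 0L) abort("read_len must be positive")
  if (primer_offset < 0L || primer_offset >= n)
    abort("primer_offset must be in [0, length)")
  if (sub_rate < 0 || sub_rate > 1) abort("sub_rate must be in [0, 1]")
  circular <- topology(s) == "circular"
  avail <- if (circular) read_len else min(read_len, n - primer_offset)
  src <- if (circular) paste0(unclass(s), unclass(s)) else unclass(s)
  bases <- substr(src, primer_offset + 1L, primer_offset + avail)
  set.seed(seed)
  err <- which(runif(avail) < sub_rate)
  if (length(err)) {
    chars <- strsplit(bases, "", fixed = TRUE)[[1]]
    for (i in err) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    bases <- paste(chars, collapse = "")
  }
  structure(list(bases = dna(bases), origin = origin,
                 primer_offset = as.integer(primer_offset),
                 error_positions = err),
            class = "sanger_read")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# best (position, mismatches) of `anchor` in `s` with at most `tol`
# mismatches; exact fixed search when tol == 0
anchor_search <- function(s, anchor, tol = 0L) {
  if (tol == 0L) {
    at <- regexpr(anchor, s, fixed = TRUE)
    if (at < 0L) return(NULL)
    return(list(pos = as.integer(at), mismatches = 0L))
  }
  m <- nchar(anchor)
  n <- nchar(s)
  if (m > n) return(NULL)
  best <- NULL
  for (i in seq_len(n - m + 1L)) {
    d <- hamming(substr(s, i, i + m - 1L), anchor)
    if (d <= tol && (is.null(best) || d < best$mismatches))
      best <- list(pos = i, mismatches = d)
  }
  best
}

#' Verify a colony read against an expected cassette
#'
#' Classifies a simulated colony-sequencing read as positive or negative for
#' an expected shRNAmir. The construct-invariant 19-nt loop is used as an
#' exact anchor (a mismatch tolerance is configurable for noisy reads);
#' the read is searched in both orientations, then the 22-mers flanking the
#' loop are compared with the expected sense and guide strands. The read is
#' positive iff the loop is found, the full sense-loop-guide window is
#' covered, and both stem mismatch counts are within `mismatch_budget`.
#' Garbage input never raises: it is reported `not_found` and negative.
#'
#' @param read A `sanger_read` (or plain sequence string).
#' @param expected The expected [cassette()].
#' @param mismatch_budget Allowed mismatches per stem (default 0, the
#'   strictest reading of a "positive" clone).
#' @param anchor_tolerance Allowed mismatches in the loop anchor (default 0).
#' @return A list of class `verify_report`: `positive`, `orientation`
#'   (`"forward"`, `"reverse"`, `"not_found"`), `loop_found`, `sense_match`
#'   and `guide_match` (mismatch counts, NA when not covered), `notes`.
#' @export
verify_read <- function(read, expected, mismatch_budget = 0L,
                        anchor_tolerance = 0L) {
  stopifnot(inherits(expected, "shrnamir_cassette"))
  bases <- if (inherits(read, "sanger_read")) unclass(read$bases)
           else as.character(as_dna(read))
  report <- function(positive, orientation, loop_found,
                     sense_match = NA_integer_, guide_match = NA_integer_,
                     notes = "") {
    structure(list(positive = positive, orientation = orientation,
                   loop_found = loop_found,
                   sense_match = sense_match, guide_match = guide_match,
                   notes = notes), class = "verify_report")
  }
  for (orientation in c("forward", "reverse")) {
    s <- if (orientation == "forward") bases else revcomp_chr(bases)
    hit <- anchor_search(s, expected$loop, anchor_tolerance)
    if (is.null(hit)) next
    sense_from <- hit$pos - 22L
    guide_to <- hit$pos + nchar(expected$loop) + 21L
    if (sense_from < 1L || guide_to > nchar(s)) {
      return(report(FALSE, orientation, TRUE,
                    notes = "read does not cover the full sense-loop-guide window"))
    }
    sense_mm <- hamming(substr(s, sense_from, hit$pos - 1L), expected$sense)
    guide_mm <- hamming(substr(s, hit$pos + nchar(expected$loop), guide_to),
                        expected$guide)
    positive <- sense_mm <= mismatch_budget && guide_mm <= mismatch_budget
    return(report(positive, orientation, TRUE, sense_mm, guide_mm,
                  notes = if (positive) "" else "stem mismatches over budget"))
  }
  report(FALSE, "not_found", FALSE, notes = "loop anchor not found")
}

#' @export
print.verify_report <- function(x, ...) {
  cat(sprintf("<verify_report> %s (%s)\n",
              if (x$positive) "POSITIVE" else "negative", x$orientation))
  if (nzchar(x$notes)) cat(" ", x$notes, "\n")
  invisible(x)
}

#' @exportS3Method
tidy.verify_report <- function(x, ...) {
  tibble::tibble(positive = x$positive, orientation = x$orientation,
                 loop_found = x$loop_found, sense_match = x$sense_match,
                 guide_match = x$guide_match, notes = x$notes)
}

#' Summarise a colony screen
#'
#' @param reports A list of `verify_report`s, or a tibble with a `positive`
#'   column (as from `purrr::map_dfr(reports, tidy)`).
#' @return A one-row tibble: `n`, `n_positive`, `percent_positive`.
#' @export
screen_summary <- function(reports) {
  pos <- if (is.data.frame(reports)) reports$positive
         else vapply(reports, function(r) isTRUE(r$positive), logical(1))
  if (!length(pos)) abort("no verification reports supplied")
  tibble::tibble(n = length(pos), n_positive = sum(pos),
                 percent_positive = 100 * sum(pos) / length(pos))
}
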