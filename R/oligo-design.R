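# Fixed miR-AB layout. The lower stem is replaced by BamHI/ApaI sites, so a
# designed top oligo is GATCC + G + sense(22) + loop(19) + guide(22) + T +
# GGGCC (75 nt) and the bottom oligo is revcomp(top[5..71]) (67 nt), leaving
# a 5' GATC and a 3' GGCC overhang after annealing. The constants below are
# the consensus of every bundled published oligo pair; a test re-derives
# them from the fixture.
MIRAB_LOOP    <- "TAGTGAAGCCACAGATGTA"
MIRAB_FLANK5  <- "TGCTGTTGACAGTGAGCG"
MIRAB_FLANK3  <- "TGCCTACTGCCTCGGA"
MIRAB_TOP_PREFIX <- "GATCC"
MIRAB_TOP_SUFFIX <- "GGGCC"

# 1-based closed coordinates of the 97-mer regions
MIRAB_REGIONS <- list(flank5 = c(1L, 18L), sense = c(19L, 40L),
                      loop = c(41L, 59L), guide = c(60L, 81L),
                      flank3 = c(82L, 97L))

#' shRNAmir cassette record
#'
#' The parsed anatomy of a 97-nt shRNAmir: 18-nt 5' flank, 22-nt sense
#' (passenger) strand, 19-nt loop, 22-nt guide (antisense) strand and 16-nt
#' 3' flank.
#'
#' @param flank5,sense,loop,guide,flank3 Region strings (see lengths above).
#' @param name Optional label.
#' @return An object of class `shrnamir_cassette`.
#' @export
cassette <- function(sense, guide, loop = MIRAB_LOOP,
                     flank5 = MIRAB_FLANK5, flank3 = MIRAB_FLANK3,
                     name = NA_character_) {
  parts <- list(flank5 = flank5, sense = sense, loop = loop,
                guide = guide, flank3 = flank3)
  widths <- c(flank5 = 18L, sense = 22L, loop = 19L, guide = 22L, flank3 = 16L)
  parts <- lapply(parts, function(p) as.character(as_dna(p)))
  for (nm in names(widths)) {
    if (nchar(parts[[nm]]) != widths[[nm]])
      abort(sprintf("%s must be %d nt, got %d", nm, widths[[nm]],
                    nchar(parts[[nm]])), class = "mirab_layout_error")
  }
  structure(c(parts, list(name = name)), class = "shrnamir_cassette")
}

#' @export
print.shrnamir_cassette <- function(x, ...) {
  cat("<shrnamir_cassette>", if (!is.na(x$name)) x$name else "", "\n")
  cat("  sense:", x$sense, "\n  loop: ", x$loop, "\n  guide:", x$guide, "\n")
  invisible(x)
}

#' @exportS3Method
tidy.shrnamir_cassette <- function(x, ...) {
  tibble::tibble(name = x$name, flank5 = x$flank5, sense = x$sense,
                 loop = x$loop, guide = x$guide, flank3 = x$flank3)
}

#' Validate a 97-nt shRNAmir sequence
#'
#' Mirrors the error-proofing of the original oligo-conversion tool: in
#' `lenient` mode only the length-97 gate and the DNA alphabet are enforced.
#' `strict` mode (the default) additionally requires the canonical 19-nt
#' loop at positions 41-59 and warns when the stem region (positions 19-81)
#' contains an internal BamHI (GGATCC) or ApaI (GGGCCC) site, which would
#' be cut during cloning.
#'
#' @param seq 97-nt sequence (string or [dna()]).
#' @param mode `"strict"` or `"lenient"`.
#' @return A list of class `mirab_validation` with `ok`, a tibble of
#'   `issues` (`severity`, `code`, `message`, `position`), and `cassette`
#'   (`NULL` when the sequence cannot be parsed).
#' @examples
#' validate_97(reconstruct_97(cassette(
#'   sense = "ACCTGATCATCAAGAATCTTAA", guide = "TTAAGATTCTTGATGATCAGGG")))
#' @export
validate_97 <- function(seq, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  issues <- tibble::tibble(severity = character(), code = character(),
                           message = character(), position = integer())
  add <- function(severity, code, message, position = NA_integer_) {
    issues <<- dplyr::bind_rows(issues, tibble::tibble(
      severity = severity, code = code, message = message,
      position = as.integer(position)))
  }
  s <- tryCatch(as_dna(seq), error = function(e) {
    add("error", "alphabet", conditionMessage(e))
    NULL
  })
  cass <- NULL
  if (!is.null(s)) {
    n <- nchar(s)
    if (n != 97L) {
      add("error", "length", sprintf("expected 97 nt, got %d", n), n)
    } else {
      reg <- lapply(MIRAB_REGIONS, function(r) substr(s, r[1], r[2]))
      cass <- cassette(sense = reg$sense, guide = reg$guide, loop = reg$loop,
                       flank5 = reg$flank5, flank3 = reg$flank3)
      if (mode == "strict") {
        if (reg$loop != MIRAB_LOOP)
          add("error", "loop",
              sprintf("loop region (41-59) is %s, expected %s",
                      reg$loop, MIRAB_LOOP), 41L)
        stem <- substr(s, 19, 81)
        for (site in c("GGATCC", "GGGCCC")) {
          hit <- regexpr(site, stem, fixed = TRUE)
          if (hit > 0L)
            add("warning", "internal_site",
                sprintf("internal %s site in stem region", site),
                18L + as.integer(hit))
        }
      }
    }
  }
  ok <- !any(issues$severity == "error")
  structure(list(ok = ok, issues = issues,
                 cassette = if (ok) cass else NULL),
            class = "mirab_validation")
}

#' @export
print.mirab_validation <- function(x, ...) {
  cat("<mirab_validation>", if (x$ok) "OK" else "FAILED", "\n")
  if (nrow(x$issues)) print(x$issues)
  invisible(x)
}

#' @exportS3Method
glance.mirab_validation <- function(x, ...) {
  tibble::tibble(ok = x$ok,
                 n_errors = sum(x$issues$severity == "error"),
                 n_warnings = sum(x$issues$severity == "warning"))
}

#' Convert a cassette to the miR-AB oligo pair
#'
#' Emits the 75-nt top and 67-nt bottom oligo whose annealed duplex carries
#' a 5' GATC (BamHI-compatible) overhang on the top-strand 5' end and a 3'
#' GGCC (ApaI-compatible) overhang on the top-strand 3' end:
#' `top = GATCC + G + sense + loop + guide + T + GGGCC`,
#' `bottom = revcomp(top[5..71])`.
#'
#' @param cassette A [cassette()] (or a [validate_97()] result whose
#'   `$cassette` is used).
#' @return A list of class `oligo_pair` with `name`, `top`, `bottom`.
#' @examples
#' design_oligos(cassette(sense = "ACCTGATCATCAAGAATCTTAA",
#'                        guide = "TTAAGATTCTTGATGATCAGGG"))
#' @export
design_oligos <- function(cassette) {
  if (inherits(cassette, "mirab_validation")) {
    if (!cassette$ok) abort("cannot design oligos from a failed validation")
    cassette <- cassette$cassette
  }
  stopifnot(inherits(cassette, "shrnamir_cassette"))
  top <- paste0(MIRAB_TOP_PREFIX, "G", cassette$sense, cassette$loop,
                cassette$guide, "T", MIRAB_TOP_SUFFIX)
  bottom <- revcomp_chr(substr(top, 5, 71))
  structure(list(name = cassette$name, top = top, bottom = bottom),
            class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat("<oligo_pair>", if (!is.na(x$name %||% NA)) x$name else "", "\n")
  cat("  top:   ", x$top, "\n  bottom:", x$bottom, "\n")
  invisible(x)
}

#' @exportS3Method
tidy.oligo_pair <- function(x, ...) {
  tibble::tibble(name = x$name %||% NA_character_, top = x$top,
                 bottom = x$bottom)
}

#' Parse a published oligo pair back into a cassette
#'
#' Inverse of [design_oligos()]: recovers sense, loop and guide from the
#' 75-nt top oligo, checks the fixed prefix/suffix and the bottom strand
#' against `revcomp(top[5..71])`, and fills the flanks with the canonical
#' constants (the oligos do not encode them).
#'
#' @param top,bottom Oligo strings, or a single `oligo_pair`/list with
#'   `top` and `bottom` elements as first argument.
#' @param name Optional label carried onto the cassette.
#' @return A [cassette()].
#' @export
parse_oligos <- function(top, bottom = NULL, name = NA_character_) {
  if (is.list(top)) {
    pair <- top
    name <- if (!is.na(name)) name else pair$name %||% NA_character_
    bottom <- pair$bottom
    top <- pair$top
  }
  top <- as.character(as_dna(top)); bottom <- as.character(as_dna(bottom))
  if (nchar(top) != 75L)
    abort(sprintf("top oligo must be 75 nt, got %d", nchar(top)),
          class = "mirab_layout_error")
  if (nchar(bottom) != 67L)
    abort(sprintf("bottom oligo must be 67 nt, got %d", nchar(bottom)),
          class = "mirab_layout_error")
  if (substr(top, 1, 5) != MIRAB_TOP_PREFIX)
    abort(sprintf("top oligo must start with %s (found %s)",
                  MIRAB_TOP_PREFIX, substr(top, 1, 5)),
          class = "mirab_layout_error")
  if (substr(top, 71, 75) != MIRAB_TOP_SUFFIX)
    abort(sprintf("top oligo must end with %s (found %s)",
                  MIRAB_TOP_SUFFIX, substr(top, 71, 75)),
          class = "mirab_layout_error")
  expected_bottom <- revcomp_chr(substr(top, 5, 71))
  if (bottom != expected_bottom) {
    mm <- which(strsplit(bottom, "")[[1]] != strsplit(expected_bottom, "")[[1]])
    abort(sprintf(
      "bottom oligo is not the reverse complement of top[5..71]; first mismatch at bottom position %d",
      mm[1]), class = "mirab_strand_error")
  }
  cassette(sense = substr(top, 7, 28), loop = substr(top, 29, 47),
           guide = substr(top, 48, 69), name = name)
}

#' Reconstruct the 97-nt shRNAmir sequence
#'
#' Joins the canonical flanking constants to the cassette core. For a
#' cassette parsed from oligos this is canonical-flank reconstruction, not
#' recovery of the user's original flanks.
#'
#' @param cassette A [cassette()].
#' @return A linear [dna()] of length 97.
#' @export
reconstruct_97 <- function(cassette) {
  stopifnot(inherits(cassette, "shrnamir_cassette"))
  dna(paste0(cassette$flank5, cassette$sense, cassette$loop,
             cassette$guide, cassette$flank3))
}

#' Batch-convert shRNAmir sequences to oligo pairs
#'
#' Validates each record and designs its oligo pair; failures are reported
#' per record in the `status`/`message` columns rather than raised.
#'
#' @param records Tibble with `name` and `sequence` columns (as from
#'   [read_records()]), or a named character vector.
#' @param mode Validation mode, see [validate_97()].
#' @return A tibble with one row per input: `name`, `top`, `bottom`,
#'   `status` (`"ok"`/`"error"`), `message`.
#' @export
batch_design <- function(records, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (is.character(records)) {
    records <- tibble::tibble(
      name = names(records) %||% as.character(seq_along(records)),
      sequence = unname(records))
  }
  purrr::pmap_dfr(records[c("name", "sequence")], function(name, sequence) {
    res <- tryCatch({
      v <- suppressWarnings(validate_97(sequence, mode = mode))
      if (!v$ok) {
        msg <- paste(v$issues$message[v$issues$severity == "error"],
                     collapse = "; ")
        tibble::tibble(top = NA_character_, bottom = NA_character_,
                       status = "error", message = msg)
      } else {
        v$cassette$name <- name
        pair <- design_oligos(v$cassette)
        tibble::tibble(top = pair$top, bottom = pair$bottom,
                       status = "ok", message = "")
      }
    }, error = function(e) {
      tibble::tibble(top = NA_character_, bottom = NA_character_,
                     status = "error", message = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(name = name), res)
  })
}

#' Published miR-AB oligo pairs
#'
#' The bundled table of published miR-AB cloning oligos (one row per
#' shRNAmir: target gene, shRNAmir id, species, design platform, 75-nt top
#' and 67-nt bottom oligo). It is the ground truth for the oligo layout.
#'
#' @return A tibble with columns `name`, `target`, `shrna`, `species`,
#'   `designed_by`, `top`, `bottom`.
#' @examples
#' mirab_oligos()
#' @export
mirab_oligos <- function() {
  path <- system.file("extdata", "mirab_oligos.tsv", package = "mirab",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$name <- make.unique(paste(df$target, df$shrna, df$species, sep = "_"),
                         sep = "_")
  tibble::as_tibble(df[c("name", "target", "shrna", "species",
                         "designed_by", "top", "bottom")])
}
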