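# Type IIP enzymes named in the protocol. cut_top/cut_bottom are offsets of
# the strand cuts within the recognition site (0-based, from the site's 5'
# end on the forward strand); cut_top < cut_bottom leaves a 5' overhang,
# cut_top > cut_bottom a 3' overhang, equal cuts are blunt. All sites here
# are palindromic. BamHI (G^GATCC -> 5' GATC) and ApaI (GGGCC^C -> 3' GGCC)
# are validated against the published oligo-pair arithmetic in the tests.
MIRAB_ENZYMES <- tibble::tribble(
  ~name,    ~recognition, ~cut_top, ~cut_bottom,
  "BamHI",  "GGATCC",     1L,       5L,
  "ApaI",   "GGGCCC",     5L,       1L,
  "XhoI",   "CTCGAG",     1L,       5L,
  "EcoRI",  "GAATTC",     1L,       5L,
  "AfeI",   "AGCGCT",     3L,       3L,
  "ClaI",   "ATCGAT",     2L,       4L,
  "KpnI",   "GGTACC",     5L,       1L,
  "PacI",   "TTAATTAA",   5L,       3L,
  "PmeI",   "GTTTAAAC",   4L,       4L,
  "BglII",  "AGATCT",     1L,       5L
)

#' Restriction enzyme registry
#'
#' The enzymes used by the miR-AB vector system: BamHI and ApaI (the miR-AB
#' cloning sites) plus the vector-construction and screening enzymes.
#'
#' @param names Optional character vector selecting enzymes by name.
#' @return A tibble with `name`, `recognition`, `cut_top`, `cut_bottom`,
#'   `overhang` (protruding-strand sequence) and `polarity`
#'   (`"five_prime"`, `"three_prime"`, `"blunt"`).
#' @examples
#' enzymes(c("BamHI", "ApaI"))
#' @export
enzymes <- function(names = NULL) {
  reg <- dplyr::mutate(
    MIRAB_ENZYMES,
    polarity = dplyr::case_when(
      .data$cut_top < .data$cut_bottom ~ "five_prime",
      .data$cut_top > .data$cut_bottom ~ "three_prime",
      TRUE ~ "blunt"),
    overhang = substr(.data$recognition,
                      pmin(.data$cut_top, .data$cut_bottom) + 1L,
                      pmax(.data$cut_top, .data$cut_bottom)))
  if (is.null(names)) return(reg)
  missing <- setdiff(names, reg$name)
  if (length(missing))
    abort(paste("unknown enzyme(s):", paste(missing, collapse = ", ")))
  reg[match(names, reg$name), ]
}

# A fragment is stored by its forward-strand *extent*: every position
# occupied by either strand, projected onto the forward strand. Each end
# records polarity and overhang length; the overhang bases are the first /
# last `len` bases of the extent. Two sticky ends join iff polarities match
# and the extent tail of the left fragment equals the extent head of the
# right fragment (the shared overhang), so joining is
# seq_left + substring(seq_right, len + 1).
new_fragment <- function(seq, left, right, topology = "linear",
                         provenance = NA_character_) {
  structure(list(seq = as.character(as_dna(seq)),
                 left_end = left, right_end = right,
                 topology = topology, provenance = provenance),
            class = "mirab_fragment")
}

sticky_end <- function(polarity = "blunt", len = 0L) {
  stopifnot(polarity %in% c("five_prime", "three_prime", "blunt"))
  if (polarity == "blunt") len <- 0L
  list(polarity = polarity, len = as.integer(len))
}

#' Sticky-end overhang sequences of a fragment
#'
#' Overhangs are reported 5' to 3' on the protruding strand, the convention
#' under which two ends are compatible iff they share polarity and one
#' overhang is the reverse complement of the other.
#'
#' @param fragment A fragment from [digest()] or [anneal()].
#' @return A list with `left` and `right`, each `polarity` + `overhang`.
#' @export
fragment_ends <- function(fragment) {
  stopifnot(inherits(fragment, "mirab_fragment"))
  s <- fragment$seq; n <- nchar(s)
  le <- fragment$left_end; re <- fragment$right_end
  left_ov <- substr(s, 1, le$len)
  right_ov <- substr(s, n - re$len + 1L, n)
  list(
    left = list(polarity = le$polarity,
                overhang = if (le$polarity == "three_prime")
                  revcomp_chr(left_ov) else left_ov),
    right = list(polarity = re$polarity,
                 overhang = if (re$polarity == "five_prime")
                   revcomp_chr(right_ov) else right_ov))
}

#' @export
print.mirab_fragment <- function(x, ...) {
  cat(sprintf("<mirab_fragment> %s, %d nt extent (%s)\n", x$topology,
              nchar(x$seq), x$provenance %||% ""))
  if (x$topology == "linear") {
    e <- fragment_ends(x)
    cat(sprintf("  left: %s '%s'  right: %s '%s'\n", e$left$polarity,
                e$left$overhang, e$right$polarity, e$right$overhang))
  }
  invisible(x)
}

#' @exportS3Method
tidy.mirab_fragment <- function(x, ...) {
  e <- if (x$topology == "linear") fragment_ends(x) else
    list(left = list(polarity = NA, overhang = NA),
         right = list(polarity = NA, overhang = NA))
  tibble::tibble(provenance = x$provenance, topology = x$topology,
                 extent_nt = nchar(x$seq),
                 left_polarity = e$left$polarity,
                 left_overhang = e$left$overhang,
                 right_polarity = e$right$polarity,
                 right_overhang = e$right$overhang)
}

# all cut events (top-strand and bottom-strand cut coordinates, 0-based
# positions between bases) of the given enzymes on seq
cut_events <- function(seq, enz) {
  hits <- purrr::pmap_dfr(enz[c("name", "recognition", "cut_top",
                                "cut_bottom")],
    function(name, recognition, cut_top, cut_bottom) {
      h <- find_motif(seq, recognition, both_strands = TRUE)
      if (!nrow(h)) return(tibble::tibble())
      m <- nchar(recognition)
      tibble::tibble(
        enzyme = name,
        top = ifelse(h$strand == "+", h$offset + cut_top,
                     h$offset + m - cut_bottom),
        bottom = ifelse(h$strand == "+", h$offset + cut_bottom,
                        h$offset + m - cut_top))
    })
  if (!nrow(hits)) return(hits)
  n <- nchar(seq)
  hits$top <- hits$top %% n
  hits$bottom <- ((hits$bottom - hits$top + n / 2) %% n) - n / 2 + hits$top
  shift <- pmin(hits$top, hits$bottom) < 0   # sites wrapping the origin
  hits$top[shift] <- hits$top[shift] + n
  hits$bottom[shift] <- hits$bottom[shift] + n
  dplyr::distinct(dplyr::arrange(hits, .data$top))
}

end_from_cut <- function(cut) {
  d <- cut$bottom - cut$top
  sticky_end(if (d > 0) "five_prime" else if (d < 0) "three_prime"
             else "blunt", abs(d))
}

#' Digest a sequence with restriction enzymes
#'
#' Cuts at every recognition site of every enzyme, on both strands at the
#' enzyme-defined offsets. A circular input with k sites yields k fragments;
#' a linear input yields k + 1 (terminal ends blunt). A zero-site input is
#' returned as a single uncut fragment with a message.
#'
#' @param seq A [dna()] (linear or circular) or string.
#' @param enzymes Enzyme tibble from [enzymes()], or a character vector of
#'   registry names.
#' @return A list of fragments, each with typed sticky ends, ordered along
#'   the forward strand.
#' @examples
#' digest(dna("AAAGGATCCTTTT"), "BamHI")
#' @export
digest <- function(seq, enzymes) {
  s <- as_dna(seq)
  if (is.character(enzymes)) enzymes <- mirab::enzymes(enzymes)
  cuts <- cut_events(s, enzymes)
  n <- nchar(s)
  if (!nrow(cuts)) {
    inform("no recognition sites found; input returned uncut")
    return(list(new_fragment(s, sticky_end(), sticky_end(),
                             topology = topology(s), provenance = "uncut")))
  }
  # fragment between consecutive cuts: extent runs from min(top, bottom) of
  # the left cut to max(top, bottom) of the right cut, sharing the overhang
  # region with its neighbours
  k <- nrow(cuts)
  circular <- topology(s) == "circular"
  doubled <- paste0(unclass(s), unclass(s))
  frags <- list()
  if (circular) {
    for (i in seq_len(k)) {
      a <- cuts[i, ]; b <- cuts[if (i == k) 1L else i + 1L, ]
      from <- min(a$top, a$bottom)
      to <- max(b$top, b$bottom)
      if (i == k || to <= from) to <- to + n
      frags[[i]] <- new_fragment(
        substr(doubled, from + 1L, to),
        end_from_cut(a), end_from_cut(b),
        provenance = sprintf("%s/%s fragment %d", a$enzyme, b$enzyme, i))
    }
  } else {
    bounds <- rbind(data.frame(top = 0, bottom = 0, enzyme = "end"),
                    as.data.frame(cuts[c("top", "bottom", "enzyme")]),
                    data.frame(top = n, bottom = n, enzyme = "end"))
    for (i in seq_len(k + 1L)) {
      a <- bounds[i, ]; b <- bounds[i + 1L, ]
      frags[[i]] <- new_fragment(
        substr(unclass(s), min(a$top, a$bottom) + 1L, max(b$top, b$bottom)),
        end_from_cut(a), end_from_cut(b),
        provenance = sprintf("fragment %d", i))
    }
  }
  frags
}

#' Anneal two oligos into a sticky-ended duplex
#'
#' Models slow-cooled annealing as exact alignment: the bottom oligo must be
#' the reverse complement of one contiguous window of the top oligo. Any
#' unpaired top-strand 5' prefix becomes a 5' overhang and any unpaired 3'
#' suffix a 3' overhang, exactly the geometry of the miR-AB oligo pair
#' (5' GATC and 3' GGCC).
#'
#' @param top,bottom Oligo strings, or a single `oligo_pair` as first
#'   argument.
#' @return A linear fragment.
#' @examples
#' pair <- design_oligos(cassette(sense = "ACCTGATCATCAAGAATCTTAA",
#'                                guide = "TTAAGATTCTTGATGATCAGGG"))
#' fragment_ends(anneal(pair))
#' @export
anneal <- function(top, bottom = NULL) {
  prov <- "annealed duplex"
  if (is.list(top)) {
    prov <- top$name %||% prov
    bottom <- top$bottom
    top <- top$top
  }
  top <- as.character(as_dna(top)); bottom <- as.character(as_dna(bottom))
  window <- revcomp_chr(bottom)
  at <- regexpr(window, top, fixed = TRUE)
  if (at < 0L || nchar(bottom) > nchar(top))
    abort("bottom oligo has no ungapped perfect-complement placement within the top oligo",
          class = "mirab_anneal_error")
  left_len <- as.integer(at) - 1L
  right_len <- nchar(top) - (left_len + nchar(bottom))
  new_fragment(top,
               if (left_len > 0) sticky_end("five_prime", left_len)
               else sticky_end(),
               if (right_len > 0) sticky_end("three_prime", right_len)
               else sticky_end(),
               provenance = prov)
}

ends_join <- function(left_frag, right_frag) {
  re <- left_frag$right_end; le <- right_frag$left_end
  if (re$polarity != le$polarity || re$len != le$len) return(FALSE)
  if (re$len == 0L) return(TRUE)
  n <- nchar(left_frag$seq)
  substr(left_frag$seq, n - re$len + 1L, n) ==
    substr(right_frag$seq, 1, le$len)
}

join_pair <- function(left_frag, right_frag) {
  ov <- right_frag$left_end$len
  new_fragment(paste0(left_frag$seq,
                      substr(right_frag$seq, ov + 1L, nchar(right_frag$seq))),
               left_frag$left_end, right_frag$right_end,
               provenance = paste(left_frag$provenance, "+",
                                  right_frag$provenance))
}

circularize <- function(f) {
  e <- f$left_end
  if (!ends_join(f, f)) return(NULL)
  seq <- if (e$len > 0) substr(f$seq, 1, nchar(f$seq) - e$len) else f$seq
  structure(new_fragment(dna(seq, topology = "circular"), sticky_end(),
                         sticky_end(), topology = "circular",
                         provenance = paste(f$provenance, "(circular)")),
            class = c("mirab_fragment"))
}

#' Ligate fragments into circular products
#'
#' Joins compatible sticky (or blunt) ends and reports every distinct
#' circular product that uses each input fragment at most once, in the
#' orientation it was supplied (the directional two-sticky-end protocol:
#' distinct BamHI- and ApaI-type ends fix the insert orientation, so
#' orientation-flipped concatemers are out of scope). Vector
#' self-circularization is reported when a fragment's own two ends are
#' mutually compatible. Products are deduplicated by canonical rotation.
#'
#' @param fragments A list of linear fragments.
#' @return A list of circular fragments (empty, with a message, when no
#'   compatible ends exist).
#' @export
ligate <- function(fragments) {
  if (inherits(fragments, "mirab_fragment")) fragments <- list(fragments)
  lin <- purrr::keep(fragments, ~ .x$topology == "linear")
  if (!length(lin)) abort("ligation needs at least one linear fragment")
  if (length(lin) > 8L)
    abort("ligation enumeration supports at most 8 fragments")
  products <- list()
  seen <- character()
  add_product <- function(circ) {
    key <- canonical_rotation(circ$seq)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      products[[length(products) + 1L]] <<- circ
    }
  }
  # grow chains fragment by fragment (each used once, either orientation),
  # closing each chain whose outer ends are mutually compatible
  recurse <- function(chain, used) {
    circ <- circularize(chain)
    if (!is.null(circ)) add_product(circ)
    for (j in seq_along(lin)) {
      if (used[j]) next
      f <- lin[[j]]
      if (ends_join(chain, f)) {
        used2 <- used; used2[j] <- TRUE
        recurse(join_pair(chain, f), used2)
      }
    }
  }
  for (i in seq_along(lin)) {
    used <- logical(length(lin)); used[i] <- TRUE
    recurse(lin[[i]], used)   # circles found from any start are
  }                           # deduplicated by canonical rotation
  if (!length(products))
    inform("no compatible sticky-end pairings; no circular products formed")
  products
}

#' Canonical rotation of a circular sequence
#'
#' Circular identity is equality up to rotation; the canonical form is the
#' lexicographically minimal rotation.
#'
#' @param seq Circular sequence (string or [dna()]).
#' @return The canonical rotation as a plain string.
#' @export
canonical_rotation <- function(seq) {
  s <- as.character(as_dna(seq))
  n <- nchar(s)
  doubled <- paste0(s, s)
  rots <- substring(doubled, seq_len(n), seq_len(n) + n - 1L)
  min(rots)
}

#' Screen a sequence for restriction sites
#'
#' Per-enzyme hit counts and positions on both strands, used to check that
#' an insert or recoded reporter does not conflict with the vector's cloning
#' sites.
#'
#' @param seq A [dna()] or string.
#' @param enzymes Enzyme tibble or registry names (default: full registry).
#' @return A tibble with `enzyme`, `recognition`, `offset` (0-based, NA when
#'   absent), `strand` and a per-enzyme `n_sites` count.
#' @export
screen_sites <- function(seq, enzymes = NULL) {
  enz <- if (is.null(enzymes)) mirab::enzymes()
         else if (is.character(enzymes)) mirab::enzymes(enzymes)
         else enzymes
  purrr::pmap_dfr(enz[c("name", "recognition")], function(name, recognition) {
    h <- find_motif(seq, recognition, both_strands = TRUE)
    if (!nrow(h))
      return(tibble::tibble(enzyme = name, recognition = recognition,
                            offset = NA_integer_, strand = NA_character_,
                            n_sites = 0L))
    tibble::tibble(enzyme = name, recognition = recognition,
                   offset = h$offset, strand = h$strand, n_sites = nrow(h))
  })
}

#' Seeded mock miR-AB vector
#'
#' Builds a reproducible circular plasmid with exactly one BamHI site and
#' one ApaI site flanking a random stuffer (the published vectors carry a
#' ~800 bp stuffer between the cloning sites so complete digestion is
#' visible on a gel), on a backbone free of both sites. This is a synthetic
#' stand-in: the true vector sequences are distributed as plasmids and are
#' not bundled.
#'
#' @param seed Integer seed.
#' @param stuffer_len Stuffer length in bp (default 800, minimum 20).
#' @param backbone_len Backbone length in bp (default 2400).
#' @return A list with `seq` (circular [dna()]) and `features` (tibble of
#'   0-based half-open feature coordinates).
#' @examples
#' v <- make_mock_vector(seed = 1)
#' dplyr::filter(screen_sites(v$seq, c("BamHI", "ApaI")), n_sites > 0)
#' @export
make_mock_vector <- function(seed = 1L, stuffer_len = 800L,
                             backbone_len = 2400L) {
  if (stuffer_len < 20L) abort("stuffer_len must be at least 20")
  set.seed(seed)
  forbidden <- c("GGATCC", "GGGCCC")
  random_clean <- function(len) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      if (!any(vapply(forbidden, grepl, logical(1), x = s, fixed = TRUE)))
        return(s)
    }
  }
  repeat {
    backbone <- random_clean(backbone_len)
    stuffer <- random_clean(stuffer_len - 12L)  # net of the two sites
    seq <- paste0(backbone, "GGATCC", stuffer, "GGGCCC")
    circ <- dna(seq, topology = "circular")
    counts <- screen_sites(circ, c("BamHI", "ApaI"))
    if (all(tapply(counts$n_sites, counts$enzyme, max) == 1L)) break
  }
  features <- tibble::tibble(
    feature = c("backbone", "BamHI", "stuffer", "ApaI"),
    start = c(0L, backbone_len, backbone_len + 6L,
              backbone_len + 6L + stuffer_len - 12L),
    end = c(backbone_len, backbone_len + 6L,
            backbone_len + 6L + stuffer_len - 12L, nchar(seq)),
    strand = "+")
  list(seq = circ, features = features)
}

#' Clone an annealed oligo duplex into a vector
#'
#' Convenience pipeline for the miR-AB protocol: double-digests the vector
#' with BamHI and ApaI, discards the stuffer, ligates the backbone with the
#' annealed duplex and returns the unique circular construct.
#'
#' @param vector_seq Circular vector (from [make_mock_vector()] or a FASTA
#'   record).
#' @param pair An `oligo_pair` (or list with `top`/`bottom`).
#' @return A circular construct fragment.
#' @export
clone_oligos <- function(vector_seq, pair) {
  if (is.list(vector_seq) && !is.null(vector_seq$seq))
    vector_seq <- vector_seq$seq
  frags <- digest(vector_seq, c("BamHI", "ApaI"))
  insert <- anneal(pair)
  # the backbone is the fragment that does not carry the stuffer layout of
  # the insert (5' GATC left + 3' GGCC right); identify it by end geometry
  is_stufferlike <- vapply(frags, function(f) {
    e <- fragment_ends(f)
    e$left$polarity == "five_prime" && e$left$overhang == "GATC" &&
      e$right$polarity == "three_prime" && e$right$overhang == "GGCC"
  }, logical(1))
  backbone <- frags[!is_stufferlike]
  if (length(backbone) != 1L)
    abort("vector did not digest into a unique backbone with BamHI/ApaI ends")
  products <- ligate(c(backbone, list(insert)))
  # single-insert product: the one containing the insert core
  with_insert <- purrr::keep(products, function(p)
    grepl(substr(insert$seq, 5, 71), paste0(p$seq, p$seq), fixed = TRUE))
  if (!length(with_insert))
    abort("ligation produced no construct carrying the insert")
  with_insert[[1]]
}
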