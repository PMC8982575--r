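# Reporter -> (laser, band-pass filter) detection map of a five-laser cell
# sorter, plus the commonly used antibody fluorophores with matching
# spectral characteristics (mapped to the same channels). Azurite is
# detectable on either the UV or the violet laser; mOrange on either the
# blue or the yellow/green laser; every other reporter has a single usable
# channel.
channel_table_data <- function() {
  tibble::tribble(
    ~label,       ~kind,       ~laser_nm, ~filter,
    "Azurite",    "reporter",  355L,      "450/40",
    "Azurite",    "reporter",  405L,      "450/40",
    "mTagBFP2",   "reporter",  405L,      "450/40",
    "Ametrine",   "reporter",  405L,      "510/50",
    "EGFP",       "reporter",  488L,      "530/30",
    "Venus",      "reporter",  488L,      "530/30",
    "mOrange",    "reporter",  488L,      "582/15",
    "mOrange",    "reporter",  561L,      "582/15",
    "mCherry2",   "reporter",  561L,      "610/20",
    "E2-Crimson", "reporter",  633L,      "660/20"
  ) -> reporters
  equivalents <- list(
    "450/40-355" = c("Indo-1 hi", "Alexa Fluor 350", "Marina Blue"),
    "450/40-405" = c("Brilliant Violet 421", "Pacific Blue",
                     "Alexa Fluor 405", "Sytox Blue"),
    "510/50-405" = c("Brilliant Violet 510", "AmCyan", "Krome Orange"),
    "530/30-488" = c("FITC", "Alexa Fluor 488", "CFSE", "Sytox Green",
                     "Dylight 488"),
    "582/15-488" = c("PE", "PI", "Alexa Fluor 555", "Dylight 549"),
    "582/15-561" = c("PE", "PI", "Alexa Fluor 555", "Dylight 549"),
    "610/20-561" = c("PE/Texas Red", "Alexa Fluor 594", "PE-CF594",
                     "Dylight 594"),
    "660/20-633" = c("APC", "Alexa Fluor 647", "Cy5", "Sytox Red",
                     "Dylight 649"))
  ab <- purrr::imap_dfr(equivalents, function(fluors, key) {
    parts <- strsplit(key, "-", fixed = TRUE)[[1]]
    tibble::tibble(label = fluors, kind = "antibody_fluorophore",
                   laser_nm = as.integer(parts[2]), filter = parts[1])
  })
  dplyr::bind_rows(reporters, ab)
}

#' Fluorescent label / detection channel table
#'
#' The bundled map from each of the toolkit's eight fluorescent reporter
#' proteins (and the commonly used antibody fluorophores with similar
#' spectra) to the instrument channels — (laser wavelength, band-pass
#' filter) pairs — on which they are detected.
#'
#' @param kind Optionally restrict to `"reporter"` or
#'   `"antibody_fluorophore"`.
#' @return A tibble with `label`, `kind`, `laser_nm`, `filter` and a
#'   `channel` id (`"laser/filter"`); one row per usable channel.
#' @examples
#' dplyr::filter(load_channel_table(), label == "Azurite")
#' @export
load_channel_table <- function(kind = NULL) {
  tab <- dplyr::mutate(channel_table_data(),
                       channel = paste0(.data$laser_nm, "nm:", .data$filter))
  if (!is.null(kind)) tab <- tab[tab$kind %in% kind, ]
  tab
}

#' Instrument presets
#'
#' Two bundled flow-cytometer configurations: `"4laser"` with 405/488/561/
#' 633 nm excitation (the standard sorter configuration used for the
#' six-reporter panel) and `"5laser"` adding the 355 nm UV laser. A custom
#' instrument is a plain integer vector of laser wavelengths.
#'
#' @param preset `"4laser"` or `"5laser"`, or an integer vector of laser
#'   wavelengths in nm.
#' @return A list of class `mirab_instrument` with `name`, `lasers` and
#'   `channels` (the channel-table channels available on those lasers).
#' @export
instrument <- function(preset = "4laser") {
  lasers <- if (is.numeric(preset)) {
    as.integer(preset)
  } else {
    switch(preset,
           "4laser" = c(405L, 488L, 561L, 633L),
           "5laser" = c(355L, 405L, 488L, 561L, 633L),
           abort(sprintf("unknown instrument preset '%s'", preset)))
  }
  tab <- load_channel_table()
  channels <- sort(unique(tab$channel[tab$laser_nm %in% lasers]))
  structure(list(name = if (is.numeric(preset)) "custom" else preset,
                 lasers = lasers, channels = channels),
            class = "mirab_instrument")
}

#' @export
print.mirab_instrument <- function(x, ...) {
  cat(sprintf("<mirab_instrument> %s: lasers %s nm, %d channels\n", x$name,
              paste(x$lasers, collapse = "/"), length(x$channels)))
  invisible(x)
}

# usable instrument channels per label
label_channels <- function(labels, inst, table = load_channel_table()) {
  aliases <- c(GFP = "EGFP")   # common shorthand
  canon <- ifelse(labels %in% names(aliases), aliases[labels], labels)
  unknown <- setdiff(canon, table$label)
  if (length(unknown))
    abort(paste("unknown label(s):", paste(unknown, collapse = ", ")))
  setNames(lapply(canon, function(l) {
    intersect(unique(table$channel[table$label == l]), inst$channels)
  }), labels)
}

#' Assign fluorescent labels to distinct detection channels
#'
#' Decides whether a set of labels is pairwise distinguishable on an
#' instrument under the channel-exclusivity model: two labels conflict iff
#' they are forced onto the same (laser, filter) channel. The decision is a
#' maximum bipartite matching between labels and the instrument's channels
#' restricted to each label's usable channels; the panel is feasible iff
#' every label is matched. When infeasible, a minimal Hall-violator witness
#' is reported: a smallest label subset whose joint usable channels number
#' fewer than the subset.
#'
#' @param labels Character vector of label names (reporters and/or antibody
#'   fluorophores; `"GFP"` is accepted for `"EGFP"`).
#' @param instrument An [instrument()] or preset name.
#' @return A list of class `channel_assignment`: `feasible`, `assignment`
#'   (tibble `label` -> `channel`, NA for unmatched labels) and
#'   `conflict_set` (character, empty when feasible).
#' @examples
#' feasible_assignment(c("Azurite", "GFP", "Ametrine", "mOrange",
#'                       "mCherry2", "E2-Crimson"), instrument("4laser"))
#' @export
feasible_assignment <- function(labels, instrument = mirab::instrument()) {
  if (!length(labels)) abort("labels must be non-empty")
  if (anyDuplicated(labels)) abort("duplicate labels in panel")
  if (is.character(instrument)) instrument <- mirab::instrument(instrument)
  usable <- label_channels(labels, instrument)
  channels <- sort(unique(unlist(usable)))
  match_to <- rep(NA_character_, length(labels))
  names(match_to) <- labels
  if (length(channels)) {
    edges <- purrr::imap_dfr(usable, function(ch, lab) {
      if (!length(ch)) return(tibble::tibble())
      tibble::tibble(label = lab, channel = ch)
    })
    if (nrow(edges)) {
      verts <- c(labels, channels)
      g <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = verts,
                              type = c(rep(FALSE, length(labels)),
                                       rep(TRUE, length(channels)))))
      m <- igraph::max_bipartite_match(g)$matching
      match_to[labels] <- unname(m[labels])
    }
  }
  feasible <- !any(is.na(match_to))
  conflict <- character()
  if (!feasible) {
    # smallest label subset S with |union of usable channels of S| < |S|
    for (size in seq_along(labels)) {
      combos <- utils::combn(labels, size, simplify = FALSE)
      viol <- purrr::detect(combos, function(set) {
        length(unique(unlist(usable[set]))) < length(set)
      })
      if (!is.null(viol)) { conflict <- viol; break }
    }
  }
  structure(list(
    feasible = feasible,
    assignment = tibble::tibble(label = labels,
                                channel = unname(match_to[labels])),
    conflict_set = conflict), class = "channel_assignment")
}

#' @export
print.channel_assignment <- function(x, ...) {
  cat("<channel_assignment>",
      if (x$feasible) "feasible" else
        paste0("INFEASIBLE; conflict {",
               paste(x$conflict_set, collapse = ", "), "}"), "\n")
  print(x$assignment)
  invisible(x)
}

#' @exportS3Method
tidy.channel_assignment <- function(x, ...) x$assignment

#' @exportS3Method
glance.channel_assignment <- function(x, ...) {
  tibble::tibble(feasible = x$feasible,
                 n_labels = nrow(x$assignment),
                 n_assigned = sum(!is.na(x$assignment$channel)),
                 conflict = paste(x$conflict_set, collapse = "+"))
}

#' Enumerate barcode populations
#'
#' All 2^n presence/absence combinations of n fluorescent reporters, in
#' canonical order: "none" first, then by number of positive reporters and
#' reporter order, the all-positive population last. Positive reporters are
#' joined with "+" (e.g. `"Azurite+GFP+"`).
#'
#' @param reporters Character vector of 1-8 distinct reporter names.
#' @return Character vector of 2^n population labels.
#' @examples
#' enumerate_populations(c("Azurite", "GFP"))
#' @export
enumerate_populations <- function(reporters) {
  n <- length(reporters)
  if (n < 1L || n > 8L) abort("between 1 and 8 reporters required")
  if (anyDuplicated(reporters)) abort("duplicate reporter names")
  subsets <- unlist(lapply(0:n, function(k) {
    utils::combn(seq_len(n), k, simplify = FALSE)
  }), recursive = FALSE)
  vapply(subsets, function(idx) population_label(reporters, idx),
         character(1))
}

population_label <- function(reporters, idx) {
  if (!length(idx)) "none"
  else paste0(paste(reporters[idx], collapse = "+"), "+")
}

#' Panel assignment plot
#'
#' Tile plot of labels against instrument channels, marking usable channels
#' and the assigned channel per label.
#'
#' @param object A `channel_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.channel_assignment <- function(object, ...) {
  tab <- load_channel_table()
  usable <- dplyr::semi_join(tab,
    tibble::tibble(label = sub("^GFP$", "EGFP", object$assignment$label)),
    by = "label")
  usable$assigned <- paste0(usable$label, usable$channel) %in%
    paste0(sub("^GFP$", "EGFP", object$assignment$label),
           object$assignment$channel)
  ggplot2::ggplot(usable,
                  ggplot2::aes(x = .data$channel, y = .data$label,
                               fill = .data$assigned)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey85"),
                               name = "assigned") +
    ggplot2::labs(x = "detection channel (laser:filter)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
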