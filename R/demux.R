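#' Simulation configuration for multicolor barcode experiments
#'
#' Default conditions emulate the four-reporter cotransduction readout:
#' four retroviruses at equal ratio, each infecting ~30% of cells
#' independently, reporter intensities log-normal with well-separated
#' negative/positive states, and one surface-stain channel per target gene
#' whose level drops by the knockdown fraction in cells carrying the linked
#' reporter.
#'
#' @param n_cells Number of cells (events).
#' @param reporters Tibble with columns `name`, `p` (transduction
#'   probability), `neg_mean`, `neg_sd`, `pos_mean`, `pos_sd` (log10
#'   intensity).
#' @param targets Tibble with columns `stain`, `control_mfi` (linear
#'   scale), `knockdown` (fraction in [0, 1]) and `reporter` (the linked
#'   reporter name).
#' @param meas_sd Log10 measurement noise of the stain channels.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 50000L,
                       reporters = default_reporters(),
                       targets = default_targets(),
                       meas_sd = 0.1,
                       seed = 1L) {
  stopifnot(all(c("name", "p", "neg_mean", "neg_sd", "pos_mean",
                  "pos_sd") %in% names(reporters)),
            all(c("stain", "control_mfi", "knockdown", "reporter") %in%
                  names(targets)))
  if (any(reporters$p < 0 | reporters$p > 1))
    abort("transduction probabilities must be in [0, 1]")
  if (any(targets$knockdown < 0 | targets$knockdown > 1))
    abort("knockdown fractions must be in [0, 1]")
  if (any(c(reporters$neg_sd, reporters$pos_sd, meas_sd) < 0))
    abort("standard deviations must be non-negative")
  if (any(reporters$pos_mean <= reporters$neg_mean))
    abort("positive log10 mean must exceed negative log10 mean per reporter")
  if (!all(targets$reporter %in% reporters$name))
    abort("every target must link to a simulated reporter")
  structure(list(n_cells = as.integer(n_cells), reporters = reporters,
                 targets = targets, meas_sd = meas_sd,
                 seed = as.integer(seed)), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_reporters <- function() {
  tibble::tibble(
    name = c("Azurite", "GFP", "Ametrine", "mCherry2"),
    p = 0.3, neg_mean = 2.0, neg_sd = 0.15, pos_mean = 3.5, pos_sd = 0.20)
}

#' @rdname sim_config
#' @export
default_targets <- function() {
  tibble::tibble(
    stain = c("CD127", "CD90", "CD44", "CD8a"),
    control_mfi = 1000,
    knockdown = 0.9,
    reporter = c("Azurite", "GFP", "Ametrine", "mCherry2"))
}

#' Simulate per-cell flow-cytometry events
#'
#' For each cell, every reporter is positive independently with its
#' transduction probability and its intensity is drawn from the matching
#' log-normal state. Each stain's intensity is its control level, reduced
#' by the knockdown fraction when the linked reporter is positive, times
#' multiplicative log-normal measurement noise. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return An event tibble, one row per cell: `cell_id`, one intensity
#'   column per reporter, one per stain, and hidden truth columns
#'   `truth_<reporter>` (logical).
#' @export
simulate_events <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  out <- tibble::tibble(cell_id = seq_len(n))
  truth <- list()
  for (i in seq_len(nrow(config$reporters))) {
    r <- config$reporters[i, ]
    pos <- runif(n) < r$p
    log10_int <- rnorm(n, mean = ifelse(pos, r$pos_mean, r$neg_mean),
                       sd = ifelse(pos, r$pos_sd, r$neg_sd))
    out[[r$name]] <- 10^log10_int
    truth[[r$name]] <- pos
  }
  for (i in seq_len(nrow(config$targets))) {
    t <- config$targets[i, ]
    level <- t$control_mfi * ifelse(truth[[t$reporter]], 1 - t$knockdown, 1)
    # a fully silenced target still leaves background staining, never zero
    level <- pmax(level, 1e-3 * t$control_mfi)
    out[[t$stain]] <- level * 10^rnorm(n, 0, config$meas_sd)
  }
  for (nm in names(truth)) out[[paste0("truth_", nm)]] <- truth[[nm]]
  out
}

#' Gate events on control-derived thresholds and label populations
#'
#' The paper's gates are drawn by hand; the reproducible surrogate here
#' thresholds each reporter channel at a high quantile of an untransduced
#' control sample, then assigns each event to one of the 2^n barcode
#' populations named by [enumerate_populations()].
#'
#' @param events Event tibble from [simulate_events()] (or any tibble with
#'   one intensity column per reporter).
#' @param control_events Event tibble of untransduced cells only (same
#'   reporter columns).
#' @param reporters Character vector of reporter column names; defaults to
#'   the reporters found in `control_events`.
#' @param quantile Control quantile used as gate (default 0.999).
#' @return `events` with added logical `gate_<reporter>` columns and a
#'   `population` column.
#' @export
gate_events <- function(events, control_events, reporters = NULL,
                        quantile = 0.999) {
  if (!nrow(control_events)) abort("control event table is empty")
  if (is.null(reporters)) {
    reporters <- intersect(names(control_events),
                           setdiff(names(events), "cell_id"))
    reporters <- reporters[!grepl("^(gate_|truth_)", reporters)]
    reporters <- reporters[vapply(control_events[reporters], is.numeric,
                                  logical(1))]
  }
  if (!length(reporters)) abort("no reporter channels to gate on")
  thresholds <- vapply(reporters, function(r) {
    stats::quantile(control_events[[r]], quantile, names = FALSE)
  }, numeric(1))
  gates <- tibble::as_tibble(setNames(
    lapply(reporters, function(r) events[[r]] > thresholds[[r]]),
    paste0("gate_", reporters)))
  gate_mat <- as.matrix(gates)
  # bit-code each gate vector and look the label up once per pattern
  codes <- as.integer(gate_mat %*% 2^(seq_along(reporters) - 1L))
  lookup <- vapply(0:(2^length(reporters) - 1L), function(code) {
    population_label(reporters,
                     which(bitwAnd(code, 2^(seq_along(reporters) - 1L)) > 0))
  }, character(1))
  labels <- lookup[codes + 1L]
  dplyr::bind_cols(events, gates) |>
    dplyr::mutate(population = factor(
      labels, levels = enumerate_populations(reporters)))
}

#' Per-population MFI and knockdown quantification
#'
#' Computes each population's mean fluorescence intensity (MFI) on each
#' stain channel and the knockdown percentage relative to a matched control
#' population: `100 * (1 - MFI_pop / MFI_control)`. MFI is the geometric
#' mean by default (intensities are log-normal); the arithmetic mean is
#' available. Populations below `min_events` are flagged, not dropped.
#'
#' @param events Gated event tibble from [gate_events()].
#' @param control_map Named character vector mapping each stain column to
#'   its control population label (usually `"none"`).
#' @param stat `"geometric"` (default) or `"arithmetic"` MFI.
#' @param min_events Minimum events for a reliable estimate (default 100).
#' @return A `knockdown_table` tibble: `population`, `stain`, `n_events`,
#'   `mfi`, `control_mfi`, `knockdown_percent`, `flagged`.
#' @export
quantify_knockdown <- function(events, control_map,
                               stat = c("geometric", "arithmetic"),
                               min_events = 100L) {
  stat <- match.arg(stat)
  if (!"population" %in% names(events))
    abort("events must be gated first (no population column)")
  if (is.null(names(control_map)) && length(control_map) == 1L)
    control_map <- setNames(
      rep(control_map, length(stain_columns(events))),
      stain_columns(events))
  mfi_fun <- if (stat == "geometric") function(x) exp(mean(log(x)))
             else mean
  stains <- names(control_map)
  missing <- setdiff(stains, names(events))
  if (length(missing))
    abort(paste("stain column(s) not in events:",
                paste(missing, collapse = ", ")))
  out <- purrr::map_dfr(stains, function(st) {
    ctrl_pop <- control_map[[st]]
    ctrl <- events[[st]][events$population == ctrl_pop]
    if (!length(ctrl))
      abort(sprintf("control population '%s' for stain %s is empty",
                    ctrl_pop, st))
    ctrl_mfi <- mfi_fun(ctrl)
    events |>
      dplyr::group_by(.data$population, .drop = FALSE) |>
      dplyr::summarise(n_events = dplyr::n(),
                       mfi = if (dplyr::n() > 0) mfi_fun(.data[[st]])
                             else NA_real_,
                       .groups = "drop") |>
      dplyr::mutate(stain = st, control_mfi = ctrl_mfi,
                    knockdown_percent = 100 * (1 - .data$mfi / ctrl_mfi),
                    flagged = .data$n_events < min_events) |>
      dplyr::select("population", "stain", "n_events", "mfi",
                    "control_mfi", "knockdown_percent", "flagged")
  })
  class(out) <- c("knockdown_table", class(out))
  out
}

stain_columns <- function(events) {
  setdiff(names(events)[vapply(events, is.numeric, logical(1))],
          c("cell_id"))
}

#' @exportS3Method
glance.knockdown_table <- function(x, ...) {
  tibble::tibble(n_populations = dplyr::n_distinct(x$population),
                 n_stains = dplyr::n_distinct(x$stain),
                 n_flagged = sum(x$flagged))
}

#' Knockdown summary plot
#'
#' Bar panel of knockdown percentage per population, one facet per stain,
#' flagged (low-event) populations hatched out by transparency.
#'
#' @param object A `knockdown_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.knockdown_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$population,
                               y = .data$knockdown_percent,
                               alpha = !.data$flagged)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::facet_wrap(ggplot2::vars(.data$stain)) +
    ggplot2::labs(x = NULL, y = "knockdown (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Reporter intensity distribution plot
#'
#' Density of log10 intensity per reporter channel, coloured by gate when
#' the events are gated.
#'
#' @param events Event tibble (gated or not).
#' @param reporters Reporter columns to show; defaults to all gate columns
#'   or all numeric channels.
#' @return A ggplot.
#' @export
plot_events <- function(events, reporters = NULL) {
  if (is.null(reporters)) {
    gcols <- grep("^gate_", names(events), value = TRUE)
    reporters <- if (length(gcols)) sub("^gate_", "", gcols)
                 else stain_columns(events)
  }
  long <- tidyr::pivot_longer(events, dplyr::all_of(reporters),
                              names_to = "channel",
                              values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = log10(.data$intensity))) +
    ggplot2::geom_density(fill = "#2c7fb8", alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "log10 intensity", y = "density") +
    ggplot2::theme_minimal()
}
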