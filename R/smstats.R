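#' Select single-pixel events from a corrected cube
#'
#' A pixel becomes an event iff its corrected spectrum attains its maximum
#' at a channel inside the marker band window AND that maximum exceeds the
#' threshold `tau`. By default `tau` is applied on the normalized
#' intensity scale (corrected cube divided by its global maximum), which
#' makes the 0.03 default transferable across acquisitions; set
#' `normalize = FALSE` for an absolute threshold. Thresholding removes
#' noise events so artificial molecular events are not counted.
#'
#' @param cube corrected [hyper_cube()].
#' @param maps list of concentration images (from [unmix_cube()]) aligned
#'   with the cube grid; the first two are taken as the 14NA and 15NA
#'   components.
#' @param tau intensity threshold (default 0.03 on the normalized scale).
#' @param window band window in cm^-1 (default `c(715, 745)`).
#' @param normalize divide by the cube's global maximum before
#'   thresholding (default TRUE).
#' @return An `event_table` data frame with columns `row`, `col`, `C14`,
#'   `C15`, `ratio` (`C14 / (C14 + C15)`), `smax`, `class` (`NA` until
#'   [classify_events()]). Pixels with `C14 + C15 <= 0` are dropped; their
#'   count is in `attr(, "dropped_zero_concentration")`.
#' @export
select_events <- function(cube, maps, tau = 0.03, window = c(715, 745),
                          normalize = TRUE) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (tau <= 0) stop("tau must be > 0")
  idx <- window_channels(cube$axis, window)
  m <- cube_matrix(cube)
  mx <- apply(m, 1L, max)
  amax <- apply(m, 1L, which.max)
  scale <- if (normalize) max(m) else 1
  if (scale <= 0) scale <- 1
  sel <- (amax %in% idx) & (mx / scale > tau)
  d <- dim(cube$data)
  rows <- ((seq_len(d[1] * d[2]) - 1L) %% d[1]) + 1L
  cols <- ((seq_len(d[1] * d[2]) - 1L) %/% d[1]) + 1L
  C14 <- as.numeric(maps[[1]])[sel]
  C15 <- if (length(maps) >= 2L) as.numeric(maps[[2]])[sel] else
    rep(0, sum(sel))
  tot <- C14 + C15
  keep <- tot > 0
  tab <- data.frame(row = rows[sel][keep], col = cols[sel][keep],
                    C14 = C14[keep], C15 = C15[keep],
                    ratio = (C14 / tot)[keep],
                    smax = (mx[sel] / scale)[keep],
                    class = rep(NA_character_, sum(keep)))
  attr(tab, "dropped_zero_concentration") <- sum(!keep)
  attr(tab, "tau") <- tau
  attr(tab, "window") <- window
  class(tab) <- c("event_table", "data.frame")
  tab
}

#' Classify events by their relative 14NA contribution
#'
#' Operationalizes the bianalyte reading of the ratio histogram: ratios at
#' the edges are single-molecule events of one isotopologue, ratios near
#' the middle are mixtures.
#'
#' @param table an `event_table`.
#' @param sm_edges `c(lo, hi)`: `ratio <= lo` is `SM15`, `ratio >= hi` is
#'   `SM14` (default `c(0.1, 0.9)`).
#' @param mix_band `c(lo, hi)`: ratios inside are `MIX` (default
#'   `c(0.3, 0.7)`); everything else is `AMBIG`.
#' @return The table with its `class` column filled.
#' @export
classify_events <- function(table, sm_edges = c(0.1, 0.9),
                            mix_band = c(0.3, 0.7)) {
  stopifnot(inherits(table, "event_table"))
  if (sm_edges[1] >= sm_edges[2] || mix_band[1] >= mix_band[2] ||
      sm_edges[1] > mix_band[1] || mix_band[2] > sm_edges[2])
    stop("inverted classification edges")
  p <- table$ratio
  cl <- rep("AMBIG", length(p))
  cl[p <= sm_edges[1]] <- "SM15"
  cl[p >= sm_edges[2]] <- "SM14"
  cl[p >= mix_band[1] & p <= mix_band[2]] <- "MIX"
  table$class <- cl
  table
}

#' Histogram of the relative 14NA contribution
#'
#' Counts over `[0, 1]` with half-open bins (the last bin closed), so
#' counts always sum to the table size.
#'
#' @param table an `event_table`, or a numeric vector of ratios.
#' @param n_bins number of bins (default 20).
#' @return List of class `ratio_histogram`: `counts`, `breaks`, `mids`.
#' @export
ratio_histogram <- function(table, n_bins = 20L) {
  p <- if (is.numeric(table)) table else table$ratio
  if (length(p) == 0L) stop("empty event table: no histogram to form")
  bin <- pmin(floor(p * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  structure(list(counts = counts, breaks = breaks,
                 mids = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2),
            class = "ratio_histogram")
}

#' @export
print.ratio_histogram <- function(x, ...) {
  cat("<ratio_histogram>", sum(x$counts), "events in", length(x$counts),
      "bins\n")
  invisible(x)
}

#' Probability that an occupied hot spot is spectrally pure
#'
#' Under Poisson(mu) occupancy with each molecule independently 14NA with
#' probability `f`, the probability that all molecules in an occupied hot
#' spot share one species is
#' `(exp(-mu (1 - f)) + exp(-mu f) - 2 exp(-mu)) / (1 - exp(-mu))`,
#' which for `f = 1/2` reduces to
#' `2 (exp(-mu/2) - exp(-mu)) / (1 - exp(-mu))`. This is the analytic
#' expectation behind reading histogram edges as single-molecule events:
#' at low mean occupancy nearly every detected hot spot is pure.
#'
#' @param mu mean occupancy (> 0); vectorized.
#' @param f probability a molecule is 14NA (default 0.5).
#' @return Probability in (0, 1].
#' @export
bianalyte_pure_event_probability <- function(mu, f = 0.5) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  (exp(-mu * (1 - f)) + exp(-mu * f) - 2 * exp(-mu)) / (1 - exp(-mu))
}

#' Monte-Carlo bianalyte histogram
#'
#' Simulates `n_hotspots` hot spots: Poisson(mu) occupancy, species
#' Bernoulli(f), per-molecule weights equal or log-normal, detection if
#' the total hot-spot signal exceeds `detect_threshold` (the simulation
#' analogue of the experimental intensity threshold). Returns the ratio
#' histogram plus pure/mixed fractions.
#'
#' @param mu mean occupancy.
#' @param f probability a molecule is 14NA (default 0.5).
#' @param n_hotspots number of hot spots (default 1e4).
#' @param weights `"equal"` or `"lognormal"` per-molecule weights.
#' @param weight_sdlog log-SD of log-normal weights (default 0.4).
#' @param detect_threshold minimum total signal for detection (default 0,
#'   i.e. any occupied hot spot is detected).
#' @param n_bins histogram bins (default 20).
#' @param seed integer seed.
#' @return List of class `bianalyte_sim`: `histogram`, `ratios`,
#'   `n_detected`, `fraction_pure` (ratio exactly 0 or 1),
#'   `fraction_edge` (ratio <= 0.1 or >= 0.9), `fraction_mixed`
#'   (0.3 <= ratio <= 0.7).
#' @export
simulate_bianalyte_histogram <- function(mu, f = 0.5, n_hotspots = 1e4,
                                         weights = c("equal", "lognormal"),
                                         weight_sdlog = 0.4,
                                         detect_threshold = 0,
                                         n_bins = 20L, seed = 1L) {
  if (mu < 0) stop("mu must be >= 0")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  weights <- match.arg(weights)
  if (n_hotspots < 100) warning("few hot spots; histogram will be coarse")
  with_seed(stage_seed(seed, "bianalyte"), {
    n <- rpois(n_hotspots, mu)
    occupied <- which(n > 0L)
    ratios <- numeric(0)
    if (length(occupied)) {
      tot <- n[occupied]
      n14 <- rbinom(length(occupied), tot, f)
      if (weights == "equal") {
        w14 <- as.numeric(n14)
        wtot <- as.numeric(tot)
      } else {
        w14 <- wtot <- numeric(length(occupied))
        for (i in seq_along(occupied)) {
          w <- rlnorm(tot[i], 0, weight_sdlog)
          wtot[i] <- sum(w)
          w14[i] <- sum(w[seq_len(n14[i])])
        }
      }
      det <- wtot > detect_threshold
      ratios <- (w14 / wtot)[det]
    }
    if (length(ratios) == 0L)
      stop("no detected hot spots; increase n_hotspots or mu")
    structure(list(
      histogram = ratio_histogram(ratios, n_bins = n_bins),
      ratios = ratios,
      n_detected = length(ratios),
      fraction_pure = mean(ratios == 0 | ratios == 1),
      fraction_edge = mean(ratios <= 0.1 | ratios >= 0.9),
      fraction_mixed = mean(ratios >= 0.3 & ratios <= 0.7)),
      class = "bianalyte_sim")
  })
}

#' Local enhancement factor relative to normal SRS
#'
#' Power- and concentration-normalized ratio of the per-molecule local
#' signal to the per-molecule reference signal:
#' `EF = (I_local / N_local) / (I_ref / N_ref) *
#'  (P_pump_ref * P_stokes_ref) / (P_pump_local * P_stokes_local)`.
#'
#' @param I_local,I_ref measured intensities.
#' @param N_local,N_ref molecule numbers contributing to each.
#' @param P_pump_local,P_stokes_local,P_pump_ref,P_stokes_ref laser powers.
#' @return The enhancement factor (dimensionless).
#' @export
enhancement_factor <- function(I_local, N_local, I_ref, N_ref,
                               P_pump_local, P_stokes_local,
                               P_pump_ref, P_stokes_ref) {
  v <- c(I_local, N_local, I_ref, N_ref, P_pump_local, P_stokes_local,
         P_pump_ref, P_stokes_ref)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all intensities, molecule counts and powers must be > 0")
  (I_local / N_local) / (I_ref / N_ref) *
    (P_pump_ref * P_stokes_ref) / (P_pump_local * P_stokes_local)
}
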