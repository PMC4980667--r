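## RT-qPCR and density-gradient profile quantitation.

#' Primer efficiency from a serial-dilution standard curve
#'
#' Least-squares fit of Ct against log10(dilution factor); the amplification
#' efficiency per cycle is `10^(-1/slope)` (a slope of -3.3219 corresponds
#' to perfect doubling, efficiency 2.0). Published assay slopes fall around
#' -3.46 to -4.15 with R^2 ~ 0.99.
#'
#' @param dilution_factors strictly positive dilution factors (>= 3 points)
#' @param cts observed Ct values, one per dilution point
#' @return list: slope, r_squared, efficiency
#' @export
primer_efficiency <- function(dilution_factors, cts) {
  if (length(dilution_factors) < 3L)
    stop("need at least 3 dilution points", call. = FALSE)
  if (any(dilution_factors <= 0))
    stop("dilution factors must be strictly positive", call. = FALSE)
  if (length(dilution_factors) != length(cts))
    stop("dilution_factors and cts must have equal length", call. = FALSE)
  fit <- lm(cts ~ log10(dilution_factors))
  slope <- unname(coef(fit)[2])
  if (is.na(slope) || slope >= 0)
    stop("standard-curve slope must be negative (more template must lower ",
         "Ct)", call. = FALSE)
  ## computed directly; summary.lm warns on exactly collinear input
  sst <- sum((cts - mean(cts))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = slope,
       r_squared = r2,
       efficiency = 10^(-1 / slope))
}

#' Percent-of-input from a qPCR co-IP assay (delta-delta-Ct)
#'
#' Computes `100 * input_fraction * efficiency^(ct_input - ct_ip) /
#' ip_fraction`: the IP signal expressed relative to the total input, where
#' `input_fraction` is the fraction of material assayed as input (5% in the
#' published design) and `ip_fraction` the fraction of the IP eluate assayed
#' (90%). Values above 100% are flagged with a warning but reported as-is.
#'
#' @param ct_input,ct_ip mean Ct of technical triplicates, cycles
#' @param efficiency amplification factor per cycle in (1, 2]
#' @param input_fraction fraction of input material assayed, in (0, 1]
#' @param ip_fraction fraction of the IP material assayed, in (0, 1]
#' @return percent of input (numeric scalar)
#' @export
percent_input <- function(ct_input, ct_ip, efficiency = 2,
                          input_fraction = 0.05, ip_fraction = 0.90) {
  stopifnot(ct_input > 0, ct_ip > 0,
            efficiency > 1, efficiency <= 2,
            input_fraction > 0, input_fraction <= 1,
            ip_fraction > 0, ip_fraction <= 1)
  pct <- 100 * input_fraction * efficiency^(ct_input - ct_ip) / ip_fraction
  if (pct > 100)
    warning("percent of input exceeds 100% (", signif(pct, 4),
            "%); check efficiency and fractions", call. = FALSE)
  pct
}

#' Normalize gradient profiles and locate peak fractions
#'
#' Each profile (intensities over fractions 1..n, typically 22 with the
#' pellet as the last fraction) is normalized to sum 1; the peak is the
#' argmax fraction with ties broken toward the lowest index; pairwise peak
#' shifts are reported as `peak_b - peak_a` in fractions.
#'
#' @param profiles named list (or data.frame columns) of non-negative
#'   intensity vectors of equal length
#' @return list: `normalized` (data.table fraction x profile), `peaks`
#'   (named integer vector), `shifts` (data.table: from, to, shift)
#' @export
profile_stats <- function(profiles) {
  profiles <- as.list(profiles)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be named", call. = FALSE)
  lens <- vapply(profiles, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("profiles must cover the same fractions", call. = FALSE)
  norm <- lapply(profiles, function(x) {
    if (any(x < 0) || all(x == 0))
      stop("intensities must be >= 0 with at least one nonzero value",
           call. = FALSE)
    x / sum(x)
  })
  peaks <- vapply(norm, which.max, integer(1))  # which.max: lowest on ties
  combos <- expand.grid(from = names(profiles), to = names(profiles),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$from != combos$to, ]
  shifts <- data.table(from = combos$from, to = combos$to,
                       shift = peaks[combos$to] - peaks[combos$from])
  normalized <- data.table(fraction = seq_len(lens[1]))
  for (nm in names(norm)) normalized[, (nm) := norm[[nm]]]
  list(normalized = normalized, peaks = peaks, shifts = shifts)
}
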