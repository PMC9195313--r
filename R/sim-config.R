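## Simulation configuration: the study conditions the synthetic data
## emulates. Stimulation timings follow the paradigm (6 categories x 50
## pictures, ISI 2800-3000 ms, 300 ms fixation cross, 1500 ms stimulus);
## effect tables mirror the direction of the reported group differences.

#' Default evoked-deflection table
#'
#' One row per Gaussian-windowed monophasic deflection. Amplitudes are raw
#' (negative = surface-negative peak, plotted upward after the ERP sign
#' flip). `group` is "O", "M" or "both"; `category` is a single category,
#' "faces" (the five non-mosaic categories) or "all". Deflections are
#' common to all contacts of a region, so they behave as far-field
#' potentials: present against the scalp reference, cancelled by bipolar
#' derivation.
#'
#' @return data.frame
#' @export
default_erp_components <- function() {
  rbind(
    data.frame(region = "fusiform", group = "both", category = "all",
               center_ms = 110, width_ms = 50, amplitude_uV = -6),
    data.frame(region = "fusiform", group = "both", category = "faces",
               center_ms = 240, width_ms = 60, amplitude_uV = -12),
    data.frame(region = "fusiform", group = "both", category = "mosaic",
               center_ms = 240, width_ms = 60, amplitude_uV = -4),
    data.frame(region = "fusiform", group = "O", category = "faces",
               center_ms = 360, width_ms = 60, amplitude_uV = -8),
    data.frame(region = "fusiform", group = "M", category = "faces",
               center_ms = 360, width_ms = 60, amplitude_uV = -4),
    data.frame(region = "amygdala", group = "both", category = "faces",
               center_ms = 240, width_ms = 60, amplitude_uV = -8),
    data.frame(region = "amygdala", group = "both", category = "mosaic",
               center_ms = 240, width_ms = 60, amplitude_uV = -3),
    data.frame(region = "amygdala", group = "O", category = "faces",
               center_ms = 360, width_ms = 60, amplitude_uV = -6),
    data.frame(region = "amygdala", group = "M", category = "faces",
               center_ms = 360, width_ms = 60, amplitude_uV = -2),
    data.frame(region = "hippocampus", group = "both", category = "all",
               center_ms = 240, width_ms = 60, amplitude_uV = -4),
    data.frame(region = "parahippocampal", group = "both", category = "faces",
               center_ms = 360, width_ms = 60, amplitude_uV = -7),
    data.frame(region = "parahippocampal", group = "both", category = "mosaic",
               center_ms = 360, width_ms = 60, amplitude_uV = -3)
  )
}

#' Default induced-gamma table
#'
#' Band-limited bursts with random per-trial carrier phase. `db_increase`
#' is the mean decibel elevation over the stated window and band relative
#' to the channel's own background power in that band. Directions mirror
#' the reported group contrasts: face-selective gamma in amygdala and
#' fusiform gyrus of Group O only; famous-face gamma in the hippocampus of
#' both groups (late window); non-selective gamma in the parahippocampal
#' gyrus.
#'
#' @return data.frame
#' @export
default_gamma_effects <- function() {
  rbind(
    data.frame(region = "amygdala", group = "O", category = "faces",
               f_lo = 45, f_hi = 150, win_lo_ms = 0, win_hi_ms = 750,
               db_increase = 3),
    data.frame(region = "amygdala", group = "M", category = "faces",
               f_lo = 45, f_hi = 150, win_lo_ms = 0, win_hi_ms = 750,
               db_increase = 0.5),
    data.frame(region = "fusiform", group = "O", category = "faces",
               f_lo = 45, f_hi = 150, win_lo_ms = 0, win_hi_ms = 750,
               db_increase = 3),
    data.frame(region = "fusiform", group = "M", category = "faces",
               f_lo = 45, f_hi = 150, win_lo_ms = 0, win_hi_ms = 750,
               db_increase = 1),
    data.frame(region = "hippocampus", group = "both", category = "famous",
               f_lo = 45, f_hi = 150, win_lo_ms = 250, win_hi_ms = 1000,
               db_increase = 2),
    data.frame(region = "parahippocampal", group = "both", category = "all",
               f_lo = 45, f_hi = 150, win_lo_ms = 0, win_hi_ms = 750,
               db_increase = 2)
  )
}

#' Default cross-regional coupling table
#'
#' Lagged phase-to-amplitude modulation between region pairs, applied to
#' face trials only: low-frequency phase in the fusiform gyrus modulates
#' amygdala gamma amplitude, and parahippocampal phase modulates
#' hippocampal gamma amplitude.
#'
#' @return data.frame
#' @export
default_coupling_specs <- function() {
  rbind(
    data.frame(phase_region = "fusiform", amp_region = "amygdala",
               phase_freq_hz = 6, amp_lo = 60, amp_hi = 90,
               modulation_depth = 0.8, lag_ms = 15, categories = "faces"),
    data.frame(phase_region = "parahippocampal", amp_region = "hippocampus",
               phase_freq_hz = 10, amp_lo = 90, amp_hi = 140,
               modulation_depth = 0.8, lag_ms = 15, categories = "faces")
  )
}

#' Simulation configuration
#'
#' Bundles every free parameter of the synthetic two-group iEEG study.
#' Defaults encode the stimulation paradigm (six categories of 50 pictures,
#' interstimulus interval uniform in 2800-3000 ms, 300 ms fixation, 1500 ms
#' stimulus) and illustrative effect sizes.
#'
#' @param n_patients_per_group patients per group (O = no mesial temporal
#'   seizure onset zone, M = mesial temporal seizure onset zone)
#' @param regions depth-electrode target regions per patient
#' @param n_contacts contacts per region (>= 2 enables bipolar derivation)
#' @param fs sampling rate, 1024 or 2048 Hz
#' @param n_per_category stimuli per category
#' @param isi_range_ms interstimulus interval range (ms)
#' @param fixation_ms fixation-cross duration (ms)
#' @param stim_ms stimulus duration (ms)
#' @param noise list(one_over_f_exponent, scale): background 1/f^alpha
#'   exponent and standard deviation in uV
#' @param erp_components evoked-deflection table, see
#'   [default_erp_components()]
#' @param gamma_effects induced-gamma table, see [default_gamma_effects()]
#' @param coupling_specs coupling table, see [default_coupling_specs()]
#' @param seed master RNG seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_patients_per_group = 3,
                       regions = REGIONS,
                       n_contacts = 2,
                       fs = 1024,
                       n_per_category = 50,
                       isi_range_ms = c(2800, 3000),
                       fixation_ms = 300,
                       stim_ms = 1500,
                       noise = list(one_over_f_exponent = 1.5, scale = 20),
                       erp_components = default_erp_components(),
                       gamma_effects = default_gamma_effects(),
                       coupling_specs = default_coupling_specs(),
                       seed = 1L) {
  if (n_patients_per_group < 1 || n_per_category < 1 || n_contacts < 1)
    stop("configuration error: counts must be positive")
  if (!fs %in% c(1024, 2048))
    stop("configuration error: fs must be 1024 or 2048")
  if (length(isi_range_ms) != 2 || isi_range_ms[1] > isi_range_ms[2])
    stop("configuration error: invalid isi_range_ms")
  if (!all(regions %in% REGIONS))
    stop("configuration error: unknown region label: ",
         paste(setdiff(regions, REGIONS), collapse = ", "))
  if (!all(is.finite(erp_components$amplitude_uV)))
    stop("configuration error: non-finite ERP amplitude")
  if (nrow(coupling_specs)) {
    if (any(coupling_specs$modulation_depth < 0 |
            coupling_specs$modulation_depth > 1))
      stop("configuration error: modulation_depth must lie in [0, 1]")
    if (any(coupling_specs$phase_freq_hz < 3 | coupling_specs$phase_freq_hz > 20))
      stop("configuration error: phase_freq_hz outside [3, 20]")
    if (any(coupling_specs$amp_lo < 45 | coupling_specs$amp_hi > 200))
      stop("configuration error: amp band outside [45, 200]")
    if (any(abs(coupling_specs$lag_ms) >= 750))
      stop("configuration error: |lag_ms| must be below the 750 ms window")
  }
  structure(list(
    n_patients_per_group = as.integer(n_patients_per_group),
    regions = regions, n_contacts = as.integer(n_contacts), fs = fs,
    n_per_category = as.integer(n_per_category),
    isi_range_ms = isi_range_ms, fixation_ms = fixation_ms,
    stim_ms = stim_ms, noise = noise, erp_components = erp_components,
    gamma_effects = gamma_effects, coupling_specs = coupling_specs,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients_per_group, "patients/group,",
      length(x$regions), "regions x", x$n_contacts, "contacts, fs =", x$fs,
      "Hz,", x$n_per_category, "stimuli/category, seed =", x$seed, "\n")
  invisible(x)
}

## Does a trial category fall under an effect-table category selector?
category_matches <- function(selector, category) {
  if (selector == "all") return(rep(TRUE, length(category)))
  if (selector == "faces") return(category %in% FACE_CATEGORIES)
  category == selector
}

group_matches <- function(selector, group) {
  selector == "both" | selector == group
}
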