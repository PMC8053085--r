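# Synthetic-data generators: every pipeline input can be produced with
# known ground truth, so each stage is testable without instrument data.
# All generators are deterministic functions of (spec, seed); intensity
# noise is multiplicative lognormal (peak heights are positive) with
# unit mean, binding/heat noise is additive Gaussian.

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# deterministic pseudo-random base peak position for a residue
base_position <- function(residue_id) {
  c(shift_n = 106 + (residue_id * 7) %% 28 + (residue_id %% 3) * 0.37,
    shift_h = 6.8 + ((residue_id * 13) %% 33) / 10)
}

#' Specification for a synthetic real-time phosphorylation series
#'
#' States the world the kinetics generator emulates: a handful of
#' well-shifted reporter residues, each showing three peak positions
#' (non-, mono-, di-phosphorylated species) whose intensities follow
#' pseudo-first-order consecutive kinetics, HSQC spectra every 30 min,
#' multiplicative intensity noise, a detection floor that makes
#' near-baseline species peaks drop out, and optionally unobservable
#' (exchange-broadened) residues. Default rates k1 = 10, k2 = 1.4 per
#' hour place the mono-species maximum at 0.73 around 0.23 h and the
#' di-species fraction above 0.9 by 2 h, the qualitative behaviour of
#' the monitored reaction.
#'
#' @param residues reporter residue ids (default Ala12, Gly27, Trp84).
#' @param atom_groups `"bb"`/`"sc"` per reporter (Trp84 is the indole
#'   side chain).
#' @param k1,k2 true rates (per hour).
#' @param time_hours acquisition times (default every 30 min over 4 h).
#' @param offset_b,offset_c (shift_n, shift_h) ppm displacement of the
#'   mono- and di-phosphorylated peaks from the unmodified position;
#'   must exceed the matching tolerances.
#' @param total_intensity per-residue total peak intensity.
#' @param noise_cv multiplicative intensity coefficient of variation.
#' @param detection_floor species fraction below which a peak is lost
#'   near baseline (default 0.02).
#' @param unobservable_residues residues omitted from every list.
#' @param seed RNG seed.
#' @return list of class `kinetics_sim_spec`.
#' @export
kinetics_sim_spec <- function(residues = c(12L, 27L, 84L),
                              atom_groups = c("bb", "bb", "sc"),
                              k1 = 10, k2 = 1.4,
                              time_hours = seq(0, 4, by = 0.5),
                              offset_b = c(1.5, 0.15),
                              offset_c = c(3.0, 0.30),
                              total_intensity = 1e6,
                              noise_cv = 0.02,
                              detection_floor = 0.02,
                              unobservable_residues = integer(),
                              seed = 1L) {
  stopifnot(length(residues) == length(atom_groups), k1 >= 0, k2 >= 0,
            noise_cv >= 0, detection_floor >= 0)
  structure(list(residues = residues, atom_groups = atom_groups,
                 k1 = k1, k2 = k2, time_hours = time_hours,
                 offset_b = offset_b, offset_c = offset_c,
                 total_intensity = total_intensity, noise_cv = noise_cv,
                 detection_floor = detection_floor,
                 unobservable_residues = unobservable_residues,
                 seed = seed),
            class = "kinetics_sim_spec")
}

#' Generate a synthetic real-time HSQC series
#'
#' Per residue and time point, the species intensities are
#' `total_intensity * f_species * lognormal noise`, with species peaks
#' whose true fraction is below the detection floor omitted (so species
#' appear and disappear over the reaction, as in real spectra). Peaks
#' are emitted unassigned (positions identify them), since a single
#' residue would otherwise carry three backbone assignments in one
#' list. Unobservable residues are absent from every list.
#'
#' @param spec a [kinetics_sim_spec()].
#' @return list with `series` ([spectrum_series()]), `triplets`
#'   ([species_triplets()]), `truth` (noise-free `fraction_series`) and
#'   the `spec`.
#' @export
generate_kinetics_series <- function(spec = kinetics_sim_spec()) {
  stopifnot(inherits(spec, "kinetics_sim_spec"))
  keep <- !(spec$residues %in% spec$unobservable_residues)
  res <- spec$residues[keep]
  ags <- spec$atom_groups[keep]
  tri <- do.call(rbind, lapply(seq_along(res), function(i) {
    p <- base_position(res[i])
    data.frame(residue_id = res[i], atom_group = ags[i],
               species = c("A", "B", "C"),
               shift_n = p["shift_n"] + c(0, spec$offset_b[1], spec$offset_c[1]),
               shift_h = p["shift_h"] + c(0, spec$offset_b[2], spec$offset_c[2]),
               stringsAsFactors = FALSE)
  }))
  triplets <- species_triplets(tri)
  truth <- model_consecutive(spec$time_hours, spec$k1, spec$k2)
  pls <- with_seed(spec$seed, {
    lapply(seq_along(spec$time_hours), function(it) {
      rows <- list()
      for (i in seq_along(res)) {
        fr <- c(truth$f_a[it], truth$f_b[it], truth$f_c[it])
        noise <- lognormal_noise(3, spec$noise_cv)
        for (s in 1:3) {
          if (fr[s] < spec$detection_floor) next
          trow <- triplets[triplets$residue_id == res[i], ][s, ]
          rows[[length(rows) + 1]] <- data.frame(
            residue_id = NA_integer_, atom_group = "bb",
            assignment = "?-?",
            shift_n = trow$shift_n, shift_h = trow$shift_h,
            intensity = spec$total_intensity * fr[s] * noise[s],
            stringsAsFactors = FALSE)
        }
      }
      peaks <- if (length(rows)) do.call(rbind, rows) else
        data.frame(residue_id = integer(), atom_group = character(),
                   assignment = character(), shift_n = numeric(),
                   shift_h = numeric(), intensity = numeric())
      peak_list(peaks, label = sprintf("t=%gh", spec$time_hours[it]))
    })
  })
  list(series = spectrum_series(spec$time_hours, pls),
       triplets = triplets,
       truth = fraction_series(truth$time_hours, truth$f_a, truth$f_b,
                               truth$f_c, n_residues_used = length(res)),
       spec = spec)
}

#' Specification for synthetic 15N relaxation tables
#'
#' Defaults mirror the published acquisition design: R1 decays over
#' 10-1500 ms in triplicate, R2 decays over 18.5-185 ms in
#' quadruplicate, nOe saturated/reference pairs in triplicate. Default
#' true values (R1 1.3 1/s, R2 16 1/s, nOe 0.80) are typical of a
#' rigid ~20 kDa dimer at 700 MHz.
#'
#' @param residues residue ids.
#' @param r1,r2,noe true per-residue values (recycled).
#' @param r1_delays,r2_delays delay grids in seconds.
#' @param r1_replicates,r2_replicates,noe_replicates replicate counts.
#' @param noise_cv multiplicative intensity CV (default 0.03).
#' @param i0 true intensity at zero delay.
#' @param unobservable_residues residues emitted with no rows.
#' @param seed RNG seed.
#' @return list of class `relax_sim_spec`.
#' @export
relax_sim_spec <- function(residues = 1:50,
                           r1 = 1.3, r2 = 16, noe = 0.80,
                           r1_delays = c(0.010, 0.050, 0.100, 0.200, 0.350,
                                         0.500, 0.700, 0.900, 1.200, 1.500),
                           r2_delays = seq(0.0185, 0.185, length.out = 11),
                           r1_replicates = 3L, r2_replicates = 4L,
                           noe_replicates = 3L,
                           noise_cv = 0.03, i0 = 1e6,
                           unobservable_residues = integer(),
                           seed = 1L) {
  n <- length(residues)
  spec <- list(residues = residues,
               r1 = rep_len(r1, n), r2 = rep_len(r2, n), noe = rep_len(noe, n),
               r1_delays = r1_delays, r2_delays = r2_delays,
               r1_replicates = r1_replicates, r2_replicates = r2_replicates,
               noe_replicates = noe_replicates,
               noise_cv = noise_cv, i0 = i0,
               unobservable_residues = unobservable_residues, seed = seed)
  if (any(spec$r1 <= 0) || any(spec$r2 <= 0)) stopf("rates must be positive")
  structure(spec, class = "relax_sim_spec")
}

#' Generate synthetic relaxation decay and nOe tables
#'
#' Decays are `I0 * exp(-R * tau)` times lognormal noise per replicate;
#' nOe rows are generated as (noe * I0, I0) pairs times noise.
#' Unobservable residues are emitted with no rows. Output is the long
#' table consumed by [fit_relaxation()].
#'
#' @param spec a [relax_sim_spec()].
#' @return list with `table` (data.frame) and `spec`.
#' @export
generate_relaxation <- function(spec = relax_sim_spec()) {
  stopifnot(inherits(spec, "relax_sim_spec"))
  tbl <- with_seed(spec$seed, {
    rows <- list()
    for (i in seq_along(spec$residues)) {
      rid <- spec$residues[i]
      if (rid %in% spec$unobservable_residues) next
      for (rep_i in seq_len(spec$r1_replicates)) {
        ideal <- spec$i0 * exp(-spec$r1[i] * spec$r1_delays)
        rows[[length(rows) + 1]] <- data.frame(
          residue = rid, experiment = "R1", delay_s = spec$r1_delays,
          sat = NA, replicate = rep_i,
          intensity = ideal * lognormal_noise(length(ideal), spec$noise_cv))
      }
      for (rep_i in seq_len(spec$r2_replicates)) {
        ideal <- spec$i0 * exp(-spec$r2[i] * spec$r2_delays)
        rows[[length(rows) + 1]] <- data.frame(
          residue = rid, experiment = "R2", delay_s = spec$r2_delays,
          sat = NA, replicate = rep_i,
          intensity = ideal * lognormal_noise(length(ideal), spec$noise_cv))
      }
      for (rep_i in seq_len(spec$noe_replicates)) {
        nz <- lognormal_noise(2, spec$noise_cv)
        rows[[length(rows) + 1]] <- data.frame(
          residue = rid, experiment = "noe", delay_s = NA_real_,
          sat = c(TRUE, FALSE), replicate = rep_i,
          intensity = c(spec$noe[i] * spec$i0 * nz[1], spec$i0 * nz[2]))
      }
    }
    do.call(rbind, rows)
  })
  list(table = tbl, spec = spec)
}

#' Specification for synthetic binding data
#'
#' `type = "titration"` emulates the surface fluorescence assay (a
#' two-fold dilution series from 1.6 to 200 nM by default, 10 C);
#' `type = "itc"` emulates a calorimetric titration (20 uM cell, 100 uM
#' syringe, 25 x 10 uL injections into a 1.4 mL cell, 15 C). Noise is
#' additive Gaussian, `noise_sd` in signal units or microcalories.
#'
#' @param type `"titration"` or `"itc"`.
#' @param kd true dissociation constant (M); defaults to 2.5e-9 for a
#'   titration (the tight fluorescence regime) and 40e-9 for ITC (a
#'   Wiseman c-value of 100 at the default cell concentration).
#' @param n true stoichiometry (ITC).
#' @param delta_h true binding enthalpy, kcal/mol (ITC).
#' @param offset true dilution-heat offset, ucal per injection (ITC).
#' @param s0,smax true baseline and plateau signal (titration).
#' @param conc_M concentration schedule (titration).
#' @param cell_conc_M,syringe_conc_M,cell_volume_L,injection_volumes_L
#'   ITC schedule.
#' @param temperature_c experiment temperature.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed.
#' @return list of class `binding_sim_spec`.
#' @export
binding_sim_spec <- function(type = c("titration", "itc"),
                             kd = NULL, n = 0.2, delta_h = -10,
                             offset = -0.2,
                             s0 = 100, smax = 600,
                             conc_M = 1.6e-9 * 2^(0:7),
                             cell_conc_M = 20e-6, syringe_conc_M = 100e-6,
                             cell_volume_L = 1.4e-3,
                             injection_volumes_L = rep(10e-6, 25),
                             temperature_c = NULL,
                             noise_sd = 0, seed = 1L) {
  type <- match.arg(type)
  if (is.null(kd)) kd <- if (type == "itc") 40e-9 else 2.5e-9
  if (kd <= 0) stopf("kd must be positive")
  if (is.null(temperature_c)) temperature_c <- if (type == "itc") 15 else 10
  structure(list(type = type, kd = kd, n = n, delta_h = delta_h,
                 offset = offset, s0 = s0, smax = smax, conc_M = conc_M,
                 cell_conc_M = cell_conc_M, syringe_conc_M = syringe_conc_M,
                 cell_volume_L = cell_volume_L,
                 injection_volumes_L = injection_volumes_L,
                 temperature_c = temperature_c,
                 noise_sd = noise_sd, seed = seed),
            class = "binding_sim_spec")
}

#' Generate a synthetic titration curve or ITC experiment
#'
#' Evaluates the corresponding forward model on the schedule and adds
#' Gaussian noise; deterministic under a fixed seed.
#'
#' @param spec a [binding_sim_spec()].
#' @return a [titration_curve()] or [itc_experiment()] with the
#'   generating spec attached as `attr(, "truth")`.
#' @export
generate_binding <- function(spec = binding_sim_spec()) {
  stopifnot(inherits(spec, "binding_sim_spec"))
  out <- with_seed(spec$seed, {
    if (spec$type == "titration") {
      y <- spec$s0 + (spec$smax - spec$s0) * spec$conc_M / (spec$kd + spec$conc_M)
      y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
      titration_curve(spec$conc_M, y, spec$temperature_c)
    } else {
      expt <- itc_experiment(spec$cell_conc_M, spec$syringe_conc_M,
                             spec$cell_volume_L, spec$injection_volumes_L,
                             heats_ucal = rep(0, length(spec$injection_volumes_L)),
                             temperature_c = spec$temperature_c)
      h <- itc_forward_heats(spec$n, spec$kd, spec$delta_h, spec$offset, expt)
      expt$heats_ucal <- h + stats::rnorm(length(h), 0, spec$noise_sd)
      expt
    }
  })
  attr(out, "truth") <- spec
  out
}
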