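#' Tissue conductivities of the volume conductor
#'
#' Default values: anisotropic endoneurium (0.0826 S/m transverse, 0.571
#' S/m longitudinal, fibers running along z), perineurium 880e-6 S/m,
#' epineurium 0.0826 S/m, saline 2 S/m.
#'
#' @param endoneurium Length-3 vector `(sigma_x, sigma_y, sigma_z)`, S/m.
#' @param perineurium,epineurium,saline Scalars, S/m.
#' @param perineurium_attenuation Scalar field attenuation applied once per
#'   perineurium sheet between source and fiber.
#' @return An object of class `tissue_conductivities`.
#' @export
tissue_conductivities <- function(endoneurium = c(0.0826, 0.0826, 0.571),
                                  perineurium = 880e-6,
                                  epineurium = 0.0826,
                                  saline = 2,
                                  perineurium_attenuation = 0.3) {
  stopifnot(length(endoneurium) == 3)
  if (any(c(endoneurium, perineurium, epineurium, saline) <= 0))
    stop("all conductivities must be positive")
  if (endoneurium[3] <= endoneurium[1])
    stop("longitudinal endoneurial conductivity must exceed transverse")
  structure(list(endoneurium = endoneurium, perineurium = perineurium,
                 epineurium = epineurium, saline = saline,
                 perineurium_attenuation = perineurium_attenuation),
            class = "tissue_conductivities")
}

#' Extracellular potential of a point source in an anisotropic medium
#'
#' Analytic potential of a point current source in an unbounded medium with
#' a diagonal conductivity tensor,
#' `V = I / (4 pi sqrt(sy sz dx^2 + sx sz dy^2 + sx sy dz^2))`,
#' attenuated by a scalar factor per perineurium sheet crossed between the
#' source and the field point.  With distances in mm, current in uA and
#' conductivities in S/m the result is in mV.  The potential is linear in
#' the injected current.
#'
#' @param source Length-3 source position, mm.
#' @param current Injected current, uA.
#' @param points Field point(s): length-3 vector or n x 3 matrix, mm.
#' @param cond A [tissue_conductivities()].
#' @param crossings Number of perineurium sheets between source and field
#'   point.
#' @return Potential(s) in mV.
#' @export
extracellular_potential <- function(source, current, points,
                                    cond = tissue_conductivities(),
                                    crossings = 0) {
  stopifnot(length(source) == 3)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  s <- cond$endoneurium
  dx <- points[, 1] - source[1]
  dy <- points[, 2] - source[2]
  dz <- points[, 3] - source[3]
  q <- s[2] * s[3] * dx^2 + s[1] * s[3] * dy^2 + s[1] * s[2] * dz^2
  if (any(q <= 0)) stop("field point coincides with the source")
  cond$perineurium_attenuation^crossings * current / (4 * pi * sqrt(q))
}

#' Electrode model
#'
#' Both devices are reduced to point current sources at the distances of
#' interest (>= 50 um): the needle to its tip apex (optionally a short
#' line of sources along the exposed cone for the larger tip-exposure
#' variant) and the intrafascicular array (TIME) to the centers of its
#' paired mirrored active sites.  Printed geometry is retained as
#' metadata.
#'
#' @param kind `"needle"` or `"TIME"`.
#' @param position Length-3 reference position (needle tip apex / midpoint
#'   between the mirrored sites), mm.
#' @param tip_exposure_um For the needle: length of the de-insulated cone,
#'   um.  50 gives a single point source; larger values spread the source
#'   over three points along the shank axis.
#' @param site_offset_mm For TIME: lateral offset of the left/right active
#'   sites from the reference position, mm.
#' @return An object of class `electrode_model` with a `sources(site)`
#'   field returning an n x 3 matrix of point-source positions, each
#'   carrying an equal share of the injected current.
#' @export
electrode_model <- function(kind = c("needle", "TIME"),
                            position = c(0, 0, 0),
                            tip_exposure_um = 50,
                            site_offset_mm = 0.2) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 3)
  geometry <- if (kind == "needle") {
    list(shank_diameter_um = 250, cone_semi_angle_deg = 12.78,
         tip_exposure_um = tip_exposure_um)
  } else {
    list(site_radius_um = 40, body_length_mm = 4, body_width_mm = 0.35,
         body_thickness_um = 20, site_offset_mm = site_offset_mm)
  }
  sources <- function(site = c("tip", "L", "R")) {
    site <- match.arg(site)
    if (kind == "needle") {
      if (site != "tip") stop("needle has a single 'tip' site")
      if (tip_exposure_um <= 50) {
        matrix(position, ncol = 3)
      } else {
        # spread over the exposed cone along the insertion (x) axis
        off <- c(0, 0.5, 1) * tip_exposure_um / 1000
        cbind(position[1] + off, position[2], position[3])
      }
    } else {
      if (site == "tip") stop("TIME sites are 'L' or 'R'")
      sgn <- if (site == "L") -1 else 1
      matrix(c(position[1], position[2] + sgn * site_offset_mm, position[3]),
             ncol = 3)
    }
  }
  structure(list(kind = kind, position = position, geometry = geometry,
                 sources = sources),
            class = "electrode_model")
}

#' Stimulation pulse
#'
#' Cathodic-first biphasic charge-balanced square pulse.  The charge per
#' phase is `amplitude * width`.
#'
#' @param amplitude Current amplitude, uA.
#' @param width Phase width, us (default 100, the width used with the
#'   implanted interface).
#' @return An object of class `stim_pulse` with `charge_nC`.
#' @export
stim_pulse <- function(amplitude = 160, width = 100) {
  if (amplitude * width <= 0) stop("pulse charge must be positive")
  structure(list(amplitude = amplitude, width = width,
                 shape = "cathodic_biphasic_balanced_square",
                 charge_nC = amplitude * width / 1000),
            class = "stim_pulse")
}

#' Default charge grid for recruitment curves
#'
#' Fine 1 nC resolution up to 100 nC (intrafascicular and adjacent
#' placements), coarser steps up to 1500 nC to resolve shielded
#' placements.
#'
#' @return Strictly increasing charge grid, nC.
#' @export
default_charge_grid <- function() c(seq(0, 100, by = 1), seq(103, 1500, by = 3))

# fascicle radii (mm) per size class
.fascicle_radius <- c(large = 0.8, medium = 0.4, small = 0.2)
.populations_per_class <- c(large = 9, medium = 5, small = 1)

#' Sample a sensory-fiber population within a fascicle
#'
#' Places `n_fibers` touch/pressure afferents in a disc inside the
#' fascicle.  Population 1 spreads over the whole fascicle; higher ids
#' shrink the disc monotonically (nested extents) and displace its
#' centroid at random within the fascicle, emulating the anatomical
#' uncertainty in the placement and extension of fibers innervating one
#' hand district.  Fiber diameters are drawn from the touch/pressure
#' Gaussian (mean 9 um, sd 2 um, truncated at 3 um); each fiber also
#' draws a random axial offset of its node grid relative to the electrode
#' plane.
#'
#' @param fascicle_class `"large"`, `"medium"` or `"small"`.
#' @param population_id 1-9 (large), 1-5 (medium), 1 (small).
#' @param seed Integer seed.
#' @param n_fibers Fibers per fascicle (default 100).
#' @param diameter_mean,diameter_sd,diameter_min Fiber-diameter Gaussian,
#'   um.
#' @return An object of class `fiber_population`: data frame `fibers`
#'   (`x`, `y` mm; `diameter` um; `z_offset` mm) plus fascicle metadata.
#' @export
sample_population <- function(fascicle_class = c("large", "medium", "small"),
                              population_id = 1, seed = NULL, n_fibers = 100,
                              diameter_mean = 9, diameter_sd = 2,
                              diameter_min = 3) {
  fascicle_class <- match.arg(fascicle_class)
  max_id <- .populations_per_class[[fascicle_class]]
  if (!(population_id %in% seq_len(max_id)))
    stop("population_id must be in 1..", max_id, " for ", fascicle_class,
         " fascicles")
  r_f <- .fascicle_radius[[fascicle_class]]
  frac <- if (max_id == 1) 1 else 1 - 0.85 * (population_id - 1) / (max_id - 1)
  r_pop <- r_f * frac
  with_seed(seed, {
    if (population_id == 1) {
      cx <- 0; cy <- 0
    } else {
      rc <- (r_f - r_pop) * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      cx <- rc * cos(th); cy <- rc * sin(th)
    }
    rr <- r_pop * sqrt(runif(n_fibers))
    th <- runif(n_fibers, 0, 2 * pi)
    d <- diameter_mean + diameter_sd * rnorm(n_fibers)
    while (any(d < diameter_min))
      d[d < diameter_min] <- diameter_mean + diameter_sd * rnorm(sum(d < diameter_min))
    fibers <- data.frame(x = cx + rr * cos(th), y = cy + rr * sin(th),
                         diameter = d,
                         z_offset = runif(n_fibers, -0.5, 0.5))
    structure(list(fibers = fibers, fascicle_class = fascicle_class,
                   fascicle_radius = r_f, population_id = population_id,
                   extent_radius = r_pop, centroid = c(cx, cy)),
              class = "fiber_population")
  })
}

# electrode placements relative to the target fascicle (radius r_f):
# source position and number of perineurium sheets crossed to reach the
# fascicle interior
.placement_geometry <- function(placement, r_f) {
  peri <- 0.03 * 2 * r_f
  switch(placement,
         within   = list(pos = c(0.5 * r_f, 0, 0), crossings = 0),
         adjacent = list(pos = c(r_f + peri + 0.15, 0, 0), crossings = 1),
         shielded = list(pos = c(r_f + peri + 0.8, 0, 0), crossings = 2),
         stop("unknown placement '", placement, "'"))
}

#' Extracellular potential profile along a fiber, per unit current
#'
#' Potential at the fiber's 21 node positions for a +1 uA source current,
#' averaged over the electrode's point sources and attenuated by the
#' perineurium sheets implied by the placement.
#'
#' @param fiber One row of a `fiber_population` (`x`, `y`, `diameter`,
#'   `z_offset`).
#' @param electrode An [electrode_model()].
#' @param site Active site (`"tip"`, `"L"` or `"R"`).
#' @param cond A [tissue_conductivities()].
#' @param crossings Perineurium sheets between source and fiber.
#' @param n_nodes Number of nodes of Ranvier.
#' @return Numeric vector of node potentials, mV per uA.
#' @export
fiber_node_potentials <- function(fiber, electrode, site = "tip",
                                  cond = tissue_conductivities(),
                                  crossings = 0, n_nodes = 21) {
  L_mm <- 100 * fiber$diameter / 1000      # internodal spacing, mm
  z <- ((seq_len(n_nodes)) - (n_nodes + 1) / 2) * L_mm + fiber$z_offset
  pts <- cbind(fiber$x, fiber$y, z)
  src <- electrode$sources(site)
  v <- rep(0, n_nodes)
  for (i in seq_len(nrow(src)))
    v <- v + extracellular_potential(src[i, ], 1 / nrow(src), pts,
                                     cond, crossings)
  v
}

#' Recruitment threshold of a single fiber
#'
#' Bisection on pulse amplitude at fixed width: the fiber's node potentials
#' are scaled by the candidate amplitude and the 21-node axon model is
#' integrated under the cathodic-first biphasic pulse; the fiber is
#' recruited when a propagating action potential reaches the last node of
#' Ranvier.
#'
#' @inheritParams fiber_node_potentials
#' @param pulse_width_us Phase width, us.
#' @param amp_cap Largest amplitude tried, uA (`NA` returned beyond it).
#' @return Threshold charge in nC (`NA` if not recruitable below the cap).
#' @export
fiber_threshold <- function(fiber, electrode, site = "tip",
                            cond = tissue_conductivities(),
                            crossings = 0, pulse_width_us = 100,
                            amp_cap = 2e4) {
  ve <- fiber_node_potentials(fiber, electrode, site, cond, crossings)
  amp <- axon_threshold_cpp(ve, fiber$diameter, pulse_width_us,
                            amp_cap = amp_cap)
  amp * pulse_width_us / 1000
}

#' Recruitment curve of a fiber population
#'
#' Fraction of the population recruited as a function of injected charge:
#' per-fiber threshold charges are found by bisection on amplitude at
#' fixed pulse width, then evaluated against the charge grid.
#'
#' @param population A [sample_population()] object.
#' @param electrode An [electrode_model()].
#' @param site Active site.
#' @param placement `"within"`, `"adjacent"` or `"shielded"` (sets source
#'   position and perineurium crossings); `NULL` to use the electrode's own
#'   position with `crossings`.
#' @param cond A [tissue_conductivities()].
#' @param charge_grid Increasing charge grid, nC.
#' @param pulse_width_us Phase width, us.
#' @param crossings Perineurium crossings when `placement` is `NULL`.
#' @return An object of class `recruitment_curve`: `charges`,
#'   `fraction_recruited`, per-fiber `thresholds_nC`, and case metadata.
#' @export
recruitment_curve <- function(population, electrode, site = "tip",
                              placement = NULL,
                              cond = tissue_conductivities(),
                              charge_grid = default_charge_grid(),
                              pulse_width_us = 100, crossings = 0) {
  stopifnot(inherits(population, "fiber_population"),
            inherits(electrode, "electrode_model"))
  if (is.unsorted(charge_grid, strictly = TRUE))
    stop("charge_grid must be strictly increasing")
  if (!is.null(placement)) {
    geom <- .placement_geometry(placement, population$fascicle_radius)
    electrode <- electrode_model(electrode$kind, geom$pos,
                                 tip_exposure_um = electrode$geometry$tip_exposure_um %||% 50,
                                 site_offset_mm = electrode$geometry$site_offset_mm %||% 0.2)
    crossings <- geom$crossings
  }
  thr <- vapply(seq_len(nrow(population$fibers)), function(i)
    fiber_threshold(population$fibers[i, ], electrode, site, cond,
                    crossings, pulse_width_us), numeric(1))
  # fibers not recruitable below the amplitude cap count as never recruited
  frac <- vapply(charge_grid, function(q) mean(!is.na(thr) & thr <= q),
                 numeric(1))
  structure(list(charges = charge_grid, fraction_recruited = frac,
                 thresholds_nC = thr, site = site,
                 electrode_kind = electrode$kind,
                 placement = placement),
            class = "recruitment_curve")
}

#' Charge at a given recruitment fraction
#'
#' Linear interpolation on the recruitment curve; `NA` when the curve
#' never reaches the requested fraction.
#'
#' @param curve A [recruitment_curve()].
#' @param fraction Target recruitment fraction (default 0.10).
#' @return Charge in nC, or `NA`.
#' @export
charge_at_recruitment <- function(curve, fraction = 0.10) {
  f <- curve$fraction_recruited
  q <- curve$charges
  if (max(f) < fraction) return(NA_real_)
  i <- which(f >= fraction)[1]
  if (i == 1 || f[i] == f[i - 1]) return(q[i])
  q[i - 1] + (fraction - f[i - 1]) / (f[i] - f[i - 1]) * (q[i] - q[i - 1])
}

#' Enumerate the device-comparison simulation plan
#'
#' Cross product of 3 electrode placements (within / adjacent / shielded
#' relative to the target fascicle) and the population ensembles (9 large
#' + 5 medium + 1 small = 15); the needle contributes one case per cell
#' and the intrafascicular array two (mirrored left/right active sites),
#' giving 45 needle and 90 TIME cases.
#'
#' @return A data frame with one row per case: `device`, `placement`,
#'   `fascicle_class`, `population`, `site` and a unique `case` key.
#' @export
enumerate_simulation_plan <- function() {
  placements <- c("within", "adjacent", "shielded")
  pops <- do.call(rbind, lapply(names(.populations_per_class), function(cl)
    data.frame(fascicle_class = cl,
               population = seq_len(.populations_per_class[[cl]]))))
  grid <- merge(data.frame(placement = placements), pops)
  needle <- cbind(device = "needle", grid, site = "tip")
  time_l <- cbind(device = "TIME", grid, site = "L")
  time_r <- cbind(device = "TIME", grid, site = "R")
  plan <- rbind(needle, time_l, time_r)
  plan$case <- with(plan, paste(device, placement, fascicle_class,
                                population, site, sep = "/"))
  rownames(plan) <- NULL
  plan[order(plan$device, plan$placement, plan$fascicle_class,
             plan$population, plan$site), ]
}

#' Run the recruitment plan
#'
#' Computes a recruitment curve and its 10%-recruitment charge for every
#' case of a simulation plan.  Populations are re-sampled per (placement,
#' fascicle class, population id) cell with seeds derived from the master
#' seed, and shared between the devices of a cell so that the comparison
#' is matched.
#'
#' @param plan A plan from [enumerate_simulation_plan()] (possibly a
#'   subset).
#' @param seed Master seed.
#' @param n_fibers Fibers per fascicle.
#' @param charge_grid Charge grid, nC.
#' @param tip_exposure_um Needle tip-exposure variant, um.
#' @param cond A [tissue_conductivities()].
#' @param fraction Recruitment level extracted from each curve.
#' @return The plan with columns `charge_at_level` (nC) and `reached`
#'   appended; the curves as an attribute `curves`.
#' @export
run_recruitment_plan <- function(plan = enumerate_simulation_plan(),
                                 seed = 1, n_fibers = 100,
                                 charge_grid = default_charge_grid(),
                                 tip_exposure_um = 50,
                                 cond = tissue_conductivities(),
                                 fraction = 0.10) {
  key <- with(plan, paste(placement, fascicle_class, population, sep = "/"))
  ukey <- unique(key)
  pops <- list()
  for (i in seq_along(ukey)) {
    row <- plan[match(ukey[i], key), ]
    pops[[ukey[i]]] <- sample_population(row$fascicle_class, row$population,
                                         seed = derive_seed(seed, i),
                                         n_fibers = n_fibers)
  }
  charge <- numeric(nrow(plan))
  curves <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    pop <- pops[[paste(row$placement, row$fascicle_class, row$population,
                       sep = "/")]]
    el <- electrode_model(ifelse(row$device == "needle", "needle", "TIME"),
                          tip_exposure_um = tip_exposure_um)
    cur <- recruitment_curve(pop, el, site = row$site,
                             placement = row$placement, cond = cond,
                             charge_grid = charge_grid)
    curves[[i]] <- cur
    charge[i] <- charge_at_recruitment(cur, fraction)
  }
  out <- plan
  out$charge_at_level <- charge
  out$reached <- !is.na(charge)
  attr(out, "curves") <- curves
  out
}

#' Compare needle and intrafascicular stimulation
#'
#' Extracts the charge needed for the target recruitment level from every
#' case and compares the two devices with a Kruskal-Wallis rank test at
#' the given level.  Cases whose curve never reaches the level are
#' excluded and counted.
#'
#' @param results Output of [run_recruitment_plan()] (or any data frame
#'   with `device` and `charge_at_level`).
#' @param alpha Significance level.
#' @return A list of class `device_comparison`: `p_value`, `significant`,
#'   per-device medians and case counts, and `n_excluded`.
#' @export
compare_devices <- function(results, alpha = 0.05) {
  if (!all(c("device", "charge_at_level") %in% names(results)))
    stop("results must have columns device and charge_at_level")
  ok <- is.finite(results$charge_at_level)
  n_excluded <- sum(!ok)
  r <- results[ok, ]
  if (!all(c("needle", "TIME") %in% r$device))
    stop("both device result sets must be nonempty")
  kw <- kruskal.test(charge_at_level ~ factor(device), data = r)
  med <- tapply(r$charge_at_level, r$device, median)
  structure(list(p_value = kw$p.value,
                 significant = kw$p.value < alpha,
                 alpha = alpha,
                 medians_nC = med,
                 n_cases = table(r$device),
                 n_excluded = n_excluded),
            class = "device_comparison")
}

#' @export
print.device_comparison <- function(x, ...) {
  cat(sprintf("Charge at recruitment level: needle median %.2f nC (n=%d), TIME median %.2f nC (n=%d)\n",
              x$medians_nC[["needle"]], x$n_cases[["needle"]],
              x$medians_nC[["TIME"]], x$n_cases[["TIME"]]))
  cat(sprintf("Kruskal-Wallis p = %.3g (%s at alpha = %g); %d case(s) excluded\n",
              x$p_value,
              if (x$significant) "different" else "not different",
              x$alpha, x$n_excluded))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
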