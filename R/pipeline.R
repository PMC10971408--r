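#' Default pipeline configuration
#'
#' Nested list of every tunable pipeline parameter with the toy-crystal
#' defaults. Any subset can be overridden by a sectioned `key = value`
#' config file ([read_pipeline_config()]); unknown keys are rejected.
#'
#' @return Named list of sections: `toy`, `data`, `supercell`, `maps`,
#'   `fits`.
#' @export
default_pipeline_config <- function() {
  list(
    toy = list(
      cell = c(25, 20, 18, 90, 90, 90), spacegroup = "P1", n_residues = 10,
      loop_from = 5, loop_to = 7, loop_shift = 1.2,
      occ_closed = 0.64, occ_closed_30s = 0.39, nucleophile_resid = 3,
      occ_reactive = 0.85, occ_adduct = 0.53, occ_water = 0.64,
      adp_scale = 15, adp_bump_30s = 4, seed = 1
    ),
    data = list(dmin = 1.8, noise_frac = 0.02, seed_on = 11, seed_off = 12),
    supercell = list(dims = c(2, 2, 2), frames = 3, seed = 7,
                     method = "quota", ensemble_maps = TRUE),
    maps = list(sigma_threshold = 3.2, peak_max_dist = 5,
                iaddat_threshold = 3, iaddat_radius = 2.5, cc_radius = 2.0),
    fits = list(titration_pka = 5.7, titration_noise_sd = 0.02,
                titration_seed = 21, temperature = 298)
  )
}

#' Read a sectioned key = value pipeline config
#'
#' Plain-text format: `[section]` headers, `key = value` lines, `#`
#' comments. Values are parsed as numeric vectors where possible. Unknown
#' sections or keys are an error, so configs stay diffable provenance.
#'
#' @param path Config file path.
#' @return A full config list (defaults overridden by the file).
#' @export
read_pipeline_config <- function(path) {
  cfg <- default_pipeline_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(cfg)) {
        stop("unknown config section: [", section, "]", call. = FALSE)
      }
      next
    }
    if (is.null(section)) stop("config line outside any section: ", ln, call. = FALSE)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg[[section]])) {
      stop("unknown key '", key, "' in section [", section, "]", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(strsplit(val, "[[:space:],]+")[[1]]))
    cfg[[section]][[key]] <- if (anyNA(num)) {
      if (val %in% c("true", "false")) val == "true" else val
    } else num
  }
  cfg
}

pipeline_spec_from_config <- function(cfg) {
  toy <- cfg$toy
  toy_crystal_spec(
    cell = unit_cell(toy$cell[1], toy$cell[2], toy$cell[3],
                     toy$cell[4], toy$cell[5], toy$cell[6]),
    spacegroup = toy$spacegroup, n_residues = toy$n_residues,
    loop_range = toy$loop_from:toy$loop_to, loop_shift = toy$loop_shift,
    occ_closed = toy$occ_closed, occ_closed_30s = toy$occ_closed_30s,
    nucleophile_resid = toy$nucleophile_resid,
    occ_reactive = toy$occ_reactive, occ_adduct = toy$occ_adduct,
    occ_water = toy$occ_water, adp_scale = toy$adp_scale,
    adp_bump_30s = toy$adp_bump_30s, seed = toy$seed
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> observe -> supercell ensemble -> difference
#' maps -> peaks/IADDAT/CC -> ADP analytics -> titration fits, logging
#' stage timings to stderr. Stage failures are caught: completed results
#' are kept and the error recorded under `errors`, so a partial report is
#' still machine-readable.
#'
#' @param config Config list ([default_pipeline_config()]) or a path to a
#'   config file.
#' @param out Optional path; when given, the report is written there as
#'   JSON.
#' @return An `analysis_report` list; identical configs and seeds
#'   reproduce it exactly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  report <- list(provenance = list(
    config = config,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("mdmx")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  ))
  report$errors <- list()
  state <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    message(sprintf("[%s] start", name))
    res <- tryCatch(fun(), error = function(e) {
      message(sprintf("[%s] FAILED: %s", name, conditionMessage(e)))
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    message(sprintf("[%s] done (%.1f s)", name, proc.time()[3] - t0))
    res
  }

  report$simulate <- stage("simulate", function() {
    spec <- pipeline_spec_from_config(config)
    state$pair <- make_toy_pair(spec)
    state$spec <- spec
    list(
      n_atoms_0s = nrow(state$pair$state_0s$atoms),
      n_atoms_30s = nrow(state$pair$state_30s$atoms),
      occupancies = list(
        closed_0s = spec$occ_closed, closed_30s = spec$occ_closed_30s,
        reactive = spec$occ_reactive, adduct = spec$occ_adduct,
        water = spec$occ_water
      ),
      modification_fraction_pct =
        modification_fraction(spec$occ_adduct, spec$occ_reactive)
    )
  })

  report$observe <- stage("observe", function() {
    d <- config$data
    state$obs_on <- make_observations(state$pair$state_30s, dmin = d$dmin,
                                      noise_frac = d$noise_frac,
                                      seed = d$seed_on)
    state$obs_off <- make_observations(state$pair$state_0s, dmin = d$dmin,
                                       noise_frac = d$noise_frac,
                                       seed = d$seed_off)
    list(n_reflections = nrow(state$obs_on$tbl), dmin = d$dmin,
         noise_frac = d$noise_frac)
  })

  report$diffmap <- stage("diffmap", function() {
    m <- config$maps
    sc <- scale_amplitudes(state$obs_on, state$obs_off)
    state$map_exp <- fo_minus_fo_map(state$obs_on, state$obs_off,
                                     phase_model = state$pair$state_0s,
                                     dmin = config$data$dmin)
    peaks <- find_peaks(state$map_exp, threshold_sigma = m$sigma_threshold,
                        model = state$pair$state_0s,
                        max_dist = m$peak_max_dist)
    state$peaks <- peaks
    prof <- iaddat(state$map_exp, state$pair$state_0s,
                   threshold_sigma = m$iaddat_threshold,
                   radius = m$iaddat_radius)
    state$iaddat <- prof
    wat <- state$pair$state_30s$atoms
    wat <- wat[wat$resname == "HOH", ]
    water_peak <- NA_real_
    if (nrow(wat) && nrow(peaks)) {
      d <- min_image_dist(state$map_exp$cell,
                          as.matrix(peaks[, c("fx", "fy", "fz")]),
                          c(wat$fx[1], wat$fy[1], wat$fz[1]))
      cand <- peaks$height_sigma[d < 3 & peaks$sign == "+"]
      if (length(cand)) water_peak <- max(cand)
    }
    list(scale_k = sc$k, n_peaks = nrow(peaks),
         n_pos = sum(peaks$sign == "+"), n_neg = sum(peaks$sign == "-"),
         strongest = if (nrow(peaks)) peaks$height_sigma[1] else NA_real_,
         water_peak_sigma = water_peak,
         iaddat = as.data.frame(prof))
  })

  report$ensemble <- stage("ensemble", function() {
    sc <- config$supercell
    if (!isTRUE(sc$ensemble_maps)) return(list(skipped = TRUE))
    ens_on <- make_ensemble(state$pair$state_30s, dims = sc$dims,
                            n_frames = sc$frames, seed = sc$seed,
                            method = sc$method)
    ens_off <- make_ensemble(state$pair$state_0s, dims = sc$dims,
                             n_frames = sc$frames, seed = sc$seed + 1,
                             method = sc$method)
    f_on <- sf_ensemble(ens_on, "all", dmin = config$data$dmin)
    f_off <- sf_ensemble(ens_off, "all", dmin = config$data$dmin)
    state$map_md <- fo_minus_fo_map(
      to_amplitudes(f_on), to_amplitudes(f_off),
      phase_model = state$pair$state_0s, dmin = config$data$dmin
    )
    cc_loop <- map_cc_masked(
      state$map_md, state$map_exp,
      select_residues(state$pair$state_0s, state$spec$loop_range[1],
                      max(state$spec$loop_range)),
      selection = "mainchain", radius = config$maps$cc_radius
    )
    cc_all <- map_cc_masked(state$map_md, state$map_exp,
                            state$pair$state_0s, selection = "mainchain",
                            radius = config$maps$cc_radius)
    freq <- conformer_frequencies(ens_on$model)
    list(n_copies = nrow(ens_on$model$copies), n_frames = sc$frames,
         n_adducts = sum(ens_on$model$copies$adduct),
         conformer_freq = as.data.frame(freq),
         cc_loop_mainchain = cc_loop, cc_all_mainchain = cc_all)
  })

  report$adp <- stage("adp", function() {
    bd <- residue_bdiff(state$pair$state_30s, state$pair$state_0s)
    rm0 <- rosenfield(state$pair$state_0s, bins = 30)
    list(bdiff = as.data.frame(bd),
         bdiff_max_resid = bd$resid[which.max(bd$value)],
         rosenfield_mean_abs = mean(rm0$binned),
         rigid_body = is_rigid_body(rm0))
  })

  report$titration <- stage("titration", function() {
    f <- config$fits
    series <- make_titration(titration_spec(
      pka = f$titration_pka, noise_sd = f$titration_noise_sd,
      seed = f$titration_seed
    ))
    fit <- fit_pka(series, n_boot = 200, seed = f$titration_seed)
    dg <- delta_g(state$spec$occ_closed, 1 - state$spec$occ_closed,
                  temperature = f$temperature)
    list(pka = fit$pka, ci = fit$ci, direction = fit$direction,
         delta_g_loop_kj_mol = dg)
  })

  class(report) <- "analysis_report"
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  report
}

# convert a complex reflection set to an amplitude set
to_amplitudes <- function(r) {
  reflection_set(r$cell, tibble::tibble(
    h = r$tbl$h, k = r$tbl$k, l = r$tbl$l, fobs = Mod(r$tbl$F), sigf = 0
  ), dmin = r$dmin)
}

min_image_dist <- function(cell, frac_pts, target) {
  d <- sweep(frac_pts, 2, target)
  d <- d - round(d)
  sqrt(rowSums((d %*% t(cell$orth))^2))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  if (!is.null(x$diffmap)) {
    cat(sprintf("  peaks: %d (strongest %.1f sigma; water site %.1f sigma)\n",
                x$diffmap$n_peaks, x$diffmap$strongest,
                x$diffmap$water_peak_sigma))
  }
  if (!is.null(x$ensemble) && is.null(x$ensemble$skipped)) {
    cat(sprintf("  ensemble vs experimental map CC (loop mainchain): %.2f\n",
                x$ensemble$cc_loop_mainchain))
  }
  if (!is.null(x$titration)) {
    cat(sprintf("  titration pKa: %.2f; loop delta G: %.2f kJ/mol\n",
                x$titration$pka, x$titration$delta_g_loop_kj_mol))
  }
  if (length(x$errors)) {
    cat("  FAILED stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
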