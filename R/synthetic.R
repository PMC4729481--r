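# Synthetic MIFE-like flux datasets with known ground truth.

#' Measurement-noise model for synthetic flux traces
#'
#' Gaussian noise with standard deviation `relative_sd * |J| + floor_sd`
#' (nmol m-2 s-1), emulating the scatter of microelectrode flux recordings:
#' a signal-proportional component plus an absolute electrode noise floor.
#'
#' @param relative_sd fraction of the local absolute flux.
#' @param floor_sd absolute component, nmol m-2 s-1.
#' @param seed integer seed making generation reproducible.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.05, floor_sd = 2, seed = 1L) {
  if (relative_sd < 0 || floor_sd < 0)
    stop("noise standard deviations must be >= 0")
  structure(list(relative_sd = relative_sd, floor_sd = floor_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

.known_ions <- c("H", "K", "Na", "Cl")

new_flux_dataset <- function(records, provenance = list()) {
  records <- records[order(records$condition, records$ion, records$time_s), ]
  rownames(records) <- NULL
  structure(records,
            sign_convention = "outward_positive",
            provenance = provenance,
            class = c("flux_dataset", "data.frame"))
}

#' Generate a synthetic flux dataset from a simulated scenario
#'
#' Simulates the scenario, samples the selected net fluxes on a regular
#' grid, converts them to nmol m-2 s-1 (outward positive) and adds
#' measurement noise. The generating parameters and seed are recorded in
#' the dataset's provenance, so estimation routines can be benchmarked
#' against known ground truth.
#'
#' @param params an `ion_params` object (the ground truth).
#' @param schedule an `ion_schedule`.
#' @param sample_step sampling interval, s.
#' @param noise a [noise_model()]; use `noise_model(0, 0)` for noiseless
#'   sampling.
#' @param ions which net fluxes to record.
#' @param condition condition label (by convention `"KCl_<dose>mM"`).
#' @param ... passed to [simulate_fluxes()].
#' @return A `flux_dataset`: data frame with columns `time_s`, `condition`,
#'   `ion`, `flux_nmol_m2_s`; attributes `sign_convention` and `provenance`.
#' @export
synthesize_fluxes <- function(params, schedule, sample_step = 5,
                              noise = noise_model(), ions = c("K", "H"),
                              condition = "synthetic", ...) {
  stopifnot(sample_step > 0)
  ions <- match.arg(ions, .known_ions, several.ok = TRUE)
  t_grid <- seq(schedule$t_start, schedule$t_start + schedule$span,
                by = sample_step)
  traj <- simulate_fluxes(params, schedule, times = t_grid, ...)
  keep <- traj$time %in% t_grid
  recs <- do.call(rbind, lapply(ions, function(ion) {
    data.frame(time_s = traj$time[keep], condition = condition, ion = ion,
               flux_nmol_m2_s = traj[[paste0("J_", ion)]][keep] * 1e9)
  }))
  if (noise$relative_sd > 0 || noise$floor_sd > 0) {
    set.seed(noise$seed)
    sd_vec <- noise$relative_sd * abs(recs$flux_nmol_m2_s) + noise$floor_sd
    recs$flux_nmol_m2_s <- recs$flux_nmol_m2_s +
      stats::rnorm(nrow(recs), 0, sd_vec)
  }
  new_flux_dataset(recs, provenance = list(
    source = "synthetic", params = params$name, schedule_events =
      attr(traj, "events"), sample_step = sample_step,
    relative_sd = noise$relative_sd, floor_sd = noise$floor_sd,
    seed = noise$seed))
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat(sprintf("Flux dataset: %d records, %d condition(s) x ions {%s}\n",
              nrow(x), length(unique(x$condition)),
              paste(sort(unique(x$ion)), collapse = ", ")))
  cat(sprintf("  sign convention: %s | source: %s\n",
              attr(x, "sign_convention"),
              if (is.null(attr(x, "provenance")$source)) "unknown"
              else attr(x, "provenance")$source))
  invisible(x)
}

#' Write a flux dataset to CSV
#'
#' The dialect is a plain CSV with header `time_s,condition,ion,
#' flux_nmol_m2_s`, preceded by `#`-prefixed metadata lines carrying the
#' sign convention and provenance.
#'
#' @param dataset a `flux_dataset`.
#' @param path output path.
#' @param digits significant digits used for the flux column.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(dataset, path, digits = 8) {
  stopifnot(inherits(dataset, "flux_dataset"))
  prov <- attr(dataset, "provenance")
  meta <- c(paste0("# sign_convention: ", attr(dataset, "sign_convention")),
            if (!is.null(prov$source)) paste0("# source: ", prov$source),
            if (!is.null(prov$params)) paste0("# params: ", prov$params),
            if (!is.null(prov$seed)) paste0("# seed: ", prov$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("time_s,condition,ion,flux_nmol_m2_s", con)
  writeLines(paste(format(dataset$time_s, trim = TRUE, scientific = FALSE),
                   dataset$condition, dataset$ion,
                   formatC(dataset$flux_nmol_m2_s, digits = digits,
                           format = "g"),
                   sep = ","), con)
  invisible(path)
}

#' Read a flux dataset from CSV
#'
#' Reads the dialect written by [write_flux_csv()]. A file flagged
#' `influx_positive` in its metadata is converted to the model's
#' outward-positive convention (fluxes negated) on load.
#'
#' @param path CSV path.
#' @return A `flux_dataset` (always outward positive).
#' @export
read_flux_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  sign_conv <- sub("^# sign_convention:\\s*", "",
                   grep("^# sign_convention:", meta, value = TRUE))
  if (length(sign_conv) != 1 ||
      !sign_conv %in% c("outward_positive", "influx_positive"))
    stop("missing or unknown sign_convention metadata in ", path)
  body_start <- length(meta) + 1L
  header <- strsplit(lines[body_start], ",")[[1]]
  required <- c("time_s", "condition", "ion", "flux_nmol_m2_s")
  if (!identical(header, required))
    stop("expected header ", paste(required, collapse = ","),
         " in ", path, " (line ", body_start, ")")
  df <- utils::read.csv(text = lines[-seq_len(body_start - 1L)],
                        stringsAsFactors = FALSE)
  bad <- which(!df$ion %in% .known_ions)
  if (length(bad))
    stop("unknown ion label '", df$ion[bad[1]], "' at data row ", bad[1],
         " of ", path)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$flux_nmol_m2_s))
  if (length(bad))
    stop("non-numeric record at data row ", bad[1], " of ", path)
  for (key in split(seq_len(nrow(df)), list(df$condition, df$ion),
                    drop = TRUE)) {
    if (is.unsorted(df$time_s[key]))
      stop("times not sorted within trace (", df$condition[key[1]], ", ",
           df$ion[key[1]], ") starting at data row ", key[1], " of ", path)
  }
  if (sign_conv == "influx_positive")
    df$flux_nmol_m2_s <- -df$flux_nmol_m2_s
  new_flux_dataset(df, provenance = list(source = path,
                                         original_convention = sign_conv))
}

#' Four-condition synthetic fixture bundle
#'
#' Generates the full study design from parameter set P2a: the fit protocol
#' (KCl at 300 s, glucose at 600 s) at the four KCl doses 0.01, 0.1, 1 and
#' 10 mM, K+ and H+ traces each, with default measurement noise.
#'
#' @param seed integer seed for the noise.
#' @param sample_step sampling interval, s.
#' @param noise optional [noise_model()] overriding the default (its seed
#'   is re-derived from `seed` per condition).
#' @param params ground-truth parameter set.
#' @return A `flux_dataset` with 8 traces, condition labels
#'   `"KCl_<dose>mM"`.
#' @export
fixture_suite <- function(seed = 1L, sample_step = 5,
                          noise = noise_model(), params = parameter_set("P2a")) {
  doses <- c(0.01, 0.1, 1, 10)
  sets <- lapply(seq_along(doses), function(i) {
    sc <- canonical_scenarios(doses[i], step = sample_step)$fit
    nm <- noise_model(noise$relative_sd, noise$floor_sd,
                      seed = seed * 8L + i)
    synthesize_fluxes(params, sc, sample_step = sample_step, noise = nm,
                      condition = sprintf("KCl_%gmM", doses[i]))
  })
  out <- new_flux_dataset(do.call(rbind, sets),
                          provenance = list(source = "synthetic",
                                            params = params$name,
                                            seed = seed,
                                            sample_step = sample_step,
                                            relative_sd = noise$relative_sd,
                                            floor_sd = noise$floor_sd,
                                            doses = doses))
  out
}

#' KCl dose encoded in a condition label
#'
#' Parses labels of the form `"KCl_<dose>mM"` used throughout the package.
#'
#' @param condition character vector of condition labels.
#' @return Numeric doses, mM.
#' @export
condition_dose <- function(condition) {
  m <- regmatches(condition,
                  regexpr("^KCl_([0-9.eE+-]+)mM$", condition))
  if (length(m) != length(condition) || any(!nzchar(m)))
    stop("condition labels must have the form 'KCl_<dose>mM'; got: ",
         paste(unique(condition[!grepl("^KCl_[0-9.eE+-]+mM$", condition)]),
               collapse = ", "))
  as.numeric(sub("^KCl_", "", sub("mM$", "", condition)))
}
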