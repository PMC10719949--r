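#' Run the full pipeline for one subject
#'
#' Orchestrates one end-to-end run: obtain the recording (load from disk or
#' simulate), re-reference, build the NREM/artifact mask, detect events, nest
#' spindles, compute densities and laterality indices, and (optionally)
#' write annotations, tables, scalp maps and a JSON report. Deterministic
#' given the configuration and seed.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with fields:
#' \describe{
#'   \item{subject}{subject identifier (default "s1").}
#'   \item{simulation}{list of [simulationSpec()] arguments; when present
#'     the subject is simulated and no recording is read.}
#'   \item{recording, hypnogram}{input paths for real data; \code{format}
#'     optionally forces the reader.}
#'   \item{reference}{\code{"auricle_average"}, \code{"linked_mastoids"} or
#'     \code{"none"}; \code{pre_referenced = TRUE} only sets the flag.}
#'   \item{artifact_threshold, artifact_pad}{mask parameters (default 500
#'     uV, 1 s).}
#'   \item{groups}{role -> label lists for [resolveGroups()]; synthetic
#'     subjects default to hemisphere parity groups.}
#'   \item{coupling_window}{nesting window (default -0.5..1).}
#'   \item{outdir}{when set, annotations/CSV/JSON (and maps when
#'     \code{write_maps = TRUE}) are written there.}
#' }
#'
#' @param cfg configuration list or YAML path.
#' @return list with \code{subject}, \code{detection}, \code{nested},
#'   \code{density}, \code{laterality}, \code{groups}, \code{mask_minutes},
#'   \code{counts} (stage tallies), \code{truth} and \code{recovery} (for
#'   simulated subjects), and \code{files} written.
#' @export
runSubject <- function(cfg) {
  if (is.character(cfg)) cfg <- readGroupsConfig(cfg)
  subject <- cfg$subject %||% "s1"
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    spec <- do.call(simulationSpec, cfg$simulation)
    sim <- simulateSubject(spec)
    rec <- sim$recording
    truth <- sim$truth
    hyp <- new("Hypnogram", epochLength = 30,
               stages = rep("NREM",
                            ceiling(nrow(samples(rec)) / samplingRate(rec) / 30)))
  } else {
    if (is.null(cfg$recording) || is.null(cfg$hypnogram))
      stop("stage io: config needs either 'simulation' or ",
           "'recording' + 'hypnogram'")
    rec <- loadRecording(cfg$recording, cfg$format %||% "auto")
    hyp <- readHypnogram(cfg$hypnogram)
  }
  refScheme <- cfg$reference %||% "none"
  if (refScheme != "none")
    rec <- applyReference(rec, refScheme,
                          preReferenced = isTRUE(cfg$pre_referenced))
  mask <- buildMask(rec, hyp,
                    artifactThreshold = cfg$artifact_threshold %||% 500,
                    artifactPad = cfg$artifact_pad %||% 1)
  mins <- nremMinutes(mask)
  message(sprintf("[%s] mask: %.1f-%.1f retained NREM min/channel",
                  subject, min(mins), max(mins)))
  detection <- detectEvents(rec, mask)
  window <- as.numeric(cfg$coupling_window %||% c(-0.5, 1.0))
  nested <- nestSpindles(detection$slow, detection$spindles, window)
  message(sprintf("[%s] events: %d slow (%d SO, %d delta), %d spindles, %d nested",
                  subject, nrow(detection$slow),
                  sum(detection$slow$kind == "SO"),
                  sum(detection$slow$kind == "delta"),
                  nrow(detection$spindles), nrow(nested)))
  density <- computeDensity(detection, nested, mins, subject)
  groups <- if (!is.null(cfg$groups))
    resolveGroups(cfg$groups, channelNames(rec))
  else resolveGroups(list(), channelNames(rec))
  laterality <- lateralityResult(density, groups)
  recovery <- if (!is.null(truth)) matchEvents(truth, detection) else NULL

  files <- character(0)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    evPath <- file.path(cfg$outdir, paste0(subject, "_events.tsv"))
    writeEvents(detection, evPath, nested)
    dePath <- file.path(cfg$outdir, paste0(subject, "_density.csv"))
    utils::write.csv(density, dePath, row.names = FALSE)
    liPath <- file.path(cfg$outdir, paste0(subject, "_laterality.csv"))
    utils::write.csv(laterality, liPath, row.names = FALSE)
    files <- c(events = evPath, density = dePath, laterality = liPath)
    if (isTRUE(cfg$write_maps)) {
      for (tt in unique(density$event_type)) {
        v <- density$density[density$event_type == tt]
        names(v) <- density$channel[density$event_type == tt]
        ok <- tryCatch({
          mp <- scalpMap(v)
          p <- file.path(cfg$outdir, paste0(subject, "_map_", tt, ".png"))
          plotScalpMap(mp, p, main = paste(subject, tt))
          files[paste0("map_", tt)] <- p
          TRUE
        }, error = function(e) FALSE)
      }
    }
    report <- list(subject = subject,
                   parameters = pipelineDefaults(),
                   mask_minutes = as.list(mins),
                   counts = list(slow = nrow(detection$slow),
                                 spindles = nrow(detection$spindles),
                                 nested = nrow(nested)),
                   laterality = laterality,
                   files = as.list(files))
    rpPath <- file.path(cfg$outdir, paste0(subject, "_report.json"))
    jsonlite::write_json(report, rpPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    files["report"] <- rpPath
  }
  list(subject = subject, detection = detection, nested = nested,
       density = density, laterality = laterality, groups = groups,
       mask_minutes = mins,
       counts = c(slow = nrow(detection$slow),
                  spindles = nrow(detection$spindles),
                  nested = nrow(nested)),
       truth = truth, recovery = recovery, files = files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection defaults echoed into every report
#'
#' One place for the analysis defaults: slow band 0.1-4 Hz, spindle band
#' 10-16 Hz, 40th/85th trough/peak percentiles, envelope thresholds mu+1.5
#' sigma and mu+2.5 sigma, 500 ms minimum spindle duration, 150-500 ms SO
#' peak-trough lag (delta up to 500 ms), coupling window -0.5..+1.0 s,
#' artifact mask 500 uV with 1 s pad.
#'
#' @return named list of defaults.
#' @export
pipelineDefaults <- function() {
  list(slow_band_hz = c(0.1, 4), spindle_band_hz = c(10, 16),
       trough_percentile = 0.40, peak_percentile = 0.85,
       spindle_lower_sd = 1.5, spindle_upper_sd = 2.5,
       min_spindle_duration_s = 0.5, so_peak_trough_lag_s = c(0.150, 0.500),
       delta_max_lag_s = 0.500, coupling_window_s = c(-0.5, 1.0),
       artifact_threshold_uv = 500, artifact_pad_s = 1,
       gaussian_smooth_s = 0.2)
}

#' Run a cohort and the group statistics
#'
#' Runs every subject, aggregates stroke-subject densities into the
#' long-format electrode table (stroke = 1, contralateral CM/CNM = 0), and
#' runs the cohort statistics: a linear mixed-effects model per event type
#' ([fitMixedModel()]), paired stroke-vs-CM t-tests per medication group
#' (pairing stroke electrodes with their mirrors), and a one-way ANOVA of
#' stroke-electrode densities across medication groups. Statistics whose
#' preconditions are unmet are skipped with a notice.
#'
#' @param cfgs list of subject configurations (see [runSubject()]).
#' @param outdir optional directory for the cohort JSON report and text
#'   summary.
#' @return list with \code{subjects} (per-subject results),
#'   \code{laterality} (stacked LI table), \code{long_table},
#'   \code{mixed_models}, \code{t_tests}, \code{anova}, \code{skipped}.
#' @export
runCohort <- function(cfgs, outdir = NULL) {
  subjects <- lapply(cfgs, runSubject)
  names(subjects) <- vapply(subjects, `[[`, "", "subject")
  lat <- do.call(rbind, lapply(subjects, `[[`, "laterality"))
  rownames(lat) <- NULL
  skipped <- character(0)

  longRows <- list()
  for (s in subjects) {
    g <- s$groups
    if (!length(g@stroke)) next
    den <- s$density
    cls <- rbind(data.frame(channel = g@stroke, electrode_class = 1),
                 data.frame(channel = c(g@contralateralMirror,
                                        g@contralateralNonMirror),
                            electrode_class = 0))
    m <- merge(den, cls, by = "channel")
    m$patient <- s$subject
    m$medication_group <- g@medicationGroup
    longRows[[s$subject]] <- m[, c("patient", "medication_group",
                                   "electrode_class", "channel",
                                   "event_type", "density")]
  }
  long <- if (length(longRows)) do.call(rbind, c(longRows,
                                                 make.row.names = FALSE))
          else NULL

  types <- c("SO", "delta", "spindle", "SO_spindle", "delta_spindle")
  mixed <- list(); ttests <- list(); anova <- list()
  if (!is.null(long) && length(unique(long$patient)) >= 2) {
    for (tt in types) {
      sub <- long[long$event_type == tt, ]
      mixed[[tt]] <- tryCatch(fitMixedModel(sub),
                              error = function(e) {
                                skipped <<- c(skipped, paste("mixed", tt,
                                                             conditionMessage(e)))
                                NULL
                              })
    }
    for (grp in unique(long$medication_group)) {
      for (tt in types) {
        sub <- long[long$medication_group == grp & long$event_type == tt, ]
        pairs <- pairStrokeMirror(sub, subjects)
        key <- paste(grp, tt, sep = ".")
        if (is.null(pairs) || nrow(pairs) < 2) {
          skipped <- c(skipped, paste("t-test", key, "(too few pairs)"))
          next
        }
        ttests[[key]] <- tryCatch(
          c(pairedTTest(pairs$stroke, pairs$contra), n_pairs = nrow(pairs)),
          error = function(e) {
            skipped <<- c(skipped, paste("t-test", key, conditionMessage(e)))
            NULL
          })
      }
    }
    for (tt in types) {
      sub <- long[long$event_type == tt & long$electrode_class == 1, ]
      gs <- split(sub$density, sub$medication_group)
      gs <- gs[lengths(gs) >= 2]
      if (length(gs) >= 2) {
        anova[[tt]] <- tryCatch(oneWayAnova(gs), error = function(e) {
          skipped <<- c(skipped, paste("anova", tt, conditionMessage(e)))
          NULL
        })
      } else skipped <- c(skipped, paste("anova", tt, "(too few groups)"))
    }
  } else {
    skipped <- c(skipped, "cohort statistics (fewer than 2 stroke subjects)")
    message("cohort statistics skipped: fewer than 2 stroke subjects")
  }

  out <- list(subjects = subjects, laterality = lat, long_table = long,
              mixed_models = mixed, t_tests = ttests, anova = anova,
              skipped = skipped)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    rp <- file.path(outdir, "cohort_report.json")
    jsonlite::write_json(
      list(laterality = lat,
           mixed_models = mixed, t_tests = ttests, anova = anova,
           skipped = skipped, parameters = pipelineDefaults()),
      rp, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    txt <- file.path(outdir, "cohort_summary.txt")
    writeLines(cohortSummaryText(out), txt)
    out$files <- c(report = rp, summary = txt)
  }
  out
}

# stroke density paired with its mirrored CM electrode's density
pairStrokeMirror <- function(sub, subjects) {
  rows <- list()
  for (p in unique(sub$patient)) {
    g <- subjects[[p]]$groups
    sp <- sub[sub$patient == p, ]
    for (ch in intersect(g@stroke, sp$channel)) {
      mir <- mirrorElectrode(ch)
      if (!mir %in% sp$channel) next
      rows[[paste(p, ch)]] <- data.frame(
        stroke = sp$density[sp$channel == ch][1],
        contra = sp$density[sp$channel == mir][1])
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

cohortSummaryText <- function(res) {
  out <- c("Cohort summary", "==============", "")
  agg <- stats::aggregate(value ~ event_type, data = res$laterality, FUN = mean)
  out <- c(out, "Mean laterality index by event type:",
           sprintf("  %-14s %.3f", agg$event_type, agg$value), "")
  if (length(res$mixed_models)) {
    out <- c(out, "Mixed-effects models (density ~ electrode class):")
    for (tt in names(res$mixed_models)) {
      m <- res$mixed_models[[tt]]
      if (is.null(m)) next
      out <- c(out, sprintf(
        "  %-14s estimate %.3f  p %.4f  R2 %.3f  d %.2f (%s)",
        tt, m$estimate, m$p, m$r2, m$d, m$magnitude))
    }
    out <- c(out, "")
  }
  if (length(res$skipped))
    out <- c(out, "Skipped:", paste(" ", res$skipped))
  out
}
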