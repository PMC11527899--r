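# Session container I/O (delimited text + JSON manifest) and the
# end-to-end pipeline driver.

#' Write a session recording to disk
#'
#' Serializes a session as delimited text (one file per signal stream, one
#' column per channel with a header row) plus a JSON manifest holding the
#' participant id, sample rates, montage, schedule, ground-truth events,
#' seeds and processing provenance.
#'
#' @param session A `session_recording`.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- names(session$intensity$intensity)
  files <- list(accel = "accel.tsv", resp = "resp.tsv")
  for (w in wl) files[[paste0("fnirs_", w)]] <- sprintf("fnirs_%s.tsv", w)

  data.table::fwrite(data.table::data.table(accel = session$accel),
                     file.path(dir, files$accel), sep = "\t")
  data.table::fwrite(data.table::data.table(resp = session$resp),
                     file.path(dir, files$resp), sep = "\t")
  for (w in wl) {
    data.table::fwrite(data.table::as.data.table(session$intensity$intensity[[w]]),
                       file.path(dir, files[[paste0("fnirs_", w)]]), sep = "\t")
  }
  data.table::fwrite(session$montage, file.path(dir, "montage.tsv"), sep = "\t")

  manifest <- list(
    participant = session$participant,
    sample_rates = session$sample_rates,
    wavelengths = wl,
    i0 = session$i0,
    seed = session$seed,
    files = files,
    n_samples = list(
      accel = length(session$accel),
      resp = length(session$resp),
      fnirs = nrow(session$intensity$intensity[[wl[1]]])
    ),
    schedule = list(
      segments = session$schedule$segments,
      onsets = session$schedule$onsets,
      rests = session$schedule$rests,
      duration = session$schedule$duration,
      protocol = unclass(session$schedule$protocol)
    ),
    truth = list(events = session$truth$events, apneas = session$truth$apneas),
    provenance = session$provenance
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session recording from disk
#'
#' Loads a session written by [write_session()], validating each stream
#' against the manifest's declared lengths (an integrity error on mismatch)
#' and re-assembling the schedule and ground truth. The ground-truth
#' concentration series is not serialized, so `truth$conc` is `NULL` on a
#' loaded session. A montage without short-separation channels loads with a
#' warning.
#'
#' @param dir Session directory.
#'
#' @return A `session_recording`.
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("No manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)

  read_stream <- function(key) {
    path <- file.path(dir, man$files[[key]])
    if (!file.exists(path)) {
      stop(sprintf("Missing stream file `%s` (%s).", key, man$files[[key]]),
           call. = FALSE)
    }
    data.table::fread(path, sep = "\t")
  }
  accel <- read_stream("accel")[[1]]
  resp <- read_stream("resp")[[1]]
  if (length(accel) != man$n_samples$accel ||
      length(resp) != man$n_samples$resp) {
    stop("Integrity error: stream length does not match the manifest.",
         call. = FALSE)
  }
  montage <- tibble::as_tibble(data.table::fread(file.path(dir, "montage.tsv"),
                                                 sep = "\t"))
  if (!any(montage$type == "short")) {
    warning("Session montage has no short-separation channels.",
            call. = FALSE)
  }
  wl <- as.character(man$wavelengths)
  intensity <- lapply(wl, function(w) {
    m <- as.matrix(read_stream(paste0("fnirs_", w)))
    if (nrow(m) != man$n_samples$fnirs) {
      stop("Integrity error: fNIRS length does not match the manifest.",
           call. = FALSE)
    }
    m
  })
  names(intensity) <- wl
  fs <- man$sample_rates$fnirs
  time <- seq(0, by = 1 / fs, length.out = man$n_samples$fnirs)

  protocol <- do.call(protocol_spec, man$schedule$protocol[
    setdiff(names(man$schedule$protocol), character(0))])
  schedule <- structure(
    list(segments = tibble::as_tibble(man$schedule$segments),
         onsets = tibble::as_tibble(man$schedule$onsets),
         rests = tibble::as_tibble(man$schedule$rests),
         duration = man$schedule$duration,
         protocol = protocol),
    class = "swallow_schedule"
  )
  raw <- structure(
    list(time = time, intensity = intensity, channels = montage,
         i0 = man$i0, sample_rate = fs),
    class = "raw_intensity"
  )
  structure(
    list(
      participant = man$participant,
      sample_rates = man$sample_rates,
      montage = montage,
      schedule = schedule,
      intensity = raw,
      accel = accel,
      resp = resp,
      truth = list(events = tibble::as_tibble(man$truth$events),
                   apneas = tibble::as_tibble(man$truth$apneas),
                   conc = NULL),
      i0 = man$i0,
      seed = man$seed,
      provenance = man$provenance
    ),
    class = "session_recording"
  )
}

#' Run the full analysis pipeline
#'
#' End-to-end driver. In `"session"` mode it generates (or loads) one
#' session, detects and labels swallow onsets, processes raw intensity to
#' corrected concentrations, and computes the baseline-normalized median-HDR
#' summary and grand averages. In `"cohort"` mode it simulates a cohort-level
#' HDR table, fits the backward-elimination mixed model and computes Tukey
#' position contrasts. All randomness derives from `seed`, so repeated runs
#' are identical.
#'
#' @param config Named list of options. Common: `mode` (`"session"` or
#'   `"cohort"`). Session mode: `protocol`, `channels`, `hrf`, `noise`,
#'   `optics`, `session_dir` (load instead of simulate), `band`, `pre`,
#'   `post`. Cohort mode: `n_participants`, `protocol`, `hrf`,
#'   `sigma_participant`, `sigma_event`, `alpha`.
#' @param seed Integer seed (default 1).
#' @param out_dir Optional output directory; when given, writes
#'   `events.json`, `hdr_summary.csv` and `grand_average.csv` (session mode)
#'   or `hdr_summary.csv` and `model_report.json` (cohort mode).
#'
#' @return A list of stage outputs (session mode: `session`, `events`,
#'   `conc`, `hdr`, `hdr_summary`, `grand_average`; cohort mode: `events`,
#'   `hdr_summary`, `model`, `contrasts`).
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  mode <- config$mode %||% "session"
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  if (mode == "session") {
    protocol <- config$protocol %||% protocol_spec()
    session <- if (!is.null(config$session_dir)) {
      read_session(config$session_dir)
    } else {
      simulate_session(
        protocol = protocol,
        channels = config$channels %||% default_montage(),
        hrf = config$hrf %||% hrf_params(),
        noise = config$noise %||% noise_params(),
        optics = config$optics %||% default_optics(),
        seed = seed
      )
    }
    events <- detect_swallows(session)
    conc <- process_session(session,
                            optics = config$optics %||% default_optics(),
                            band = config$band %||% c(0.01, 0.5))
    ev <- dplyr::mutate(events, participant = session$participant)
    epochs <- extract_epochs(conc, ev, pre = config$pre %||% 10,
                             post = config$post %||% 20)
    epochs <- baseline_normalize(epochs)
    hdr <- median_hdr(epochs)
    spp <- session$schedule$protocol$swallows_per_position_per_block
    hdr_summary <- aggregate_hdr(hdr, swallows_per_segment = spp)
    ga <- grand_average(epochs)
    if (!is.null(out_dir)) {
      jsonlite::write_json(events, file.path(out_dir, "events.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      data.table::fwrite(hdr_summary, file.path(out_dir, "hdr_summary.csv"))
      data.table::fwrite(ga, file.path(out_dir, "grand_average.csv"))
    }
    list(session = session, events = events, conc = conc, hdr = hdr,
         hdr_summary = hdr_summary, grand_average = ga)
  } else if (mode == "cohort") {
    protocol <- config$protocol %||% protocol_spec()
    ev <- simulate_hdr_events(
      n_participants = config$n_participants %||% 26,
      protocol = protocol,
      hrf = config$hrf %||% hrf_params(),
      sigma_participant = config$sigma_participant %||% 0.7,
      sigma_event = config$sigma_event %||% 2.0,
      seed = seed
    )
    hdr_summary <- aggregate_hdr(
      ev, swallows_per_segment = protocol$swallows_per_position_per_block)
    model <- backward_eliminate(hdr_summary,
                                alpha = config$alpha %||% 0.05)
    contrasts <- if ("position" %in% model$retained) {
      tukey_contrasts(model, "position")
    } else NULL
    if (!is.null(out_dir)) {
      data.table::fwrite(hdr_summary, file.path(out_dir, "hdr_summary.csv"))
      report <- list(
        retained = model$retained,
        elimination_path = model$path,
        coefficients = model$coefficients,
        contrasts = if (!is.null(contrasts)) contrasts$contrasts else NULL,
        emmeans = if (!is.null(contrasts)) contrasts$emmeans else NULL,
        alpha = model$alpha,
        df_method = model$df_method,
        seed = seed
      )
      jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", force = TRUE)
    }
    list(events = ev, hdr_summary = hdr_summary, model = model,
         contrasts = contrasts)
  } else {
    stop(sprintf("Unknown pipeline mode `%s`.", mode), call. = FALSE)
  }
}
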