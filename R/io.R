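# File formats: respiratory traces as 2-column TSV with a `# modality:`
# header, phase series as 4-column TSV, phantom volumes as NIfTI-1 with a
# ground-truth JSON sidecar, ratings/condition tables as CSV, study config
# as YAML.

#' Write / read a respiratory trace as TSV
#'
#' Two tab-separated columns `time_s`, `amplitude`, preceded by comment
#' header lines `# modality:`, `# subject_id:` and `# fs:`.
#'
#' @param signal A `resp_signal` tibble.
#' @param path Output file path.
#' @return `write_signal_tsv` returns `path` invisibly; `read_signal_tsv`
#'   returns a `resp_signal`.
#' @export
write_signal_tsv <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# modality: ", attr(signal, "modality", exact = TRUE) %||% "camera"),
    paste0("# subject_id: ", attr(signal, "subject_id", exact = TRUE) %||% "s01"),
    paste0("# fs: ", format(signal_fs(signal), digits = 12)),
    "time_s\tamplitude"
  ), con)
  utils::write.table(signal[, c("time_s", "amplitude")], con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                          sep = "\t")
  fs_txt <- get_field("fs", NA)
  resp_signal(
    df$time_s, df$amplitude,
    fs = if (is.na(fs_txt)) NULL else as.numeric(fs_txt),
    modality = get_field("modality", "camera"),
    subject_id = get_field("subject_id", "s01")
  )
}

#' Write / read a phase series as TSV
#'
#' Columns `time_s`, `amplitude`, `bin`, `accepted` (0/1), tab-separated
#' with a header row.
#'
#' @param phase A `resp_phase` tibble.
#' @param path File path.
#' @return `write_phase_tsv` returns `path` invisibly; `read_phase_tsv`
#'   returns a `resp_phase` tibble.
#' @export
write_phase_tsv <- function(phase, path) {
  df <- dplyr::mutate(phase, accepted = as.integer(.data$accepted))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_tsv
#' @export
read_phase_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- tibble(
    time_s = df$time_s, amplitude = df$amplitude,
    bin = as.integer(df$bin), accepted = df$accepted > 0
  )
  class(out) <- c("resp_phase", class(out))
  attr(out, "n_bins") <- 100L
  out
}

#' Write / read a phantom volume as NIfTI-1 with a JSON sidecar
#'
#' The 4D magnitude image goes to `<path>` (NIfTI-1); the generating
#' specification (including the ground-truth edge width) goes to
#' `<path>.json`.
#'
#' @param volume A `phantom_volume`.
#' @param path Output path, e.g. `"phantom.nii.gz"`.
#' @return `write_phantom_nifti` returns `path` invisibly;
#'   `read_phantom_nifti` returns a `phantom_volume` (with `spec = NULL` if
#'   no sidecar is found).
#' @export
write_phantom_nifti <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume$data), path)
  spec <- unclass(volume$spec)
  jsonlite::write_json(spec, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  spec <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    spec <- structure(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                      class = "phantom_spec")
  }
  structure(list(data = arr, spec = spec), class = "phantom_volume")
}

#' Read a study configuration from YAML
#'
#' The YAML must carry a top-level `seed` key; remaining keys override
#' [study_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("study config must have a top-level `seed` key.")
  do.call(study_config, cfg)
}
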