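.modality_suffixes <- c(t1 = "_t1", t1ce = "_t1ce", t2 = "_t2",
                        flair = "_flair")

#' Read a subject directory of NIfTI modalities as one sample
#'
#' Expects one NIfTI file per modality with the conventional suffixes
#' `_t1`, `_t1ce`, `_t2`, `_flair` (`.nii` or `.nii.gz`); channels are
#' stacked in that fixed order.  An optional `_seg` file is read as the
#' ground-truth mask.  Header/affine metadata of the first modality is
#' kept so masks can be written back aligned.
#'
#' @param path Subject directory.
#' @param label Optional `"HGG"`/`"LGG"` label.
#' @return A sample list: `volume` (4D array), `label`, `mask` (or
#'   `NULL`), `split`, `case_id`, `reference` (NIfTI header carrier).
#' @export
read_case <- function(path, label = NA_character_) {
  if (!dir.exists(path)) stop("read_case: no such directory: ", path)
  find_one <- function(suffix) {
    hits <- list.files(path, pattern = paste0(suffix, "\\.nii(\\.gz)?$"),
                       full.names = TRUE)
    if (length(hits) == 0L) {
      stop(sprintf("read_case: missing modality file with suffix '%s' in %s",
                   suffix, path))
    }
    hits[1]
  }
  imgs <- lapply(.modality_suffixes, function(s) RNifti::readNifti(find_one(s)))
  d <- dim(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d)) {
      stop("read_case: modality volumes have inconsistent dims")
    }
  }
  vol <- array(0, dim = c(d, 4L))
  for (i in 1:4) vol[, , , i] <- as.array(imgs[[i]])

  seg_files <- list.files(path, pattern = "_seg\\.nii(\\.gz)?$",
                          full.names = TRUE)
  mask <- if (length(seg_files) > 0L) {
    as.array(RNifti::readNifti(seg_files[1])) > 0
  } else NULL
  list(volume = vol, label = label, mask = mask, split = NA_character_,
       case_id = basename(normalizePath(path)), reference = imgs[[1]])
}

#' Write a sample's channels (and mask) as NIfTI files
#'
#' @param sample A sample list with `volume` (4D) and optionally `mask`.
#' @param dir Output directory (created if missing).
#' @param case_id File-name stem; defaults to the sample's `case_id`.
#' @return Invisibly, the paths written.
#' @export
write_case_nifti <- function(sample, dir, case_id = NULL) {
  if (is.null(case_id)) case_id <- sample$case_id
  if (is.null(case_id) || is.na(case_id)) case_id <- "case"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(.modality_suffixes)) {
    p <- file.path(dir, paste0(case_id, .modality_suffixes[i], ".nii.gz"))
    RNifti::writeNifti(sample$volume[, , , i], p)
    paths <- c(paths, p)
  }
  if (!is.null(sample$mask)) {
    p <- file.path(dir, paste0(case_id, "_seg.nii.gz"))
    RNifti::writeNifti(array(as.integer(sample$mask), dim = dim(sample$mask)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a metrics report as JSON with a CSV twin
#'
#' @param report Named list of scalar metrics (as from
#'   [classification_metrics()], possibly extended).
#' @param path Output `.json` path; a `.csv` with the same stem is written
#'   alongside.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  out <- c(list(schema_version = "1.0"), report)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv_path <- sub("\\.json$", ".csv", path)
  flat <- unlist(out)
  utils::write.csv(
    data.frame(metric = names(flat), value = unname(flat),
               stringsAsFactors = FALSE),
    csv_path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics report written by [write_report()]
#'
#' @param path JSON path.
#' @return Named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.known_config_sections <- c("seed", "out_dir", "verbosity", "cohort",
                            "network", "train", "preprocess", "optimizer")

#' Read and validate a run configuration
#'
#' YAML configuration with sections mirroring the module configs
#' (`cohort`, `network`, `train`, `preprocess`, `optimizer`) plus global
#' `seed`, `out_dir`, `verbosity`.  Unknown top-level keys are rejected
#' (fail fast: metaheuristic runs are expensive to silently misconfigure).
#'
#' @param path YAML file path.
#' @return Named list of the validated sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_config_sections)
  if (length(unknown) > 0L) {
    stop("read_run_config: unknown top-level keys: ",
         paste(unknown, collapse = ", "))
  }
  cfg
}
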