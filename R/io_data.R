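#' Construct an EEG epoch record
#'
#' An `eeg_record` holds one fixed-length, single-channel EEG epoch as a raw
#' amplitude vector together with its provenance. Amplitudes are kept exactly
#' as read: the downstream network consumes raw signals without filtering or
#' unit conversion.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units). Must be
#'   non-empty and finite.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param set_id Set label, e.g. `"A"`--`"E"` for Bonn-style data or
#'   `"F"`--`"H"` for EEG-Epilepsy-style data. Synthetic sets may use class
#'   names.
#' @param dataset_id Dataset identifier, typically `"bonn"`,
#'   `"eeg_epilepsy"` or `"synthetic"`.
#' @param source_path Provenance string (file path or generator tag).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, sampling_rate, set_id = NA_character_,
                       dataset_id = NA_character_, source_path = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("eeg_record: 'samples' must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("eeg_record: 'samples' contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("eeg_record: 'sampling_rate' must be a positive scalar", call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         set_id = as.character(set_id), dataset_id = as.character(dataset_id),
         source_path = as.character(source_path)),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> set %s (%s): %d samples @ %.2f Hz\n",
              x$set_id, x$dataset_id, length(x$samples), x$sampling_rate))
  invisible(x)
}

#' Read one ASCII epoch file
#'
#' Reads a plain-text epoch file with one numeric amplitude per line (the
#' distribution format of the Bonn EEG sets, and the canonical ingestion
#' format of this package for all datasets).
#'
#' @param path Path to the ASCII file.
#' @param expected_length Optional integer; if given, the file must contain
#'   exactly this many samples.
#' @param sampling_rate Sampling rate recorded on the returned epoch
#'   (default 173.61 Hz, the Bonn acquisition rate).
#' @param set_id,dataset_id Labels stored on the returned record.
#' @return An [eeg_record()].
#' @export
read_ascii_epoch <- function(path, expected_length = NULL,
                             sampling_rate = 173.61,
                             set_id = NA_character_,
                             dataset_id = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("read_ascii_epoch: cannot read '%s': no such file", path),
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- line_no[which(is.na(vals))[1L]]
    stop(sprintf("read_ascii_epoch: '%s' line %d is not numeric: '%s'",
                 path, bad, trimws(lines[bad])), call. = FALSE)
  }
  if (length(vals) == 0L) {
    stop(sprintf("read_ascii_epoch: '%s' contains no samples", path),
         call. = FALSE)
  }
  if (!is.null(expected_length) && length(vals) != expected_length) {
    stop(sprintf(
      "read_ascii_epoch: '%s' has %d samples, expected %d",
      path, length(vals), as.integer(expected_length)), call. = FALSE)
  }
  eeg_record(vals, sampling_rate, set_id = set_id, dataset_id = dataset_id,
             source_path = path)
}

#' Write one epoch back to ASCII
#'
#' Inverse of [read_ascii_epoch()]: one sample per line, full double
#' precision, so a round trip reproduces the samples exactly.
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_epoch <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  writeLines(format(record$samples, digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' Load a whole set of epoch files from a directory
#'
#' Every file in `directory` is read as one epoch. Files are taken in
#' lexicographic order so that record order (and hence cross-validation
#' fold membership) is reproducible across platforms.
#'
#' @param directory Directory containing one ASCII epoch file per record.
#' @param set_id Set label stamped on every record.
#' @param expected_length,sampling_rate,dataset_id Passed through to
#'   [read_ascii_epoch()].
#' @param pattern Optional filename regexp filter (default: all files).
#' @return List of [eeg_record()] objects.
#' @export
load_set <- function(directory, set_id, expected_length = NULL,
                     sampling_rate = 173.61, dataset_id = NA_character_,
                     pattern = NULL) {
  if (!dir.exists(directory)) {
    stop(sprintf("load_set: directory '%s' does not exist", directory),
         call. = FALSE)
  }
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- sort(files, method = "radix")  # locale-independent ordering
  if (length(files) == 0L) {
    stop(sprintf("load_set: directory '%s' contains no epoch files", directory),
         call. = FALSE)
  }
  lapply(files, read_ascii_epoch, expected_length = expected_length,
         sampling_rate = sampling_rate, set_id = set_id,
         dataset_id = dataset_id)
}

#' Define an experimental case
#'
#' A case maps named classes to disjoint groups of sets, e.g. seizure
#' detection as `{A,B,C,D}` vs `{E}`.
#'
#' @param case_id Case identifier string.
#' @param class_groups Named list; names are class names, values are
#'   character vectors of member set ids. Groups must be disjoint.
#' @param dataset_id Dataset the case belongs to.
#' @return Object of class `case_definition`.
#' @export
case_definition <- function(case_id, class_groups, dataset_id) {
  stopifnot(is.list(class_groups), length(names(class_groups)) ==
              length(class_groups))
  members <- unlist(class_groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("case_definition: member sets overlap between classes", call. = FALSE)
  }
  if (!length(class_groups) %in% c(2L, 3L, 5L)) {
    stop("case_definition: number of classes must be 2, 3 or 5", call. = FALSE)
  }
  structure(list(case_id = case_id, class_groups = class_groups,
                 dataset_id = dataset_id),
            class = "case_definition")
}

#' @export
print.case_definition <- function(x, ...) {
  grp <- vapply(x$class_groups, paste, "", collapse = "")
  cat(sprintf("<case %s> [%s] %s\n", x$case_id, x$dataset_id,
              paste(grp, collapse = " vs. ")))
  invisible(x)
}

#' The 17 built-in experimental cases
#'
#' Twelve cases on the five Bonn sets (A, B: surface recordings from healthy
#' volunteers with eyes open / closed; C, D: interictal intracranial
#' recordings; E: ictal recordings) and five cases on the three
#' EEG-Epilepsy sets (F: ictal; G: interictal; H: preictal, treated as
#' normal). They span binary, ternary and five-class problems, from the
#' classic A vs. E seizure screen to the full A-B-C-D-E separation.
#'
#' @return List of 17 [case_definition()] objects, Bonn cases `"1"`--`"12"`
#'   followed by EEG-Epilepsy cases `"I"`--`"V"`.
#' @export
builtin_cases <- function() {
  b <- function(id, groups) case_definition(id, groups, "bonn")
  e <- function(id, groups) case_definition(id, groups, "eeg_epilepsy")
  list(
    b("1",  list("Normal (eyes open)" = "A", "Ictal" = "E")),
    b("2",  list("Normal (eyes closed)" = "B", "Ictal" = "E")),
    b("3",  list("Normal" = c("A", "B"), "Ictal" = "E")),
    b("4",  list("Interictal" = "C", "Ictal" = "E")),
    b("5",  list("Interictal" = "D", "Ictal" = "E")),
    b("6",  list("Interictal" = c("C", "D"), "Ictal" = "E")),
    b("7",  list("Normal" = "A", "Interictal" = "D")),
    b("8",  list("Non-seizure" = c("A", "B", "C", "D"), "Seizure" = "E")),
    b("9",  list("Normal" = c("A", "B"), "Epileptic" = c("C", "D", "E"))),
    b("10", list("Normal" = "A", "Interictal" = "C", "Ictal" = "E")),
    b("11", list("Normal" = c("A", "B"), "Interictal" = c("C", "D"),
                 "Ictal" = "E")),
    b("12", list("Normal (eyes open)" = "A", "Normal (eyes closed)" = "B",
                 "Interictal (C)" = "C", "Interictal (D)" = "D",
                 "Ictal" = "E")),
    e("I",   list("Ictal" = "F", "Interictal" = "G")),
    e("II",  list("Ictal" = "F", "Preictal" = "H")),
    e("III", list("Interictal" = "G", "Preictal" = "H")),
    e("IV",  list("Seizure" = "F", "Seizure-free" = c("G", "H"))),
    e("V",   list("Ictal" = "F", "Interictal" = "G", "Preictal" = "H"))
  )
}

#' Construct a labeled dataset
#'
#' @param records List of [eeg_record()] objects sharing one epoch length.
#' @param labels Integer class indices (1-based into `class_names`).
#' @param class_names Ordered character vector of class names.
#' @param dataset_id Dataset identifier.
#' @return Object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(records, labels, class_names,
                            dataset_id = NA_character_) {
  labels <- as.integer(labels)
  if (length(records) != length(labels)) {
    stop("labeled_dataset: records and labels differ in length", call. = FALSE)
  }
  if (length(records) == 0L) {
    stop("labeled_dataset: empty dataset", call. = FALSE)
  }
  if (any(labels < 1L | labels > length(class_names))) {
    stop("labeled_dataset: labels must index class_names", call. = FALSE)
  }
  lens <- vapply(records, function(r) length(r$samples), 1L)
  if (length(unique(lens)) != 1L) {
    stop("labeled_dataset: records have differing epoch lengths", call. = FALSE)
  }
  structure(list(records = records, labels = labels,
                 class_names = as.character(class_names),
                 dataset_id = dataset_id),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_along(x$class_names),
                      labels = x$class_names))
  cat(sprintf("<labeled_dataset> %d epochs x %d samples, %d classes\n",
              length(x$records), length(x$records[[1L]]$samples),
              length(x$class_names)))
  print(tab)
  invisible(x)
}

#' Number of epochs in a labeled dataset
#' @param x A [labeled_dataset()].
#' @return Integer count.
#' @export
n_epochs <- function(x) length(x$records)

#' Epoch length of a labeled dataset
#' @param x A [labeled_dataset()].
#' @return Integer number of samples per epoch.
#' @export
epoch_length <- function(x) length(x$records[[1L]]$samples)

#' Subset a labeled dataset by record index
#' @param x A [labeled_dataset()].
#' @param idx Integer indices of records to keep.
#' @return A [labeled_dataset()] with the selected records, class names
#'   unchanged.
#' @export
subset_dataset <- function(x, idx) {
  labeled_dataset(x$records[idx], x$labels[idx], x$class_names, x$dataset_id)
}

#' Assemble the dataset for one experimental case
#'
#' Concatenates the member sets of each class, in class order, and assigns
#' integer labels. Record order inside a set is preserved, so the result is
#' deterministic given deterministic set loading.
#'
#' @param records_by_set Named list mapping set id to a list of
#'   [eeg_record()] objects (e.g. from [load_set()]).
#' @param case A [case_definition()].
#' @return A [labeled_dataset()] whose `class_names` come from the case.
#' @export
assemble_case <- function(records_by_set, case) {
  stopifnot(inherits(case, "case_definition"))
  missing_sets <- setdiff(unlist(case$class_groups), names(records_by_set))
  if (length(missing_sets) > 0L) {
    stop(sprintf("assemble_case: case %s requires set(s) %s not present",
                 case$case_id, paste(missing_sets, collapse = ", ")),
         call. = FALSE)
  }
  records <- list()
  labels <- integer(0)
  for (k in seq_along(case$class_groups)) {
    for (s in case$class_groups[[k]]) {
      recs <- records_by_set[[s]]
      records <- c(records, recs)
      labels <- c(labels, rep.int(k, length(recs)))
    }
  }
  labeled_dataset(records, labels, names(case$class_groups), case$dataset_id)
}

#' Serialize a labeled dataset to CSV (+ JSON sidecar)
#'
#' One row per record: `record`, `set_id`, `label`, then the samples
#' `s1..sL`. A JSON sidecar stores class names and dataset metadata.
#'
#' @param x A [labeled_dataset()].
#' @param csv_path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @param case Optional [case_definition()] recorded in the sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_labeled_dataset <- function(x, csv_path, case = NULL) {
  stopifnot(inherits(x, "labeled_dataset"))
  mat <- t(vapply(x$records, function(r) r$samples,
                  numeric(epoch_length(x))))
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  df <- data.frame(record = seq_len(nrow(mat)),
                   set_id = vapply(x$records, function(r) r$set_id, ""),
                   label = x$labels, check.names = FALSE)
  utils::write.csv(cbind(df, as.data.frame(mat)), csv_path,
                   row.names = FALSE)
  meta <- list(dataset_id = x$dataset_id, class_names = x$class_names,
               n_records = n_epochs(x), epoch_length = epoch_length(x),
               sampling_rate = x$records[[1L]]$sampling_rate)
  if (!is.null(case)) {
    meta$case <- list(case_id = case$case_id,
                      class_groups = case$class_groups)
  }
  jsonlite::write_json(meta, sub("\\.csv$", ".json", csv_path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(csv_path)
}
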