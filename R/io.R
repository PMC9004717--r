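#' Read a longitudinal trial from two CSV files
#'
#' Loads the long-format surrogate file (one row per subject-visit) and
#' the per-subject endpoint file, applies an optional column-name mapping,
#' validates, and returns a [trial_dataset()]. Malformed rows (non-numeric
#' week or surrogate, endpoint or arm outside \{0, 1\}, duplicated
#' subject-week pairs) are reported with their file line numbers.
#'
#' @param surrogate_path CSV with (mapped) columns `subject_id`, `arm`,
#'   `week`, `surrogate`.
#' @param endpoint_path CSV with (mapped) columns `subject_id`,
#'   `endpoint`; an `arm` column here is accepted and cross-checked.
#' @param mapping named character vector translating the required names to
#'   the file's column names, e.g. `c(week = "visit_week")`.
#' @return A [trial_dataset()].
#' @export
read_trial_csv <- function(surrogate_path, endpoint_path,
                           mapping = character(0)) {
  sv <- read_mapped_csv(surrogate_path, c("subject_id", "arm", "week", "surrogate"),
                        mapping)
  ep <- read_mapped_csv(endpoint_path, c("subject_id", "endpoint"), mapping,
                        optional = "arm")
  check_numeric_col(sv, "week", surrogate_path)
  check_numeric_col(sv, "surrogate", surrogate_path)
  arm_by_subject <- tapply(sv$arm, sv$subject_id, function(a) {
    u <- unique(a)
    if (length(u) != 1L) NA else u
  })
  if (anyNA(arm_by_subject)) {
    bad <- names(arm_by_subject)[is.na(arm_by_subject)]
    stop("inconsistent arm within subject(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  subjects <- data.frame(subject_id = names(arm_by_subject),
                         arm = as.numeric(arm_by_subject))
  subjects <- merge(subjects, ep[c("subject_id", "endpoint")],
                    by = "subject_id", all.x = TRUE)
  if (anyNA(subjects$endpoint)) {
    bad <- subjects$subject_id[is.na(subjects$endpoint)]
    stop("no endpoint for subject(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  data <- trial_dataset(subjects, sv[c("subject_id", "week", "surrogate")])
  message(sprintf("read %d subjects, %d visit rows from %s",
                  nrow(subjects), nrow(sv), surrogate_path))
  data
}

read_mapped_csv <- function(path, required, mapping, optional = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (std in intersect(names(mapping), c(required, optional))) {
    src <- mapping[[std]]
    if (src %in% names(df)) names(df)[names(df) == src] <- std
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

check_numeric_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad)) {
    stop("non-numeric '", col, "' in ", path, " at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  invisible(v)
}

#' Write a trial dataset to the two-CSV layout
#'
#' Inverse of [read_trial_csv()]: writes the long-format surrogate file
#' and the per-subject endpoint file. Reading the pair back reproduces the
#' dataset.
#'
#' @param data a [trial_dataset()].
#' @param surrogate_path,endpoint_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_trial_csv <- function(data, surrogate_path, endpoint_path) {
  stopifnot(inherits(data, "trial_data"))
  long <- merge(data$visits, data$subjects[c("subject_id", "arm")],
                by = "subject_id")
  long <- long[order(long$subject_id, long$week),
               c("subject_id", "arm", "week", "surrogate")]
  utils::write.csv(long, surrogate_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data$subjects[c("subject_id", "arm", "endpoint")],
                   endpoint_path, row.names = FALSE, quote = FALSE)
  invisible(c(surrogate_path, endpoint_path))
}

#' Write a surrogacy report as CSV plus a text rendering
#'
#' Writes one row per design with paired (MI, ITMA) columns per entropy
#' order, full precision, preceded by provenance comment lines (config
#' hash, seed, package version). A human-readable table rounded to 4
#' decimals is written alongside (`<path>.txt`). [read_report()] restores
#' the CSV values exactly.
#'
#' @param report a `"surrogacy_report"` from [design_sweep()].
#' @param path output CSV path.
#' @param measure which measure to tabulate: `"ts"` for
#'   \eqn{I_\alpha(T,S|Z)}, `"tz"` for the Prentice \eqn{I_\alpha(T,Z|S)},
#'   or `"both"`.
#' @return Invisibly, the wide data.frame written.
#' @export
write_report <- function(report, path, measure = c("both", "ts", "tz")) {
  stopifnot(inherits(report, "surrogacy_report"), nrow(report) > 0)
  measure <- match.arg(measure)
  cols <- switch(measure,
                 ts = c(mi = "mi_TS_given_Z", itma = "itma_TS"),
                 tz = c(mi = "mi_TZ_given_S", itma = "itma_TZ"),
                 both = c(mi_TS = "mi_TS_given_Z", itma_TS = "itma_TS",
                          mi_TZ = "mi_TZ_given_S", itma_TZ = "itma_TZ"))
  alphas <- sort(unique(report$alpha))
  designs <- unique(report$design)
  wide <- data.frame(design = designs, stringsAsFactors = FALSE)
  for (a in alphas) {
    sub <- report[report$alpha == a, ]
    sub <- sub[match(designs, sub$design), ]
    for (nm in names(cols)) {
      wide[[sprintf("%s_alpha%s", nm, format(a))]] <- sub[[cols[[nm]]]]
    }
  }
  meta <- attr(report, "meta")
  prov <- c(
    sprintf("# hcsurrogacy %s", as.character(utils::packageVersion("hcsurrogacy"))),
    sprintf("# seed: %s", format(meta$seed)),
    sprintf("# arms: control %d, treatment %d", meta$n_control, meta$n_treatment),
    sprintf("# config hash: %s", report_hash(report)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  fmt <- wide
  num <- vapply(fmt, is.numeric, logical(1))
  # %.17g survives the write/parse round trip bit for bit
  fmt[num] <- lapply(fmt[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  utils::write.csv(fmt, con, row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  invisible(wide)
}

# order-insensitive content hash of the numeric payload
report_hash <- function(report) {
  payload <- paste(
    capture_digits(report$design),
    capture_digits(report$alpha),
    capture_digits(report$mi_TS_given_Z),
    capture_digits(report$mi_TZ_given_S), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(payload) * seq_along(utf8ToInt(payload))) %% .Machine$integer.max)
}

capture_digits <- function(x) paste(format(x, digits = 15), collapse = ",")

#' Read back a report CSV written by [write_report()]
#'
#' @param path CSV path.
#' @return The wide data.frame, numeric values at full precision.
#' @export
read_report <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML or JSON
#'
#' A run configuration drives the command-line workflow: entropy orders
#' (`alphas`), visit-schedule `designs` (list of week vectors), `seed`,
#' permutation count (`n_perm`), and an optional column-name `mapping`
#' for input CSVs.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
  cfg$alphas <- as.numeric(cfg$alphas %||% c(0.5, 1, 2))
  if (any(cfg$alphas <= 0)) stop("alphas must be positive", call. = FALSE)
  cfg$designs <- lapply(cfg$designs %||% list(c(0, 24, 48, 72, 96)), as.numeric)
  cfg$seed <- as.integer(cfg$seed %||% 20220131L)
  cfg$n_perm <- as.integer(cfg$n_perm %||% 200L)
  cfg$mapping <- unlist(cfg$mapping %||% character(0))
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
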