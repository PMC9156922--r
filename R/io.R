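# File formats: raw-trial delimited text and the per-trial analysis table.
#
# Raw-trial files carry their metadata in `# key=value` header lines
# followed by a delimited table (comma or tab, auto-detected) with a force
# column in N and optional per-leg marker columns in m at their own sample
# rate (marker rows fill the top of the table; the remainder is empty).
# Numbers are written with 17 significant digits so write -> read is an
# identity at full double precision.

#' Pipeline configuration defaults
#'
#' Collects the tunable constants of the processing chain in one validated
#' list. The defaults are the conventional values for treadmill running
#' analysis: fourth-order zero-phase Butterworth filtering at 30 Hz (force)
#' and 6 Hz (markers), a 20 N contact-detection threshold, 50 ms minimum
#' contact and 20 ms minimum aerial debounce, a 16-step analysis window,
#' and g = 9.81 m s^-2.
#'
#' @param force_cutoff,marker_cutoff low-pass cut-offs in Hz.
#' @param filter_order Butterworth order per pass.
#' @param threshold contact-detection threshold in N.
#' @param min_contact,min_aerial debounce durations in s.
#' @param detect_on which force signal the contact threshold is applied to:
#'   `"raw"` (drift-corrected, unfiltered; the default — zero-phase low-pass
#'   filtering smears sharp stance onsets by several samples, which biases
#'   contact times) or `"filtered"`.
#' @param window analysis window in steps, or `"all"`.
#' @param min_steps minimum usable steps per leg per trial.
#' @param saturation_min_run consecutive saturated samples that flag a trial.
#' @param g gravitational acceleration in m s^-2.
#' @param speeds analysed speed set in m s^-1.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(force_cutoff = 30, marker_cutoff = 6, filter_order = 4L,
                       threshold = 20, min_contact = 0.05, min_aerial = 0.02,
                       detect_on = c("raw", "filtered"),
                       window = 16L, min_steps = 4L, saturation_min_run = 3L,
                       g = 9.81, speeds = 3:7) {
  detect_on <- match.arg(detect_on)
  check_scalar(force_cutoff, "force_cutoff", positive = TRUE)
  check_scalar(marker_cutoff, "marker_cutoff", positive = TRUE)
  check_scalar(threshold, "threshold", positive = TRUE)
  check_scalar(min_contact, "min_contact", positive = TRUE)
  check_scalar(min_aerial, "min_aerial", positive = TRUE)
  check_scalar(g, "g", positive = TRUE)
  structure(list(force_cutoff = force_cutoff, marker_cutoff = marker_cutoff,
                 filter_order = as.integer(filter_order), threshold = threshold,
                 min_contact = min_contact, min_aerial = min_aerial,
                 detect_on = detect_on,
                 window = window, min_steps = as.integer(min_steps),
                 saturation_min_run = as.integer(saturation_min_run),
                 g = g, speeds = speeds),
            class = "run_config")
}

.fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write / read a raw trial file
#'
#' @param grf a [grf_trial()].
#' @param markers a [marker_trial()] or `NULL`.
#' @param path file path.
#' @param delim delimiter, `","` or `"\t"` (reading auto-detects).
#' @return `write_raw_trial()` returns `path` invisibly; `read_raw_trial()`
#'   returns a list with `grf` and `markers` (`NULL` when the file has no
#'   marker columns).
#' @export
write_raw_trial <- function(grf, markers = NULL, path, delim = ",") {
  stopifnot(inherits(grf, "grf_trial"))
  meta <- c(subject = grf$subject, rsp_model = grf$rsp_model,
            stiffness_cat = grf$stiffness_cat,
            height_offset_cm = .fmt(grf$height_offset_cm),
            speed_mps = .fmt(grf$belt_speed),
            body_mass_kg = .fmt(grf$body_mass),
            sample_rate_hz = .fmt(grf$sample_rate),
            saturation_level_n = if (is.null(grf$saturation_level)) ""
                                 else .fmt(grf$saturation_level))
  if (!is.null(markers))
    meta <- c(meta, marker_sample_rate_hz = .fmt(markers$sample_rate))
  lines <- sprintf("# %s=%s", names(meta), unname(meta))
  n <- length(grf$force)
  cols <- list(force = .fmt(grf$force))
  if (!is.null(markers)) {
    padto <- function(x) c(.fmt(x), rep("", max(0L, n - length(x))))[seq_len(max(n, length(x)))]
    cols$marker_affected <- padto(markers$affected)
    cols$marker_unaffected <- padto(markers$unaffected)
    cols$force <- c(cols$force, rep("", length(cols$marker_affected) - n))
  }
  body <- do.call(paste, c(cols, sep = delim))
  writeLines(c(lines, paste(names(cols), collapse = delim), body), path)
  invisible(path)
}

#' @rdname write_raw_trial
#' @export
read_raw_trial <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  need <- c("speed_mps", "body_mass_kg", "sample_rate_hz")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_("missing metadata: %s", paste(miss, collapse = ", "))
  body <- lines[!hdr]
  delim <- if (grepl("\t", body[1])) "\t" else ","
  cn <- strsplit(body[1], delim, fixed = TRUE)[[1]]
  cells <- strsplit(body[-1], delim, fixed = TRUE)
  tab <- lapply(seq_along(cn), function(j)
    vapply(cells, function(r) if (j <= length(r)) r[j] else "", ""))
  names(tab) <- cn
  if (!"force" %in% cn) stop_("no `force` column in %s", path)
  parse_num <- function(x, col) {
    keep <- nzchar(x)
    v <- suppressWarnings(as.numeric(x[keep]))
    if (anyNA(v)) {
      bad <- which(keep)[which(is.na(v))[1]]
      stop_("non-numeric %s sample at data line %d", col, bad)
    }
    v
  }
  num <- function(key) as.numeric(meta[[key]])
  grf <- grf_trial(
    force = parse_num(tab$force, "force"),
    sample_rate = num("sample_rate_hz"),
    body_mass = num("body_mass_kg"), belt_speed = num("speed_mps"),
    subject = if (is.null(meta$subject)) NA_character_ else meta$subject,
    rsp_model = if (is.null(meta$rsp_model)) NA_character_ else meta$rsp_model,
    stiffness_cat = if (is.null(meta$stiffness_cat)) NA_character_ else meta$stiffness_cat,
    height_offset_cm = if (is.null(meta$height_offset_cm) ||
                           !nzchar(meta$height_offset_cm)) NA_real_
                       else num("height_offset_cm"),
    saturation_level = if (is.null(meta$saturation_level_n) ||
                           !nzchar(meta$saturation_level_n)) NULL
                       else num("saturation_level_n"))
  markers <- NULL
  if (all(c("marker_affected", "marker_unaffected") %in% cn)) {
    if (is.null(meta$marker_sample_rate_hz))
      stop_("missing metadata: marker_sample_rate_hz")
    markers <- marker_trial(
      affected = parse_num(tab$marker_affected, "marker_affected"),
      unaffected = parse_num(tab$marker_unaffected, "marker_unaffected"),
      sample_rate = num("marker_sample_rate_hz"))
  }
  list(grf = grf, markers = markers)
}

# canonical analysis-table vocabulary
.required_cols <- c("subject", "rsp_model", "stiffness_cat",
                    "height_offset_cm", "speed")
.metric_cols <- c("lc_al", "lc_ul", "favg_al", "favg_ul", "fstep_al",
                  "fstep_ul", "si_lc", "si_favg", "si_fstep")

#' Read a per-trial analysis table
#'
#' Reads a CSV of per-trial gait metrics and covariates into the canonical
#' column vocabulary, applying a user-supplied column mapping for tables
#' with other header names (e.g. a study's deposited supplementary file).
#' Categorical values are normalised (typographic minus signs, case
#' variants of "Rec"), rows flagged saturated/excluded are dropped, and
#' speeds are filtered to the analysed set.
#'
#' @param path CSV file path.
#' @param mapping named character vector mapping canonical names to source
#'   column names, e.g. `c(speed = "Velocity", lc_al = "AL_Lc")`. Canonical
#'   columns already present need no entry.
#' @param speeds allowed speeds in m s^-1; rows at other speeds are dropped
#'   (with a message). `NULL` keeps all.
#' @param drop_excluded drop rows whose `saturated` or `excluded` column is
#'   true/nonzero.
#' @return Data frame of trial rows in canonical columns.
#' @export
read_analysis_table <- function(path, mapping = NULL, speeds = 3:7,
                                drop_excluded = TRUE) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(tab))
        stop_("mapped source column `%s` (for `%s`) not in table", src, canon)
      names(tab)[names(tab) == src] <- canon
    }
  }
  miss <- setdiff(.required_cols, names(tab))
  if (length(miss))
    stop_("required column(s) missing after mapping: %s",
          paste(miss, collapse = ", "))
  tab$rsp_model <- tryCatch(
    normalize_category(tab$rsp_model, RSP_MODELS, "RSP model"),
    error = function(e) {
      bad <- which(!(gsub("−|–", "-", trimws(tab$rsp_model))
                     %in% RSP_MODELS))[1]
      stop_("%s (row %d)", conditionMessage(e), bad)
    })
  tab$stiffness_cat <- tryCatch(
    normalize_category(tab$stiffness_cat, STIFFNESS_CATS, "stiffness category"),
    error = function(e) {
      x <- gsub("−|–", "-", trimws(tab$stiffness_cat))
      x[x %in% c("rec", "REC", "recommended", "Recommended")] <- "Rec"
      stop_("%s (row %d)", conditionMessage(e),
            which(!(x %in% STIFFNESS_CATS))[1])
    })
  for (flag in c("saturated", "excluded")) {
    if (drop_excluded && flag %in% names(tab)) {
      drop <- as.logical(tab[[flag]]) %in% TRUE | tab[[flag]] %in% c(1, "1")
      if (any(drop))
        message(sprintf("dropped %d %s trial(s)", sum(drop), flag))
      tab <- tab[!drop, , drop = FALSE]
    }
  }
  if (!is.null(speeds)) {
    keep <- tab$speed %in% speeds
    if (any(!keep))
      message(sprintf("dropped %d trial(s) outside speeds {%s}",
                      sum(!keep), paste(speeds, collapse = ",")))
    tab <- tab[keep, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write a coefficient table or trial table as CSV
#'
#' Coefficient tables are written with the fixed column order
#' `term, estimate, ci_lo, ci_hi, se, t, p`.
#'
#' @param x an `"rsp_lmm"` fit, its coefficient data frame, or a trial-row
#'   data frame.
#' @param path output path.
#' @export
write_result_csv <- function(x, path) {
  if (inherits(x, "rsp_lmm")) x <- x$coefficients
  if (all(c("term", "estimate") %in% names(x)))
    x <- x[, intersect(c("term", "estimate", "ci_lo", "ci_hi", "se", "t", "p"),
                       names(x)), drop = FALSE]
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
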