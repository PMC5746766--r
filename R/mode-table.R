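#' Vibrational mode tables
#'
#' A `mode_table` holds the normal modes of one molecule (or molecular form):
#' for each mode a 1-based index, the harmonic wavenumber in cm^-1, the Raman
#' scattering activity in A^4/amu as emitted by quantum-chemistry codes, and an
#' optional free-text assignment label such as "CH wagging, ring deformation".
#' Modes are kept sorted by ascending wavenumber. Imaginary frequencies
#' (negative wavenumbers, the signature of a failed geometry optimization) are
#' retained and flagged rather than dropped, so they stay visible downstream.
#'
#' @param wavenumber numeric vector of harmonic wavenumbers (cm^-1).
#' @param activity numeric vector of Raman activities (A^4/amu), `>= 0`.
#' @param assignment optional character vector of assignment labels.
#' @param index optional integer mode numbers; defaults to file order.
#' @param label free-text molecule/form identifier (e.g. `"DA0"`).
#' @param source provenance string (filename and dialect).
#'
#' @return An object of class `mode_table`: a list with elements `modes`
#'   (a data frame with columns `index`, `wavenumber`, `activity`,
#'   `assignment`, `imaginary`), `label` and `source`.
#' @export
mode_table <- function(wavenumber, activity,
                       assignment = NULL, index = NULL,
                       label = "", source = "") {
  n <- length(wavenumber)
  if (length(activity) != n) {
    stop("`wavenumber` and `activity` must have the same length", call. = FALSE)
  }
  if (is.null(assignment)) assignment <- rep(NA_character_, n)
  if (is.null(index)) index <- seq_len(n)
  if (anyDuplicated(index)) {
    stop("mode indices must be unique", call. = FALSE)
  }
  if (any(!is.finite(wavenumber))) {
    stop("wavenumbers must be finite", call. = FALSE)
  }
  if (any(activity < 0, na.rm = TRUE)) {
    stop("Raman activities must be >= 0", call. = FALSE)
  }
  modes <- data.frame(
    index = as.integer(index),
    wavenumber = as.numeric(wavenumber),
    activity = as.numeric(activity),
    assignment = as.character(assignment),
    imaginary = wavenumber < 0,
    stringsAsFactors = FALSE
  )
  modes <- modes[order(modes$wavenumber, modes$index), , drop = FALSE]
  rownames(modes) <- NULL
  structure(
    list(modes = modes, label = label, source = source),
    class = "mode_table"
  )
}

#' @export
print.mode_table <- function(x, ...) {
  n <- nrow(x$modes)
  cat(sprintf("<mode_table> %s: %d mode%s",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              n, if (n == 1) "" else "s"))
  if (n > 0) {
    cat(sprintf(", %g-%g cm-1", min(x$modes$wavenumber), max(x$modes$wavenumber)))
    n_im <- sum(x$modes$imaginary)
    if (n_im > 0) cat(sprintf(" [%d imaginary]", n_im))
  }
  cat("\n")
  if (n > 0) print(utils::head(x$modes, 10L))
  if (n > 10) cat(sprintf("... %d more modes\n", n - 10L))
  invisible(x)
}

#' Number of modes in a table
#' @param table a `mode_table`.
#' @return integer count of modes.
#' @export
n_modes <- function(table) {
  stopifnot(inherits(table, "mode_table"))
  nrow(table$modes)
}

tsv_header <- c("index", "wavenumber_cm-1", "raman_activity", "assignment")

#' Read a vibrational mode table
#'
#' Reads a `mode_table` either from quantum-chemistry frequency output
#' (`dialect = "qm_output"`: plain-text blocks with `Frequencies --` lines and
#' matching `Raman Activ --` lines, up to three mode columns per line) or from
#' a tab-separated file (`dialect = "tsv"`, the format written by
#' [write_mode_table()]). With `dialect = "auto"` the first non-blank lines are
#' sniffed: a line containing `Frequencies --` selects the QM dialect,
#' otherwise TSV is assumed.
#'
#' When a QM log contains several frequency jobs (e.g. an optimization
#' restarted with a tighter grid), the last complete set of frequency blocks
#' wins. A `Frequencies --` line without a matching activity line is a parse
#' error that names the offending line number. Negative (imaginary)
#' frequencies are kept, flagged in the `imaginary` column, and reported with
#' a warning.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect one of `"auto"`, `"qm_output"`, `"tsv"`.
#' @param label molecule/form label stored on the result.
#' @return A [mode_table()].
#' @export
read_mode_table <- function(source, dialect = c("auto", "qm_output", "tsv"),
                            label = "") {
  dialect <- match.arg(dialect)
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- read_text_lines(source)
    src_name <- basename(source)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
    src_name <- "<text>"
  }
  if (dialect == "auto") {
    head_lines <- lines[nzchar(trimws(lines))]
    dialect <- if (any(grepl("Frequencies\\s+--", utils::head(head_lines, 50L)))) {
      "qm_output"
    } else {
      "tsv"
    }
  }
  tab <- switch(dialect,
    qm_output = parse_qm_output(lines, label = label),
    tsv = parse_tsv_modes(lines, label = label)
  )
  tab$source <- paste0(src_name, " [", dialect, "]")
  if (any(tab$modes$imaginary)) {
    warning(sprintf("%d imaginary frequenc%s retained and flagged",
                    sum(tab$modes$imaginary),
                    if (sum(tab$modes$imaginary) == 1) "y" else "ies"),
            call. = FALSE)
  }
  tab
}

# QM logs are ASCII in practice; fall back to Latin-1 if UTF-8 fails.
read_text_lines <- function(path) {
  lines <- tryCatch(
    readLines(path, encoding = "UTF-8", warn = FALSE),
    error = function(e) readLines(path, encoding = "latin1", warn = FALSE)
  )
  if (any(!validEnc(lines))) {
    lines <- iconv(lines, from = "latin1", to = "UTF-8")
  }
  lines
}

# Classic three-modes-per-block frequency output. Each job lists blocks of up
# to 3 modes: a line of mode numbers, "Frequencies --", then property lines
# among which "Raman Activ --" carries the activities. A new job (restarted
# frequency calculation) is detected when the running mode numbering restarts
# at 1; only the last complete job is kept.
parse_qm_output <- function(lines, label = "") {
  freq_re <- "Frequencies\\s+--"
  activ_re <- "Raman\\s+Activ\\s+--"
  jobs <- list()
  cur_wn <- numeric(0)
  cur_ac <- numeric(0)
  pending_freq <- NULL
  pending_line <- NA_integer_
  flush_pending <- function() {
    if (!is.null(pending_freq)) {
      stop(sprintf(
        "malformed block: 'Frequencies' line %d has no matching 'Raman Activ' line",
        pending_line
      ), call. = FALSE)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl(freq_re, ln)) {
      flush_pending()
      vals <- numeric_fields(sub(paste0(".*", freq_re), "", ln))
      if (length(vals) < 1L || length(vals) > 3L) {
        stop(sprintf("malformed 'Frequencies' line %d", i), call. = FALSE)
      }
      # numbering restart at mode 1 means a fresh frequency job
      if (length(cur_wn) > 0L && mode_block_restarts(lines, i)) {
        jobs[[length(jobs) + 1L]] <- list(wn = cur_wn, ac = cur_ac)
        cur_wn <- numeric(0)
        cur_ac <- numeric(0)
      }
      pending_freq <- vals
      pending_line <- i
    } else if (grepl(activ_re, ln)) {
      if (is.null(pending_freq)) {
        stop(sprintf(
          "malformed block: 'Raman Activ' line %d has no preceding 'Frequencies' line",
          i
        ), call. = FALSE)
      }
      vals <- numeric_fields(sub(paste0(".*", activ_re), "", ln))
      if (length(vals) != length(pending_freq)) {
        stop(sprintf(
          "malformed block: 'Raman Activ' line %d carries %d values but 'Frequencies' line %d carries %d",
          i, length(vals), pending_line, length(pending_freq)
        ), call. = FALSE)
      }
      cur_wn <- c(cur_wn, pending_freq)
      cur_ac <- c(cur_ac, vals)
      pending_freq <- NULL
      pending_line <- NA_integer_
    }
  }
  flush_pending()
  if (length(cur_wn) > 0L) {
    jobs[[length(jobs) + 1L]] <- list(wn = cur_wn, ac = cur_ac)
  }
  if (length(jobs) == 0L) {
    return(mode_table(numeric(0), numeric(0), label = label))
  }
  last <- jobs[[length(jobs)]]
  mode_table(last$wn, last$ac, index = seq_along(last$wn), label = label)
}

# Does the mode-number line above this Frequencies line restart at 1? The
# numbering line sits a couple of lines up (a symmetry-label line usually
# intervenes); stop the upward scan at the previous block's property lines.
mode_block_restarts <- function(lines, i) {
  j <- i - 1L
  looked <- 0L
  while (j >= 1L && looked < 6L) {
    txt <- trimws(lines[[j]])
    if (nzchar(txt)) {
      if (grepl("^\\d+(\\s+\\d+)*$", txt)) {
        nums <- as.integer(strsplit(txt, "\\s+")[[1]])
        return(nums[1] == 1L)
      }
      if (grepl("--", txt, fixed = TRUE)) return(FALSE)
      looked <- looked + 1L
    }
    j <- j - 1L
  }
  FALSE
}

numeric_fields <- function(txt) {
  parts <- strsplit(trimws(txt), "\\s+")[[1]]
  parts <- parts[nzchar(parts)]
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals)) {
    stop("non-numeric field in frequency block", call. = FALSE)
  }
  vals
}

parse_tsv_modes <- function(lines, label = "") {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty input: a TSV mode table needs at least a header line",
         call. = FALSE)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header[1:3]), tsv_header[1:3])) {
    stop(sprintf("unrecognized TSV header: %s", lines[[1]]), call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0L) {
    return(mode_table(numeric(0), numeric(0), label = label))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  idx <- integer(length(body))
  wn <- ac <- numeric(length(body))
  asg <- character(length(body))
  for (k in seq_along(body)) {
    f <- fields[[k]]
    if (length(f) < 3L) {
      stop(sprintf("malformed TSV row at line %d", k + 1L), call. = FALSE)
    }
    idx[k] <- suppressWarnings(as.integer(f[1]))
    wn[k] <- suppressWarnings(as.numeric(f[2]))
    ac[k] <- suppressWarnings(as.numeric(f[3]))
    asg[k] <- if (length(f) >= 4L && nzchar(f[4])) f[4] else NA_character_
    if (is.na(idx[k]) || is.na(wn[k]) || is.na(ac[k])) {
      stop(sprintf("non-numeric cell in TSV row at line %d", k + 1L),
           call. = FALSE)
    }
  }
  mode_table(wn, ac, assignment = asg, index = idx, label = label)
}

#' Write a vibrational mode table
#'
#' Serializes a [mode_table()] as tab-separated text with the fixed column
#' order `index`, `wavenumber_cm-1`, `raman_activity`, `assignment`. Floats
#' are written with 17 significant digits so that a write/read round trip
#' reproduces the table exactly.
#'
#' @param table a `mode_table`.
#' @param path optional file path; when `NULL` the TSV text is returned as a
#'   character vector of lines.
#' @return Invisibly, the character vector of lines (also written to `path`
#'   when given).
#' @export
write_mode_table <- function(table, path = NULL) {
  stopifnot(inherits(table, "mode_table"))
  m <- table$modes
  rows <- sprintf("%d\t%s\t%s\t%s",
                  m$index,
                  sprintf("%.17g", m$wavenumber),
                  sprintf("%.17g", m$activity),
                  ifelse(is.na(m$assignment), "", m$assignment))
  out <- c(paste(tsv_header, collapse = "\t"), rows)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
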