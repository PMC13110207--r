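# CSV schemas and shape checks.
#
# Three input tables drive the pipeline:
#   site_agg.csv : site, n_screen, n_enrolled, y_fail, y_window, y_bii,
#                  n_bii, m_shift  (one row per site)
#   labs.csv     : site, lab_value       (one row per enrolled participant)
#   times.csv    : site, screening_time  (one row per screened participant)
# Extra columns are preserved on read and ignored by computation.

.site_agg_cols <- c("site", "n_screen", "n_enrolled", "y_fail",
                    "y_window", "y_bii", "n_bii", "m_shift")
.count_cols <- setdiff(.site_agg_cols, "site")

.long_schema <- list(labs  = c("site", "lab_value"),
                     times = c("site", "screening_time"))

# Count-bound rules shared by read_site_agg (strict) and validate_dataset
# (reporting).  Returns a data.frame(site, rule, message), empty when clean.
check_site_agg <- function(agg) {
  v <- list()
  bad <- function(mask, rule, msg) {
    if (any(mask)) {
      data.frame(site = as.character(agg$site[mask]), rule = rule,
                 message = msg, stringsAsFactors = FALSE)
    } else NULL
  }
  v[[length(v) + 1L]] <- if (anyDuplicated(agg$site)) {
    dup <- unique(agg$site[duplicated(agg$site)])
    data.frame(site = as.character(dup), rule = "unique_site",
               message = "site identifiers must be unique",
               stringsAsFactors = FALSE)
  } else NULL
  for (cl in .count_cols) {
    v[[length(v) + 1L]] <- bad(agg[[cl]] < 0, paste0("nonneg_", cl),
                               sprintf("%s must be >= 0", cl))
  }
  v[[length(v) + 1L]] <- bad(agg$y_fail > agg$n_screen, "y_fail_le_n_screen",
                             "y_fail must not exceed n_screen")
  v[[length(v) + 1L]] <- bad(agg$n_enrolled > agg$n_screen,
                             "n_enrolled_le_n_screen",
                             "n_enrolled must not exceed n_screen")
  v[[length(v) + 1L]] <- bad(agg$y_window > agg$n_enrolled,
                             "y_window_le_n_enrolled",
                             "y_window must not exceed n_enrolled")
  v[[length(v) + 1L]] <- bad(agg$y_bii > agg$n_bii, "y_bii_le_n_bii",
                             "y_bii must not exceed n_bii")
  v[[length(v) + 1L]] <- bad(!agg$m_shift %in% c(0, 1), "m_shift_binary",
                             "m_shift must be 0 or 1")
  out <- do.call(rbind, v[!vapply(v, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(site = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE)
  }
  out
}

.parse_counts <- function(df, cols, path) {
  for (cl in cols) {
    x <- df[[cl]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) | num != floor(num))
    if (length(bad)) {
      stopf("%s: column '%s' must hold integer counts (first bad row: %d)",
            basename(path), cl, bad[1L])
    }
    df[[cl]] <- as.integer(num)
  }
  df
}

#' Read a per-site aggregate table
#'
#' Reads `site_agg.csv` (columns `site`, `n_screen`, `n_enrolled`,
#' `y_fail`, `y_window`, `y_bii`, `n_bii`, `m_shift`, order-insensitive),
#' parses the count columns as integers, and checks the count-bound
#' invariants (e.g. `y_fail <= n_screen`).  Extra columns are preserved
#' but ignored by downstream computation.
#'
#' @param path path to a CSV file.
#' @param check error on invariant violations (default `TRUE`).  With
#'   `check = FALSE` the raw typed table is returned so that
#'   [validate_dataset()] can report the violations instead.
#' @return A `data.frame` with one row per site.
#' @export
read_site_agg <- function(path, check = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.site_agg_cols, names(df))
  if (length(missing)) {
    stopf("%s: missing required column(s): %s", basename(path),
          paste(missing, collapse = ", "))
  }
  df$site <- trimws(as.character(df$site))
  df <- .parse_counts(df, .count_cols, path)
  if (check) {
    viol <- check_site_agg(df)
    if (nrow(viol)) {
      stopf("%s: invariant violation(s): %s", basename(path),
            paste(sprintf("[%s] %s: %s", viol$site, viol$rule,
                          viol$message), collapse = "; "))
    }
  }
  df
}

#' Read a long-form participant table
#'
#' `kind = "labs"` reads `(site, lab_value)` records (one per enrolled
#' participant); `kind = "times"` reads `(site, screening_time)` records
#' (one per screened participant, strictly positive days).  Rows are
#' preserved in file order.
#'
#' @param path path to a CSV file.
#' @param kind `"labs"` or `"times"`.
#' @return A two-column `data.frame` (extra columns preserved).
#' @export
read_long_table <- function(path, kind = c("labs", "times")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  cols <- .long_schema[[kind]]
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("%s: missing required column(s): %s", basename(path),
          paste(missing, collapse = ", "))
  }
  df$site <- trimws(as.character(df$site))
  val <- cols[2L]
  num <- suppressWarnings(as.numeric(df[[val]]))
  if (anyNA(num) && nrow(df)) {
    stopf("%s: column '%s' must be numeric (first bad row: %d)",
          basename(path), val, which(is.na(num))[1L])
  }
  df[[val]] <- num
  if (nrow(df) && any(!is.finite(num))) {
    stopf("%s: column '%s' must be finite", basename(path), val)
  }
  if (kind == "times" && nrow(df) && any(num <= 0)) {
    stopf("%s: screening_time must be > 0 (first bad row: %d)",
          basename(path), which(num <= 0)[1L])
  }
  attr(df, "kind") <- kind
  df
}

#' Cross-table consistency checks
#'
#' Reports every site where the number of lab rows differs from
#' `n_enrolled`, the number of time rows differs from `n_screen`, a site
#' appears in `labs`/`times` but not in the aggregate table, or a
#' count-bound invariant of the aggregate table is violated.  Inputs are
#' never mutated and the report is independent of row order.
#'
#' @param agg per-site aggregate table ([read_site_agg()]).
#' @param labs long lab table ([read_long_table()]).
#' @param times long screening-time table.
#' @return An object of class `rbm_validation`: a list with `violations`
#'   (data.frame `site`, `rule`, `message`) and `pass` (`TRUE` iff no
#'   violations).
#' @export
validate_dataset <- function(agg, labs, times) {
  viol <- check_site_agg(agg)
  add <- function(site, rule, message) {
    rbind(viol, data.frame(site = as.character(site), rule = rule,
                           message = message, stringsAsFactors = FALSE))
  }
  lab_n <- table(factor(labs$site, levels = unique(labs$site)))
  for (s in agg$site) {
    nl <- sum(labs$site == s)
    if (nl != agg$n_enrolled[agg$site == s][1L]) {
      viol <- add(s, "lab_rows_eq_n_enrolled",
                  sprintf("lab rows (%d) must equal n_enrolled (%d)", nl,
                          agg$n_enrolled[agg$site == s][1L]))
    }
    nt <- sum(times$site == s)
    if (nt != agg$n_screen[agg$site == s][1L]) {
      viol <- add(s, "time_rows_eq_n_screen",
                  sprintf("time rows (%d) must equal n_screen (%d)", nt,
                          agg$n_screen[agg$site == s][1L]))
    }
  }
  for (s in setdiff(unique(labs$site), agg$site)) {
    viol <- add(s, "orphan_lab_site", "site present in labs but not in site_agg")
  }
  for (s in setdiff(unique(times$site), agg$site)) {
    viol <- add(s, "orphan_time_site", "site present in times but not in site_agg")
  }
  rownames(viol) <- NULL
  structure(list(violations = viol, pass = nrow(viol) == 0L),
            class = "rbm_validation")
}

#' @export
print.rbm_validation <- function(x, ...) {
  if (x$pass) {
    cat("Dataset validation: PASS (no violations)\n")
  } else {
    cat(sprintf("Dataset validation: FAIL (%d violation%s)\n",
                nrow(x$violations), if (nrow(x$violations) == 1) "" else "s"))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Write the three input tables of a trial dataset
#'
#' Writes `site_agg.csv`, `labs.csv`, `times.csv` (and `truth.csv` when
#' ground-truth labels are present, as for simulated trials) into `dir`.
#'
#' @param trial an `rbm_trial` object ([simulate_trial()]) or a list with
#'   elements `site_agg`, `labs`, `times` and optionally `truth`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(site_agg = file.path(dir, "site_agg.csv"),
             labs = file.path(dir, "labs.csv"),
             times = file.path(dir, "times.csv"))
  write.csv(trial$site_agg, paths[["site_agg"]], row.names = FALSE)
  write.csv(trial$labs, paths[["labs"]], row.names = FALSE)
  write.csv(trial$times, paths[["times"]], row.names = FALSE)
  if (!is.null(trial$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    write.csv(trial$truth, paths[["truth"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a trial dataset from a directory
#'
#' Counterpart of [write_trial()]: reads `site_agg.csv`, `labs.csv` and
#' `times.csv` from `dir` and validates their consistency.
#'
#' @param dir directory containing the three CSVs.
#' @param check error when [validate_dataset()] fails (default `TRUE`).
#' @return An `rbm_trial` list with elements `site_agg`, `labs`, `times`
#'   and `validation`.
#' @export
read_trial <- function(dir, check = TRUE) {
  agg <- read_site_agg(file.path(dir, "site_agg.csv"), check = FALSE)
  labs <- read_long_table(file.path(dir, "labs.csv"), "labs")
  times <- read_long_table(file.path(dir, "times.csv"), "times")
  rep <- validate_dataset(agg, labs, times)
  if (check && !rep$pass) {
    stopf("trial dataset failed validation (%d violation(s)); run validate_dataset() for details",
          nrow(rep$violations))
  }
  structure(list(site_agg = agg, labs = labs, times = times,
                 truth = NULL, validation = rep),
            class = "rbm_trial")
}
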