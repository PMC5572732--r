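CSV_SCHEMAS <- list(
  sessions = 1L, choice = 1L, epm = 1L, bal = 1L, traits = 1L,
  criteria = 1L, screening = 1L
)

SESSION_COLUMNS <- c("rat_id", "phase", "session_index", "period",
                     "active_presses", "inactive_presses", "rewards",
                     "shocks")

write_schema_csv <- function(x, path, schema) {
  stopifnot(schema %in% names(CSV_SCHEMAS))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#audtrait %s v%d", schema, CSV_SCHEMAS[[schema]]), con,
             sep = "\n")
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

read_schema_csv <- function(path, schema) {
  stopifnot(schema %in% names(CSV_SCHEMAS))
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#audtrait")) {
    m <- regmatches(first,
                    regexec("^#audtrait ([a-z_]+) v([0-9]+)$", first))[[1]]
    if (length(m) != 3 || m[2] != schema) {
      stop("file ", path, " does not carry an '", schema, "' schema header.",
           call. = FALSE)
    }
    if (as.integer(m[3]) > CSV_SCHEMAS[[schema]]) {
      stop("file ", path, " uses schema version ", m[3],
           " which is newer than the supported v", CSV_SCHEMAS[[schema]],
           "; refusing to read.", call. = FALSE)
    }
  }
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tibble::as_tibble(x)
}

#' Write / read session records
#'
#' CSV with a fixed header, UTF-8 encoding, LF line endings, and a leading
#' schema-version comment line; readers refuse files written under a future
#' schema version. Reading validates the count invariants (non-negative
#' counts, rewards never exceeding active presses, shocks only in punishment
#' sessions) and reports offending row numbers.
#'
#' @param x SessionRecord tibble (see [simulate_sessions()]).
#' @param path File path.
#' @return `write_sessions()` returns the path invisibly; `read_sessions()`
#'   returns a validated tibble.
#' @export
write_sessions <- function(x, path) {
  miss <- setdiff(SESSION_COLUMNS, names(x))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  write_schema_csv(x[SESSION_COLUMNS], path, "sessions")
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  x <- read_schema_csv(path, "sessions")
  if (nrow(x) == 0) {
    warning("empty session file: ", path, call. = FALSE)
    return(x)
  }
  unknown <- setdiff(names(x), SESSION_COLUMNS)
  if (length(unknown) > 0) {
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(SESSION_COLUMNS, names(x))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  counts <- c("active_presses", "inactive_presses", "rewards", "shocks")
  neg <- which(Reduce(`|`, lapply(x[counts], function(v) v < 0)))
  if (length(neg) > 0) {
    stop("negative count(s) at data row(s): ",
         paste(utils::head(neg, 10), collapse = ", "), call. = FALSE)
  }
  over <- which(x$rewards > x$active_presses)
  if (length(over) > 0) {
    stop("rewards exceed active presses at data row(s): ",
         paste(utils::head(over, 10), collapse = ", "), call. = FALSE)
  }
  shock <- which(x$shocks > 0 & x$phase != "punishment_test")
  if (length(shock) > 0) {
    stop("shocks outside punishment sessions at data row(s): ",
         paste(utils::head(shock, 10), collapse = ", "), call. = FALSE)
  }
  x
}

#' Pipeline run configuration
#'
#' Bundles the stage configurations with one root seed and an optional
#' output directory. Serializing with [write_run_config()] and re-running the
#' deserialized configuration reproduces all outputs exactly.
#'
#' @param seed Root integer seed for every stochastic stage.
#' @param cohort A [trait_config()] (its own seed is overridden by `seed`).
#' @param sessions A [session_config()].
#' @param screening A [screening_config()].
#' @param choice A [choice_config()].
#' @param epm An [epm_config()].
#' @param bal A [bal_config()].
#' @param output_dir Optional directory for stage CSV/JSON outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 20170825,
                       cohort = trait_config(seed = seed),
                       sessions = session_config(),
                       screening = screening_config(),
                       choice = choice_config(),
                       epm = epm_config(),
                       bal = bal_config(),
                       output_dir = NULL) {
  cohort$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), cohort = cohort, sessions = sessions,
         screening = screening, choice = choice, epm = epm, bal = bal,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- rapply(unclass(config), unclass, how = "replace")
  # 17 significant digits round-trip IEEE doubles exactly, so a re-run of
  # the serialized configuration is bit-reproducible
  yaml::write_yaml(plain, path, precision = 17)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild <- function(fields, ctor, drop = character(0)) {
    fields <- fields[setdiff(names(fields), c(drop, "nodrug_total_min"))]
    fields <- lapply(fields, function(f) {
      if (is.list(f) && all(vapply(f, function(e) {
        is.atomic(e) && length(e) == 1
      }, logical(1)))) unlist(f) else f
    })
    do.call(ctor, fields)
  }
  run_config(
    seed = raw$seed,
    cohort = rebuild(raw$cohort, trait_config),
    sessions = rebuild(raw$sessions, session_config),
    screening = rebuild(raw$screening, screening_config),
    choice = rebuild(raw$choice, choice_config),
    epm = rebuild(raw$epm, epm_config),
    bal = rebuild(raw$bal, bal_config),
    output_dir = raw$output_dir
  )
}
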