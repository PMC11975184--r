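#' The run-record JSON schema
#'
#' Returns the JSON schema document (as a parsed list) that every persisted
#' cultivation-run record must satisfy.  The schema ships with the package
#' at \code{inst/extdata/run_schema.json} and uses the draft-07 keyword
#' subset \code{type}, \code{required}, \code{properties}, \code{items},
#' \code{minItems}/\code{maxItems}, \code{minimum}/\code{maximum},
#' \code{exclusiveMinimum} and \code{enum}.
#'
#' @return Parsed schema (nested list).
#' @export
run_schema <- function() {
  path <- system.file("extdata", "run_schema.json", package = "choopt")
  if (path == "") path <- file.path("inst", "extdata", "run_schema.json")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Validate a run record against the schema
#'
#' Checks one record (a parsed list or a JSON string) against
#' [run_schema()].  Only schema-conforming records may enter the run
#' database; validation failures are reported with JSON paths so the
#' offending field can be located.
#'
#' @param document A parsed record (list) or a single JSON string.
#' @param schema Schema to validate against (default [run_schema()]).
#'
#' @return A list with elements \code{valid} (logical) and
#'   \code{violations} (data frame with columns \code{path},
#'   \code{message}; zero rows when valid).
#' @examples
#' run <- simulate_run(std_condition(), simulator_params(), seed = 1)
#' validate_record(run_to_record(run))$valid
#' @export
validate_record <- function(document, schema = run_schema()) {
  if (is.character(document)) {
    if (length(document) != 1L) stop_choopt("validate_record: expected a single JSON string")
    document <- tryCatch(jsonlite::fromJSON(document, simplifyVector = FALSE),
                         error = function(e) {
                           stop_choopt("validate_record: unparseable JSON (%s)",
                                       conditionMessage(e))
                         })
  }
  if (!is.list(document)) stop_choopt("validate_record: document must be a list or JSON string")
  violations <- schema_check(document, schema, "$")
  list(valid = nrow(violations) == 0L, violations = violations)
}

# recursive validator for the draft-07 keyword subset used by run_schema()
schema_check <- function(x, schema, path) {
  bad <- function(msg) data.frame(path = path, message = msg, stringsAsFactors = FALSE)
  out <- data.frame(path = character(0), message = character(0), stringsAsFactors = FALSE)

  if (!is.null(schema$type)) {
    ok <- switch(schema$type,
      object = is.list(x) && (length(x) == 0L || !is.null(names(x))),
      array = is.list(x) && is.null(names(x)) || (is.atomic(x) && length(x) != 1L),
      string = is.character(x) && length(x) == 1L,
      number = is.numeric(x) && length(x) == 1L,
      integer = is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x),
      TRUE
    )
    if (!ok) return(bad(sprintf("expected type '%s'", schema$type)))
  }
  if (identical(schema$type, "object")) {
    for (req in unlist(schema$required)) {
      if (!req %in% names(x)) out <- rbind(out, bad(sprintf("missing required key '%s'", req)))
    }
    for (key in names(schema$properties)) {
      if (key %in% names(x)) {
        out <- rbind(out, schema_check(x[[key]], schema$properties[[key]],
                                       paste0(path, ".", key)))
      }
    }
  }
  if (identical(schema$type, "array")) {
    n <- length(x)
    if (!is.null(schema$minItems) && n < schema$minItems) {
      out <- rbind(out, bad(sprintf("fewer than %d items", schema$minItems)))
    }
    if (!is.null(schema$maxItems) && n > schema$maxItems) {
      out <- rbind(out, bad(sprintf("more than %d items", schema$maxItems)))
    }
    if (!is.null(schema$items)) {
      items <- if (is.atomic(x)) as.list(x) else x
      for (i in seq_along(items)) {
        out <- rbind(out, schema_check(items[[i]], schema$items,
                                       sprintf("%s[%d]", path, i - 1L)))
      }
    }
  }
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.null(schema$minimum) && x < schema$minimum) {
      out <- rbind(out, bad(sprintf("%g below minimum %g", x, schema$minimum)))
    }
    if (!is.null(schema$maximum) && x > schema$maximum) {
      out <- rbind(out, bad(sprintf("%g above maximum %g", x, schema$maximum)))
    }
    if (!is.null(schema$exclusiveMinimum) && x <= schema$exclusiveMinimum) {
      out <- rbind(out, bad(sprintf("%g not above exclusive minimum %g",
                                    x, schema$exclusiveMinimum)))
    }
    if (!is.null(schema$enum) && !x %in% unlist(schema$enum)) {
      out <- rbind(out, bad(sprintf("%g not in enum {%s}", x,
                                    paste(unlist(schema$enum), collapse = ","))))
    }
  }
  out
}

#' Convert between runs and plain-list records
#'
#' \code{run_to_record} turns a \code{cho_run} into the nested-list form
#' matching [run_schema()]; \code{record_to_run} is its inverse.  Records
#' round-trip through JSON without loss (modulo key ordering).
#'
#' @param run A \code{cho_run}.
#' @param record A record list as produced by \code{run_to_record} or read
#'   from the run database.
#' @return A record list, or a \code{cho_run}.
#' @export
run_to_record <- function(run) {
  stopifnot(inherits(run, "cho_run"))
  cond <- unclass(run$condition)
  samples <- lapply(seq_len(nrow(run$samples)), function(i) {
    s <- as.list(run$samples[i, ])
    s$day <- as.integer(s$day)
    s
  })
  list(run_id = run$run_id, condition = cond, samples = samples,
       sample_flags = as.list(run$sample_flags), flags = as.list(run$flags),
       metadata = run$metadata)
}

#' @rdname run_to_record
#' @export
record_to_run <- function(record) {
  cond <- do.call(process_condition, record$condition)
  samples <- do.call(rbind, lapply(record$samples, function(s) {
    as.data.frame(s[c("day", "vcd", "viability", "diameter", "glc", "gln", "lac", "titer")])
  }))
  run <- list(run_id = record$run_id, condition = cond, samples = samples,
              sample_flags = as.character(unlist(record$sample_flags)),
              flags = as.character(unlist(record$flags)),
              metadata = record$metadata)
  class(run) <- "cho_run"
  run
}

#' Persist cultivation runs as newline-delimited JSON
#'
#' Each run is stored as one schema-validated JSON document per line.  A
#' flat file of validated documents stands in for a document database:
#' records are findable by \code{run_id}, self-describing and
#' round-trippable.
#'
#' @param runs List of \code{cho_run} objects.
#' @param path File path for the collection.
#' @param validate Validate every record against [run_schema()] before
#'   writing (default TRUE); invalid records abort the write.
#' @return \code{write_runs}: the path, invisibly.  \code{read_runs}: a
#'   list of \code{cho_run} objects.
#' @export
write_runs <- function(runs, path, validate = TRUE) {
  schema <- run_schema()
  lines <- vapply(seq_along(runs), function(i) {
    rec <- run_to_record(runs[[i]])
    if (validate) {
      rep <- validate_record(rec, schema)
      if (!rep$valid) {
        stop_choopt("run %d (%s) fails schema validation: %s", i, rec$run_id,
                    paste(rep$violations$path, rep$violations$message,
                          sep = ": ", collapse = "; "))
      }
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_runs
#' @export
read_runs <- function(path, validate = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  schema <- run_schema()
  lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    if (validate) {
      rep <- validate_record(rec, schema)
      if (!rep$valid) {
        stop_choopt("line %d fails schema validation: %s", i,
                    paste(rep$violations$path, rep$violations$message,
                          sep = ": ", collapse = "; "))
      }
    }
    record_to_run(rec)
  })
}

#' Flatten runs into the model-ready point table
#'
#' Produces one row per (run, day): the nine model inputs (the eight
#' condition setpoints, with \code{-1} as the "none" sentinel, plus process
#' time) and the four KPI outputs evaluated as running statistics over the
#' trajectory up to that day: running maximum VCD, titer at the day,
#' running maximum mean diameter, and the running mean cell-specific
#' productivity ([qp_mean()] over days 1..t; defined as 0 on day 0).
#' Whole-run (day-12) KPIs repeated on every row are available via
#' \code{outputs = "whole_run"}.
#'
#' @param runs List of \code{cho_run} objects.
#' @param outputs \code{"running"} (default) or \code{"whole_run"}.
#' @return A data frame with columns \code{run_id}, the nine inputs
#'   ([input_features()]), the four outputs ([kpi_names()]), and
#'   \code{flags}.
#' @examples
#' runs <- generate_dataset(build_design("STD"), simulator_params(), seed = 1)
#' nrow(flatten_to_points(runs))  # 3 runs x 13 days
#' @export
flatten_to_points <- function(runs, outputs = c("running", "whole_run")) {
  outputs <- match.arg(outputs)
  rows <- lapply(runs, function(run) {
    s <- run$samples
    expected <- 0:12
    if (nrow(s) != length(expected) || any(s$day != expected)) {
      missing <- setdiff(expected, s$day)
      stop_choopt("run %s has missing or irregular days: %s", run$run_id,
                  paste(missing, collapse = ","))
    }
    n <- nrow(s)
    qp_run <- vapply(seq_len(n), function(t) {
      if (t == 1L) 0 else qp_mean(s$titer[1:t], s$vcd[1:t])
    }, numeric(1))
    vcd_max <- cummax(s$vcd)
    diam_max <- cummax(s$diameter)
    if (outputs == "whole_run") {
      vcd_max <- rep(vcd_max[n], n)
      diam_max <- rep(diam_max[n], n)
      titer <- rep(s$titer[n], n)
      qp_run <- rep(qp_run[n], n)
    } else {
      titer <- s$titer
    }
    cond <- run$condition
    data.frame(
      run_id = run$run_id,
      do_setpoint = cond$do_setpoint, ph_setpoint = cond$ph_setpoint,
      gln_start = cond$gln_start, glc_start = cond$glc_start,
      ph_shift_day = as.numeric(cond$ph_shift_day), vcd0 = cond$vcd0,
      feed_start_day = as.numeric(cond$feed_start_day),
      glc_feed_target = cond$glc_feed_target,
      process_time = as.numeric(s$day),
      vcd_max_to_t = vcd_max, titer_at_t = titer,
      diameter_max_to_t = diam_max, qp_mean_to_t = qp_run,
      flags = run$sample_flags,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write point tables as CSV
#'
#' Fixed column order: \code{run_id}, the nine inputs, the four outputs,
#' \code{flags}.
#'
#' @param points Point table from [flatten_to_points()].
#' @param path CSV file path.
#' @return \code{write_points}: the path, invisibly; \code{read_points}:
#'   the point data frame.
#' @export
write_points <- function(points, path) {
  cols <- c("run_id", CHO_INPUT_FEATURES, CHO_KPI_NAMES, "flags")
  utils::write.csv(points[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$flags[is.na(out$flags)] <- ""
  out
}
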