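session_schema_version <- function() "gb-session/1"

required_session_fields <- c("schema", "id", "kind", "condition", "n_blocks",
                             "blocks")
required_test_fields <- c("target_x", "target_y", "q1", "q2", "q3",
                          "x", "y", "distance", "missing")

#' Write a session record to JSON
#'
#' Serializes a session (agent or synthetic human) to one JSON document
#' in the package's session schema. Numbers are written at full
#' precision, so \code{read_session(write_session(x))} reproduces the
#' record exactly; missing trials keep explicit \code{NA} markers, never
#' zeros.
#'
#' @param session A session record.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  x <- session
  attr(x, "ground_truth") <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a session record from JSON
#'
#' @param path Path to a file written by \code{\link{write_session}}.
#' @return A validated session record.
#' @export
read_session <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$schema) || !identical(x$schema, session_schema_version()))
    stop("schema version mismatch in ", path, ": found ",
         if (is.null(x$schema)) "<none>" else x$schema)
  x$blocks <- lapply(x$blocks, function(b) {
    if (is.null(b$test)) stop("missing required field in ", path, ": test")
    rows <- b$test
    fields <- unique(unlist(lapply(rows, names)))
    test <- as.data.frame(lapply(stats::setNames(fields, fields),
                                 function(f) {
      vals <- lapply(rows, function(r) if (is.null(r[[f]])) NA else r[[f]])
      if (f == "missing") vapply(vals, isTRUE, TRUE) else
        vapply(vals, function(v) suppressWarnings(as.numeric(v)), 0)
    }))
    if (!is.null(b$training))
      b$training <- lapply(b$training, function(v)
        if (is.list(v)) unlist(v) else v)
    b$block <- as.integer(b$block)
    b$test <- test
    b
  })
  x$mapping <- if (length(x$mapping)) as.integer(unlist(x$mapping)) else NULL
  x$n_blocks <- as.integer(x$n_blocks)
  validate_session(x, path = path)
  x
}

validate_session <- function(session, path = NULL) {
  where <- if (is.null(path)) "" else paste0(" in ", path)
  miss <- setdiff(required_session_fields, names(session))
  if (length(miss))
    stop("missing required field(s)", where, ": ",
         paste(miss, collapse = ", "))
  if (!session$kind %in% c("agent", "synthetic_human", "imported_human"))
    stop("unknown session kind", where, ": ", session$kind)
  if (length(session$blocks) != session$n_blocks)
    stop("malformed document", where, ": n_blocks = ", session$n_blocks,
         " but ", length(session$blocks), " blocks present")
  for (b in session$blocks) {
    if (is.null(b$test)) stop("missing required field", where, ": test")
    miss <- setdiff(required_test_fields, names(b$test))
    if (length(miss))
      stop("missing required field(s)", where, ": test$",
           paste(miss, collapse = ", test$"))
    bad <- b$test$missing & !is.na(b$test$q1)
    if (any(bad))
      stop("malformed document", where,
           ": missing trials must carry no posture")
  }
  invisible(TRUE)
}

#' Write a population of sessions to a directory
#'
#' One JSON file per session (named after the session id) plus an
#' \code{index.json} with the store metadata.
#'
#' @param population A \code{gb_population} or \code{human_population}
#'   object, or a bare list of session records.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_session_store <- function(population, dir) {
  sessions <- if (is.list(population) && !is.null(population$sessions))
    population$sessions else population
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(sessions))
  for (i in seq_along(sessions)) {
    files[i] <- paste0(sessions[[i]]$id, ".json")
    write_session(sessions[[i]], file.path(dir, files[i]))
  }
  jsonlite::write_json(
    list(schema = session_schema_version(), n_sessions = length(sessions),
         files = files),
    file.path(dir, "index.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read every session in a directory
#'
#' @param dir Directory written by \code{\link{write_session_store}} (or
#'   any directory of schema-conformant session JSON files).
#' @return List of session records.
#' @export
read_session_store <- function(dir) {
  files <- sort(setdiff(list.files(dir, pattern = "\\.json$"), "index.json"))
  if (length(files) == 0) stop("no session files found in ", dir)
  lapply(file.path(dir, files), read_session)
}

#' Import an externally deposited session archive
#'
#' Converts a directory (or zip archive) of third-party session JSON
#' files into the internal schema, driven by a user-supplied field map
#' built from the archive's own format legend. The importer validates
#' the expected composition (by default 20 human and 200 simulation
#' files) and reports, rather than fails on, count mismatches; it also
#' reports the total number of missing human test trials so the value
#' can be checked against the documented one.
#'
#' @param path Directory or .zip file with the deposited JSON files.
#' @param field_map Named list mapping internal field names to the keys
#'   used in the archive: needs \code{condition}, \code{kind},
#'   \code{blocks}, \code{test}, \code{posture} (length-3 key vector or
#'   single key of a 3-vector), \code{target}, \code{missing}; optional
#'   \code{mapping}, \code{id}.
#' @param expected_counts Named vector with expected file counts per
#'   kind.
#' @return List of class \code{"s1_import"}: \code{sessions},
#'   \code{counts}, \code{count_ok}, \code{n_missing_human_trials},
#'   \code{problems}.
#' @export
import_s1_dataset <- function(path, field_map,
                              expected_counts = c(human = 20,
                                                  simulation = 200)) {
  if (grepl("\\.zip$", path)) {
    tmp <- tempfile("s1_")
    utils::unzip(path, exdir = tmp)
    path <- tmp
  }
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE,
                      recursive = TRUE)
  if (length(files) == 0) stop("no JSON files found in ", path)
  need <- c("condition", "kind", "blocks", "test", "posture", "target",
            "missing")
  miss <- setdiff(need, names(field_map))
  if (length(miss))
    stop("unmapped field(s): ", paste(miss, collapse = ", "))
  sessions <- list(); problems <- character()
  n_missing_human <- 0L
  kinds <- character()
  for (f in files) {
    raw <- jsonlite::read_json(f, simplifyVector = TRUE)
    kind_raw <- raw[[field_map$kind]]
    kind <- if (grepl("sim|agent", kind_raw, ignore.case = TRUE))
      "agent" else "imported_human"
    kinds <- c(kinds, if (kind == "agent") "simulation" else "human")
    blocks_raw <- raw[[field_map$blocks]]
    if (is.null(blocks_raw)) {
      problems <- c(problems, paste0(f, ": no '", field_map$blocks,
                                     "' field"))
      next
    }
    if (is.data.frame(blocks_raw))
      blocks_raw <- lapply(seq_len(nrow(blocks_raw)), function(i)
        lapply(blocks_raw, function(col) col[[i]])) # nolint
    blocks <- vector("list", length(blocks_raw))
    for (bi in seq_along(blocks_raw)) {
      tr <- blocks_raw[[bi]][[field_map$test]]
      tr <- if (is.data.frame(tr)) tr else as.data.frame(tr)
      pk <- field_map$posture; tk <- field_map$target
      Q <- if (length(pk) == 3) as.matrix(tr[, pk]) else
        do.call(rbind, tr[[pk]])
      Tg <- if (length(tk) == 2) as.matrix(tr[, tk]) else
        do.call(rbind, tr[[tk]])
      missing <- as.logical(tr[[field_map$missing]])
      E <- matrix(NA_real_, nrow(Q), 2)
      ok <- !missing & stats::complete.cases(Q)
      if (any(ok)) E[ok, ] <- forward_kinematics(Q[ok, , drop = FALSE])
      if (kind == "imported_human") n_missing_human <-
          n_missing_human + sum(missing)
      test <- data.frame(target_x = Tg[, 1], target_y = Tg[, 2],
                         q1 = Q[, 1], q2 = Q[, 2], q3 = Q[, 3],
                         x = E[, 1], y = E[, 2],
                         distance = sqrt((E[, 1] - Tg[, 1])^2 +
                                           (E[, 2] - Tg[, 2])^2),
                         missing = missing)
      test[missing, c("q1", "q2", "q3", "x", "y", "distance")] <- NA_real_
      blocks[[bi]] <- list(block = bi, training = NULL, test = test)
    }
    id <- if (!is.null(field_map$id)) as.character(raw[[field_map$id]]) else
      tools::file_path_sans_ext(basename(f))
    sessions[[length(sessions) + 1]] <- list(
      schema = session_schema_version(), id = id, kind = kind,
      condition = as.character(raw[[field_map$condition]]),
      mapping = if (!is.null(field_map$mapping))
        as.integer(raw[[field_map$mapping]]) else NULL,
      seed = NA_integer_, n_blocks = length(blocks), blocks = blocks)
  }
  counts <- table(kinds)
  count_ok <- all(names(expected_counts) %in% names(counts)) &&
    all(counts[names(expected_counts)] == expected_counts)
  if (!count_ok)
    problems <- c(problems, paste0(
      "file counts ", paste(names(counts), counts, sep = "=",
                            collapse = ", "),
      " differ from expected ",
      paste(names(expected_counts), expected_counts, sep = "=",
            collapse = ", ")))
  structure(list(sessions = sessions, counts = counts,
                 count_ok = count_ok,
                 n_missing_human_trials = n_missing_human,
                 problems = problems),
            class = "s1_import")
}

#' Reproduce the simulation study end to end
#'
#' Chains the pipeline: trains Goal Babbling populations in both
#' conditions, runs the synergy analysis, and writes tidy CSV summaries
#' (population learning curves, variance fractions, solution locations,
#' q2 loadings, summed variance) plus a run log with seed and
#' configuration. All randomness derives from \code{seed}.
#'
#' @param seed Integer base seed.
#' @param out_dir Output directory for the CSV tables; \code{NULL} skips
#'   writing.
#' @param n_agents Agents per condition.
#' @param config A \code{\link{gb_config}} object.
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @return List with both populations, the combined
#'   \code{\link{analyze_sessions}} result and the summary tables.
#' @export
reproduce_study <- function(seed = 1L, out_dir = NULL, n_agents = 100,
                            config = gb_config(),
                            geometry = build_task_geometry()) {
  pop1 <- run_population("H1", n_agents, geometry, config,
                         base_seed = seed)
  pop2 <- run_population("H2", n_agents, geometry, config,
                         base_seed = seed + 10000L)
  an <- analyze_sessions(c(pop1$sessions, pop2$sessions), bin_size = 1,
                         geometry = geometry)
  curves <- rbind(cbind(condition = "H1", population_error_curve(pop1)),
                  cbind(condition = "H2", population_error_curve(pop2)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(curves, file.path(out_dir, "learning_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(an$fractions, file.path(out_dir,
                                             "variance_fractions.csv"),
                     row.names = FALSE)
    utils::write.csv(an$location, file.path(out_dir, "solution_location.csv"),
                     row.names = FALSE)
    utils::write.csv(an$q2, file.path(out_dir, "q2_loading.csv"),
                     row.names = FALSE)
    utils::write.csv(an$variance, file.path(out_dir, "summed_variance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed, n_agents = n_agents,
                              config = unclass(config)[
                                !vapply(config, is.null, TRUE)],
                              timestamp = format(Sys.time())),
                         file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(H1 = pop1, H2 = pop2, analysis = an, curves = curves))
}
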