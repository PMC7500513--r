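#' Session dataset: the canonical data model
#'
#' A session holds every recorded trial of every team, the click events and
#' PAS (Perceptual Awareness Scale) responses, optional avatar trajectories,
#' and the world configuration. Designs may be unbalanced: a team may have
#' fewer recorded trials than the nominal 20.
#'
#' @param events data frame with columns \code{team_id, trial_number, player,
#'   click_time_s, click_position, target, pas}: one row per click. Absent
#'   target/PAS are \code{NA}. PAS responses exist only for clicks, so they
#'   live on the click row.
#' @param trials data frame with columns \code{team_id, trial_number}: the
#'   roster of recorded trials (needed because trials without any click carry
#'   no event row).
#' @param world a \code{\link{world_config}}.
#' @param trajectories optional data frame \code{team_id, trial_number,
#'   time_s, player, avatar_position} with native (unresampled) timestamps;
#'   \code{NULL} for event-only ("trajectory-free") sessions.
#' @return an object of class \code{pc_session}.
#' @export
session_dataset <- function(events, trials, world = world_config(),
                            trajectories = NULL) {
  ds <- structure(list(events = as.data.frame(events),
                       trials = as.data.frame(trials),
                       world = world,
                       trajectories = if (is.null(trajectories)) NULL
                                      else as.data.frame(trajectories)),
                  class = "pc_session")
  validate_session(ds)
  ds
}

empty_events <- function() {
  data.frame(team_id = integer(), trial_number = integer(), player = integer(),
             click_time_s = numeric(), click_position = numeric(),
             target = character(), pas = integer(), stringsAsFactors = FALSE)
}

#' @export
print.pc_session <- function(x, ...) {
  cat("<pc_session>", nrow(x$trials), "trials in",
      length(unique(x$trials$team_id)), "team(s);",
      nrow(x$events), "clicks;",
      if (is.null(x$trajectories)) "trajectory-free\n" else
        sprintf("%d trajectory samples\n", nrow(x$trajectories)))
  invisible(x)
}

#' Validate a session dataset
#'
#' Enforces the structural invariants of the data model: trial roster
#' uniqueness, at most one click per player and trial, click times within the
#' trial duration, positions within the space, PAS in 1..4 and only on click
#' rows, and every event belonging to a rostered trial.
#'
#' @param ds a \code{pc_session}.
#' @return \code{ds}, invisibly; stops with an informative error otherwise.
#' @export
validate_session <- function(ds) {
  ev <- ds$events
  tr <- ds$trials
  w <- ds$world
  need <- c("team_id", "trial_number", "player", "click_time_s",
            "click_position", "target", "pas")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events: missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("team_id", "trial_number") %in% names(tr)))
    stop("trials: need columns team_id, trial_number")
  if (anyDuplicated(tr[c("team_id", "trial_number")]))
    stop("trials: duplicated team_id/trial_number")
  if (nrow(ev)) {
    if (!all(ev$player %in% c(1L, 2L)))
      stop("events: player must be 1 or 2")
    if (anyNA(ev$click_time_s) || anyNA(ev$click_position))
      stop("events: click_time_s/click_position must be present on every row ",
           "(a PAS response without a click is not representable)")
    key <- paste(ev$team_id, ev$trial_number, ev$player)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("events: more than one click for team/trial/player ", d)
    }
    bad <- which(ev$click_time_s < 0 | ev$click_time_s > w$trial_duration)
    if (length(bad))
      stop(sprintf("events row %d: click_time_s %.3f outside [0, %g]",
                   bad[1L], ev$click_time_s[bad[1L]], w$trial_duration))
    bad <- which(ev$click_position < 0 | ev$click_position >= w$space_length)
    if (length(bad))
      stop(sprintf("events row %d: click_position %.3f outside [0, %g)",
                   bad[1L], ev$click_position[bad[1L]], w$space_length))
    badt <- which(!is.na(ev$target) & !ev$target %in% object_kinds())
    if (length(badt))
      stop(sprintf("events row %d: unknown target '%s'",
                   badt[1L], ev$target[badt[1L]]))
    badp <- which(!is.na(ev$pas) & !ev$pas %in% 1:4)
    if (length(badp))
      stop(sprintf("events row %d: pas must be in 1..4", badp[1L]))
    evkey <- paste(ev$team_id, ev$trial_number)
    trkey <- paste(tr$team_id, tr$trial_number)
    orphan <- which(!evkey %in% trkey)
    if (length(orphan))
      stop(sprintf("events row %d: trial %s not in the trial roster",
                   orphan[1L], evkey[orphan[1L]]))
  }
  if (!is.null(ds$trajectories) && nrow(ds$trajectories)) {
    tj <- ds$trajectories
    if (!all(c("team_id", "trial_number", "time_s", "player",
               "avatar_position") %in% names(tj)))
      stop("trajectories: wrong columns")
    if (any(tj$avatar_position < 0 | tj$avatar_position >= w$space_length))
      stop("trajectories: avatar_position outside [0, space_length)")
    if (any(tj$time_s < 0 | tj$time_s > w$trial_duration))
      stop("trajectories: time_s outside [0, trial_duration]")
  }
  invisible(ds)
}

fmt_num <- function(x, digits) {
  out <- ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  sub("^(-?\\d+)\\.?0*$", "\\1", sub("0+$", "", out))
}

fmt_int <- function(x) ifelse(is.na(x), "", format(x, scientific = FALSE, trim = TRUE))

#' Write a session dataset to disk
#'
#' Two formats are supported. \code{"csv"} writes a directory containing
#' \code{events.csv} (one row per click: \code{team_id, trial_number, player,
#' click_time_s, click_position, target, pas}; empty string encodes an absent
#' target or PAS), \code{trials.csv} (the trial roster), \code{world.json}
#' (the world configuration) and, when trajectories are present,
#' \code{trajectories.csv}. \code{"json"} writes a single \code{session.json}
#' mirroring the same content. Output is deterministic: rewriting an
#' unmodified dataset reproduces identical bytes. Timestamps carry
#' millisecond precision; positions six decimals; decimal point, no locale.
#'
#' @param ds a \code{pc_session}.
#' @param path directory (csv) or file path (json).
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(ds, path, format = c("csv", "json")) {
  format <- match.arg(format)
  validate_session(ds)
  ev <- ds$events
  ev <- ev[order(ev$team_id, ev$trial_number, ev$player), , drop = FALSE]
  tr <- ds$trials
  tr <- tr[order(tr$team_id, tr$trial_number), , drop = FALSE]
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    evo <- data.frame(team_id = fmt_int(ev$team_id),
                      trial_number = fmt_int(ev$trial_number),
                      player = fmt_int(ev$player),
                      click_time_s = fmt_num(ev$click_time_s, 3),
                      click_position = fmt_num(ev$click_position, 6),
                      target = ifelse(is.na(ev$target), "", ev$target),
                      pas = fmt_int(ev$pas), stringsAsFactors = FALSE)
    utils::write.csv(evo, file.path(path, "events.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(team_id = fmt_int(tr$team_id),
                                trial_number = fmt_int(tr$trial_number)),
                     file.path(path, "trials.csv"), row.names = FALSE,
                     quote = FALSE)
    writeLines(jsonlite::toJSON(unclass(ds$world), auto_unbox = TRUE,
                                digits = NA),
               file.path(path, "world.json"))
    if (!is.null(ds$trajectories)) {
      tj <- ds$trajectories
      tj <- tj[order(tj$team_id, tj$trial_number, tj$player, tj$time_s), ,
               drop = FALSE]
      tjo <- data.frame(team_id = fmt_int(tj$team_id),
                        trial_number = fmt_int(tj$trial_number),
                        time_s = fmt_num(tj$time_s, 3),
                        player = fmt_int(tj$player),
                        avatar_position = fmt_num(tj$avatar_position, 6),
                        stringsAsFactors = FALSE)
      utils::write.csv(tjo, file.path(path, "trajectories.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  } else {
    obj <- list(world = unclass(ds$world),
                trials = tr,
                events = ev)
    if (!is.null(ds$trajectories)) obj$trajectories <- ds$trajectories
    writeLines(jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                                digits = NA, na = "null", pretty = TRUE),
               path)
  }
  invisible(path)
}

read_csv_strict <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
}

parse_num <- function(x, file, col) {
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("%s line %d: cannot parse %s value '%s'",
                 file, bad[1L] + 1L, col, x[bad[1L]]))
  out
}

#' Read a session dataset from disk
#'
#' Inverse of \code{\link{write_session}}. For \code{"csv"}, \code{path} is a
#' directory containing \code{events.csv} and optionally \code{trials.csv},
#' \code{world.json} and \code{trajectories.csv}; when \code{trials.csv} is
#' absent the roster is inferred as trials 1..max(trial_number) per team.
#' Malformed rows are reported with file and line context; all data-model
#' invariants are checked.
#'
#' @param path directory (csv) or file (json).
#' @param format \code{"csv"} or \code{"json"}.
#' @return a \code{pc_session}.
#' @export
read_session <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    evf <- file.path(path, "events.csv")
    if (!file.exists(evf)) stop("not found: ", evf)
    raw <- read_csv_strict(evf)
    need <- c("team_id", "trial_number", "player", "click_time_s",
              "click_position", "target", "pas")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop(evf, ": missing column(s): ", paste(miss, collapse = ", "))
    ev <- data.frame(
      team_id = as.integer(parse_num(raw$team_id, evf, "team_id")),
      trial_number = as.integer(parse_num(raw$trial_number, evf, "trial_number")),
      player = as.integer(parse_num(raw$player, evf, "player")),
      click_time_s = parse_num(raw$click_time_s, evf, "click_time_s"),
      click_position = parse_num(raw$click_position, evf, "click_position"),
      target = ifelse(raw$target == "", NA_character_, raw$target),
      pas = as.integer(parse_num(raw$pas, evf, "pas")),
      stringsAsFactors = FALSE)
    if (nrow(ev) == 0L) ev <- empty_events()
    wf <- file.path(path, "world.json")
    world <- if (file.exists(wf)) {
      do.call(world_config, jsonlite::fromJSON(wf))
    } else world_config()
    trf <- file.path(path, "trials.csv")
    if (file.exists(trf)) {
      rtr <- read_csv_strict(trf)
      tr <- data.frame(
        team_id = as.integer(parse_num(rtr$team_id, trf, "team_id")),
        trial_number = as.integer(parse_num(rtr$trial_number, trf, "trial_number")))
    } else {
      tr <- infer_roster(ev)
    }
    tjf <- file.path(path, "trajectories.csv")
    tj <- NULL
    if (file.exists(tjf)) {
      rtj <- read_csv_strict(tjf)
      tj <- data.frame(
        team_id = as.integer(parse_num(rtj$team_id, tjf, "team_id")),
        trial_number = as.integer(parse_num(rtj$trial_number, tjf, "trial_number")),
        time_s = parse_num(rtj$time_s, tjf, "time_s"),
        player = as.integer(parse_num(rtj$player, tjf, "player")),
        avatar_position = parse_num(rtj$avatar_position, tjf, "avatar_position"))
    }
    session_dataset(ev, tr, world, tj)
  } else {
    obj <- jsonlite::fromJSON(path)
    world <- do.call(world_config, obj$world)
    ev <- as.data.frame(obj$events)
    if (!nrow(ev)) ev <- empty_events()
    ev$target <- as.character(ev$target)
    ev$pas <- as.integer(ev$pas)
    tr <- as.data.frame(obj$trials)
    tj <- if (!is.null(obj$trajectories)) as.data.frame(obj$trajectories) else NULL
    session_dataset(ev, tr, world, tj)
  }
}

infer_roster <- function(ev) {
  if (!nrow(ev))
    return(data.frame(team_id = integer(), trial_number = integer()))
  do.call(rbind, lapply(split(ev, ev$team_id), function(e) {
    data.frame(team_id = e$team_id[1L],
               trial_number = seq_len(max(e$trial_number)))
  })) -> tr
  rownames(tr) <- NULL
  tr
}
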