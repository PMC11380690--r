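#' Write a session recording to a directory container
#'
#' Plain-text container: `F.tsv` and `Fneu.tsv` (cells x frames,
#' tab-separated) plus `meta.yaml` with the frame rate and identifiers.
#' Round-trips are exact to full float precision.
#'
#' @param rec a `session_recording`
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
write_session <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, file)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  write_mat(rec$F, "F.tsv")
  write_mat(rec$Fneu, "Fneu.tsv")
  meta <- list(frame_rate = rec$frame_rate, mouse_id = rec$mouse_id,
               session_id = rec$session_id, phase = rec$phase,
               task_rule = rec$task_rule,
               n_cells = nrow(rec$F), n_frames = ncol(rec$F))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a session recording from a directory container
#'
#' @param path directory written by [write_session()]
#' @return a `session_recording`
#' @export
read_session <- function(path) {
  for (f in c("meta.yaml", "F.tsv", "Fneu.tsv")) {
    if (!file.exists(file.path(path, f)))
      stop("session container is missing '", f, "'", call. = FALSE)
  }
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  read_mat <- function(file, n_cells) {
    if (n_cells == 0) return(matrix(numeric(0), 0, meta$n_frames))
    as.matrix(utils::read.table(file.path(path, file), sep = "\t",
                                header = FALSE,
                                colClasses = "numeric")) |>
      unname()
  }
  f <- read_mat("F.tsv", meta$n_cells)
  fneu <- read_mat("Fneu.tsv", meta$n_cells)
  if (!all(dim(f) == dim(fneu)))
    stop("F and Fneu shapes differ in container", call. = FALSE)
  if (any(is.na(f)))
    stop("F contains missing values", call. = FALSE)
  structure(list(F = f, Fneu = fneu, frame_rate = meta$frame_rate,
                 mouse_id = meta$mouse_id, session_id = meta$session_id,
                 phase = meta$phase, task_rule = meta$task_rule),
            class = "session_recording")
}

#' Write / read a trial table as TSV
#'
#' Lick timestamps are serialised as a comma-joined string column.
#'
#' @param trials a `trial_table`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_trial_table <- function(trials, file) {
  out <- trials
  out$lick_times <- vapply(trials$lick_times, function(v)
    paste(format(v, digits = 17, trim = TRUE), collapse = ","),
    character(1))
  out$lick_times[out$lick_times == ""] <- NA_character_
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(file)
}

#' @rdname write_trial_table
#' @param file TSV path written by [write_trial_table()]
#' @export
read_trial_table <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$lick_times <- I(lapply(df$lick_times, function(s) {
    if (is.na(s) || s == "") numeric(0)
    else as.numeric(strsplit(s, ",")[[1]])
  }))
  class(df) <- c("trial_table", class(df))
  df
}

#' Cross-session cell-correspondence table
#'
#' @param mouse_id,global_cell_id,session_id,cell_index equal-length
#'   vectors; `cell_index` is the within-session row of the cell
#' @return a validated `tracked_cell_map` data frame
#' @export
tracked_cell_map <- function(mouse_id, global_cell_id, session_id,
                             cell_index) {
  df <- data.frame(mouse_id = mouse_id, global_cell_id = global_cell_id,
                   session_id = session_id, cell_index = cell_index,
                   stringsAsFactors = FALSE)
  key <- paste(df$global_cell_id, df$session_id)
  if (anyDuplicated(key))
    stop("duplicate (global_cell_id, session_id) mapping", call. = FALSE)
  class(df) <- c("tracked_cell_map", class(df))
  df
}

#' Align tracked cells across sessions
#'
#' Returns, for each requested session, the within-session row order that
#' puts the same global cell on the same row everywhere. Cells absent from
#' any requested session are dropped (matched-cell analyses) with a logged
#' count.
#'
#' @param map a `tracked_cell_map`
#' @param session_ids sessions to align (default: all in the map)
#' @return list with `global_cell_ids` (row identity) and `rows` (named
#'   list of per-session index vectors)
#' @export
align_tracked_cells <- function(map, session_ids = NULL) {
  if (is.null(session_ids)) session_ids <- unique(map$session_id)
  unknown <- setdiff(session_ids, map$session_id)
  if (length(unknown) > 0)
    stop("map references no cells for session(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  per_session <- lapply(session_ids, function(s)
    map[map$session_id == s, c("global_cell_id", "cell_index")])
  common <- Reduce(intersect, lapply(per_session, `[[`, "global_cell_id"))
  n_all <- length(unique(map$global_cell_id[map$session_id %in% session_ids]))
  if (length(common) == 0)
    stop("no matched cells across the requested sessions", call. = FALSE)
  if (n_all > length(common))
    message(n_all - length(common),
            " cell(s) dropped: not tracked in every requested session")
  common <- sort(common)
  rows <- lapply(per_session, function(ps)
    ps$cell_index[match(common, ps$global_cell_id)])
  names(rows) <- session_ids
  list(global_cell_ids = common, rows = rows)
}
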