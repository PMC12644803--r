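# Session logs on disk: positions.csv (one row per 120 Hz tick), events.csv
# (one row per collection) and config.json (game configuration + seed).

#' Write a session log to a directory
#'
#' @param session A `ccf_session` from [simulate_dyad()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ccf_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$positions, file.path(dir, "positions.csv"),
                   row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  cfg <- unclass(session$config)
  cfg <- cfg[setdiff(names(cfg), c("hover_ticks", "dt", "target_radius"))]
  jsonlite::write_json(c(cfg, list(seed = session$seed)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session log from a directory
#'
#' Reads `positions.csv`, `events.csv` and `config.json` back into a
#' `ccf_session`. Position samples outside the field (possible in deposited
#' logs that do not clamp the cursor at the border) are clamped to the field
#' bounds with a warning.
#'
#' @param dir Directory written by [write_session()] (or an external log in
#'   the same schema).
#' @return A `ccf_session`.
#' @export
read_session <- function(dir) {
  positions <- utils::read.csv(file.path(dir, "positions.csv"))
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  seed <- meta$seed
  meta <- meta[setdiff(names(meta), "seed")]
  config <- do.call(game_config, meta)

  needed <- c("t_s", "ax_cm", "ay_cm", "bx_cm", "by_cm")
  if (!all(needed %in% names(positions)))
    stop("positions.csv must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  coord <- c("ax_cm", "ay_cm", "bx_cm", "by_cm")
  out_of_field <- vapply(positions[coord], function(v)
    any(v < 0 | v > config$field_side), logical(1L))
  if (any(out_of_field)) {
    warning("out-of-field position samples clamped to the field bounds")
    for (cl in coord)
      positions[[cl]] <- pmin(pmax(positions[[cl]], 0), config$field_side)
  }
  structure(list(positions = positions, events = events, config = config,
                 seed = seed),
            class = "ccf_session")
}
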