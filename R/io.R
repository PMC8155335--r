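# Trajectory serialization: extended XYZ and a LAMMPS-dump-compatible
# dialect, plus observable CSV output.

#' Write a state as one trajectory frame
#'
#' Supported formats: extended XYZ (`species x y z mol` columns with a
#' Lattice/Properties comment line) and a LAMMPS-dump dialect
#' (`id type mol x y z vx vy vz`).
#'
#' @param state A \code{dpd_state}.
#' @param path Output file; opened in append mode when \code{append}.
#' @param format \code{"xyz"} or \code{"dump"}.
#' @param digits Coordinate precision.
#' @param append Append to an existing trajectory file?
#' @return Invisibly, \code{path}.
#' @export
write_frame <- function(state, path, format = c("xyz", "dump"),
                        digits = 6, append = FALSE) {
  format <- match.arg(format)
  n <- n_beads(state)
  labels <- bead_types()[state$type]
  fmtnum <- function(x) formatC(x, digits = digits, format = "g")
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (format == "xyz") {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=species:S:1:pos:R:3:mol:I:1 step=%d',
      fmtnum(state$box[1]), fmtnum(state$box[2]), fmtnum(state$box[3]),
      state$step), con)
    writeLines(paste(labels, fmtnum(state$pos[, 1]), fmtnum(state$pos[, 2]),
                     fmtnum(state$pos[, 3]), state$mol), con)
  } else {
    writeLines(c("ITEM: TIMESTEP", as.character(state$step),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste(0, fmtnum(state$box[1])),
                 paste(0, fmtnum(state$box[2])),
                 paste(0, fmtnum(state$box[3])),
                 "ITEM: ATOMS id type mol x y z vx vy vz"), con)
    writeLines(paste(seq_len(n), state$type, state$mol,
                     fmtnum(state$pos[, 1]), fmtnum(state$pos[, 2]),
                     fmtnum(state$pos[, 3]), fmtnum(state$vel[, 1]),
                     fmtnum(state$vel[, 2]), fmtnum(state$vel[, 3])), con)
  }
  invisible(path)
}

parse_error <- function(path, line, msg) {
  stop(sprintf("%s: parse error at line %d: %s", path, line, msg),
       call. = FALSE)
}

#' Read one trajectory frame
#'
#' Parses the first frame of an extended-XYZ or LAMMPS-dump file written
#' by [write_frame()] (or by an external engine with matching columns).
#' Topology is not stored in these formats; bonds/angles are empty
#' unless a template state is supplied.
#'
#' @param path Input file.
#' @param format \code{"auto"} (sniffed), \code{"xyz"} or \code{"dump"}.
#' @param template Optional \code{dpd_state} supplying topology and
#'   velocities (for XYZ).
#' @return A \code{dpd_state}.
#' @export
read_frame <- function(path, format = c("auto", "xyz", "dump"),
                       template = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) parse_error(path, length(lines), "truncated file")
  if (format == "auto")
    format <- if (grepl("^ITEM: TIMESTEP", lines[1])) "dump" else "xyz"
  if (format == "xyz") {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) parse_error(path, 1, "expected bead count")
    if (length(lines) < n + 2) parse_error(path, length(lines),
                                           "truncated frame body")
    lat <- regmatches(lines[2],
                      regexec('Lattice="([^"]+)"', lines[2]))[[1]]
    if (length(lat) < 2) parse_error(path, 2, "missing Lattice")
    lat_v <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    box <- lat_v[c(1, 5, 9)]
    step <- 0L
    stm <- regmatches(lines[2], regexec("step=(\\d+)", lines[2]))[[1]]
    if (length(stm) == 2) step <- as.integer(stm[2])
    body <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
    ncol_body <- lengths(body)
    if (any(ncol_body < 4))
      parse_error(path, 2 + which(ncol_body < 4)[1], "too few columns")
    m <- do.call(rbind, body)
    type <- m[, 1]
    pos <- matrix(as.numeric(m[, 2:4]), n, 3)
    if (anyNA(pos)) parse_error(path, 3, "non-numeric coordinates")
    mol <- if (ncol(m) >= 5) as.integer(m[, 5]) else integer(n)
    st <- dpd_state(box, pos, vel = if (!is.null(template)) template$vel,
                    type = type, mol = mol,
                    bonds = if (!is.null(template)) template$bonds,
                    angles = if (!is.null(template)) template$angles,
                    step = step)
    return(st)
  }
  # LAMMPS dump dialect
  ts_i <- which(lines == "ITEM: TIMESTEP")[1]
  if (is.na(ts_i)) parse_error(path, 1, "missing ITEM: TIMESTEP")
  step <- as.integer(trimws(lines[ts_i + 1]))
  n_i <- which(lines == "ITEM: NUMBER OF ATOMS")[1]
  n <- suppressWarnings(as.integer(trimws(lines[n_i + 1])))
  if (is.na(n)) parse_error(path, n_i + 1, "expected bead count")
  b_i <- grep("^ITEM: BOX BOUNDS", lines)[1]
  box <- vapply(1:3, function(d) {
    v <- as.numeric(strsplit(trimws(lines[b_i + d]), "\\s+")[[1]])
    v[2] - v[1]
  }, numeric(1))
  a_i <- grep("^ITEM: ATOMS", lines)[1]
  cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[a_i]), "\\s+")[[1]]
  need <- c("id", "type", "mol", "x", "y", "z")
  if (!all(need %in% cols))
    parse_error(path, a_i, paste("need columns", paste(need, collapse = " ")))
  if (length(lines) < a_i + n)
    parse_error(path, length(lines), "truncated frame body")
  body <- strsplit(trimws(lines[(a_i + 1):(a_i + n)]), "\\s+")
  m <- suppressWarnings(
    matrix(as.numeric(do.call(rbind, body)), n, length(cols)))
  if (anyNA(m)) parse_error(path, a_i + 1, "non-numeric atom data")
  ord <- order(m[, match("id", cols)])
  m <- m[ord, , drop = FALSE]
  pos <- m[, match(c("x", "y", "z"), cols)]
  vel <- if (all(c("vx", "vy", "vz") %in% cols))
    m[, match(c("vx", "vy", "vz"), cols)] else NULL
  dpd_state(box, pos, vel = vel, type = as.integer(m[, match("type", cols)]),
            mol = as.integer(m[, match("mol", cols)]),
            bonds = if (!is.null(template)) template$bonds,
            angles = if (!is.null(template)) template$angles,
            step = step)
}

#' Write an observable time series as CSV
#' @param obs Observable data.frame from [dpd_run()].
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_observables <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Write a radial or stress profile as CSV with a JSON header
#' @param profile A \code{radial_profile} or \code{stress_profile}.
#' @param path Output path; the header line is a `#`-prefixed JSON
#'   object recording bins, frames and selection.
#' @return Invisibly, \code{path}.
#' @export
write_profile <- function(profile, path) {
  hdr <- jsonlite::toJSON(
    list(bin_width = profile$bin_width, n_frames = profile$n_frames,
         types = profile$types),
    auto_unbox = TRUE, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}
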