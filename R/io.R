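#' Write a trajectory to extended XYZ or LAMMPS dump
#'
#' Extended XYZ carries the box in a \code{Lattice} field and per-atom
#' columns species/pos/vel/mol; the LAMMPS dump dialect uses orthogonal box
#' bounds and columns id mol type x y z vx vy vz, sorted by id. Chain
#' identity rides in the mol column in both formats.
#'
#' @param path Output file.
#' @param frames A \code{pb_frame} or list of them.
#' @param topo \code{pb_topology}.
#' @param format "xyz" (extended XYZ) or "lammps".
#' @export
write_trajectory <- function(path, frames, topo,
                             format = c("xyz", "lammps")) {
  format <- match.arg(format)
  if (inherits(frames, "pb_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    check_frame_topo(fr, topo)
    n <- topo$n_beads
    box <- if (is.finite(fr$box)) fr$box else
      2 * max(abs(fr$positions)) + 10
    if (format == "xyz") {
      writeLines(as.character(n), con)
      writeLines(sprintf(
        'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3:vel:R:3:mol:I:1 Time=%d pbc="%s %s %s"',
        box, box, box, as.integer(fr$time),
        fr$periodic, fr$periodic, fr$periodic), con)
      writeLines(sprintf("B %.10g %.10g %.10g %.10g %.10g %.10g %d",
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3], fr$velocities[, 1],
                         fr$velocities[, 2], fr$velocities[, 3],
                         topo$chain_id), con)
    } else {
      writeLines(c("ITEM: TIMESTEP", as.character(as.integer(fr$time)),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   sprintf("ITEM: BOX BOUNDS %s",
                           if (fr$periodic) "pp pp pp" else "ff ff ff"),
                   sprintf("0 %.10g", box), sprintf("0 %.10g", box),
                   sprintf("0 %.10g", box),
                   "ITEM: ATOMS id mol type x y z vx vy vz"), con)
      writeLines(sprintf("%d %d 1 %.10g %.10g %.10g %.10g %.10g %.10g",
                         seq_len(n), topo$chain_id,
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3], fr$velocities[, 1],
                         fr$velocities[, 2], fr$velocities[, 3]), con)
    }
  }
  invisible(path)
}

parse_error <- function(path, line, what) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, line, what),
       call. = FALSE)
}

#' Read a trajectory file
#'
#' Counterpart of \code{\link{write_trajectory}}. Multi-frame files are
#' supported; LAMMPS dumps with unsorted atom ids are reordered by id.
#' Malformed or truncated files raise a parse error naming the line.
#'
#' @param path Input file.
#' @param format "xyz" or "lammps".
#' @return List with \code{frames} (list of \code{pb_frame}) and \code{topo}
#'   (reconstructed from the mol column, assuming linear chains of
#'   consecutive beads).
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  mol <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    if (format == "xyz") {
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n)) parse_error(path, i, "expected atom count")
      if (i + 1 > length(lines)) parse_error(path, i + 1, "missing comment line")
      hdr <- lines[i + 1]
      box <- Inf; periodic <- FALSE; tm <- 0L
      lm <- regmatches(hdr, regexec('Lattice="([^"]+)"', hdr))[[1]]
      if (length(lm) == 2) {
        lat <- as.numeric(strsplit(trimws(lm[2]), "\\s+")[[1]])
        box <- lat[1]
      }
      if (grepl("pbc=\"TRUE", hdr) || grepl("pbc=\"T T T", hdr))
        periodic <- TRUE
      tmm <- regmatches(hdr, regexec("Time=([-0-9]+)", hdr))[[1]]
      if (length(tmm) == 2) tm <- as.integer(tmm[2])
      if (i + 1 + n > length(lines))
        parse_error(path, length(lines), "truncated frame body")
      rows <- lines[i + 2:(n + 1)]
      tok <- strsplit(trimws(rows), "\\s+")
      bad <- which(vapply(tok, length, 1L) < 8)
      if (length(bad)) parse_error(path, i + 1 + bad[1], "expected 8 columns")
      m <- t(vapply(tok, function(t) as.numeric(t[2:8]), numeric(7)))
      if (any(is.na(m))) parse_error(path, i + 1 + which(rowSums(is.na(m)) > 0)[1],
                                     "non-numeric field")
      mol_f <- as.integer(m[, 7])
      frames[[length(frames) + 1]] <-
        make_frame(m[, 1:3], m[, 4:6], box = box, periodic = periodic,
                   time = tm)
      if (is.null(mol)) mol <- mol_f
      i <- i + 2 + n
    } else {
      if (!grepl("^ITEM: TIMESTEP", lines[i]))
        parse_error(path, i, "expected ITEM: TIMESTEP")
      if (i + 8 > length(lines)) parse_error(path, length(lines), "truncated header")
      tm <- as.integer(trimws(lines[i + 1]))
      if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2]))
        parse_error(path, i + 2, "expected ITEM: NUMBER OF ATOMS")
      n <- suppressWarnings(as.integer(trimws(lines[i + 3])))
      if (is.na(n)) parse_error(path, i + 3, "bad atom count")
      if (!grepl("^ITEM: BOX BOUNDS", lines[i + 4]))
        parse_error(path, i + 4, "expected ITEM: BOX BOUNDS")
      periodic <- grepl("pp", lines[i + 4])
      b1 <- as.numeric(strsplit(trimws(lines[i + 5]), "\\s+")[[1]])
      box <- b1[2] - b1[1]
      if (!grepl("^ITEM: ATOMS", lines[i + 8]))
        parse_error(path, i + 8, "expected ITEM: ATOMS")
      cols <- strsplit(trimws(sub("^ITEM: ATOMS", "", lines[i + 8])),
                       "\\s+")[[1]]
      need <- c("id", "mol", "x", "y", "z")
      if (!all(need %in% cols))
        parse_error(path, i + 8, paste("missing columns:",
                                       paste(setdiff(need, cols),
                                             collapse = ", ")))
      if (i + 8 + n > length(lines))
        parse_error(path, length(lines), "truncated frame body")
      rows <- lines[i + 9:(n + 8)]
      tok <- strsplit(trimws(rows), "\\s+")
      bad <- which(vapply(tok, length, 1L) != length(cols))
      if (length(bad)) parse_error(path, i + 8 + bad[1], "wrong column count")
      m <- t(vapply(tok, as.numeric, numeric(length(cols))))
      if (any(is.na(m))) parse_error(path, i + 8 + which(rowSums(is.na(m)) > 0)[1],
                                     "non-numeric field")
      colnames(m) <- cols
      ord <- order(m[, "id"])
      m <- m[ord, , drop = FALSE]
      vel <- if (all(c("vx", "vy", "vz") %in% cols))
        m[, c("vx", "vy", "vz")] else NULL
      frames[[length(frames) + 1]] <-
        make_frame(m[, c("x", "y", "z")], vel, box = box,
                   periodic = periodic, time = tm)
      if (is.null(mol)) mol <- as.integer(m[, "mol"])
      i <- i + 9 + n
    }
  }
  if (!length(frames)) stop("no frames found in ", path)
  topo <- make_topology(as.integer(table(factor(mol, levels = unique(mol)))))
  list(frames = frames, topo = topo)
}

#' Write a flat key-value run configuration
#'
#' TOML-dialect flat file: \code{key = value} lines with optional
#' \code{[section]} headers flattened as \code{section.key}. Values may be
#' numbers, booleans, quoted strings, or arrays of numbers. Round-trips
#' losslessly through \code{\link{read_config}}.
#'
#' @param config Named list (possibly nested one level).
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  fmt1 <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15)
  }
  fmt <- function(v) {
    if (length(v) > 1) paste0("[", paste(vapply(v, fmt1, ""),
                                         collapse = ", "), "]")
    else fmt1(v)
  }
  out <- character(0)
  flat <- names(config)[!vapply(config, is.list, TRUE)]
  for (k in flat) out <- c(out, sprintf("%s = %s", k, fmt(config[[k]])))
  for (k in setdiff(names(config), flat)) {
    out <- c(out, "", sprintf("[%s]", k))
    for (k2 in names(config[[k]]))
      out <- c(out, sprintf("%s = %s", k2, fmt(config[[k]][[k2]])))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' @param path Config file written by \code{\link{write_config}} (or by
#'   hand in the same dialect).
#' @return Nested named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  out <- list()
  section <- NULL
  for (ln in seq_along(lines)) {
    s <- trimws(sub("#.*$", "", lines[ln]))
    if (!nzchar(s)) next
    if (grepl("^\\[.*\\]$", s)) {
      section <- sub("^\\[(.*)\\]$", "\\1", s)
      out[[section]] <- out[[section]] %||% list()
      next
    }
    m <- regmatches(s, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", s))[[1]]
    if (length(m) != 3) parse_error(path, ln, "expected key = value")
    key <- m[2]; val <- trimws(m[3])
    parsed <-
      if (grepl('^".*"$', val)) sub('^"(.*)"$', "\\1", val)
      else if (val %in% c("true", "false")) val == "true"
      else if (grepl("^\\[.*\\]$", val))
        as.numeric(strsplit(gsub("[][]", "", val), ",")[[1]])
      else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) parse_error(path, ln, paste("bad value:", val))
        num
      }
    if (is.null(section)) out[[key]] <- parsed
    else out[[section]][[key]] <- parsed
  }
  out
}

#' Write an observable series to CSV with provenance
#'
#' @param series Data frame.
#' @param path Output CSV.
#' @param provenance Named list written alongside as
#'   \code{<path>.provenance.json}.
#' @export
write_series_csv <- function(series, path, provenance = NULL) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
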