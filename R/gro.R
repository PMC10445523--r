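# GRO-format coordinate I/O (GROMACS dialect) and minimal topology listing.
#
# Fixed columns: resid(5) resname(-5) atom(5) atomnr(5) x(8.3) y z, nm, one
# residue per molecule, numbering modulo 100000.  Component tags are encoded
# in the residue name through a component map and reconstructed on read.

#' Default component/residue-name map
#'
#' Maps component tags to the residue names written to GRO files (and back):
#' `oleosome_core` -> `TRIO`, `oleosome_shell` -> `DPPC`, `free_tag` ->
#' `TRIF`, `water` -> `W`.  The bare-droplet triolein is renamed `TRIF` so
#' the two oil components stay distinguishable in the file.
#'
#' @return A named character vector (names are component tags).
#' @export
default_component_map <- function() {
  c(oleosome_core = "TRIO", oleosome_shell = "DPPC",
    free_tag = "TRIF", water = "W")
}

#' Write / read bead systems as GRO files
#'
#' `write_gro` writes a single frame; `write_gro_frames` appends every frame
#' of a [frame_set()] to one multi-frame file with the frame time recorded
#' as `t=` in the title.  `read_gro` reads the first frame;
#' `read_gro_frames` reads all frames into a `frame_set`.  Positions
#' round-trip to 0.001 nm (the format's precision) and all labels exactly.
#'
#' @param system a `bead_system` with a box.
#' @param path file path.
#' @param component_map named character vector mapping component tags to
#'   residue names (see [default_component_map()]); inverted on read.
#' @param title title line (a `t= <ps>` suffix is appended when `time` is
#'   given).
#' @param time frame time in ps, written into the title.
#' @return `read_gro` returns a `bead_system`; writers return `path`
#'   invisibly.
#' @export
write_gro <- function(system, path, component_map = default_component_map(),
                      title = "oleodrop system", time = NULL,
                      append = FALSE) {
  stopifnot(inherits(system, "bead_system"))
  if (is.null(system$box)) stop("cannot write a fragment without a box")
  miss <- setdiff(unique(system$component), names(component_map))
  if (length(miss)) {
    stop("no residue name mapped for component(s): ",
         paste(miss, collapse = ", "))
  }
  n <- n_beads(system)
  resname <- unname(component_map[system$component])
  lines <- c(
    if (is.null(time)) title else sprintf("%s t= %.3f", title, time),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            system$molid %% 100000L, resname,
            substr(system$atom, 1L, 5L), seq_len(n) %% 100000L,
            system$pos[, 1], system$pos[, 2], system$pos[, 3]),
    sprintf("%10.5f%10.5f%10.5f", system$box[1], system$box[2],
            system$box[3]))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_gro
#' @export
read_gro <- function(path, component_map = default_component_map()) {
  lines <- readLines(path)
  parse_gro_block(lines, 1L, path, component_map)$system
}

#' @rdname write_gro
#' @param frames a [frame_set()] (for `write_gro_frames`).
#' @export
write_gro_frames <- function(frames, path,
                             component_map = default_component_map(),
                             title = "oleodrop trajectory") {
  stopifnot(inherits(frames, "frame_set"))
  if (file.exists(path)) file.remove(path)
  for (f in seq_along(frames$frames)) {
    write_gro(frames$frames[[f]], path, component_map = component_map,
              title = title, time = frames$times[f], append = f > 1L)
  }
  invisible(path)
}

#' @rdname write_gro
#' @export
read_gro_frames <- function(path, component_map = default_component_map()) {
  lines <- readLines(path)
  at <- 1L
  systems <- list()
  times <- numeric()
  while (at <= length(lines)) {
    if (!nzchar(trimws(lines[at]))) { at <- at + 1L; next }
    blk <- parse_gro_block(lines, at, path, component_map)
    systems[[length(systems) + 1L]] <- blk$system
    times <- c(times, blk$time)
    at <- blk$next_line
  }
  if (!length(systems)) stop("no frames found in ", path)
  if (anyNA(times)) times <- seq_along(systems) - 1
  frame_set(systems, times)
}

parse_gro_block <- function(lines, at, path, component_map) {
  if (at + 1L > length(lines)) stop("truncated GRO file ", path)
  title <- lines[at]
  n <- suppressWarnings(as.integer(trimws(lines[at + 1L])))
  if (is.na(n) || n < 0L) {
    stop(sprintf("%s line %d: malformed atom count '%s'", path, at + 1L,
                 lines[at + 1L]))
  }
  if (at + 1L + n + 1L > length(lines)) {
    stop(sprintf("%s: truncated frame starting at line %d", path, at))
  }
  al <- lines[(at + 2L):(at + 1L + n)]
  molid <- suppressWarnings(as.integer(substr(al, 1L, 5L)))
  resname <- trimws(substr(al, 6L, 10L))
  atom <- trimws(substr(al, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
  bad <- which(is.na(molid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop(sprintf("%s line %d: malformed atom record '%s'", path,
                 at + 1L + bad[1], al[bad[1]]))
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[at + 2L + n]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3L || anyNA(boxv[1:3])) {
    stop(sprintf("%s line %d: malformed box line", path, at + 2L + n))
  }
  inv <- stats::setNames(names(component_map), component_map)
  unknown <- setdiff(unique(resname), names(inv))
  component <- ifelse(resname %in% names(inv), inv[resname], resname)
  if (length(unknown)) {
    warning("unmapped residue name(s) kept as component tags: ",
            paste(unknown, collapse = ", "))
  }
  # residue numbering wraps at 100000: rebuild contiguous molecule ids from
  # changes in the (resid, resname) pair
  brk <- c(TRUE, molid[-1L] != molid[-n] | resname[-1L] != resname[-n])
  time <- NA_real_
  tm <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
  if (length(tm) == 2L) time <- as.numeric(tm[2])
  list(system = bead_system(cbind(x, y, z), cumsum(brk), atom,
                            unname(component), resname, box = boxv[1:3]),
       time = time,
       next_line = at + 3L + n)
}

#' Minimal topology listing
#'
#' Writes molecule names and counts in system order (consecutive runs of the
#' same residue name), the minimal bookkeeping an engine topology needs to
#' mirror the coordinate file.
#'
#' @param system a `bead_system`.
#' @param path file path.
#' @param component_map as in [write_gro()].
#' @export
write_topology <- function(system, path,
                           component_map = default_component_map()) {
  stopifnot(inherits(system, "bead_system"))
  resname <- unname(component_map[system$component])
  first <- !duplicated(system$molid)
  r <- rle(resname[first])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[ molecules ]",
               sprintf("%-8s %d", r$values, r$lengths)), con)
  invisible(path)
}
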