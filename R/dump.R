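#' One per-atom trajectory frame
#'
#' A single frame of a text-dump trajectory: integer timestep, axis-aligned
#' box bounds, and per-atom ids, coordinates and the six components of the
#' per-atom stress*volume tensor (xx, yy, zz, xy, xz, yz) in atm*A^3, the
#' real-units convention of per-atom virial output. Atoms are stored sorted
#' by id.
#'
#' @param timestep integer timestep of the frame.
#' @param box_bounds 3x2 numeric matrix, rows x/y/z, columns lo/hi; each
#'   interval must have positive extent.
#' @param ids unique positive integer atom ids.
#' @param coords n x 3 matrix of coordinates (Angstrom), finite.
#' @param stress_pv n x 6 matrix of per-atom stress*volume components
#'   (atm*A^3).
#' @return an object of class `atom_frame`.
#' @export
atom_frame <- function(timestep, box_bounds, ids, coords, stress_pv) {
  box_bounds <- matrix(as.numeric(box_bounds), 3L, 2L)
  if (any(box_bounds[, 2] - box_bounds[, 1] <= 0))
    stop_param("box intervals must have positive extent")
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop_param("atom ids must be unique")
  coords <- matrix(as.numeric(coords), ncol = 3L)
  stress_pv <- matrix(as.numeric(stress_pv), ncol = 6L)
  if (nrow(coords) != length(ids) || nrow(stress_pv) != length(ids))
    stop_param("ids, coords and stress_pv must agree in atom count")
  if (any(!is.finite(coords))) stop_param("coordinates must be finite")
  ord <- order(ids)
  dimnames(box_bounds) <- list(c("x", "y", "z"), c("lo", "hi"))
  colnames(coords) <- c("x", "y", "z")
  colnames(stress_pv) <- TENSOR_COMPONENTS
  structure(list(timestep = as.integer(timestep), box_bounds = box_bounds,
                 ids = ids[ord], coords = coords[ord, , drop = FALSE],
                 stress_pv = stress_pv[ord, , drop = FALSE]),
            class = "atom_frame")
}

#' @export
print.atom_frame <- function(x, ...) {
  cat(sprintf("Atom frame: timestep %d, %d atoms, box %s\n",
              x$timestep, length(x$ids),
              paste(sprintf("[%g, %g]", x$box_bounds[, 1], x$box_bounds[, 2]),
                    collapse = " x ")))
  invisible(x)
}

## Map dump ATOMS column names to canonical roles. Stress columns are either
## named sxx..syz directly or carry a [1]..[6] suffix (per-atom compute style),
## taken in the conventional xx,yy,zz,xy,xz,yz order.
resolve_dump_columns <- function(cols) {
  role <- setNames(rep(NA_character_, length(cols)), cols)
  for (nm in c("id", "x", "y", "z", "ix", "iy", "iz"))
    role[cols == nm] <- nm
  for (k in 1:6) {
    direct <- which(cols == TENSOR_COMPONENTS[k])
    suff <- grep(sprintf("\\[%d\\]$", k), cols)
    hit <- c(direct, suff)
    if (length(hit) > 0) role[hit[1]] <- TENSOR_COMPONENTS[k]
  }
  for (nm in c("id", "x", "y", "z"))
    if (!nm %in% role) stop_format("dump ATOMS header lacks column '", nm, "'")
  for (k in 1:6)
    if (!TENSOR_COMPONENTS[k] %in% role)
      stop_format("dump ATOMS header lacks stress column '",
                  TENSOR_COMPONENTS[k], "' (or a [", k, "]-suffixed compute)")
  role
}

parse_one_frame <- function(lines, start) {
  i <- start
  expect_item <- function(what) {
    if (i > length(lines) || !startsWith(lines[i], paste0("ITEM: ", what)))
      stop_format("expected 'ITEM: ", what, "' at line ", i)
  }
  expect_item("TIMESTEP")
  timestep <- as.integer(lines[i + 1]); i <- i + 2
  expect_item("NUMBER OF ATOMS")
  natoms <- as.integer(lines[i + 1]); i <- i + 2
  if (is.na(natoms) || natoms < 0) stop_format("bad atom count")
  expect_item("BOX BOUNDS")
  bb <- t(vapply(lines[i + 1:3],
                 function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]][1:2]),
                 numeric(2)))
  i <- i + 4
  expect_item("ATOMS")
  cols <- strsplit(trimws(sub("^ITEM: ATOMS\\s*", "", lines[i])), "\\s+")[[1]]
  role <- resolve_dump_columns(cols)
  i <- i + 1
  if (i + natoms - 1 > length(lines)) stop_format("truncated ATOMS section")
  body <- lines[i + seq_len(natoms) - 1]
  vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                 nrow = natoms, byrow = TRUE)
  if (ncol(vals) != length(cols)) stop_format("ATOMS row width mismatch")
  if (any(is.na(vals))) stop_format("non-numeric ATOMS field")
  get <- function(nm) vals[, which(role == nm)[1]]
  coords <- cbind(get("x"), get("y"), get("z"))
  # unwrap wrapped coordinates when image flags are present
  L <- bb[, 2] - bb[, 1]
  for (k in 1:3) {
    flag <- c("ix", "iy", "iz")[k]
    if (flag %in% role) coords[, k] <- coords[, k] + get(flag) * L[k]
  }
  stress <- vapply(TENSOR_COMPONENTS, get, numeric(natoms))
  if (natoms == 1L) stress <- matrix(stress, nrow = 1L)
  frame <- atom_frame(timestep, bb, get("id"), coords, stress)
  list(frame = frame, next_line = i + natoms)
}

#' Read a text-dump trajectory
#'
#' Parses `ITEM:`-delimited frames (TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS /
#' ATOMS) from the standard text dump dialect. The ATOMS header line defines
#' the column order; required columns are `id x y z` plus six stress*volume
#' components (named `sxx syy szz sxy sxz syz`, or any names suffixed
#' `[1]`..`[6]` in that component order). Image-flag columns `ix iy iz`, when
#' present, unwrap the coordinates on read. Atoms are sorted by id within
#' each frame. A malformed trailing frame is dropped with a warning; frames
#' before it are preserved.
#'
#' @param path path to a dump file.
#' @return list of [atom_frame] in file order.
#' @export
read_dump <- function(path) {
  lines <- readLines(path)
  starts <- which(startsWith(lines, "ITEM: TIMESTEP"))
  if (length(starts) == 0L) stop_format("no 'ITEM: TIMESTEP' records found")
  frames <- list()
  i <- starts[1]
  while (i <= length(lines)) {
    res <- tryCatch(parse_one_frame(lines, i), error = function(e) e)
    if (inherits(res, "error")) {
      if (length(frames) == 0L) stop(res)
      warning("malformed trailing frame dropped: ", conditionMessage(res),
              call. = FALSE)
      break
    }
    frames[[length(frames) + 1L]] <- res$frame
    i <- res$next_line
    if (i <= length(lines) && !startsWith(lines[i], "ITEM: TIMESTEP")) {
      warning("trailing non-frame content ignored after frame ",
              length(frames), call. = FALSE)
      break
    }
  }
  frames
}

#' Write frames in the text dump dialect
#'
#' Inverse of [read_dump()]; emits columns
#' `id x y z sxx syy szz sxy sxz syz`.
#'
#' @param frames list of [atom_frame].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dump <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(c("ITEM: TIMESTEP", as.character(fr$timestep),
                 "ITEM: NUMBER OF ATOMS", as.character(length(fr$ids)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("%.17g %.17g", fr$box_bounds[, 1], fr$box_bounds[, 2]),
                 paste("ITEM: ATOMS id x y z", paste(TENSOR_COMPONENTS, collapse = " "))),
               con)
    rows <- cbind(fr$ids, fr$coords, fr$stress_pv)
    writeLines(apply(rows, 1L, function(r)
      paste(c(sprintf("%d", as.integer(r[1])), sprintf("%.17g", r[-1])),
            collapse = " ")), con)
  }
  invisible(path)
}
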