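# Readers/writers for the external file formats the pipeline touches:
# XEASY-style peak lists, .prot-style chemical shift lists, CYANA-style
# .upl/.aco restraint files, PDB coordinate files, and NUS schedule files.
# All parsers validate strictly and fail with the offending line number
# rather than silently truncating.

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

.strip_comments <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.num_or_stop <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad))
    stop("malformed ", what, " in ", path, " line ", lineno[bad[1]],
         ": '", x[bad[1]], "'")
  v
}

#' Read a peak list
#'
#' Whitespace-separated dialect modeled on XEASY: one peak per line with
#' columns \code{id, w1, ..., wD, intensity, spectrum_id} (D = 2 or 3
#' chemical shifts in ppm).  Lines starting with '#' are comments.  The
#' \code{tsv} dialect is identical but tab-separated.
#'
#' @param path file path.
#' @param dialect \code{"xeasy"} (any whitespace) or \code{"tsv"} (tabs).
#' @return data.frame of class \code{peak_list} with columns
#'   \code{peak_id, w1, w2[, w3], intensity, spectrum_id}.
#' @export
read_peak_list <- function(path, dialect = c("xeasy", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- .strip_comments(.read_lines_checked(path))
  if (length(raw$lines) == 0) return(empty_peak_list())
  split_re <- if (dialect == "tsv") "\t" else "\\s+"
  toks <- strsplit(trimws(raw$lines), split_re)
  nc <- lengths(toks)
  if (length(unique(nc)) != 1)
    stop("inconsistent column count in ", path, " line ",
         raw$lineno[which(nc != nc[1])[1]])
  if (!nc[1] %in% c(5, 6))
    stop("peak list must have 5 (2D) or 6 (3D) columns, found ", nc[1],
         " in ", path)
  ndim <- nc[1] - 3L
  m <- do.call(rbind, toks)
  out <- data.frame(
    peak_id = as.integer(.num_or_stop(m[, 1], path, raw$lineno, "peak id")),
    stringsAsFactors = FALSE)
  for (d in seq_len(ndim))
    out[[paste0("w", d)]] <- .num_or_stop(m[, 1 + d], path, raw$lineno,
                                          paste0("shift w", d))
  out$intensity <- .num_or_stop(m[, 2 + ndim], path, raw$lineno, "intensity")
  out$spectrum_id <- m[, 3 + ndim]
  if (any(!is.finite(out$intensity)))
    stop("non-finite intensity in ", path)
  class(out) <- c("peak_list", "data.frame")
  out
}

empty_peak_list <- function(ndim = 2) {
  out <- data.frame(peak_id = integer(0))
  for (d in seq_len(ndim)) out[[paste0("w", d)]] <- numeric(0)
  out$intensity <- numeric(0)
  out$spectrum_id <- character(0)
  class(out) <- c("peak_list", "data.frame")
  out
}

#' @rdname read_peak_list
#' @param peaks a \code{peak_list} data.frame.
#' @export
write_peak_list <- function(peaks, path, dialect = c("xeasy", "tsv")) {
  dialect <- match.arg(dialect)
  wcols <- grep("^w[0-9]$", names(peaks), value = TRUE)
  sep <- if (dialect == "tsv") "\t" else "  "
  rows <- apply(cbind(peaks$peak_id,
                      format(as.matrix(peaks[wcols]), trim = TRUE, digits = 6),
                      format(peaks$intensity, trim = TRUE, digits = 10),
                      peaks$spectrum_id), 1, paste, collapse = sep)
  writeLines(c("# peak list: id  w(ppm) x dim  intensity  spectrum_id",
               rows), path)
  invisible(path)
}

#' Read or write a chemical shift list
#'
#' .prot-style columns: \code{id, shift(ppm), error, atom, residue_index}
#' with an optional sixth residue-type column (written by
#' \code{write_shift_list}, so that round trips preserve residue types).
#' Duplicate (residue, atom) entries and unknown residue types are rejected.
#'
#' @param path file path.
#' @return data.frame of class \code{shift_table} with columns
#'   \code{resno, restype, atom, shift, error}.
#' @export
read_shift_list <- function(path) {
  raw <- .strip_comments(.read_lines_checked(path))
  if (length(raw$lines) == 0)
    return(structure(data.frame(resno = integer(0), restype = character(0),
                                atom = character(0), shift = numeric(0),
                                error = numeric(0)),
                     class = c("shift_table", "data.frame")))
  toks <- strsplit(trimws(raw$lines), "\\s+")
  nc <- lengths(toks)
  if (any(!nc %in% c(5, 6)))
    stop("shift list line ", raw$lineno[which(!nc %in% c(5, 6))[1]],
         " in ", path, ": expected 5 or 6 columns")
  m <- t(vapply(toks, function(x) c(x, rep(NA, 6 - length(x))), character(6)))
  out <- data.frame(
    resno = as.integer(.num_or_stop(m[, 5], path, raw$lineno, "residue index")),
    restype = ifelse(is.na(m[, 6]), "UNK", m[, 6]),
    atom = m[, 4],
    shift = .num_or_stop(m[, 2], path, raw$lineno, "shift"),
    error = .num_or_stop(m[, 3], path, raw$lineno, "shift error"),
    stringsAsFactors = FALSE)
  known <- out$restype != "UNK"
  bad <- known & !(toupper(out$restype) %in% residue_types())
  if (any(bad))
    stop("unknown residue type '", out$restype[which(bad)[1]], "' in ", path)
  key <- paste(out$resno, out$atom)
  if (anyDuplicated(key))
    stop("duplicate shift entry for residue/atom ",
         key[duplicated(key)][1], " in ", path)
  if (any(!is.finite(out$shift))) stop("non-finite shift in ", path)
  class(out) <- c("shift_table", "data.frame")
  out
}

#' @rdname read_shift_list
#' @param shifts a \code{shift_table} data.frame.
#' @export
write_shift_list <- function(shifts, path) {
  rows <- sprintf("%4d %9.3f %7.3f %-6s %4d %s",
                  seq_len(nrow(shifts)), shifts$shift,
                  if (is.null(shifts$error)) rep(0, nrow(shifts)) else shifts$error,
                  shifts$atom, shifts$resno, shifts$restype)
  writeLines(c("# shift list: id shift error atom residue restype", rows), path)
  invisible(path)
}

#' Read or write distance restraints (.upl)
#'
#' CYANA-like columns \code{res_i restype_i atom_i res_j restype_j atom_j
#' upper} with an optional trailing integer group id; lines sharing a group
#' id form one ambiguous restraint (any-of semantics under the r^-6 sum).
#' Lines without a group id each form their own group.
#'
#' @param path file path.
#' @return data.frame of class \code{restraint_set}; one row per assignment
#'   option with columns \code{group, res_i, restype_i, atom_i, res_j,
#'   restype_j, atom_j, upper, lower}.
#' @export
read_upl <- function(path) {
  raw <- .strip_comments(.read_lines_checked(path))
  if (length(raw$lines) == 0) return(empty_restraint_set())
  toks <- strsplit(trimws(raw$lines), "\\s+")
  nc <- lengths(toks)
  if (any(!nc %in% c(7, 8)))
    stop("upl line ", raw$lineno[which(!nc %in% c(7, 8))[1]], " in ", path,
         ": expected 7 or 8 columns")
  m <- t(vapply(toks, function(x) c(x, rep(NA, 8 - length(x))), character(8)))
  grp <- ifelse(is.na(m[, 8]), NA, m[, 8])
  explicit <- !is.na(grp)
  gid <- integer(nrow(m))
  gid[explicit] <- as.integer(.num_or_stop(grp[explicit], path,
                                           raw$lineno[explicit], "group id"))
  if (any(!explicit)) {
    auto <- max(c(0L, gid[explicit])) + seq_len(sum(!explicit))
    gid[!explicit] <- auto
  }
  out <- data.frame(
    group = gid,
    res_i = as.integer(.num_or_stop(m[, 1], path, raw$lineno, "residue")),
    restype_i = m[, 2], atom_i = m[, 3],
    res_j = as.integer(.num_or_stop(m[, 4], path, raw$lineno, "residue")),
    restype_j = m[, 5], atom_j = m[, 6],
    upper = .num_or_stop(m[, 7], path, raw$lineno, "upper bound"),
    lower = 1.0,
    stringsAsFactors = FALSE)
  validate_restraints(out)
  class(out) <- c("restraint_set", "data.frame")
  out
}

empty_restraint_set <- function() {
  structure(data.frame(group = integer(0), res_i = integer(0),
                       restype_i = character(0), atom_i = character(0),
                       res_j = integer(0), restype_j = character(0),
                       atom_j = character(0), upper = numeric(0),
                       lower = numeric(0), stringsAsFactors = FALSE),
            class = c("restraint_set", "data.frame"))
}

validate_restraints <- function(r) {
  if (any(r$lower > r$upper))
    stop("restraint bound inversion: lower > upper in group ",
         r$group[which(r$lower > r$upper)[1]])
  if (any(r$lower <= 0)) stop("restraint lower bound must be positive")
  invisible(r)
}

#' @rdname read_upl
#' @param restraints a \code{restraint_set} data.frame.
#' @export
write_upl <- function(restraints, path) {
  validate_restraints(restraints)
  rows <- sprintf("%4d %-4s %-5s %4d %-4s %-5s %7.2f  %d",
                  restraints$res_i, restraints$restype_i, restraints$atom_i,
                  restraints$res_j, restraints$restype_j, restraints$atom_j,
                  restraints$upper, restraints$group)
  writeLines(c("# upl: res_i restype_i atom_i res_j restype_j atom_j upper group",
               rows), path)
  invisible(path)
}

#' Read or write dihedral restraints (.aco)
#'
#' Columns \code{residue restype angle lower upper} with angles in degrees;
#' angle names follow the torsion naming of the builder (PHI, PSI, CHI1,
#' CHI2).  A lower bound above the upper bound is rejected.
#'
#' @param path file path.
#' @return data.frame of class \code{dihedral_restraints}.
#' @export
read_aco <- function(path) {
  raw <- .strip_comments(.read_lines_checked(path))
  if (length(raw$lines) == 0)
    return(structure(data.frame(resno = integer(0), restype = character(0),
                                angle = character(0), lower = numeric(0),
                                upper = numeric(0)),
                     class = c("dihedral_restraints", "data.frame")))
  toks <- strsplit(trimws(raw$lines), "\\s+")
  if (any(lengths(toks) != 5))
    stop("aco line ", raw$lineno[which(lengths(toks) != 5)[1]], " in ", path,
         ": expected 5 columns")
  m <- do.call(rbind, toks)
  out <- data.frame(
    resno = as.integer(.num_or_stop(m[, 1], path, raw$lineno, "residue")),
    restype = m[, 2], angle = toupper(m[, 3]),
    lower = .num_or_stop(m[, 4], path, raw$lineno, "lower"),
    upper = .num_or_stop(m[, 5], path, raw$lineno, "upper"),
    stringsAsFactors = FALSE)
  if (any(out$lower > out$upper))
    stop("aco bound inversion (lower > upper) at line ",
         raw$lineno[which(out$lower > out$upper)[1]], " in ", path)
  class(out) <- c("dihedral_restraints", "data.frame")
  out
}

#' @rdname read_aco
#' @param aco a \code{dihedral_restraints} data.frame.
#' @export
write_aco <- function(aco, path) {
  rows <- sprintf("%4d %-4s %-5s %9.1f %9.1f", aco$resno, aco$restype,
                  aco$angle, aco$lower, aco$upper)
  writeLines(c("# aco: residue restype angle lower upper", rows), path)
  invisible(path)
}

.pdb_atom_name <- function(name) {
  # PDB v3 alignment: 1-char-element names occupy columns 14-16
  ifelse(nchar(name) < 4, sprintf(" %-3s", name), name)
}

#' Write one structure or an ensemble as a PDB file
#'
#' Fixed-column ATOM records (8.3 coordinate fields); a list of structures
#' is written as MODEL/ENDMDL blocks.
#'
#' @param structure a \code{cartesian_structure} or list of them.
#' @param path output path.
#' @export
write_pdb_model <- function(structure, path) {
  models <- if (inherits(structure, "cartesian_structure")) list(structure)
            else structure
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    at <- models[[m]]$atoms
    lines <- sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), .pdb_atom_name(at$name), at$resname, at$resno,
      at$x, at$y, at$z, at$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (possibly multi-model) PDB file
#'
#' Single-chain polypeptide models; returns a list of
#' \code{cartesian_structure} objects (length 1 for single-model files).
#' Non-monotonic residue numbering triggers a warning, not an error.
#'
#' @param path file path.
#' @export
read_pdb_model <- function(path) {
  lines <- .read_lines_checked(path)
  rec <- substring(lines, 1, 6)
  model_breaks <- which(trimws(rec) == "MODEL")
  parse_block <- function(block) {
    at <- block[startsWith(block, "ATOM  ") | startsWith(block, "HETATM")]
    if (length(at) == 0) return(NULL)
    name <- trimws(substring(at, 13, 16))
    resname <- trimws(substring(at, 18, 20))
    resno <- as.integer(trimws(substring(at, 23, 26)))
    x <- as.numeric(substring(at, 31, 38))
    y <- as.numeric(substring(at, 39, 46))
    z <- as.numeric(substring(at, 47, 54))
    if (any(is.na(x) | is.na(y) | is.na(z)))
      stop("malformed coordinate field in ", path)
    if (any(diff(resno) < 0))
      warning("non-monotonic residue numbering in ", path)
    atoms <- data.frame(name = name, resno = resno, resname = resname,
                        element = substring(name, 1, 1), x = x, y = y, z = z,
                        stringsAsFactors = FALSE)
    structure(list(atoms = atoms,
                   sequence = resname[!duplicated(resno)]),
              class = "cartesian_structure")
  }
  if (length(model_breaks) == 0) {
    s <- parse_block(lines)
    return(if (is.null(s)) list() else list(s))
  }
  ends <- which(trimws(rec) == "ENDMDL")
  out <- vector("list", length(model_breaks))
  for (k in seq_along(model_breaks)) {
    out[[k]] <- parse_block(lines[(model_breaks[k] + 1):(ends[k] - 1)])
  }
  out
}

#' Read or write a NUS sampling schedule
#'
#' One line per sampled point, "i j" with 0-based grid indices.  The writer
#' records the grid size in a comment header, which the reader uses when
#' \code{n1}/\code{n2} are not supplied.  Duplicate or out-of-grid points
#' are rejected.
#'
#' @param schedule a \code{nus_schedule} (see [generate_schedule()]).
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  writeLines(c(sprintf("# nus schedule n1=%d n2=%d fraction=%g",
                       schedule$n1, schedule$n2, schedule$fraction),
               sprintf("%d %d", schedule$points[, 1], schedule$points[, 2])),
             path)
  invisible(path)
}

#' @rdname write_schedule
#' @param n1,n2 grid sizes (complex points per indirect dimension); read
#'   from the header when omitted.
#' @export
read_schedule <- function(path, n1 = NULL, n2 = NULL) {
  lines <- .read_lines_checked(path)
  hdr <- grep("^#.*n1=", lines, value = TRUE)
  if (length(hdr) && (is.null(n1) || is.null(n2))) {
    n1 <- as.integer(sub(".*n1=([0-9]+).*", "\\1", hdr[1]))
    n2 <- as.integer(sub(".*n2=([0-9]+).*", "\\1", hdr[1]))
  }
  if (is.null(n1) || is.null(n2))
    stop("grid size unknown: pass n1 and n2 or use a header-bearing file")
  raw <- .strip_comments(lines)
  toks <- strsplit(trimws(raw$lines), "\\s+")
  if (any(lengths(toks) != 2))
    stop("schedule line ", raw$lineno[which(lengths(toks) != 2)[1]],
         " in ", path, ": expected 'i j'")
  m <- do.call(rbind, toks)
  pts <- cbind(as.integer(.num_or_stop(m[, 1], path, raw$lineno, "index")),
               as.integer(.num_or_stop(m[, 2], path, raw$lineno, "index")))
  if (any(pts[, 1] < 0 | pts[, 1] >= n1 | pts[, 2] < 0 | pts[, 2] >= n2))
    stop("schedule point outside the ", n1, "x", n2, " grid in ", path)
  if (anyDuplicated(paste(pts[, 1], pts[, 2])))
    stop("duplicate schedule point in ", path)
  structure(list(n1 = n1, n2 = n2, points = pts,
                 fraction = nrow(pts) / (n1 * n2), seed = NA_integer_,
                 scheme = "file"),
            class = "nus_schedule")
}

#' Read or write sampled time-domain data
#'
#' Plain-text format: a header recording the grid and noise level, then one
#' line per scheduled point "i j re im" (0-based indices).
#'
#' @param data a \code{time_domain_data}.
#' @param path file path.
#' @export
write_fid <- function(data, path) {
  sc <- data$schedule
  writeLines(c(sprintf("# fid n1=%d n2=%d sigma=%.10g", sc$n1, sc$n2,
                       ifelse(is.na(data$noise_sigma), -1,
                              data$noise_sigma)),
               sprintf("%d %d %.10g %.10g", sc$points[, 1], sc$points[, 2],
                       Re(data$values), Im(data$values))), path)
  invisible(path)
}

#' @rdname write_fid
#' @export
read_fid <- function(path) {
  lines <- .read_lines_checked(path)
  hdr <- grep("^# fid", lines, value = TRUE)
  if (length(hdr) == 0) stop("missing fid header in ", path)
  n1 <- as.integer(sub(".*n1=([0-9]+).*", "\\1", hdr[1]))
  n2 <- as.integer(sub(".*n2=([0-9]+).*", "\\1", hdr[1]))
  sig <- as.numeric(sub(".*sigma=([-0-9.eE+]+).*", "\\1", hdr[1]))
  raw <- .strip_comments(lines)
  m <- do.call(rbind, strsplit(trimws(raw$lines), "\\s+"))
  if (ncol(m) != 4) stop("fid line must be 'i j re im' in ", path)
  pts <- cbind(as.integer(m[, 1]), as.integer(m[, 2]))
  sched <- structure(list(n1 = n1, n2 = n2, points = pts,
                          fraction = nrow(pts) / (n1 * n2),
                          seed = NA_integer_, scheme = "file"),
                     class = "nus_schedule")
  time_domain_data(complex(real = as.numeric(m[, 3]),
                           imaginary = as.numeric(m[, 4])),
                   sched, noise_sigma = if (sig < 0) NA_real_ else sig)
}

#' Read or write a reconstructed 2D spectrum
#'
#' Text grid with an axis-metadata header: one line per grid row of
#' whitespace-separated intensities.
#'
#' @param spectrum a \code{spectrum2d}.
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  z <- spectrum$intensities
  writeLines(c(sprintf("# spectrum n1=%d n2=%d id=%s", nrow(z), ncol(z),
                       spectrum$id),
               paste("# ppm1", paste(signif(spectrum$ppm1, 8),
                                     collapse = " ")),
               paste("# ppm2", paste(signif(spectrum$ppm2, 8),
                                     collapse = " ")),
               apply(z, 1, function(r) paste(signif(r, 8), collapse = " "))),
             path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- .read_lines_checked(path)
  hdr <- grep("^# spectrum", lines, value = TRUE)
  if (length(hdr) == 0) stop("missing spectrum header in ", path)
  id <- sub(".*id=(\\S+).*", "\\1", hdr[1])
  ax <- function(tag) {
    l <- grep(paste0("^# ", tag), lines, value = TRUE)
    as.numeric(strsplit(trimws(sub(paste0("# ", tag), "", l[1])),
                        "\\s+")[[1]])
  }
  raw <- .strip_comments(lines)
  z <- do.call(rbind, lapply(strsplit(trimws(raw$lines), "\\s+"),
                             as.numeric))
  new_spectrum2d(z, ppm1 = ax("ppm1"), ppm2 = ax("ppm2"), id = id)
}
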