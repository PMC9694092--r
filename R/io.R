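# Readers and writers: multi-frame XYZ and GRO trajectories, xvg-style
# two-column energy series, frequency tables, thermo tables (TSV/JSON) and
# the JSON run configuration.

#' Read a multi-frame XYZ trajectory
#'
#' XYZ coordinates are assumed to be in Angstrom and are converted to nm
#' unless `unit = "nm"`.
#'
#' @param path File path.
#' @param unit `"angstrom"` (default) or `"nm"`.
#' @return List: `coords` (`frames x atoms x 3`, nm), `atoms` (names),
#'   `comments` (one per frame).
#' @export
read_xyz <- function(path, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  fac <- if (unit == "angstrom") 0.1 else 1
  frames <- list(); comments <- character(0); atoms <- NULL
  i <- 1L; nf <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("XYZ parse error at line ", i, ": expected atom count")
    nf <- nf + 1L
    if (i + 1L + nat > length(lines))
      stop("XYZ parse error: truncated frame ", nf, " starting at line ", i)
    comments <- c(comments, lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad))
      stop("XYZ parse error at line ", i + 1L + bad[1], " (frame ", nf, ")")
    nm <- vapply(toks, `[[`, character(1), 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("XYZ parse error: non-numeric coordinates in frame ", nf)
    if (is.null(atoms)) atoms <- nm
    else if (length(nm) != length(atoms))
      stop("inconsistent atom count in frame ", nf)
    frames[[nf]] <- xyz * fac
    i <- i + 2L + nat
  }
  if (!nf) stop("no frames found in ", path)
  coords <- array(0, c(nf, length(atoms), 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  list(coords = coords, atoms = atoms, comments = comments)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param coords `frames x atoms x 3` array or single `atoms x 3` matrix
#'   (nm; written in Angstrom unless `unit = "nm"`).
#' @param atoms Atom names.
#' @param path Output path.
#' @param comments Per-frame comment lines.
#' @param unit Output unit.
#' @export
write_xyz <- function(coords, atoms, path, comments = NULL,
                      unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  fac <- if (unit == "angstrom") 10 else 1
  nf <- dim(coords)[1]; nat <- dim(coords)[2]
  if (is.null(comments)) comments <- sprintf("frame %d", seq_len(nf))
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(nat), comments[f]), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", atoms,
                       coords[f, , 1] * fac, coords[f, , 2] * fac,
                       coords[f, , 3] * fac), con)
  }
  invisible(path)
}

#' Read a multi-frame GRO file
#'
#' Fixed-format GRO (positions in nm, 3 decimals).  Velocities, if present,
#' are ignored.
#'
#' @param path File path.
#' @return List: `coords` (`frames x atoms x 3`, nm), `atoms` (atom names),
#'   `titles`, `box` (per-frame box vectors).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); titles <- character(0); boxes <- list(); atoms <- NULL
  i <- 1L; nf <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1)
      stop("GRO parse error at line ", i + 1L, ": expected atom count")
    nf <- nf + 1L
    if (i + 2L + nat > length(lines))
      stop("GRO parse error: truncated frame ", nf)
    block <- lines[(i + 2L):(i + 1L + nat)]
    nm <- trimws(substr(block, 11, 15))
    x <- as.numeric(substr(block, 21, 28))
    y <- as.numeric(substr(block, 29, 36))
    z <- as.numeric(substr(block, 37, 44))
    if (any(!is.finite(c(x, y, z))))
      stop("GRO parse error: bad coordinates in frame ", nf)
    if (is.null(atoms)) atoms <- nm
    else if (length(nm) != length(atoms))
      stop("inconsistent atom count in frame ", nf)
    titles <- c(titles, title)
    boxes[[nf]] <- as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                       "\\s+")[[1]])
    frames[[nf]] <- cbind(x, y, z)
    i <- i + 3L + nat
  }
  if (!nf) stop("no frames found in ", path)
  coords <- array(0, c(nf, length(atoms), 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  list(coords = coords, atoms = atoms, titles = titles, box = boxes)
}

#' Write a multi-frame GRO file
#'
#' @param coords `frames x atoms x 3` array or `atoms x 3` matrix (nm).
#' @param atoms Atom names.
#' @param path Output path.
#' @param box Box vector (nm), default 5 nm cube.
#' @export
write_gro <- function(coords, atoms, path, box = c(5, 5, 5)) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  nf <- dim(coords)[1]; nat <- dim(coords)[2]
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(sprintf("frame %d", f), sprintf("%5d", nat)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MOL",
                       substr(atoms, 1, 5), seq_len(nat),
                       coords[f, , 1], coords[f, , 2], coords[f, , 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

#' Read trajectory coordinates (XYZ or GRO)
#'
#' Dispatches on `format` (or the file extension) and returns a coordinate
#' array in nm with constant atom count across frames.
#'
#' @param path File path.
#' @param format `"xyz"`, `"gro"` or `"auto"` (extension).
#' @param ... Passed to the format reader (e.g. `unit` for XYZ).
#' @return As [read_xyz()] / [read_gro()].
#' @export
read_trajectory_file <- function(path, format = c("auto", "xyz", "gro"),
                                 ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  switch(format,
         xyz = read_xyz(path, ...),
         gro = read_gro(path),
         stop("unsupported trajectory format: ", format))
}

#' Read an xvg-style energy series
#'
#' Two-column whitespace text (time/index, energy); `#` and `@` comment
#' lines are skipped.
#'
#' @param path File path.
#' @param n_frames Optional expected length; mismatch is an error.
#' @return `data.frame` with columns `time`, `value`.
#' @export
read_energy_series <- function(path, n_frames = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  if (any(vapply(toks, length, integer(1)) < 2))
    stop("expected two columns in ", path)
  tm <- as.numeric(vapply(toks, `[[`, character(1), 1))
  vl <- as.numeric(vapply(toks, `[[`, character(1), 2))
  if (any(!is.finite(tm)) || any(!is.finite(vl)))
    stop("non-numeric values in ", path)
  if (!is.null(n_frames) && length(vl) != n_frames)
    stop("alignment error: ", length(vl), " energy rows vs ", n_frames,
         " trajectory frames")
  data.frame(time = tm, value = vl)
}

#' Write an xvg-style energy series
#'
#' @param time,value Numeric vectors.
#' @param path Output path.
#' @param comment Header comment.
#' @export
write_energy_series <- function(time, value, path, comment = "energy") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("#", comment), con)
  writeLines(sprintf("%.6g %.10g", time, value), con)
  invisible(path)
}

#' Read a frequency table
#'
#' Plain text, one wavenumber (cm^-1) per line; `#` comments and blank lines
#' skipped.
#'
#' @param path File path.
#' @return Numeric wavenumber vector.
#' @export
read_frequency_table <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  wn <- suppressWarnings(as.numeric(lines))
  if (any(is.na(wn))) stop("non-numeric entry in frequency table ", path)
  wn
}

#' Write a thermo table as TSV and/or JSON
#'
#' @param table A `"thermo_table"` (from [full_thermo()]).
#' @param path Output path; `.json` writes JSON, anything else TSV with the
#'   header `T, mu_minus_href0, h_minus_href0, s, cp` plus excess columns.
#' @export
write_thermo_table <- function(table, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(table), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(as.data.frame(table), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a thermo table written by [write_thermo_table()]
#'
#' @param path File path (TSV or JSON).
#' @return `data.frame` of class `"thermo_table"`.
#' @export
read_thermo_table <- function(path) {
  d <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, header = TRUE, sep = "\t")
  }
  class(d) <- c("thermo_table", "data.frame")
  d
}

#' Read a JSON run configuration
#'
#' Validates that every referenced file exists.  Recognized fields:
#' `trajectory`, `energies`, `reference_structure`, `frequencies_quantum`,
#' `frequencies_semiclassical` (paths); `T0`, `p`, `gamma`, `k`, `k_max`,
#' `n_in`, `N`, `Tgrid` (or `Tmin`/`Tmax`/`Tstep`), `seed`.
#'
#' @param path JSON file.
#' @return List of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("trajectory", "energies", "reference_structure",
              "frequencies_quantum", "frequencies_semiclassical")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: file not found: ", cfg[[f]], " (", f, ")")
  }
  if (is.null(cfg$Tgrid) && !is.null(cfg$Tmin))
    cfg$Tgrid <- seq(cfg$Tmin, cfg$Tmax,
                     by = if (is.null(cfg$Tstep)) 10 else cfg$Tstep)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Published Gamma-state anchor parameters at T0 = 200 K
#'
#' Literature anchor table for six flexible gas-phase systems (n-butane,
#' BmimNTf2, BmimPF6, n-butanol, octadecane, n-octane): the excess free
#' energy/enthalpy/entropy differences between the reference conformation
#' and the full conformational space, the excess enthalpy (relative to the
#' reference T = 0 enthalpy) and entropy at T0, and the excess heat
#' capacity, at the box multiplier `k` chosen at 95 or 99.9 percent
#' confidence.
#'
#' @return `data.frame` with columns `system`, `nin`, `confidence`, `k`,
#'   `dmu0` (kJ/mol), `dh0` (kJ/mol), `ds0` (J/(mol K)), `h0p_rel`
#'   (kJ/mol), `s0p` (J/(mol K)), `cp0p` (J/(mol K)).
#' @export
anchor_table <- function() {
  path <- system.file("extdata", "anchor_table_200K.tsv",
                      package = "qgethermo")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
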