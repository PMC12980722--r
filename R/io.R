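#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ dialect: an atom-count line, a free-form comment line, then
#' one `element x y z` line per atom (Angstrom); frames are concatenated.
#'
#' @param path file path
#' @return list of frames, each `list(elements, xyz, comment)`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed atom-count line at line ", i, ": '", lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i, " (expected ", n, " atoms)")
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop("malformed atom line in frame starting at line ", i)
    el <- vapply(parts, `[[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(parts, function(p) p[2:4]))),
                  ncol = 3, byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop("non-numeric coordinates in frame starting at line ", i)
    frames[[length(frames) + 1L]] <- list(elements = el, xyz = xyz,
                                          comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' @rdname read_xyz
#' @param frames list of frames (`elements`, `xyz`, optional `comment`)
#' @param path output path
#' @export
write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$xyz)), con)
    writeLines(fr$comment %||% "", con)
    writeLines(sprintf("%-3s %.9g %.9g %.9g", fr$elements,
                       fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a molecule topology from JSON
#'
#' Dialect: `{name, formal_charge, atoms: [{element, atom_type, x, y, z}],
#' bonds: [[i, j], ...]}` with 0-based bond indices and Angstrom coordinates.
#'
#' @param path file path
#' @return a `molecule`
#' @export
read_topology <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "formal_charge", "atoms")
  if (!all(need %in% names(j)))
    stop("topology JSON must contain fields: ", paste(need, collapse = ", "))
  atoms <- as.data.frame(j$atoms)
  b <- j$bonds
  bonds <- if (is.null(b) || length(b) == 0) matrix(integer(), ncol = 2)
    else if (is.matrix(b)) matrix(as.integer(b), ncol = 2) + 1L
    else matrix(as.integer(unlist(b)), ncol = 2, byrow = TRUE) + 1L
  molecule(j$name, atoms, bonds, j$formal_charge)
}

#' @rdname read_topology
#' @param mol a `molecule`
#' @export
write_topology <- function(mol, path) {
  jsonlite::write_json(
    list(name = mol$name, formal_charge = mol$formal_charge,
         atoms = mol$atoms[, c("element", "atom_type", "x", "y", "z")],
         bonds = if (nrow(mol$bonds)) unname(mol$bonds - 1L) else list()),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.ff_schema <- list(
  atom_types = c("type", "chi", "eta", "q_V", "zeta_V", "zeta", "alpha"),
  bond_types = c("type1", "type2", "delta_chi", "delta_eta"),
  global = c("A_ic", "b_ic", "r_OM"))

#' Read or write a force field (JSON or YAML)
#'
#' The on-disk schema mirrors [force_field()]: `atom_types` and `bond_types`
#' records plus a `global` block. Unknown keys are rejected. Format is chosen
#' by the file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path file path
#' @return a `force_field`
#' @export
read_force_field <- function(path) {
  j <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(j), names(.ff_schema))
  if (length(extra)) stop("unknown force-field keys: ", paste(extra, collapse = ", "))
  at <- as.data.frame(do.call(rbind, lapply(.as_records(j$atom_types), as.data.frame)))
  bt <- if (!is.null(j$bond_types) && length(j$bond_types))
    as.data.frame(do.call(rbind, lapply(.as_records(j$bond_types), as.data.frame)))
  else NULL
  extra <- setdiff(names(at), .ff_schema$atom_types)
  if (length(extra)) stop("unknown atom-type keys: ", paste(extra, collapse = ", "))
  if (!is.null(bt)) {
    extra <- setdiff(names(bt), .ff_schema$bond_types)
    if (length(extra)) stop("unknown bond-type keys: ", paste(extra, collapse = ", "))
  }
  g <- j$global %||% list()
  extra <- setdiff(names(g), .ff_schema$global)
  if (length(extra)) stop("unknown global keys: ", paste(extra, collapse = ", "))
  force_field(at, bt, A_ic = g$A_ic %||% 0, b_ic = g$b_ic %||% 1,
              r_OM = g$r_OM %||% 0)
}

# yaml gives a list of records, jsonlite a data frame; normalise to records
.as_records <- function(x) {
  if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
  else x
}

#' @rdname read_force_field
#' @param ff a `force_field`
#' @export
write_force_field <- function(ff, path) {
  obj <- list(atom_types = ff$atom_types, bond_types = ff$bond_types,
              global = ff$global)
  if (grepl("\\.ya?ml$", path)) {
    obj$atom_types <- lapply(seq_len(nrow(ff$atom_types)),
                             function(i) as.list(ff$atom_types[i, ]))
    obj$bond_types <- lapply(seq_len(nrow(ff$bond_types)),
                             function(i) as.list(ff$bond_types[i, ]))
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.energy_header <- c("dimer_id", "frame_id", "r_min_A", "E_elec_kJmol",
                    "E_induc_kJmol", "E_exch_proxy_kJmol", "split")

#' Read or write a dimer energy-component table (CSV)
#'
#' Columns (validated bit-exactly): `dimer_id, frame_id, r_min_A,
#' E_elec_kJmol, E_induc_kJmol, E_exch_proxy_kJmol, split`.
#'
#' @param path file path
#' @return data frame of components
#' @export
read_energy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), .energy_header))
    stop("energy table header mismatch; expected: ",
         paste(.energy_header, collapse = ","))
  num <- c("r_min_A", "E_elec_kJmol", "E_induc_kJmol", "E_exch_proxy_kJmol")
  for (cn in num) {
    if (!is.numeric(df[[cn]])) stop("column '", cn, "' is not numeric")
    if (any(!is.finite(df[[cn]]))) stop("non-finite values in '", cn, "'")
  }
  if (!all(df$split %in% c("train", "test")))
    stop("split column must be 'train' or 'test'")
  df
}

#' @rdname read_energy_table
#' @param comp components data frame (the `components` element of a
#'   `ref_dataset`)
#' @export
write_energy_table <- function(comp, path) {
  stopifnot(identical(names(comp), .energy_header))
  fmt <- comp
  for (cn in names(fmt)) if (is.numeric(fmt[[cn]]))
    fmt[[cn]] <- sprintf("%.9g", fmt[[cn]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write ESP grids
#'
#' Two dialects: a combined whitespace table with columns `x y z value`, or a
#' split pair of files (`points` with `x y z`, `values` with one potential
#' per line under a `# esp kJ/mol/e` header). Comment lines start with `#`.
#'
#' @param points_path path of the point (or combined) file
#' @param values_path optional path of the separate values file
#' @return an `esp_grid`
#' @export
read_grid <- function(points_path, values_path = NULL) {
  lines <- readLines(points_path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1 || !(ncols %in% c(3, 4)))
    stop("grid file must have 3 (x y z) or 4 (x y z value) columns")
  m <- matrix(as.numeric(unlist(parts)), ncol = ncols, byrow = TRUE)
  if (any(!is.finite(m))) stop("non-numeric grid entries")
  pts <- m[, 1:3, drop = FALSE]
  colnames(pts) <- c("x", "y", "z")
  vals <- if (ncols == 4) m[, 4] else NULL
  if (!is.null(values_path)) {
    vl <- readLines(values_path)
    vl <- vl[nzchar(trimws(vl)) & !startsWith(trimws(vl), "#")]
    vals <- as.numeric(vl)
    if (any(!is.finite(vals))) stop("non-numeric ESP values")
    if (length(vals) != nrow(pts))
      stop("value count does not match grid point count")
  }
  structure(list(points = pts, values = vals, provenance = "external"),
            class = "esp_grid")
}

#' @rdname read_grid
#' @param grid an `esp_grid`
#' @param combined write the 4-column combined dialect (default) or the
#'   split dialect when `values_path` is given
#' @export
write_grid <- function(grid, points_path, values_path = NULL, combined = is.null(values_path)) {
  pts <- grid$points
  if (combined && !is.null(grid$values)) {
    writeLines(sprintf("%.9g %.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3],
                       grid$values), points_path)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]),
               points_path)
    if (!is.null(values_path) && !is.null(grid$values))
      writeLines(c("# esp kJ/mol/e", sprintf("%.9g", grid$values)), values_path)
  }
  invisible(points_path)
}

#' Write a reference dataset to a directory
#'
#' Emits the dimer geometries as one multi-frame XYZ per dimer pair (comment
#' line: `dimer_id frame_id r_min split`), the energy-component table as CSV
#' and a YAML manifest with the generator seed and settings.
#'
#' @param data a `ref_dataset`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_ref_dataset <- function(data, dir) {
  stopifnot(inherits(data, "ref_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  by_dimer <- split(seq_along(data$frames),
                    vapply(data$frames, `[[`, "", "dimer_id"))
  for (dd in names(by_dimer)) {
    frames <- lapply(by_dimer[[dd]], function(k) {
      fr <- data$frames[[k]]
      ma <- data$molecules[[fr$mol_a]]; mb <- data$molecules[[fr$mol_b]]
      list(elements = c(ma$atoms$element, mb$atoms$element),
           xyz = rbind(fr$xyz_a, fr$xyz_b),
           comment = sprintf("%s %s %.9g %s", fr$dimer_id, fr$frame_id,
                             fr$r_min, fr$split))
    })
    write_xyz(frames, file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", dd), ".xyz")))
  }
  write_energy_table(data$components, file.path(dir, "components.csv"))
  yaml::write_yaml(data$meta, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
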