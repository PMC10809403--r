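#' Read a GRO coordinate file
#'
#' Fixed-column GROMACS GRO dialect. Positions are in nm; the box line must
#' describe a cubic box (three equal lengths, no off-diagonal components).
#'
#' @param path File path.
#' @return Data frame with columns `resid`, `resname`, `name`, `x`, `y`, `z`
#'   (nm) and attribute `box_edge` (nm, or `NULL` when the box line is absent
#'   or zero).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO file (fewer than 3 lines): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count on line 2 of ", path)
  if (length(lines) < 2 + n + 1)
    stop("GRO file truncated: expected ", n, " atom lines in ", path)
  at <- lines[3:(2 + n)]
  parse_num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      bad <- lineno[which(is.na(v))[1]]
      stop("parse error in GRO ", what, " at line ", bad, " of ", path)
    }
    v
  }
  ln <- 2 + seq_len(n)
  out <- data.frame(
    resid = as.integer(parse_num(substr(at, 1, 5), "resid", ln)),
    resname = trimws(substr(at, 6, 10)),
    name = trimws(substr(at, 11, 15)),
    x = parse_num(substr(at, 21, 28), "x", ln),
    y = parse_num(substr(at, 29, 36), "y", ln),
    z = parse_num(substr(at, 37, 44), "z", ln),
    stringsAsFactors = FALSE
  )
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                              "\\s+")[[1]]))
  box <- box[!is.na(box)]
  if (length(box) >= 3 && any(box[1:3] > 0)) {
    if (max(abs(diff(box[1:3]))) > 1e-9 ||
        (length(box) > 3 && any(abs(box[-(1:3)]) > 1e-9)))
      stop("unsupported geometry: only cubic boxes are supported")
    attr(out, "box_edge") <- box[1]
  }
  out
}

#' Write a GRO coordinate file
#'
#' @param system A [charge_system()] or a coordinate data frame as returned by
#'   [read_gro()].
#' @param path Output file path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(system, path, title = "written by finsize") {
  co <- .as_coords(system)
  n <- nrow(co)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     co$resid %% 100000, substr(co$resname, 1, 5),
                     substr(co$name, 1, 5), seq_len(n) %% 100000,
                     co$x, co$y, co$z))
  L <- attr(co, "box_edge")
  lines <- c(lines,
             if (is.null(L)) "   0.00000   0.00000   0.00000"
             else sprintf("%10.5f%10.5f%10.5f", L, L, L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB coordinate file
#'
#' Fixed-column `ATOM`/`HETATM` records. PDB coordinates are in Angstrom and
#' converted to nm; a `CRYST1` record, when present and cubic, provides the
#' box edge (also converted to nm).
#'
#' @param path File path.
#' @return Same layout as [read_gro()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  at <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (length(at) == 0) stop("no ATOM/HETATM records in ", path)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop("parse error in PDB ", what, " record ", which(is.na(v))[1],
           " of ", path)
    v
  }
  out <- data.frame(
    resid = as.integer(num(substr(at, 23, 26), "resid")),
    resname = trimws(substr(at, 18, 21)),
    name = trimws(substr(at, 13, 16)),
    x = num(substr(at, 31, 38), "x") / 10,
    y = num(substr(at, 39, 46), "y") / 10,
    z = num(substr(at, 47, 54), "z") / 10,
    stringsAsFactors = FALSE
  )
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) >= 1) {
    abc <- num(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                 substr(cr[1], 25, 33)), "CRYST1")
    if (any(abc > 0)) {
      if (max(abs(diff(abc))) > 1e-6)
        stop("unsupported geometry: only cubic boxes are supported")
      attr(out, "box_edge") <- abc[1] / 10
    }
  }
  out
}

#' Write a PDB coordinate file
#'
#' Positions are converted from nm to Angstrom; a cubic `CRYST1` record is
#' emitted when the system is periodic.
#'
#' @inheritParams write_gro
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path, title = "written by finsize") {
  co <- .as_coords(system)
  n <- nrow(co)
  L <- attr(co, "box_edge")
  lines <- paste("REMARK    ", title)
  if (!is.null(L))
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      L * 10, L * 10, L * 10, 90, 90, 90))
  lines <- c(lines, sprintf(
    "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(n) %% 100000, substr(co$name, 1, 4), substr(co$resname, 1, 4),
    co$resid %% 10000, co$x * 10, co$y * 10, co$z * 10), "END")
  writeLines(lines, path)
  invisible(path)
}

.as_coords <- function(system) {
  if (inherits(system, "charge_system")) {
    out <- data.frame(resid = 1L, resname = "MOL", name = system$names,
                      x = system$positions[, 1], y = system$positions[, 2],
                      z = system$positions[, 3], stringsAsFactors = FALSE)
    if ("resid" %in% names(attributes(system)))
      out$resid <- attr(system, "resid")
    attr(out, "box_edge") <- system$box_edge
    out
  } else {
    if (!all(c("name", "x", "y", "z") %in% names(system)))
      stop("expected a charge_system or a coordinate data frame")
    if (is.null(system$resid)) system$resid <- 1L
    if (is.null(system$resname)) system$resname <- "MOL"
    system
  }
}

#' Read / write a charge and radius table
#'
#' Tab-separated text with header `name  charge_e  radius_nm`.
#'
#' @param path File path.
#' @return For `read_charge_table`, a data frame with those three columns.
#' @export
read_charge_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("name", "charge_e", "radius_nm")
  if (!all(need %in% names(tab)))
    stop("charge table must have header: name\tcharge_e\tradius_nm")
  tab
}

#' @rdname read_charge_table
#' @param table Data frame with columns `name`, `charge_e`, `radius_nm`.
#' @export
write_charge_table <- function(table, path) {
  write.table(table[, c("name", "charge_e", "radius_nm")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a distance series
#'
#' Tab-separated text with header `replica  frame  value_nm`, the exchange
#' format for end-to-end distance samples.
#'
#' @param path File path.
#' @return For `read_distance_series`, a data frame with columns `replica`,
#'   `frame`, `value_nm`.
#' @export
read_distance_series <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("replica", "frame", "value_nm") %in% names(tab)))
    stop("distance series must have header: replica\tframe\tvalue_nm")
  tab
}

#' @rdname read_distance_series
#' @param series Data frame with columns `replica`, `frame`, `value_nm`.
#' @export
write_distance_series <- function(series, path) {
  write.table(series[, c("replica", "frame", "value_nm")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
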