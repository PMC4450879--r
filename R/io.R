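#' Read a force-displacement protocol from CSV
#'
#' The file must have a header `time_s, displacement_mm, force_N`
#' (units fixed package-wide: s, mm, N). Time must be strictly increasing;
#' non-numeric cells (including locale decimal commas) and missing values
#' are rejected with the offending row number.
#'
#' @param path CSV path.
#' @return A protocol data frame with columns `t`, `U`, `F_exp`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("time_s", "displacement_mm", "force_N")
  if (!all(need %in% names(raw)))
    stop("protocol CSV must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(raw), collapse = ", "))
  vals <- lapply(need, function(cn) {
    x <- raw[[cn]]
    if (any(grepl(",", x, fixed = TRUE)))
      stop("column '", cn, "' contains a decimal comma (row ",
           which(grepl(",", x, fixed = TRUE))[1],
           "); protocols use the dot decimal separator")
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop("non-numeric or missing value in column '", cn, "' at row ",
           which(is.na(v))[1])
    v
  })
  tt <- vals[[1]]
  if (any(diff(tt) <= 0))
    stop("time_s must be strictly increasing; violation at row ",
         which(diff(tt) <= 0)[1] + 1L)
  data.frame(t = tt, U = vals[[2]], F_exp = vals[[3]])
}

#' Write a protocol to CSV
#'
#' Values are written with 12 significant digits so that a
#' write-then-read round trip is lossless at that precision.
#'
#' @param protocol Data frame with `t`, `U` and `F_exp` (or `F`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  FF <- if ("F_exp" %in% names(protocol)) protocol$F_exp else protocol$F
  if (is.null(FF)) stop("protocol needs an F_exp (or F) column")
  df <- data.frame(time_s = formatC(protocol$t, digits = 12, format = "g"),
                   displacement_mm = formatC(protocol$U, digits = 12, format = "g"),
                   force_N = formatC(FF, digits = 12, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write Gauss-point fields to tidy CSV
#'
#' One row per Gauss point with current coordinates, pore pressure, Darcy
#' flux, fibre and matrix stress components and the volume ratio/void
#' ratio, as recorded by [run_protocol()] / [solve_step()].
#'
#' @param gp Gauss-point matrix (attribute `gp` of a step, or one entry of
#'   a `tendon_response$fields` list).
#' @param path Output path.
#' @param t Time stamp column value (s).
#' @param params Parameters used to derive the void ratio from `J`.
#' @return `path`, invisibly.
#' @export
write_fields_csv <- function(gp, path, t = NA_real_, params = NULL) {
  df <- as.data.frame(gp)
  df$t <- t
  if (!is.null(params)) {
    e0 <- fluid_fraction(params$nfm, params$rho_s)$e0_void
    df$e_void <- df$J * (1 + e0) - 1
    df$nf <- df$e_void / (1 + df$e_void)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a field snapshot as a legacy VTK unstructured grid
#'
#' Exports the deformed mesh with nodal displacement and pore-pressure
#' fields in ASCII legacy VTK format for inspection in ParaView and
#' similar viewers.
#'
#' @param mesh A [build_mesh()] object.
#' @param state A [field_state()].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, state, path) {
  nn <- mesh$nn
  ur <- state$d[seq(1, 3 * nn, 3)]
  uz <- state$d[seq(2, 3 * nn, 3)]
  pp <- state$d[seq(3, 3 * nn, 3)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("tendonpve field snapshot t=%g s", state$t),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1] + ur,
                     mesh$nodes[, 2] + uz), con)
  writeLines(sprintf("CELLS %d %d", mesh$ne, 5 * mesh$ne), con)
  writeLines(apply(mesh$elems - 1L, 1, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", mesh$ne), con)
  writeLines(rep("9", mesh$ne), con)  # VTK_QUAD
  writeLines(sprintf("POINT_DATA %d", nn), con)
  writeLines("SCALARS pore_pressure double 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(sprintf("%.10g", pp), con)
  writeLines("VECTORS displacement double", con)
  writeLines(sprintf("%.10g %.10g 0", ur, uz), con)
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration, seed, package and R versions, and optional
#' input-file hashes, sufficient to reproduce deterministic outputs.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seed Seed used (or `NA`).
#' @param inputs Character vector of input file paths to hash (md5).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  man <- list(package = "tendonpve",
              version = as.character(packageVersion("tendonpve")),
              r_version = R.version.string,
              seed = seed, config = config, input_md5 = hashes)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
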