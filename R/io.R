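# Plain-text interchange formats. Reflections travel as CSV (with a
# commented header carrying the cell and role) or as a minimal
# structure-factor mmCIF loop; maps as binary CCP4/MRC (mode 2, P1),
# written at run time. MTZ is not supported (no reader/writer exists in
# the supported dependency set); CSV/CIF carry the same content.

#' Write a reflection set as CSV
#'
#' Columns h,k,l,f,sigf,phase; the cell, role and resolution limits go
#' into `#`-prefixed header lines so the file round-trips.
#'
#' @param rs A `reflection_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reflections_csv <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- rs$cell
  writeLines(c(
    sprintf("# cell: %.6f %.6f %.6f %.6f %.6f %.6f",
            cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
    sprintf("# role: %s", rs$role),
    "h,k,l,f,sigf,phase"), con)
  d <- rs$data
  writeLines(sprintf("%d,%d,%d,%.10g,%.10g,%s", d$h, d$k, d$l, d$f, d$sigf,
                     ifelse(is.na(d$phase), "", sprintf("%.10g", d$phase))),
             con)
  invisible(path)
}

#' Read a reflection set written by [write_reflections_csv()]
#' @param path Input path.
#' @return A `reflection_set`.
#' @export
read_reflections_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cellline <- hdr[grepl("^# cell:", hdr)]
  if (!length(cellline)) stop("missing '# cell:' header in ", path)
  cv <- as.numeric(strsplit(trimws(sub("^# cell:", "", cellline[1])), "\\s+")[[1]])
  role <- if (any(grepl("^# role:", hdr)))
    trimws(sub("^# role:", "", hdr[grepl("^# role:", hdr)][1])) else "plain"
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  ph <- if ("phase" %in% names(d)) d$phase else NULL
  out <- reflection_set(as.matrix(d[, c("h", "k", "l")]), f = abs(d$f),
                        sigf = d$sigf, phase = ph,
                        cell = unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6]),
                        role = role)
  out$data$f <- d$f          # preserve signed difference amplitudes
  out
}

#' Write a reflection set as a minimal structure-factor mmCIF
#' @param rs A `reflection_set`.
#' @param path Output path.
#' @param block Data block name.
#' @return `path`, invisibly.
#' @export
write_sf_cif <- function(rs, path, block = "trsfx") {
  cl <- rs$cell
  d <- rs$data
  lines <- c(
    sprintf("data_%s", block),
    sprintf("_cell.length_a %.6f", cl$a),
    sprintf("_cell.length_b %.6f", cl$b),
    sprintf("_cell.length_c %.6f", cl$c),
    sprintf("_cell.angle_alpha %.6f", cl$alpha),
    sprintf("_cell.angle_beta %.6f", cl$beta),
    sprintf("_cell.angle_gamma %.6f", cl$gamma),
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    "_refln.index_h", "_refln.index_k", "_refln.index_l",
    "_refln.F_meas_au", "_refln.F_meas_sigma_au", "_refln.phase_calc",
    sprintf("%d %d %d %.10g %.10g %s", d$h, d$k, d$l, d$f, d$sigf,
            ifelse(is.na(d$phase), "?", sprintf("%.10g", d$phase))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure-factor mmCIF written by [write_sf_cif()]
#' @param path Input path.
#' @return A `reflection_set`.
#' @export
read_sf_cif <- function(path) {
  lines <- readLines(path)
  getnum <- function(tag) {
    ln <- lines[startsWith(lines, tag)]
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  cell <- unit_cell(getnum("_cell.length_a"), getnum("_cell.length_b"),
                    getnum("_cell.length_c"), getnum("_cell.angle_alpha"),
                    getnum("_cell.angle_beta"), getnum("_cell.angle_gamma"))
  i0 <- max(which(startsWith(lines, "_refln."))) + 1
  rows <- lines[i0:length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  m <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
  ph <- suppressWarnings(as.numeric(m[, 6]))
  rs <- reflection_set(matrix(as.integer(m[, 1:3]), ncol = 3),
                       f = abs(as.numeric(m[, 4])), sigf = as.numeric(m[, 5]),
                       phase = ph, cell = cell)
  rs$data$f <- as.numeric(m[, 4])
  rs
}

#' Write a density map in CCP4/MRC format (mode 2, P1)
#' @param map A `density_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(map$values)
  cl <- map$cell
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NC, NR, NS
  wi(2)                      # mode 2: 32-bit float
  wi(c(0, 0, 0))             # start
  wi(d)                      # intervals
  wf(c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))
  wi(c(1, 2, 3))             # axis order
  v <- map$values
  wf(c(min(v), max(v), mean(v)))
  wi(1)                      # space group P1
  wi(0)                      # NSYMBT
  wi(rep(0, 25))             # extra
  wi(c(0, 0, 0))             # origin (MRC words 50-52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(map$map_sigma)
  wi(0)                      # NLABL
  writeBin(raw(800), con)    # labels
  wf(as.numeric(v))          # column-major == x fastest
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_ccp4_map()]
#' @param path Input path.
#' @return A `density_map`.
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float) maps are supported")
  ri(3); ri(3)
  cv <- rf(6)
  seek(con, 1024)
  v <- rf(prod(d))
  density_map(array(v, dim = d),
              unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6]))
}

#' Write a time trace (or fit) as CSV / JSON
#' @param trace A `time_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time, value = trace$value)
  if (!is.null(trace$sigma)) df$sigma <- trace$sigma
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a time trace from CSV (columns time_s, value, optional sigma)
#' @param path Input path.
#' @param label Trace label.
#' @return A `time_trace`.
#' @export
read_trace_csv <- function(path, label = "") {
  df <- utils::read.csv(path)
  time_trace(df$time_s, df$value, sigma = df$sigma, label = label)
}

#' Serialize a kinetic fit to JSON
#' @param fit A `kinetic_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(model = fit$model, status = fit$status,
                            parameters = as.list(fit$par),
                            se = as.list(fit$se), rss = fit$rss),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a two-column spectrum CSV (wavelength_nm, absorbance)
#' @param path Input path.
#' @param delay,crystal,power Optional metadata.
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, delay = NA_real_,
                              crystal = NA_character_, power = NA_real_) {
  df <- utils::read.csv(path, comment.char = "#")
  spectrum(df[[1]], df[[2]], delay = delay, crystal = crystal, power = power)
}

#' Write a spectrum as two-column CSV
#' @param spec A `spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(spec$delay)) writeLines(sprintf("# delay_s: %g", spec$delay), con)
  writeLines("wavelength_nm,absorbance", con)
  writeLines(sprintf("%.6g,%.10g", spec$wavelength, spec$absorbance), con)
  invisible(path)
}
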