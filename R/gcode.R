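# RepRap-style G-code writer and parser for planned toolpaths.
# Dialect: G21/G90 preamble, one G1 linear move per toolpath point with
# X/Y/Z (mm), optional A (rotary, deg), F (mm/min) and cumulative E
# (extruded volume, mm^3, from segment length x flow / feed). Layer and
# standoff changes are recorded as structured comments so that a parsed
# file reconstructs the full toolpath.

#' Write a toolpath as G-code
#'
#' @param path A `toolpath` object.
#' @param file Optional output file; when `NULL` the text is returned only.
#' @param decimals Coordinate precision (decimal places, default 4).
#' @param max_feed Machine feed limit (mm/min); moves beyond it raise an
#'   error listing the offending segments.
#' @return Character vector of G-code lines (invisibly when writing).
#' @export
write_gcode <- function(path, file = NULL, decimals = 4, max_feed = 12000) {
  stopifnot(inherits(path, "toolpath"))
  pts <- path$points
  lines <- c("; ropecoil toolpath",
             paste0("; substrate: ", path$substrate),
             "G21 ; millimetres", "G90 ; absolute", "G92 E0")
  fmt <- function(v) formatC(v, format = "f", digits = decimals)
  if (!is.null(pts) && nrow(pts) > 0) {
    bad <- which(pts$feed > max_feed)
    if (length(bad))
      stop_invalid("feed exceeds machine limit ", max_feed, " mm/min at point(s) ",
                   paste(head(bad, 10), collapse = ", "))
    e <- 0
    last <- list(layer = NA, standoff = NA, feed = NA)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      if (!identical(last$layer, p$layer)) {
        lines <- c(lines, paste0(";LAYER ", p$layer))
        last$layer <- p$layer
      }
      if (!isTRUE(last$standoff == p$standoff)) {
        lines <- c(lines, paste0(";STANDOFF ", fmt(p$standoff)))
        last$standoff <- p$standoff
      }
      cmd <- if (i == 1) "G0" else "G1"
      seg <- paste0(cmd, " X", fmt(p$x), " Y", fmt(p$y), " Z", fmt(p$z))
      if (!is.na(p$a)) seg <- paste0(seg, " A", fmt(p$a))
      if (i > 1) {
        q <- pts[i - 1, ]
        ds <- sqrt((p$x - q$x)^2 + (p$y - q$y)^2 + (p$z - q$z)^2)
        e <- e + ds * p$flow / p$feed  # flow uL/min == mm^3/min, so E is mm^3
        seg <- paste0(seg, " E", formatC(e, format = "f", digits = decimals))
      }
      # feed is stated on the first extruding move and whenever it changes
      if (cmd == "G1" && !isTRUE(last$feed == p$feed)) {
        seg <- paste0(seg, " F", fmt(p$feed))
        last$feed <- p$feed
      }
      lines <- c(lines, seg)
    }
  }
  lines <- c(lines, "; end")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse G-code back into a toolpath
#'
#' Inverse of [write_gcode()]: reconstructs coordinates, rotary angle, feed,
#' flow (from extrusion increments) and layer/standoff annotations. The
#' round trip is exact to the emitted decimal precision.
#'
#' @param x Character vector of G-code lines, or a file path.
#' @return A `toolpath` object.
#' @export
parse_gcode <- function(x) {
  if (length(x) == 1 && file.exists(x)) x <- readLines(x)
  layer <- 0L; standoff <- NA_real_; feed <- NA_real_
  rows <- list()
  prev <- NULL; prev_e <- 0
  for (ln in x) {
    if (grepl("^;LAYER ", ln)) {
      layer <- as.integer(sub("^;LAYER ", "", ln)); next
    }
    if (grepl("^;STANDOFF ", ln)) {
      standoff <- as.numeric(sub("^;STANDOFF ", "", ln)); next
    }
    if (!grepl("^G[01] ", ln)) next
    words <- strsplit(sub(" *;.*$", "", ln), " +")[[1]][-1]
    vals <- setNames(as.numeric(substring(words, 2)), substring(words, 1, 1))
    if ("F" %in% names(vals)) feed <- vals[["F"]]
    e <- if ("E" %in% names(vals)) vals[["E"]] else prev_e
    flow <- NA_real_
    if (!is.null(prev)) {
      ds <- sqrt((vals[["X"]] - prev$x)^2 + (vals[["Y"]] - prev$y)^2 +
                 (vals[["Z"]] - prev$z)^2)
      flow <- if (ds > 0) (e - prev_e) * feed / ds else NA_real_
    }
    row <- data.frame(x = vals[["X"]], y = vals[["Y"]], z = vals[["Z"]],
                      a = if ("A" %in% names(vals)) vals[["A"]] else NA_real_,
                      standoff = standoff, feed = feed, flow = flow,
                      layer = layer)
    rows[[length(rows) + 1L]] <- row
    prev <- row; prev_e <- e
  }
  pts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(), y = numeric(), z = numeric(), a = numeric(),
               standoff = numeric(), feed = numeric(), flow = numeric(),
               layer = integer())
  # the first (rapid) point carries no extrusion or feed; inherit from the
  # first extruding move
  if (nrow(pts) > 1) {
    if (is.na(pts$flow[1])) pts$flow[1] <- pts$flow[2]
    if (is.na(pts$feed[1])) pts$feed[1] <- pts$feed[2]
  }
  new_toolpath(pts, substrate = "parsed")
}
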