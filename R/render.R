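# Static rendering: an SVG writer (one <line> element per visible
# match, coloured by identity class, with sequence-border grid lines
# and grayed super-sequence margins) and a deterministic PNG rasteriser
# built on the same scene geometry.

#' Colour schemes for the four identity classes
#'
#' Six named palettes mapping identity classes 1-4 (low to high) to
#' colours; `"colorblind"` is deuteranopia-safe.
#'
#' @return Named list of character vectors of length 4.
#' @export
colorSchemas <- function() {
  list(
    default    = c("#fef0d9", "#fdcc8a", "#fc8d59", "#d7301f"),
    colorblind = c("#ffffcc", "#a1dab4", "#41b6c4", "#225ea8"),
    greens     = c("#edf8e9", "#bae4b3", "#74c476", "#238b45"),
    purples    = c("#f2f0f7", "#cbc9e2", "#9e9ac8", "#6a51a3"),
    heat       = c("#ffffb2", "#fecc5c", "#fd8d3c", "#e31a1c"),
    grays      = c("#f7f7f7", "#cccccc", "#969696", "#525252")
  )
}

#' Rendering options
#'
#' @param width,height Canvas size in pixels.
#' @param colorSchema Name of a palette from [colorSchemas()].
#' @param lineWidth Stroke width of match lines in pixels.
#' @param borderLines Draw sequence-border grid lines.
#' @param strongPrecision When `TRUE`, matches are drawn at true scale
#'   so sub-pixel matches vanish; when `FALSE` (default) matches
#'   shorter than `minVisualLength` pixels are padded to that length.
#' @param minVisualLength Minimum drawn match length in pixels.
#' @param margin Margin reserved for sequence names, in pixels.
#' @return A list of validated options.
#' @export
renderOptions <- function(width = 800, height = 800,
                          colorSchema = "default", lineWidth = 1.5,
                          borderLines = TRUE, strongPrecision = FALSE,
                          minVisualLength = 1, margin = 100) {
  schemas <- colorSchemas()
  if (!colorSchema %in% names(schemas))
    stop("unknown color schema '", colorSchema, "'; available: ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  stopifnot(width > 0, height > 0, lineWidth > 0, minVisualLength >= 0)
  list(width = width, height = height, colorSchema = colorSchema,
       palette = schemas[[colorSchema]], lineWidth = lineWidth,
       borderLines = borderLines, strongPrecision = strongPrecision,
       minVisualLength = minVisualLength, margin = margin)
}

# Scene geometry shared by the SVG and PNG backends: pixel-space match
# segments (after minimum-visual-length padding), sequence borders and
# grayed super-sequence margin boxes.
buildScene <- function(plot, options) {
  layQ <- layoutAxis(plot@query)
  layT <- layoutAxis(plot@target)
  if (layQ@total <= 0 || layT@total <= 0)
    stop("zero-length axis", call. = FALSE)
  w <- options$width - options$margin
  h <- options$height - options$margin
  sx <- w / layT@total
  sy <- h / layQ@total
  seg <- globalCoordinates(plot, layQ, layT)
  seg <- seg[order(-seg$blocklen), , drop = FALSE]   # draw big ones first
  x1 <- seg$x1 * sx; x2 <- seg$x2 * sx
  y1 <- seg$y1 * sy; y2 <- seg$y2 * sy
  if (!options$strongPrecision && nrow(seg)) {
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    short <- len < options$minVisualLength & len >= 0
    if (any(short)) {
      cx <- (x1 + x2) / 2; cy <- (y1 + y2) / 2
      ux <- ifelse(len > 0, (x2 - x1) / len, ifelse(seg$x2 >= seg$x1, 1, -1) / sqrt(2))
      uy <- ifelse(len > 0, (y2 - y1) / len, 1 / sqrt(2))
      half <- options$minVisualLength / 2
      x1[short] <- cx[short] - ux[short] * half
      x2[short] <- cx[short] + ux[short] * half
      y1[short] <- cy[short] - uy[short] * half
      y2[short] <- cy[short] + uy[short] * half
    }
  }
  list(layoutQ = layQ, layoutT = layT, sx = sx, sy = sy,
       plotWidth = w, plotHeight = h,
       segments = data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                             class = seg$class))
}

svgEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

truncateLabel <- function(name, maxChars) {
  long <- nchar(name) > maxChars & maxChars >= 5
  gone <- nchar(name) > maxChars & maxChars < 5
  half <- pmax(floor((maxChars - 1) / 2), 1)
  name[long] <- paste0(substr(name[long], 1, half[long]), "…",
                       substring(name[long], nchar(name[long]) - half[long] + 1))
  name[gone] <- ""
  name
}

#' Render a dot plot as SVG
#'
#' Draws one `<line>` element per visible match (after the plot's
#' active filters), coloured by identity class and placed by
#' [globalCoordinates()] scaled to the canvas. Sequence borders are
#' drawn as grid lines, margins carry (possibly truncated) sequence
#' names, and super-sequence margins are grayed. With
#' `strongPrecision`, sub-pixel matches are drawn at true scale instead
#' of being padded to `minVisualLength` pixels.
#'
#' @param plot A [DotPlot-class].
#' @param options Options from [renderOptions()].
#' @param path Optional output file.
#' @return The SVG document as a character string (invisibly when
#'   written to `path`).
#' @export
renderSvg <- function(plot, options = renderOptions(), path = NULL) {
  scene <- buildScene(plot, options)
  m <- options$margin
  W <- options$width; H <- options$height
  pw <- scene$plotWidth; ph <- scene$plotHeight
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            round(W), round(H), round(W), round(H)),
    sprintf('<rect class="background" x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            round(W), round(H)))
  # grayed super-sequence margin boxes (top margin: target; right: query)
  for (axis in c("t", "q")) {
    lay <- if (axis == "t") scene$layoutT else scene$layoutQ
    sc <- if (axis == "t") scene$sx else scene$sy
    for (g in which(lay@grayed)) {
      a <- lay@groupOffsets[g] * sc
      len <- lay@groupLengths[g] * sc
      if (axis == "t")
        out <- c(out, sprintf(
          '<rect class="super-margin" x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="#bbbbbb"/>',
          a, ph, len, m * 0.35))
      else
        out <- c(out, sprintf(
          '<rect class="super-margin" x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="#bbbbbb"/>',
          pw, a, m * 0.35, len))
    }
  }
  out <- c(out, sprintf(
    '<rect class="frame" x="0" y="0" width="%.2f" height="%.2f" fill="none" stroke="#000000"/>',
    pw, ph))
  if (options$borderLines) {
    for (off in scene$layoutT@groupOffsets[-1])
      out <- c(out, sprintf(
        '<line class="border" x1="%.2f" y1="0" x2="%.2f" y2="%.2f" stroke="#dddddd"/>',
        off * scene$sx, off * scene$sx, ph))
    for (off in scene$layoutQ@groupOffsets[-1])
      out <- c(out, sprintf(
        '<line class="border" x1="0" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#dddddd"/>',
        off * scene$sy, pw, off * scene$sy))
  }
  seg <- scene$segments
  if (nrow(seg))
    out <- c(out, sprintf(
      '<line class="match" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="%.2f"/>',
      seg$x1, seg$y1, seg$x2, seg$y2, options$palette[seg$class],
      options$lineWidth))
  # margin labels: target names along the top margin area, query names right
  for (axis in c("t", "q")) {
    lay <- if (axis == "t") scene$layoutT else scene$layoutQ
    sc <- if (axis == "t") scene$sx else scene$sy
    for (g in seq_along(lay@groups)) {
      label <- if (lay@grayed[g]) sprintf("[%d seqs]", length(lay@groups[[g]]))
               else lay@groups[[g]][1]
      mid <- (lay@groupOffsets[g] + lay@groupLengths[g] / 2) * sc
      maxChars <- max(floor(lay@groupLengths[g] * sc / 7), 0)
      label <- truncateLabel(label, maxChars)
      if (!nzchar(label)) next
      fill <- if (lay@grayed[g]) "#888888" else "#000000"
      if (axis == "t")
        out <- c(out, sprintf(
          '<text class="label" x="%.2f" y="%.2f" font-size="11" text-anchor="middle" fill="%s">%s</text>',
          mid, ph + m * 0.6, fill, svgEscape(label)))
      else
        out <- c(out, sprintf(
          '<text class="label" x="%.2f" y="%.2f" font-size="11" text-anchor="start" fill="%s">%s</text>',
          pw + m * 0.4, mid, fill, svgEscape(label)))
    }
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

# Deterministic raster backend: segments are rasterised with simple
# linear interpolation into an RGB array and written with png::writePNG,
# so identical inputs give identical bytes.
rasterScene <- function(scene, options) {
  W <- as.integer(round(options$width)); H <- as.integer(round(options$height))
  img <- array(1, dim = c(H, W, 3))
  setPx <- function(xs, ys, col) {
    xs <- as.integer(round(xs)) + 1L; ys <- as.integer(round(ys)) + 1L
    ok <- xs >= 1L & xs <= W & ys >= 1L & ys <= H
    xs <- xs[ok]; ys <- ys[ok]
    if (!length(xs)) return()
    rgb <- grDevices::col2rgb(col) / 255
    idx <- cbind(ys, xs)
    img[cbind(idx, 1L)] <<- rgb[1]
    img[cbind(idx, 2L)] <<- rgb[2]
    img[cbind(idx, 3L)] <<- rgb[3]
  }
  drawLine <- function(x1, y1, x2, y2, col, lw = 1) {
    n <- max(abs(x2 - x1), abs(y2 - y1), 1)
    t <- seq(0, 1, length.out = ceiling(n) + 1)
    xs <- x1 + t * (x2 - x1); ys <- y1 + t * (y2 - y1)
    r <- floor((lw - 1) / 2)
    for (dx in -r:r) for (dy in -r:r) setPx(xs + dx, ys + dy, col)
  }
  pw <- scene$plotWidth; ph <- scene$plotHeight
  drawLine(0, 0, pw, 0, "#000000"); drawLine(0, ph, pw, ph, "#000000")
  drawLine(0, 0, 0, ph, "#000000"); drawLine(pw, 0, pw, ph, "#000000")
  if (options$borderLines) {
    for (off in scene$layoutT@groupOffsets[-1])
      drawLine(off * scene$sx, 0, off * scene$sx, ph, "#dddddd")
    for (off in scene$layoutQ@groupOffsets[-1])
      drawLine(0, off * scene$sy, pw, off * scene$sy, "#dddddd")
  }
  seg <- scene$segments
  for (i in seq_len(nrow(seg)))
    drawLine(seg$x1[i], seg$y1[i], seg$x2[i], seg$y2[i],
             options$palette[seg$class[i]], ceiling(options$lineWidth))
  img
}

#' Render a dot plot as PNG
#'
#' Rasterises the same scene as [renderSvg()] at the requested pixel
#' size. Rendering is deterministic: identical inputs and options give
#' byte-identical files.
#'
#' @inheritParams renderSvg
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
renderPng <- function(plot, options = renderOptions(), path) {
  scene <- buildScene(plot, options)
  img <- rasterScene(scene, options)
  png::writePNG(img, path)
  invisible(path)
}

#' Render a summary profile bar graph
#'
#' A five-bar graph (four identity classes plus the uncovered fraction)
#' of a [SummaryProfile-class], as SVG or PNG.
#'
#' @param profile A [SummaryProfile-class].
#' @param options Options from [renderOptions()] (palette and size).
#' @param path Optional output file (required for PNG).
#' @return SVG text, or the PNG path invisibly.
#' @export
renderSummarySvg <- function(profile, options = renderOptions(width = 500, height = 400),
                             path = NULL) {
  W <- options$width; H <- options$height
  cols <- c(options$palette, "#eeeeee")
  labs <- c(identityClassLabels(), "no match")
  frac <- unname(profile@fractions)
  bw <- W * 0.8 / 5
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   round(W), round(H)),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
                   round(W), round(H)))
  for (i in 1:5) {
    x <- W * 0.1 + (i - 1) * bw
    bh <- frac[i] * (H - 60)
    out <- c(out, sprintf(
      '<rect class="bar" x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s" stroke="#000000"/>',
      x + bw * 0.1, H - 40 - bh, bw * 0.8, bh, cols[i]),
      sprintf('<text x="%.2f" y="%.2f" font-size="10" text-anchor="middle">%s</text>',
              x + bw / 2, H - 25, svgEscape(labs[i])),
      sprintf('<text x="%.2f" y="%.2f" font-size="10" text-anchor="middle">%.1f%%</text>',
              x + bw / 2, H - 45 - bh, 100 * frac[i]))
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) { writeLines(doc, path); return(invisible(doc)) }
  doc
}

#' @rdname renderSummarySvg
#' @export
renderSummaryPng <- function(profile, options = renderOptions(width = 500, height = 400),
                             path) {
  W <- as.integer(round(options$width)); H <- as.integer(round(options$height))
  img <- array(1, dim = c(H, W, 3))
  cols <- c(options$palette, "#eeeeee")
  frac <- unname(profile@fractions)
  bw <- W * 0.8 / 5
  for (i in 1:5) {
    x0 <- round(W * 0.1 + (i - 1) * bw + bw * 0.1)
    x1 <- round(x0 + bw * 0.8)
    bh <- round(frac[i] * (H - 60))
    if (bh < 1) next
    y0 <- H - 40 - bh; y1 <- H - 40
    rgb <- grDevices::col2rgb(cols[i]) / 255
    for (ch in 1:3)
      img[max(y0, 1):min(y1, H), max(x0, 1):min(x1, W), ch] <- rgb[ch]
  }
  png::writePNG(img, path)
  invisible(path)
}
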