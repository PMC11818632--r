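#' Draw a pipeline as an SVG diagram
#'
#' One node per stage, one edge per folder-mediated dependency (stage j
#' consumes what stage i produced); branched pipelines show as nodes with
#' out-degree above one. The document is plain SVG text, easy to edit and
#' embed.
#'
#' @param spec a validated [PipelineSpec-class].
#' @return character vector of SVG lines (write with \code{writeLines}).
#' @examples
#' svg <- drawPipeline(parsePipeline(c("copy in mid", "copy mid out")))
#' @export
drawPipeline <- function(spec) {
  stopifnot(is(spec, "PipelineSpec"))
  validObject(spec)
  s <- spec@stages
  n <- nrow(s)
  if (n == 0L) stop("cannot draw an empty pipeline", call. = FALSE)

  box_w <- 150; box_h <- 48; gap <- 60; margin <- 20
  x <- margin + (seq_len(n) - 1L) * (box_w + gap)
  y <- rep(margin, n)
  width <- margin * 2 + n * box_w + (n - 1L) * gap
  height <- margin * 2 + box_h + 24 + 6 * n  # room for skip-edge bows

  esc <- function(t) gsub("&", "&amp;", gsub("<", "&lt;", t))
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<defs><marker id="arrow" markerWidth="8" markerHeight="8" refX="7" refY="3" orient="auto"><path d="M0,0 L7,3 L0,6 z" fill="#333"/></marker></defs>')
  for (i in seq_len(n)) {
    label <- esc(s$module[i])
    sub <- esc(sprintf("%s %s %s", s$input[i], "→", s$output[i]))
    out <- c(out,
      sprintf('<rect class="stage" x="%d" y="%d" width="%d" height="%d" rx="6" fill="#eef3fb" stroke="#333"/>',
              x[i], y[i], box_w, box_h),
      sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="12" text-anchor="middle">%s</text>',
              x[i] + box_w %/% 2, y[i] + 20, label),
      sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="10" text-anchor="middle" fill="#555">%s</text>',
              x[i] + box_w %/% 2, y[i] + 36, sub))
  }
  # dependency edges: j consumes the folder i produced
  for (j in seq_len(n)) {
    prod <- which(s$output == s$input[j])
    for (i in prod[prod < j]) {
      if (i == j - 1L) {
        out <- c(out, sprintf(
          '<line class="dep" x1="%d" y1="%d" x2="%d" y2="%d" stroke="#333" marker-end="url(#arrow)"/>',
          x[i] + box_w, y[i] + box_h %/% 2, x[j] - 4, y[j] + box_h %/% 2))
      } else {  # skip edge, bow below the boxes
        midy <- margin + box_h + 18 + 6 * (j - i)
        out <- c(out, sprintf(
          '<path class="dep" d="M %d %d C %d %d, %d %d, %d %d" fill="none" stroke="#333" marker-end="url(#arrow)"/>',
          x[i] + box_w %/% 2, y[i] + box_h,
          x[i] + box_w %/% 2, midy, x[j] + box_w %/% 2, midy,
          x[j] + box_w %/% 2, y[j] + box_h + 4))
      }
    }
  }
  c(out, "</svg>")
}
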