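# Fixed-format numbers keep SVG/JSON output byte-stable across runs.
fmt <- function(x, digits = 4) sprintf(paste0("%.", digits, "f"), x)

# Position anchor on the circle: position 1 at 12 o'clock, clockwise.
circle_xy <- function(pos, L, cx, cy, r) {
  theta <- -pi / 2 + 2 * pi * (pos - 1) / L
  c(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

# Chord opacity: affine and monotone in probability, full opacity at p = 1.
chord_opacity <- function(p) 0.1 + 0.9 * p

#' Render one cluster node as an SVG circle-chord diagram
#'
#' Nucleotides sit on a circle (position 1 at 12 o'clock, clockwise, ticks
#' every 10 nt) and each basepair is a straight chord between its two
#' positions, drawn with opacity proportional to its node-conditional
#' probability. Chords for the node's path constraints are highlighted: red
#' when the MIBP is constrained present, blue when absent; all other chords
#' are black and chords below the plotting floor are omitted.
#'
#' @param node_list one node of the plain-list tree representation (an
#'   element of `report.json`'s tree, or of `tree_as_list()`).
#' @param L sequence length.
#' @param floor minimum probability for an unhighlighted chord (default
#'   0.01).
#' @param size SVG canvas size in px.
#' @return Single SVG string.
#' @export
render_node_svg <- function(node_list, L, floor = 0.01, size = 500) {
  cx <- size / 2; cy <- size / 2; r <- size * 0.42
  cons <- node_list$constraints
  cons_key <- vapply(cons, function(c) paste(c$i, c$j, sep = "-"), character(1))
  cons_state <- vapply(cons, function(c) c$state, character(1))
  lines <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" ',
           'viewBox="0 0 %d %d">'), size, size, size, size),
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#888" stroke-width="1"/>',
            fmt(cx, 1), fmt(cy, 1), fmt(r, 1)))
  for (pos in seq(10, L, by = 10)) {
    a <- circle_xy(pos, L, cx, cy, r)
    b <- circle_xy(pos, L, cx, cy, r * 1.04)
    t <- circle_xy(pos, L, cx, cy, r * 1.12)
    lines <- c(lines,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888" stroke-width="1"/>',
              fmt(a["x"], 1), fmt(a["y"], 1), fmt(b["x"], 1), fmt(b["y"], 1)),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="middle">%d</text>',
              fmt(t["x"], 1), fmt(t["y"], 1), pos))
  }
  chord <- function(i, j, p, color) {
    a <- circle_xy(i, L, cx, cy, r)
    b <- circle_xy(j, L, cx, cy, r)
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2" stroke-opacity="%s"/>',
            fmt(a["x"], 1), fmt(a["y"], 1), fmt(b["x"], 1), fmt(b["y"], 1),
            color, fmt(chord_opacity(p)))
  }
  for (m in node_list$marginals) {
    key <- paste(m$i, m$j, sep = "-")
    if (key %in% cons_key) next
    if (m$p < floor) next
    lines <- c(lines, chord(m$i, m$j, m$p, "black"))
  }
  marg_key <- vapply(node_list$marginals,
                     function(m) paste(m$i, m$j, sep = "-"), character(1))
  for (k in seq_along(cons)) {
    p <- 0
    hit <- match(cons_key[k], marg_key)
    if (!is.na(hit)) p <- node_list$marginals[[hit]]$p
    color <- if (cons_state[k] == "present") "red" else "blue"
    lines <- c(lines, chord(cons[[k]]$i, cons[[k]]$j, p, color))
  }
  paste(c(lines, "</svg>"), collapse = "\n")
}

html_node <- function(node_list, svgs, depth = 0) {
  head <- sprintf("Cluster %d &mdash; p = %s, conditional entropy = %s bits",
                  node_list$id, fmt(node_list$probability),
                  fmt(node_list$conditional_entropy))
  if (!is.null(node_list$mibp)) {
    head <- paste0(head, sprintf(" &mdash; MIBP {%d,%d} (MI sum %s bits)",
                                 node_list$mibp$i, node_list$mibp$j,
                                 fmt(node_list$mibp$mi_sum)))
  }
  body <- svgs[[as.character(node_list$id)]]
  if (length(node_list$conflicting_pairs) > 0) {
    confl <- paste(vapply(node_list$conflicting_pairs, function(cp) {
      sprintf("{%d,%d} (p = %s)", cp$i, cp$j, fmt(cp$p))
    }, character(1)), collapse = ", ")
    body <- paste0(body, sprintf("<p>Conflicting basepairs: %s</p>", confl))
  }
  kids <- ""
  if (!is.null(node_list$children)) {
    kids <- paste0(
      html_node(node_list$children$present, svgs, depth + 1),
      html_node(node_list$children$absent, svgs, depth + 1))
  }
  sprintf('<details%s><summary>%s</summary>\n%s\n%s</details>\n',
          if (depth == 0) " open" else "", head, body, kids)
}

#' Render the cluster tree report
#'
#' Writes a fully static report to `out_dir`: one `node_<id>.svg` circle
#' diagram per cluster node, a machine-readable `report.json` mirroring the
#' tree serialization (plus the resolved configuration and any extra
#' fields), and a self-contained `report.html` laying the clusters out as a
#' collapsible binary tree (`<details>`/`<summary>`, no scripts or network
#' resources) with the diagrams inlined. Output is deterministic: equal
#' trees and options produce byte-identical files.
#'
#' @param tree an `mibp_tree`, or a plain tree list (parsed `report.json`).
#' @param out_dir output directory (created if missing).
#' @param floor plotting floor for unhighlighted chords (default 0.01).
#' @param extra named list merged into the JSON report (e.g. counts).
#' @return Named list of written paths, invisibly.
#' @export
render_report <- function(tree, out_dir, floor = 0.01, extra = list()) {
  tl <- if (inherits(tree, "mibp_tree")) tree_as_list(tree) else tree
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  L <- nchar(tl$sequence$residues)
  svgs <- list()
  paths <- list()
  walk <- function(node) {
    svg <- render_node_svg(node, L, floor = floor)
    svgs[[as.character(node$id)]] <<- svg
    p <- file.path(out_dir, sprintf("node_%d.svg", node$id))
    writeLines(svg, p)
    paths[[sprintf("node_%d", node$id)]] <<- p
    if (!is.null(node$children)) {
      walk(node$children$present)
      walk(node$children$absent)
    }
  }
  walk(tl$root)
  report <- c(tl, list(plot_floor = floor), extra)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>MIBP clusters: %s</title>", tl$sequence$name),
    "<style>details{margin-left:1.5em;border-left:1px solid #ccc;padding-left:0.5em}summary{cursor:pointer;font-family:monospace}</style>",
    "</head><body>",
    sprintf("<h1>MIBP cluster tree &mdash; %s (%d nt, %d samples)</h1>",
            tl$sequence$name, L, tl$n_samples),
    html_node(tl$root, svgs),
    "</body></html>")
  html_path <- file.path(out_dir, "report.html")
  writeLines(html, html_path)
  invisible(c(list(html = html_path, json = json_path), paths))
}
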