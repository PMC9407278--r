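## Quoting rule for blocks in the text notation: blocks containing a comma,
## parenthesis, brace, slash, double quote or whitespace are wrapped in
## double quotes with backslash escapes for '"' and '\'.
lp_needs_quote <- function(block) grepl('[,(){}/"\\\\[:space:]]', block)

lp_quote_block <- function(block) {
  if (!lp_needs_quote(block)) return(block)
  paste0('"', gsub('(["\\\\])', "\\\\\\1", block), '"')
}

#' Serialize a ladderpath to the canonical text notation
#'
#' Levels are joined by `" // "` (an ASCII stand-in for the level separator
#' of the partially ordered multiset notation), blocks within a level are
#' comma-separated and sorted lexicographically, and the multiplicity
#' suffix `"(m)"` is omitted when `m = 1`.
#'
#' @param lp a `ladderpath` object.
#' @return A single string, e.g. `"{A, B, C, D, E, F // CD, EF // BCD(2)}"`.
#' @export
serialize_pom <- function(lp) {
  stopifnot(inherits(lp, "ladderpath"))
  ld <- lp$ladderons
  if (nrow(ld) == 0L) return("{}")
  items <- vapply(seq_len(nrow(ld)), function(i) {
    paste0(lp_quote_block(ld$block[i]),
           if (ld$multiplicity[i] > 1L) sprintf("(%d)", ld$multiplicity[i])
           else "")
  }, "")
  lev <- split(items, ld$level)  # ld is already sorted by level then block
  paste0("{", paste(vapply(lev, paste, "", collapse = ", "),
                    collapse = " // "), "}")
}

## split a level string into items, honouring quoted blocks
lp_split_items <- function(text, level_no) {
  items <- character(0)
  buf <- character(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L; inq <- FALSE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (inq) {
      if (ch == "\\" && i < length(chars)) {
        buf <- c(buf, chars[i + 1L]); i <- i + 2L; next
      }
      if (ch == '"') inq <- FALSE else buf <- c(buf, ch)
      # keep the quote markers out of the value but remember quoting
      if (ch == '"') buf <- c(buf, "\x01")  # sentinel: closed quote
    } else if (ch == '"') {
      inq <- TRUE
      buf <- c(buf, "\x01")  # sentinel: open quote
    } else if (ch == ",") {
      items <- c(items, paste(buf, collapse = "")); buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  if (inq)
    stop(sprintf("level %d: unterminated quoted block", level_no),
         call. = FALSE)
  items <- c(items, paste(buf, collapse = ""))
  trimws(items)
}

## parse one item "BLOCK" / "BLOCK(m)" (possibly with quote sentinels)
lp_parse_item <- function(item, level_no, item_no) {
  err <- function(msg)
    stop(sprintf("level %d, item %d: %s", level_no, item_no, msg),
         call. = FALSE)
  mult <- 1L
  quoted <- grepl("\x01", item, fixed = TRUE)
  if (quoted) {
    m <- regmatches(item, regexec("^\x01(.*)\x01(\\(([0-9]+)\\))?$", item))[[1]]
    if (length(m) == 0L) err("malformed quoted block")
    block <- m[2]
    if (nzchar(m[4])) mult <- as.integer(m[4])
  } else {
    m <- regmatches(item, regexec("^(.*?)(\\(([-0-9]+)\\))?$", item))[[1]]
    block <- m[2]
    if (nzchar(m[4])) mult <- suppressWarnings(as.integer(m[4]))
  }
  if (!nzchar(block)) err("empty block")
  if (is.na(mult) || mult < 1L) err(paste0("non-positive multiplicity for ",
                                           block))
  list(block = block, multiplicity = mult)
}

#' Parse the partially-ordered-multiset text notation
#'
#' Accepts the canonical `" // "` level separator as well as the
#' double-slash glyph used in print.  The result is a `ladderpath` bound to
#' the given basic set and target; validation is left to the caller (see
#' [validate_ladderpath()]).
#'
#' @param text notation string, e.g.
#'   `"{A, B, C, D, E, F // CD, EF // BCD(2)}"`.
#' @param basic a [basic_set()].
#' @param target a [target_system()] (or character vector).
#' @return A `ladderpath` object.
#' @export
parse_pom <- function(text, basic, target) {
  stopifnot(is_basic_set(basic))
  target <- as_target_system(target)
  text <- gsub("⫽", " // ", text)
  text <- trimws(text)
  if (!startsWith(text, "{") || !endsWith(text, "}"))
    stop("notation must be wrapped in { }", call. = FALSE)
  body <- trimws(substr(text, 2L, nchar(text) - 1L))
  if (!nzchar(body))
    return(new_ladderpath(data.frame(), basic, target, mode = "given"))
  levels <- strsplit(body, "//", fixed = TRUE)[[1]]
  rows <- list()
  for (l in seq_along(levels)) {
    items <- lp_split_items(trimws(levels[l]), l)
    for (k in seq_along(items)) {
      it <- lp_parse_item(items[k], l, k)
      rows[[length(rows) + 1L]] <-
        data.frame(block = it$block, multiplicity = it$multiplicity,
                   level = l, stringsAsFactors = FALSE)
    }
  }
  ladderons <- do.call(rbind, rows)
  if (anyDuplicated(ladderons$block))
    stop("duplicate block in notation: ",
         ladderons$block[duplicated(ladderons$block)][1], call. = FALSE)
  new_ladderpath(ladderons, basic, target, mode = "given")
}

## ---- laddergraph --------------------------------------------------------

## Build the laddergraph view: nodes (blocks by level, plus grey target
## nodes on top), edges = constituent relations from the witness
## segmentations, transitively reduced; edges leaving basic blocks are
## dimmed.
lp_laddergraph <- function(lp) {
  val <- validate_ladderpath(lp)
  if (!val$valid)
    stop("cannot draw an invalid ladderpath: ", val$reason, call. = FALSE)
  ld <- lp$ladderons
  top <- if (nrow(ld)) max(ld$level) + 1L else 2L
  nodes <- data.frame(id = ld$block,
                      label = paste0(ld$block,
                                     ifelse(ld$multiplicity > 1L,
                                            sprintf("(%d)", ld$multiplicity),
                                            "")),
                      level = ld$level, basic = ld$basic, target = FALSE,
                      stringsAsFactors = FALSE)
  edges <- list()
  add_edges <- function(seg, to) {
    for (b in unique(seg))
      edges[[length(edges) + 1L]] <<- data.frame(from = b, to = to,
                                                 stringsAsFactors = FALSE)
  }
  for (b in names(val$segmentations)) add_edges(val$segmentations[[b]], b)
  # target nodes, one per member, labelled "[xN] STRING (0)"
  for (i in seq_len(nrow(lp$target))) {
    s <- lp$target$string[i]
    tid <- paste0("target:", s)
    nodes <- rbind(nodes,
                   data.frame(id = tid,
                              label = sprintf("[×%d] %s (0)",
                                              lp$target$count[i], s),
                              level = top, basic = FALSE, target = TRUE,
                              stringsAsFactors = FALSE))
    if (s %in% ld$block) {
      add_edges(s, tid)
    } else {
      cand <- c(ld$block, setdiff(lp$basic$blocks, ld$block))
      lev <- c(ld$level, rep.int(1L, length(setdiff(lp$basic$blocks,
                                                    ld$block))))
      seg <- lp_find_segmentation(s, cand, lev, need_level = max(lev))
      if (is.null(seg)) {
        # any segmentation over the blocks will do for drawing
        for (need in sort(unique(lev), decreasing = TRUE)) {
          seg <- lp_find_segmentation(s, cand, lev, need_level = need)
          if (!is.null(seg)) break
        }
      }
      add_edges(seg, tid)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges))
           else data.frame(from = character(0), to = character(0),
                           stringsAsFactors = FALSE)
  edges <- lp_transitive_reduction(edges)
  edges$dim <- nodes$basic[match(edges$from, nodes$id)]
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

## remove every edge (u,v) for which a longer path u -> ... -> v exists
lp_transitive_reduction <- function(edges) {
  if (nrow(edges) < 2L) return(edges)
  adj <- split(edges$to, edges$from)
  reach_memo <- new.env(parent = emptyenv())
  reach <- function(v) {  # all nodes reachable from v (v excluded)
    if (!is.null(reach_memo[[v]])) return(reach_memo[[v]])
    reach_memo[[v]] <- character(0)  # DAG: no cycles, placeholder unused
    out <- character(0)
    for (w in adj[[v]]) out <- union(out, c(w, reach(w)))
    reach_memo[[v]] <- out
    out
  }
  keep <- vapply(seq_len(nrow(edges)), function(k) {
    u <- edges$from[k]; v <- edges$to[k]
    via <- setdiff(adj[[u]], v)
    !any(vapply(via, function(w) v %in% reach(w), TRUE))
  }, TRUE)
  edges[keep, , drop = FALSE]
}

#' Export a laddergraph as a Graphviz DOT document
#'
#' One node per block with multiplicity labels, target nodes in grey with a
#' `[xN]` prefix and a `(0)` multiplicity annotation, nodes ranked by
#' level, edges incident to basic blocks dimmed, and the edge set reduced
#' to the transitive reduction of the constituent relation.
#'
#' @param lp a valid `ladderpath` object.
#' @param path optional file to write to.
#' @return The DOT document as a character string (invisibly when `path`
#'   is given).
#' @export
export_laddergraph <- function(lp, path = NULL) {
  g <- lp_laddergraph(lp)
  q <- function(x) paste0('"', gsub('(["\\\\])', "\\\\\\1", x), '"')
  lines <- c("digraph laddergraph {",
             "  rankdir=BT;",
             "  node [shape=box, fontname=\"Helvetica\"];")
  for (l in sort(unique(g$nodes$level))) {
    ids <- g$nodes$id[g$nodes$level == l]
    lines <- c(lines, paste0("  { rank=same; ",
                             paste0(q(ids), ";", collapse = " "), " }"))
  }
  for (i in seq_len(nrow(g$nodes))) {
    style <- if (g$nodes$target[i])
      ", color=grey60, fontcolor=grey40, style=filled, fillcolor=grey92"
    else ""
    lines <- c(lines, sprintf("  %s [label=%s%s];",
                              q(g$nodes$id[i]), q(g$nodes$label[i]), style))
  }
  for (i in seq_len(nrow(g$edges))) {
    attr <- if (g$edges$dim[i]) " [color=grey70]" else ""
    lines <- c(lines, sprintf("  %s -> %s%s;", q(g$edges$from[i]),
                              q(g$edges$to[i]), attr))
  }
  lines <- c(lines, "}")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
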