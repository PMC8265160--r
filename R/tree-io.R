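#' Detect the format of a lineage-tree file
#'
#' Lineage trees are accepted in two on-disk formats: Newick and a
#' hierarchical JSON schema (objects with `"name"`, optional `"children"`,
#' optional `"length"`).  The format is identified from the content itself:
#' text whose first non-whitespace character opens a JSON value that
#' validates as JSON is `"json"`; text beginning with `(` or a bare label
#' and ending with `;` is `"newick"`.
#'
#' @param text raw file content as a single string.
#' @return `"newick"` or `"json"`.
#' @export
detect_tree_format <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- sub("^[[:space:]]+", "", text)
  if (!nzchar(stripped)) stop("empty tree file")
  first <- substr(stripped, 1L, 1L)
  if (first %in% c("{", "[") && jsonlite::validate(stripped)) return("json")
  trailing <- sub("[[:space:]]+$", "", stripped)
  if (endsWith(trailing, ";")) return("newick")
  stop("unrecognizable tree format: content is not valid JSON (no parseable ",
       "object/array) and not Newick (does not end with ';')")
}

# --- Newick ------------------------------------------------------------

# Characters that terminate an unquoted Newick label.
.nwk_specials <- c("(", ")", ",", ":", ";", "[", "]", "'")

#' Parse a Newick lineage tree
#'
#' Supports the common dialect: single-quoted labels (with `''` escaping a
#' quote), square-bracket comments (stripped), and whitespace outside quotes
#' ignored.  Underscores in labels are preserved verbatim.  Unlabelled
#' internal nodes are auto-named breadth-first from the root as `_n1`,
#' `_n2`, ... so that every node has a unique label usable as a join key.
#'
#' @param text Newick string (must end with `;`).
#' @param bl_mode how colon-suffixed numbers are to be interpreted:
#'   `"none"` (discard with a warning if present), `"relative"`
#'   (parent-to-child distances) or `"absolute"` (distances from the root,
#'   non-decreasing towards the leaves).
#' @return A [lineage_tree()].
#' @examples
#' tr <- parse_newick("((A:1,B:2):1,C:3);", bl_mode = "relative")
#' node_times(tr)[["A"]]  # 2
#' @export
parse_newick <- function(text, bl_mode = c("none", "relative", "absolute")) {
  bl_mode <- match.arg(bl_mode)
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pos <- 1L

  perr <- function(msg, at = pos) {
    stop("Newick parse error at position ", at, ": ", msg, call. = FALSE)
  }
  skip_ws <- function() {
    while (pos <= n) {
      c0 <- ch[pos]
      if (c0 %in% c(" ", "\t", "\n", "\r")) {
        pos <<- pos + 1L
      } else if (c0 == "[") {
        start <- pos
        while (pos <= n && ch[pos] != "]") pos <<- pos + 1L
        if (pos > n) perr("unclosed comment '['", start)
        pos <<- pos + 1L
      } else break
    }
  }
  read_label <- function() {
    skip_ws()
    if (pos <= n && ch[pos] == "'") {
      start <- pos
      pos <<- pos + 1L
      out <- character(0)
      repeat {
        if (pos > n) perr("unterminated quoted label", start)
        if (ch[pos] == "'") {
          if (pos + 1L <= n && ch[pos + 1L] == "'") {
            out <- c(out, "'")
            pos <<- pos + 2L
          } else {
            pos <<- pos + 1L
            break
          }
        } else {
          out <- c(out, ch[pos])
          pos <<- pos + 1L
        }
      }
      paste(out, collapse = "")
    } else {
      out <- character(0)
      while (pos <= n && !(ch[pos] %in% .nwk_specials) &&
             !(ch[pos] %in% c(" ", "\t", "\n", "\r"))) {
        out <- c(out, ch[pos])
        pos <<- pos + 1L
      }
      paste(out, collapse = "")
    }
  }
  read_length <- function() {
    skip_ws()
    if (pos > n || ch[pos] != ":") return(NA_real_)
    pos <<- pos + 1L
    skip_ws()
    start <- pos
    while (pos <= n && (grepl("[0-9eE.+-]", ch[pos]))) pos <<- pos + 1L
    num <- paste(ch[start:(pos - 1L)], collapse = "")
    val <- suppressWarnings(as.numeric(num))
    if (pos == start || is.na(val)) perr("expected a branch length after ':'", start)
    if (val < 0) perr("negative branch length", start)
    val
  }

  labels <- character(0)
  parent <- integer(0)
  blen <- numeric(0)
  new_node <- function(p) {
    labels[length(labels) + 1L] <<- ""
    parent[length(parent) + 1L] <<- p
    blen[length(blen) + 1L] <<- NA_real_
    length(labels)
  }

  stack <- integer(0)       # open internal nodes
  last <- NA_integer_       # node awaiting label/length
  saw_length <- FALSE
  expect_child <- TRUE      # TRUE right after '(' or ','

  skip_ws()
  repeat {
    skip_ws()
    if (pos > n) perr("unexpected end of input (missing ';')", n)
    c0 <- ch[pos]
    if (c0 == "(") {
      if (!expect_child) perr("unexpected '('")
      p <- if (length(stack)) stack[length(stack)] else NA_integer_
      node <- new_node(p)
      stack <- c(stack, node)
      pos <- pos + 1L
      expect_child <- TRUE
    } else if (c0 == ",") {
      if (expect_child) {  # empty child slot -> unnamed leaf
        p <- if (length(stack)) stack[length(stack)] else
          perr("',' outside parentheses")
        last <- new_node(p)
      }
      if (!length(stack)) perr("',' outside parentheses")
      pos <- pos + 1L
      expect_child <- TRUE
    } else if (c0 == ")") {
      if (!length(stack)) perr("unbalanced ')'")
      if (expect_child) {
        last <- new_node(stack[length(stack)])
      }
      last <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
      lab <- read_label()
      if (nzchar(lab)) labels[last] <- lab
      bl <- read_length()
      if (!is.na(bl)) { blen[last] <- bl; saw_length <- TRUE }
      expect_child <- FALSE
    } else if (c0 == ";") {
      if (length(stack)) perr("unbalanced '(' still open at ';'")
      if (expect_child && !length(labels)) perr("empty tree before ';'")
      pos <- pos + 1L
      skip_ws()
      if (pos <= n) perr("trailing content after ';'")
      break
    } else {
      if (!expect_child) perr(paste0("unexpected character '", c0, "'"))
      p <- if (length(stack)) stack[length(stack)] else NA_integer_
      last <- new_node(p)
      lab <- read_label()
      if (nzchar(lab)) labels[last] <- lab
      bl <- read_length()
      if (!is.na(bl)) { blen[last] <- bl; saw_length <- TRUE }
      expect_child <- FALSE
    }
  }

  finalize_parsed_tree(labels, parent, blen, saw_length, bl_mode)
}

# Shared tail of both parsers: auto-name blanks breadth-first, reconcile the
# requested branch-length mode with what the file contained, and construct.
finalize_parsed_tree <- function(labels, parent, blen, saw_length, bl_mode) {
  if (saw_length && bl_mode == "none") {
    warning("branch lengths present in file but bl_mode = 'none'; lengths discarded")
  }
  if (!saw_length && bl_mode != "none") {
    stop("bl_mode = '", bl_mode, "' but the file contains no branch lengths")
  }
  bl <- NULL
  if (bl_mode != "none") {
    bl <- blen
    root <- which(is.na(parent))
    if (length(root) == 1L && is.na(bl[root])) {
      bl[root] <- 0  # root distance/offset defaults to 0 when absent
    }
    missing <- which(is.na(bl))
    if (length(missing)) {
      stop("branch length missing for node(s): ",
           paste(utils::head(ifelse(nzchar(labels[missing]), labels[missing],
                                    paste0("#", missing)), 5L), collapse = ", "))
    }
  }
  tr <- structure(
    list(labels = labels, parent = parent,
         children = rebuild_children(parent),
         branch_length = bl, bl_mode = if (is.null(bl)) "none" else bl_mode,
         root = which(is.na(parent))),
    class = "lineage_tree"
  )
  tr <- autoname_blank_nodes(tr)
  lineage_tree(tr$labels, tr$parent, tr$branch_length, tr$bl_mode)
}

rebuild_children <- function(parent) {
  n <- length(parent)
  children <- rep(list(integer()), n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  children
}

# Deterministic auto-naming: blanks are visited breadth-first from the root
# and named "_n1", "_n2", ...; counters skip names already taken.
autoname_blank_nodes <- function(tree) {
  blanks <- which(!nzchar(tree$labels))
  if (!length(blanks)) return(tree)
  taken <- tree$labels[nzchar(tree$labels)]
  k <- 1L
  for (i in bfs_order(tree)) {
    if (nzchar(tree$labels[i])) next
    repeat {
      cand <- paste0("_n", k)
      k <- k + 1L
      if (!(cand %in% taken)) break
    }
    tree$labels[i] <- cand
    taken <- c(taken, cand)
  }
  tree
}

# --- JSON --------------------------------------------------------------

#' Parse a hierarchical-JSON lineage tree
#'
#' The accepted schema is one nested object per node with keys `"name"`
#' (required; an empty string is auto-named like an unlabelled Newick node),
#' `"children"` (optional list of child node objects) and `"length"`
#' (optional branch length).  Other keys are ignored with a warning.
#'
#' @inheritParams parse_newick
#' @param text JSON string.
#' @return A [lineage_tree()].
#' @export
parse_json_tree <- function(text, bl_mode = c("none", "relative", "absolute")) {
  bl_mode <- match.arg(bl_mode)
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.list(obj)) stop("JSON tree must be an object at the top level")

  labels <- character(0)
  parent <- integer(0)
  blen <- numeric(0)
  saw_length <- FALSE
  unknown <- character(0)

  walk <- function(node, p) {
    if (!is.list(node)) stop("JSON tree node is not an object")
    if (is.null(node$name)) stop("JSON tree node is missing its 'name' field")
    extra <- setdiff(names(node), c("name", "children", "length"))
    if (length(extra)) unknown <<- union(unknown, extra)
    i <- length(labels) + 1L
    labels[i] <<- as.character(node$name)
    parent[i] <<- p
    blen[i] <<- NA_real_
    if (!is.null(node$length)) {
      if (!is.numeric(node$length) && is.na(suppressWarnings(as.numeric(node$length))))
        stop("non-numeric 'length' at node '", node$name, "'")
      blen[i] <<- as.numeric(node$length)
      saw_length <<- TRUE
    }
    if (!is.null(node$children)) {
      if (!is.list(node$children) || !is.null(names(node$children)))
        stop("'children' of node '", node$name, "' must be a list of nodes")
      for (child in node$children) walk(child, i)
    }
    invisible(NULL)
  }
  walk(obj, NA_integer_)
  if (length(unknown)) {
    warning("ignored unknown JSON keys: ", paste(sort(unknown), collapse = ", "))
  }
  finalize_parsed_tree(labels, parent, blen, saw_length, bl_mode)
}

# --- Writers -----------------------------------------------------------

# Numbers are printed with the fewest digits that still re-parse to the
# exact same double (up to 17 significant digits), so every writer is
# lossless against its reader.
fmt_num <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      out <- format(v, digits = d, scientific = FALSE)
      if (grepl(".", out, fixed = TRUE)) {
        out <- sub("\\.$", "", sub("0+$", "", out))
      }
      if (as.numeric(out) == v) return(out)
    }
    out
  }, character(1))
}

needs_quoting <- function(label) {
  grepl("[][(),:;'[:space:]]", label) || !nzchar(label)
}

nwk_label <- function(label) {
  if (needs_quoting(label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else label
}

#' Serialize a lineage tree to Newick
#'
#' Labels needing protection are single-quoted; branch lengths (relative or
#' absolute, whichever mode the tree carries) are written as colon suffixes.
#' The output re-parses to an isomorphic tree.
#'
#' @param tree a `lineage_tree`.
#' @return A single Newick string ending in `;`.
#' @export
to_newick <- function(tree) {
  ser <- function(i) {
    bl <- if (tree$bl_mode == "none") "" else paste0(":", fmt_num(tree$branch_length[i]))
    kids <- tree$children[[i]]
    if (!length(kids)) return(paste0(nwk_label(tree$labels[i]), bl))
    paste0("(", paste(vapply(kids, ser, character(1)), collapse = ","), ")",
           nwk_label(tree$labels[i]), bl)
  }
  paste0(ser(tree$root), ";")
}

#' Serialize a lineage tree to hierarchical JSON
#'
#' Emits the same schema [parse_json_tree()] reads (`"name"`, `"children"`,
#' `"length"`), so any tree round-trips.
#'
#' @param tree a `lineage_tree`.
#' @return A JSON string.
#' @export
to_json <- function(tree) {
  esc <- function(s) {
    s <- gsub("\\", "\\\\", s, fixed = TRUE)
    s <- gsub('"', '\\"', s, fixed = TRUE)
    s <- gsub("\n", "\\n", s, fixed = TRUE)
    gsub("\t", "\\t", s, fixed = TRUE)
  }
  # assembled by hand so branch lengths keep full double precision
  ser <- function(i) {
    parts <- paste0('"name":"', esc(tree$labels[i]), '"')
    if (tree$bl_mode != "none") {
      parts <- c(parts, paste0('"length":', fmt_num(tree$branch_length[i])))
    }
    kids <- tree$children[[i]]
    if (length(kids)) {
      parts <- c(parts, paste0('"children":[',
                               paste(vapply(kids, ser, character(1)),
                                     collapse = ","), "]"))
    }
    paste0("{", paste(parts, collapse = ","), "}")
  }
  ser(tree$root)
}

# --- Times and branch-length conversion --------------------------------

#' Developmental time of each node
#'
#' Returns each node's distance from the root.  In absolute mode this is the
#' stored branch length itself; in relative mode it is the sum of branch
#' lengths along the root-to-node path.  Times are non-decreasing along
#' every root-to-leaf path.
#'
#' @param tree a `lineage_tree` with `bl_mode` other than `"none"`.
#' @return Named numeric vector over all node labels.
#' @export
node_times <- function(tree) {
  if (tree$bl_mode == "none") {
    stop("node_times requires branch lengths (bl_mode is 'none')")
  }
  n <- length(tree$labels)
  times <- numeric(n)
  if (tree$bl_mode == "absolute") {
    times <- tree$branch_length
  } else {
    for (i in bfs_order(tree)) {
      p <- tree$parent[i]
      times[i] <- if (is.na(p)) tree$branch_length[i] else
        times[p] + tree$branch_length[i]
    }
    # in relative mode the root's own length is an offset from time zero
  }
  stats::setNames(times, tree$labels)
}

#' Convert between relative and absolute branch-length conventions
#'
#' Node times are invariant under conversion; converting twice restores the
#' original lengths (to within 1e-9).
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param target `"relative"` or `"absolute"`.
#' @return A `lineage_tree` in the target mode.
#' @export
convert_bl_mode <- function(tree, target = c("relative", "absolute")) {
  target <- match.arg(target)
  if (tree$bl_mode == "none") {
    stop("cannot convert branch-length mode: tree has no branch lengths")
  }
  if (tree$bl_mode == target) return(tree)
  times <- node_times(tree)
  bl <- if (target == "absolute") {
    unname(times)
  } else {
    vapply(seq_along(tree$labels), function(i) {
      p <- tree$parent[i]
      if (is.na(p)) unname(times[i]) else unname(times[i] - times[p])
    }, numeric(1))
  }
  lineage_tree(tree$labels, tree$parent, bl, target)
}

# --- Validation report -------------------------------------------------

#' Validate a lineage-tree file and report its shape
#'
#' Runs format detection and the appropriate parser, collecting errors and
#' warnings into a structured report instead of stopping, so malformed files
#' can be diagnosed in one pass (this backs the CLI `validate` subcommand).
#'
#' @param text raw file content.
#' @param bl_mode branch-length interpretation passed to the parser.
#' @return A `format_report`: list with `format`, `parse_ok`, `messages`
#'   (data frame of severity/text), `n_cells`, `n_nodes`,
#'   `has_branch_lengths`, `has_polytomies`.
#' @export
validate_tree_text <- function(text, bl_mode = "none") {
  messages <- data.frame(severity = character(0), text = character(0),
                         stringsAsFactors = FALSE)
  note <- function(sev, txt) {
    messages[nrow(messages) + 1L, ] <<- list(sev, txt)
  }
  fmt <- tryCatch(detect_tree_format(text), error = function(e) {
    note("error", conditionMessage(e))
    NA_character_
  })
  tree <- NULL
  if (!is.na(fmt)) {
    parser <- if (fmt == "json") parse_json_tree else parse_newick
    tree <- withCallingHandlers(
      tryCatch(parser(text, bl_mode = bl_mode), error = function(e) {
        note("error", conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        note("warning", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  structure(list(
    format = fmt,
    parse_ok = !is.null(tree),
    messages = messages,
    n_cells = if (is.null(tree)) NA_integer_ else n_leaves(tree),
    n_nodes = if (is.null(tree)) NA_integer_ else length(tree$labels),
    has_branch_lengths = if (is.null(tree)) NA else tree$bl_mode != "none",
    has_polytomies = if (is.null(tree)) NA else has_polytomies(tree),
    tree = tree
  ), class = "format_report")
}

#' @export
print.format_report <- function(x, ...) {
  cat("<format_report> format:", ifelse(is.na(x$format), "?", x$format),
      " parse_ok:", x$parse_ok, "\n")
  if (x$parse_ok) {
    cat("  ", x$n_cells, "cells /", x$n_nodes, "nodes; branch lengths:",
        x$has_branch_lengths, "; polytomies:", x$has_polytomies, "\n")
  }
  if (nrow(x$messages)) {
    for (i in seq_len(nrow(x$messages))) {
      cat("  [", x$messages$severity[i], "] ", x$messages$text[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialize a format report as JSON
#' @param report a `format_report`.
#' @return JSON string (without the parsed tree itself).
#' @export
report_to_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(format = report$format, parse_ok = report$parse_ok,
         messages = report$messages, n_cells = report$n_cells,
         n_nodes = report$n_nodes,
         has_branch_lengths = report$has_branch_lengths,
         has_polytomies = report$has_polytomies),
    auto_unbox = TRUE, digits = NA, na = "null"))
}
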