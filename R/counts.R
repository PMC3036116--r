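#' Structure counts: the filtered pedigree decomposition
#'
#' The likelihood of a pedigree for the penetrance K depends only on counts
#' of a few structure types among the individuals descending from obligate
#' carriers: the number of affected (penetrant) carriers, of obligate
#' non-penetrant carriers, of childless normal offspring of carriers, the
#' shapes of the trees of normal descendants, the three same-sex twin-pair
#' classes, and any consanguineous loop configurations.  A
#' \code{structure_counts} object holds exactly this decomposition and fully
#' determines the likelihood.
#'
#' @param n_affected number of affected penetrant individuals (A).
#' @param n_obligate number of obligate non-penetrant carriers (B).
#' @param n_childless number of normal individuals without offspring born to
#'   an obligate carrier (C).
#' @param trees list of [normal_tree()] objects (each of depth >= 2).
#' @param twins named integer vector \code{c(both_normal=, discordant=,
#'   both_affected=)} of same-sex twin-pair counts.
#' @param consanguineous list of consanguineous trees; each element is a list
#'   with a \code{configurations} component holding one \code{structure_counts}
#'   per candidate transmitter (see [split_configurations()]).
#' @return an object of class \code{pen_counts}.
#' @seealso [read_structure_counts()], [log_likelihood()],
#'   [extract_structures()]
#' @export
structure_counts <- function(n_affected = 0, n_obligate = 0, n_childless = 0,
                             trees = list(),
                             twins = c(both_normal = 0, discordant = 0,
                                       both_affected = 0),
                             consanguineous = list()) {
  twins <- as.integer(twins)
  if (length(twins) != 3L) stop("twins must have three counts")
  names(twins) <- c("both_normal", "discordant", "both_affected")
  x <- structure(
    list(n_affected = as.integer(n_affected),
         n_obligate = as.integer(n_obligate),
         n_childless = as.integer(n_childless),
         trees = trees, twins = twins,
         consanguineous = consanguineous),
    class = "pen_counts"
  )
  validate_counts(x)
  x
}

validate_counts <- function(x) {
  cnt <- c(x$n_affected, x$n_obligate, x$n_childless, x$twins)
  if (anyNA(cnt) || any(cnt < 0L)) stop("structure counts must be >= 0")
  for (tr in x$trees) {
    if (!inherits(tr, "normal_tree")) stop("trees must be normal_tree objects")
    if (tree_depth(tr) < 2L) {
      stop("normal trees must have depth >= 2 (childless normals are counted ",
           "separately)")
    }
  }
  for (ct in x$consanguineous) {
    if (is.null(ct$configurations) || length(ct$configurations) == 0L) {
      stop("each consanguineous tree needs at least one configuration")
    }
    for (cfg in ct$configurations) {
      if (!inherits(cfg, "pen_counts")) {
        stop("consanguineous configurations must be structure_counts")
      }
    }
  }
  invisible(x)
}

# do the counts carry any information about K at all?
counts_empty <- function(x) {
  x$n_affected == 0L && x$n_obligate == 0L && x$n_childless == 0L &&
    length(x$trees) == 0L && sum(x$twins) == 0L &&
    length(x$consanguineous) == 0L
}

# elementwise sum of two decompositions (used when merging a configuration
# with the common non-inbred part); consanguineous slots must be empty
merge_counts <- function(a, b) {
  stopifnot(length(a$consanguineous) == 0L, length(b$consanguineous) == 0L)
  structure_counts(
    n_affected = a$n_affected + b$n_affected,
    n_obligate = a$n_obligate + b$n_obligate,
    n_childless = a$n_childless + b$n_childless,
    trees = c(a$trees, b$trees),
    twins = a$twins + b$twins
  )
}

#' @export
print.pen_counts <- function(x, ...) {
  cat("Structure counts: A =", x$n_affected, "affected, B =", x$n_obligate,
      "obligate non-penetrant, C =", x$n_childless, "childless normal\n")
  if (length(x$trees) > 0L) {
    cat("Normal trees:",
        paste(vapply(x$trees, tree_to_string, character(1)), collapse = "  "),
        "\n")
  }
  if (sum(x$twins) > 0L) {
    cat("Twin pairs: both normal =", x$twins[["both_normal"]],
        ", discordant =", x$twins[["discordant"]],
        ", both affected =", x$twins[["both_affected"]], "\n")
  }
  if (length(x$consanguineous) > 0L) {
    cat("Consanguineous trees:", length(x$consanguineous), "with",
        paste(vapply(x$consanguineous, function(ct) length(ct$configurations),
                     integer(1)), collapse = ", "),
        "configuration(s)\n")
  }
  invisible(x)
}

COUNTS_HEADER <- c(
  "# structure counts, version 1",
  "# line 1: A,B,C (affected penetrant; obligate non-penetrant; childless normal)",
  "# lines 2-5: trees of normal individuals with 2,3,4,5 generations:",
  "#   count followed by one serialization per tree.  A tree whose children",
  "#   are all childless is written as its offspring number; deeper trees use",
  "#   a nested parenthesis form, e.g. (2,3) is a 3-generation tree whose two",
  "#   second-generation members have 2 and 3 children.  This nested form",
  "#   extends the original flat dialect and is specific to this package.",
  "# line 6: twin-pair counts: both normal, discordant, both affected",
  "# line 7: number of consanguineous trees; each tree is then a block:",
  "#   a line with its number of configurations followed by one line per",
  "#   configuration of the form  A,B,C;tree,tree,...;tw1,tw2,tw3"
)

#' Read structure counts from a text file
#'
#' Reads the compact text format for pre-tabulated filtered-pedigree counts:
#' line 1 holds \code{A,B,C}; lines 2-5 the trees of normal individuals with
#' 2-5 generations (a count followed by one serialization per tree); line 6
#' the three twin-pair class counts; line 7 the number of consanguineous
#' trees, followed by one configuration block per tree.  Lines beginning with
#' \code{#} are comments.  See [write_structure_counts()] for the emitted
#' header documenting the dialect.
#'
#' @param path input path.
#' @return a \code{pen_counts} object.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("3,4,2", "2,2,3", "0", "0", "0", "0,0,0", "0"), f)
#' read_structure_counts(f)
read_structure_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  if (length(lines) < 7L) {
    stop("counts parse error: expected at least 7 data lines, got ",
         length(lines))
  }
  perr <- function(i, msg) {
    stop("counts parse error at line ", lineno[i], ": ", msg)
  }
  ints <- function(i, n = NULL) {
    parts <- strsplit(lines[i], ",")[[1]]
    v <- suppressWarnings(as.integer(trimws(parts)))
    if (anyNA(v)) perr(i, paste0("non-integer field in '", lines[i], "'"))
    if (any(v < 0L)) perr(i, "negative count")
    if (!is.null(n) && length(v) != n) {
      perr(i, paste0("expected ", n, " fields, got ", length(v)))
    }
    v
  }
  abc <- ints(1, 3)
  trees <- list()
  for (d in 2:5) {
    i <- d
    toks <- split_top_level(lines[i])
    cnt <- suppressWarnings(as.integer(toks[1]))
    if (is.na(cnt) || cnt < 0L) perr(i, "tree count must be a non-negative integer")
    if (length(toks) - 1L != cnt) {
      perr(i, paste0("tree count ", cnt, " does not match ",
                     length(toks) - 1L, " tree serialization(s)"))
    }
    for (tok in toks[-1]) {
      tr <- tree_from_string(tok)
      if (tree_depth(tr) != d) {
        perr(i, paste0("tree '", tok, "' has depth ", tree_depth(tr),
                       " but appears on the ", d, "-generation line"))
      }
      trees[[length(trees) + 1L]] <- tr
    }
  }
  twins <- ints(6, 3)
  ncons <- ints(7, 1)
  consang <- list()
  i <- 7L
  for (k in seq_len(ncons)) {
    i <- i + 1L
    if (i > length(lines)) stop("counts parse error: missing consanguineous block ", k)
    ncfg <- ints(i, 1)
    if (ncfg < 1L) perr(i, "a consanguineous tree needs >= 1 configuration")
    cfgs <- vector("list", ncfg)
    for (j in seq_len(ncfg)) {
      i <- i + 1L
      if (i > length(lines)) stop("counts parse error: missing configuration line")
      cfgs[[j]] <- parse_config_line(lines[i], lineno[i])
    }
    consang[[k]] <- list(label = as.character(k), configurations = cfgs)
  }
  if (i < length(lines)) {
    stop("counts parse error at line ", lineno[i + 1L], ": trailing input")
  }
  structure_counts(abc[1], abc[2], abc[3], trees = trees, twins = twins,
                   consanguineous = consang)
}

# split a comma-separated list at depth zero of parentheses
split_top_level <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  out <- character(0)
  cur <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, cur); cur <- ""
    } else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

parse_config_line <- function(line, lineno) {
  parts <- strsplit(line, ";")[[1]]
  if (length(parts) != 3L) {
    stop("counts parse error at line ", lineno,
         ": configuration must have 3 ';'-separated sections (A,B,C;trees;twins)")
  }
  abc <- suppressWarnings(as.integer(trimws(strsplit(parts[1], ",")[[1]])))
  if (length(abc) != 3L || anyNA(abc) || any(abc < 0L)) {
    stop("counts parse error at line ", lineno, ": bad A,B,C in configuration")
  }
  trees <- list()
  if (nzchar(trimws(parts[2]))) {
    trees <- lapply(split_top_level(trimws(parts[2])), tree_from_string)
  }
  tw <- suppressWarnings(as.integer(trimws(strsplit(parts[3], ",")[[1]])))
  if (length(tw) != 3L || anyNA(tw) || any(tw < 0L)) {
    stop("counts parse error at line ", lineno, ": bad twin counts in configuration")
  }
  structure_counts(abc[1], abc[2], abc[3], trees = trees, twins = tw)
}

#' Write structure counts to a text file
#'
#' Inverse of [read_structure_counts()]; emits a commented header describing
#' the dialect (including this package's nested-parenthesis extension for
#' trees deeper than two generations and for configuration blocks).
#'
#' @param counts a \code{pen_counts} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure_counts <- function(counts, path) {
  validate_counts(counts)
  depths <- vapply(counts$trees, tree_depth, integer(1))
  if (any(depths > 5L)) {
    stop("the counts file format caps normal trees at 5 generations; ",
         "deeper trees are supported in memory and from PED input only")
  }
  tree_lines <- vapply(2:5, function(d) {
    sel <- counts$trees[depths == d]
    paste(c(length(sel), vapply(sel, tree_to_string, character(1))),
          collapse = ",")
  }, character(1))
  out <- c(
    COUNTS_HEADER,
    paste(counts$n_affected, counts$n_obligate, counts$n_childless, sep = ","),
    tree_lines,
    paste(counts$twins, collapse = ","),
    as.character(length(counts$consanguineous))
  )
  for (ct in counts$consanguineous) {
    out <- c(out, as.character(length(ct$configurations)),
             vapply(ct$configurations, config_line, character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

config_line <- function(cfg) {
  paste(
    paste(cfg$n_affected, cfg$n_obligate, cfg$n_childless, sep = ","),
    paste(vapply(cfg$trees, tree_to_string, character(1)), collapse = ","),
    paste(cfg$twins, collapse = ","),
    sep = ";"
  )
}
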