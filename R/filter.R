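#' Decompose a pedigree into likelihood-relevant structures
#'
#' Produces the "filtered pedigree": every individual informative for the
#' penetrance K is classified exactly once as an affected penetrant carrier
#' (A), an obligate non-penetrant carrier (B), a childless normal born to an
#' obligate carrier (C), a node of a tree of normal individuals rooted at a
#' normal child of an obligate carrier, or a member of a same-sex twin-pair
#' class.  Married-in spouses of carriers carry no information under the
#' rare-allele assumption and are excluded entirely; individuals with
#' unknown phenotype are excluded from the likelihood with a warning (an
#' unknown-phenotype individual that demonstrably transmitted the allele
#' still transmits, but contributes no phenotype factor).
#'
#' @param ped a \code{pen_pedigree} without unresolved consanguineous loops
#'   (use [detect_consanguineous_loops()] / [split_configurations()] /
#'   [estimate_penetrance()] for those).
#' @return a \code{pen_counts} object.  Attribute \code{"classification"}
#'   holds a data.frame (id, class, tree) recording how each filtered
#'   individual was classified; trees carry their member ids.
#' @export
#' @examples
#' extract_structures(make_fixture("fig1"))  # A=3, B=4, C=2, trees 2 and 3
extract_structures <- function(ped) {
  loops <- detect_consanguineous_loops(ped)
  if (length(loops) > 0L) {
    stop("pedigree contains ", length(loops), " consanguineous loop(s); ",
         "use estimate_penetrance() or split_configurations() to resolve ",
         "transmission configurations")
  }
  extract_structures_noloop(ped)
}

extract_structures_noloop <- function(ped) {
  df <- ped$individuals
  obligate <- identify_obligate_carriers(ped)
  cls <- stats::setNames(rep(NA_character_, nrow(df)), df$id)
  tree_of <- stats::setNames(rep(NA_integer_, nrow(df)), df$id)
  phe <- stats::setNames(df$phenotype, df$id)

  obl_aff <- intersect(obligate, df$id[df$phenotype == "affected"])
  obl_nor <- intersect(obligate, df$id[df$phenotype == "normal"])
  obl_unk <- intersect(obligate, df$id[df$phenotype == "unknown"])
  cls[obl_aff] <- "affected"
  cls[obl_nor] <- "obligate"
  cls[obl_unk] <- "obligate_unknown"
  if (length(obl_unk) > 0L) {
    warning("obligate carrier(s) with unknown phenotype excluded from the ",
            "likelihood (still treated as transmitting): ",
            paste(obl_unk, collapse = ", "))
  }

  # twin pairs: childless same-sex children of an obligate carrier
  twins <- c(both_normal = 0L, discordant = 0L, both_affected = 0L)
  for (pair in unique(df$twin[!is.na(df$twin)])) {
    members <- df$id[!is.na(df$twin) & df$twin == pair]
    par <- parents_of(ped, members[1])
    if (!any(par %in% obligate)) {
      stop("twin pair '", pair, "' (", paste(members, collapse = ", "),
           ") is not born to an obligate carrier; its likelihood terms ",
           "condition on a carrier parent")
    }
    kids <- unlist(lapply(members, children_of, ped = ped))
    if (length(kids) > 0L) {
      stop("twin pair '", pair, "' has offspring; twin pairs with their own ",
           "offspring are unsupported")
    }
    sexes <- df$sex[match(members, df$id)]
    if (all(sexes %in% c("male", "female")) && sexes[1] != sexes[2]) {
      # opposite-sex twins are necessarily dizygotic: ordinary siblings
      next
    }
    phs <- phe[members]
    if (any(phs == "unknown")) {
      warning("twin pair '", pair, "' has an unknown phenotype; ",
              "pair excluded from the likelihood")
      cls[members] <- "excluded_unknown"
      next
    }
    n_aff <- sum(phs == "affected")
    class <- c("both_normal", "discordant", "both_affected")[n_aff + 1L]
    twins[[class]] <- twins[[class]] + 1L
    cls[members] <- paste0("twin_", class)
  }

  # walk normal descendants of every carrier (affected, obligate normal, or
  # unknown-phenotype transmitter)
  trees <- list()
  carriers <- c(obl_aff, obl_nor, obl_unk)
  excluded_unknown <- character(0)
  for (o in carriers) {
    for (child in children_of(ped, o)) {
      if (!is.na(cls[child])) next
      if (phe[child] == "unknown") {
        cls[child] <- "excluded_unknown"
        excluded_unknown <- c(excluded_unknown, child)
        next
      }
      if (phe[child] == "affected") {
        stop("internal error: affected individual '", child,
             "' escaped the obligate-carrier closure")
      }
      built <- build_normal_tree(ped, child, phe, obligate)
      excluded_unknown <- c(excluded_unknown, built$excluded)
      node <- built$node
      if (length(node$children) == 0L) {
        cls[child] <- "childless"
      } else {
        trees[[length(trees) + 1L]] <- node
        ids <- tree_member_ids(node)
        cls[ids] <- "tree"
        tree_of[ids] <- length(trees)
      }
    }
  }
  if (length(excluded_unknown) > 0L) {
    warning("unknown-phenotype individual(s) excluded from the likelihood ",
            "together with their descendants: ",
            paste(unique(excluded_unknown), collapse = ", "))
  }

  counts <- structure_counts(
    n_affected = sum(cls == "affected", na.rm = TRUE),
    n_obligate = sum(cls == "obligate", na.rm = TRUE),
    n_childless = sum(cls == "childless", na.rm = TRUE),
    trees = trees, twins = twins
  )
  keep <- !is.na(cls) & cls != "excluded_unknown"
  attr(counts, "classification") <- data.frame(
    id = names(cls)[keep], class = unname(cls[keep]),
    tree = unname(tree_of[keep]), stringsAsFactors = FALSE
  )
  attr(counts, "origin") <- attr(obligate, "origin")
  counts
}

# Recursively collect the all-normal descendant subtree of a normal child of
# a carrier.  Descendants with unknown phenotype are pruned (with their own
# descendants).  An affected descendant cannot occur here: it would have made
# every intermediate an obligate carrier.
build_normal_tree <- function(ped, id, phe, obligate) {
  excluded <- character(0)
  rec <- function(x) {
    kids <- children_of(ped, x)
    nodes <- list()
    for (k in kids) {
      if (phe[k] == "unknown") {
        excluded <<- c(excluded, k)
        next
      }
      if (phe[k] == "affected" || k %in% obligate) {
        stop("internal error: normal tree under '", id,
             "' touches carrier '", k, "'")
      }
      nodes[[length(nodes) + 1L]] <- rec(k)
    }
    normal_tree(nodes, id = x)
  }
  list(node = rec(id), excluded = excluded)
}

#' Human-readable report of the filtered pedigree
#'
#' Lists every structure of the filtered decomposition with the ids of its
#' members, mirroring the annotated right-hand panel of a drawn pedigree.
#'
#' @param ped a \code{pen_pedigree}.
#' @return a character vector of report lines (also printed invisibly by
#'   `cat`ing them is left to the caller).
#' @export
filtered_report <- function(ped) {
  dec <- decompose_pedigree(ped)
  counts <- dec$common
  cl <- attr(counts, "classification")
  by_class <- function(what) cl$id[cl$class == what]
  lines <- c(
    paste0("Filtered pedigree '", ped$family_id, "'"),
    paste0("  affected penetrant (A = ", counts$n_affected, "): ",
           paste(by_class("affected"), collapse = ", ")),
    paste0("  obligate non-penetrant (B = ", counts$n_obligate, "): ",
           paste(by_class("obligate"), collapse = ", ")),
    paste0("  childless normal offspring of carriers (C = ",
           counts$n_childless, "): ",
           paste(by_class("childless"), collapse = ", "))
  )
  for (i in seq_along(counts$trees)) {
    tr <- counts$trees[[i]]
    lines <- c(lines, paste0(
      "  normal tree ", i, " (", tree_to_string(tr), "): ",
      paste(tree_member_ids(tr), collapse = ", ")))
  }
  tw <- counts$twins
  if (sum(tw) > 0L) {
    lines <- c(lines, paste0(
      "  twin pairs: both normal = ", tw[["both_normal"]],
      ", discordant = ", tw[["discordant"]],
      ", both affected = ", tw[["both_affected"]]))
  }
  for (ct in dec$loops) {
    lines <- c(lines, paste0(
      "  consanguineous tree {", paste(ct$members, collapse = ", "),
      "} with candidate transmitters ",
      paste(ct$transmitters, collapse = ", ")))
  }
  lines
}
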