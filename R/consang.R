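#' Detect consanguineous loops
#'
#' Finds marriage loops in which an affected descendant could have received
#' the dominant allele through more than one ancestral line: a couple whose
#' members are both blood descendants of the carrier lineage.  Each loop is
#' returned with its candidate transmitters — the topmost member of each
#' ancestral branch through whom the allele may have reached the loop's
#' affected descendants.  Branch members that are obligate carriers
#' independently of the loop (they are affected, designated, or have an
#' affected descendant outside the loop) are not part of the ambiguity and
#' are trimmed off the branch.
#'
#' Only the classical pattern is supported — two candidate transmitting
#' lines converging on one descendant line.  More tangled inbreeding (three
#' or more routes, loops sharing members, branches that merge above the
#' couple) raises an "unsupported loop" error rather than producing silent
#' nonsense.
#'
#' @param ped a \code{pen_pedigree}.
#' @return a list of \code{consanguineous_tree} objects (empty when no loops
#'   exist), each with components \code{members} (ids whose classification
#'   depends on the transmission route), \code{transmitters} (the two
#'   candidate ids), \code{join} (the couple's child where the lines
#'   reconverge) and \code{configurations} (empty until
#'   [split_configurations()] fills it).
#' @export
#' @examples
#' detect_consanguineous_loops(make_fixture("fig1"))  # empty list
#' loops <- detect_consanguineous_loops(make_fixture("fig5"))
#' loops[[1]]$transmitters  # I-1 and II-2
detect_consanguineous_loops <- function(ped) {
  df <- ped$individuals
  affected <- df$id[df$phenotype == "affected"]
  if (length(affected) == 0L) return(list())
  obligate <- identify_obligate_carriers(ped)
  origin <- attr(obligate, "origin")
  g <- parent_graph(ped)
  phe <- stats::setNames(df$phenotype, df$id)
  designated <- df$id[df$designated]

  loops <- list()
  for (x in setdiff(affected, origin)) {
    paths <- igraph::all_simple_paths(g, from = origin, to = x, mode = "out")
    if (length(paths) <= 1L) next
    if (length(paths) > 2L) {
      stop("unsupported loop: more than two transmission routes from '",
           origin, "' to affected individual '", x, "'")
    }
    p1 <- names(paths[[1]])
    p2 <- names(paths[[2]])
    # longest common prefix = path down to the divergence vertex
    npre <- 0L
    while (npre + 1L <= min(length(p1), length(p2)) &&
           p1[npre + 1L] == p2[npre + 1L]) npre <- npre + 1L
    d <- p1[npre]
    s1 <- p1[(npre + 1L):length(p1)]
    s2 <- p2[(npre + 1L):length(p2)]
    i1 <- which(s1 %in% s2)[1]
    join <- s1[i1]
    i2 <- match(join, s2)
    if (!identical(s1[i1:length(s1)], s2[i2:length(s2)])) {
      stop("unsupported loop: transmission routes to '", x,
           "' diverge again below their first reconvergence at '", join, "'")
    }
    branch1 <- if (i1 > 1L) s1[seq_len(i1 - 1L)] else character(0)
    branch2 <- if (i2 > 1L) s2[seq_len(i2 - 1L)] else character(0)
    mate1 <- if (length(branch1) > 0L) branch1[length(branch1)] else d
    mate2 <- if (length(branch2) > 0L) branch2[length(branch2)] else d

    trim <- function(branch) {
      while (length(branch) > 0L) {
        m <- branch[1]
        indep <- phe[m] == "affected" || m %in% designated ||
          has_affected_descendant_avoiding(ped, m, join, affected)
        if (!indep) break
        branch <- branch[-1L]
      }
      branch
    }
    t1 <- trim(branch1)
    t2 <- trim(branch2)
    if (length(t1) == 0L && length(t2) == 0L) {
      # both lines carry regardless: classifications do not depend on the
      # route, so there is nothing to split
      next
    }
    top1 <- if (length(t1) > 0L) t1[1] else mate1
    top2 <- if (length(t2) > 0L) t2[1] else mate2
    members <- sort(unique(c(
      t1, t2, join,
      unlist(lapply(c(t1, t2, join), descendants_of, ped = ped))
    )))
    key <- paste(d, join, sep = "\r")
    if (!is.null(loops[[key]])) {
      if (!identical(loops[[key]]$members, members)) {
        stop("unsupported loop: inconsistent member sets for the loop ",
             "joining at '", join, "'")
      }
      next
    }
    loops[[key]] <- structure(
      list(members = members, transmitters = c(top1, top2),
           join = join, mates = c(mate1, mate2), divergence = d,
           configurations = list()),
      class = "consanguineous_tree"
    )
  }
  loops <- unname(loops)
  if (length(loops) > 1L) {
    for (i in seq_len(length(loops) - 1L)) {
      for (j in (i + 1L):length(loops)) {
        if (length(intersect(loops[[i]]$members, loops[[j]]$members)) > 0L) {
          stop("unsupported loop: consanguineous loops joining at '",
               loops[[i]]$join, "' and '", loops[[j]]$join,
               "' share members")
        }
      }
    }
  }
  loops
}

# does m have an affected descendant reachable without passing through
# `avoid`?  (used to decide whether m is obligate independently of a loop)
has_affected_descendant_avoiding <- function(ped, m, avoid, affected) {
  seen <- character(0)
  frontier <- setdiff(children_of(ped, m), avoid)
  while (length(frontier) > 0L) {
    if (any(frontier %in% affected)) return(TRUE)
    seen <- union(seen, frontier)
    nxt <- setdiff(unique(unlist(lapply(frontier, children_of, ped = ped))),
                   c(seen, avoid))
    frontier <- nxt
  }
  FALSE
}

#' @export
print.consanguineous_tree <- function(x, ...) {
  cat("Consanguineous tree joining at '", x$join, "'\n", sep = "")
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  cat("  candidate transmitters:", paste(x$transmitters, collapse = ", "),
      "\n")
  if (length(x$configurations) > 0L) {
    cat("  configurations:\n")
    for (cfg in x$configurations) {
      cat("   via ", attr(cfg, "transmitter"), ": ", config_line(cfg), "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Split a consanguineous tree into transmission configurations
#'
#' For each candidate transmitter, fixes the assumed transmission route by
#' severing the link between the loop's join individual and the mate on the
#' other line, then reclassifies the loop members by the standard filtering
#' rules: the chosen line becomes obligate, while the other line's members —
#' whose offspring through the couple are now explained by the carrier
#' partner — fall back to childless normals or trees of normal individuals.
#' A configuration in which an affected loop member cannot receive the
#' allele is dropped with a warning.
#'
#' @param tree a \code{consanguineous_tree} from
#'   [detect_consanguineous_loops()].
#' @param ped the pedigree the loop was detected in.
#' @return list of \code{pen_counts}, one per surviving configuration,
#'   counting the loop members only (the non-inbred remainder of the
#'   pedigree is the common part; see [combine_configurations()]).  Each
#'   element carries its candidate transmitter id in attribute
#'   \code{"transmitter"}.
#' @export
#' @examples
#' ped <- make_fixture("fig5")
#' loop <- detect_consanguineous_loops(ped)[[1]]
#' split_configurations(loop, ped)
split_configurations <- function(tree, ped) {
  stopifnot(inherits(tree, "consanguineous_tree"))
  all_loops <- detect_consanguineous_loops(ped)
  key <- vapply(all_loops, function(l) l$join, character(1))
  if (!(tree$join %in% key)) {
    stop("the given consanguineous tree was not detected in this pedigree")
  }
  others <- all_loops[key != tree$join]
  out <- list()
  for (side in 1:2) {
    cfg <- tryCatch(
      configuration_counts(ped, tree, side, others),
      error = function(e) {
        warning("configuration via '", tree$transmitters[side],
                "' dropped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(cfg)) out[[length(out) + 1L]] <- cfg
  }
  if (length(out) == 0L) {
    stop("no surviving configuration for the consanguineous tree joining ",
         "at '", tree$join, "'")
  }
  out
}

# counts over the loop members when transmission is fixed through `side`,
# with every other loop cut at its first side (their members are excluded
# from the restriction, so the arbitrary choice cannot leak into the result)
configuration_counts <- function(ped, tree, side, others) {
  cut_ped <- cut_loop(ped, tree, keep_side = side)
  for (ot in others) cut_ped <- cut_loop(cut_ped, ot, keep_side = 1L)
  counts <- extract_structures_noloop(cut_ped)
  restricted <- restrict_counts(counts, tree$members)
  attr(restricted, "transmitter") <- tree$transmitters[side]
  restricted
}

# replace the join's parent on the non-kept side by a dummy married-in
# founder, removing the alternative transmission route
cut_loop <- function(ped, tree, keep_side) {
  df <- ped$individuals
  drop_mate <- tree$mates[if (keep_side == 1L) 2L else 1L]
  j <- match(tree$join, df$id)
  if (is.na(j)) stop("join individual '", tree$join, "' missing")
  dummy <- paste0(".shadow.", drop_mate, ".", tree$join)
  dummy_sex <- df$sex[match(drop_mate, df$id)]
  if (identical(df$father[j], drop_mate)) {
    df$father[j] <- dummy
  } else if (identical(df$mother[j], drop_mate)) {
    df$mother[j] <- dummy
  } else {
    stop("'", drop_mate, "' is not a parent of join '", tree$join, "'")
  }
  df <- rbind(df, data.frame(
    id = dummy, father = NA_character_, mother = NA_character_,
    sex = dummy_sex, phenotype = "normal", twin = NA_character_,
    designated = FALSE, stringsAsFactors = FALSE
  ))
  pedigree(df, family_id = ped$family_id)
}

# restrict a classified decomposition to a member set; structures must not
# straddle the boundary
restrict_counts <- function(counts, members, complement = FALSE) {
  cl <- attr(counts, "classification")
  inside <- if (complement) !(cl$id %in% members) else cl$id %in% members
  pick <- function(what) sum(inside & cl$class == what)
  trees <- list()
  for (i in seq_along(counts$trees)) {
    ids <- tree_member_ids(counts$trees[[i]])
    hit <- if (complement) !(ids %in% members) else ids %in% members
    if (all(hit)) {
      trees[[length(trees) + 1L]] <- counts$trees[[i]]
    } else if (any(hit)) {
      stop("unsupported loop: a tree of normal individuals straddles the ",
           "loop boundary (", paste(ids, collapse = ", "), ")")
    }
  }
  twin_classes <- c("both_normal", "discordant", "both_affected")
  twins <- vapply(twin_classes, function(cls) {
    n_in <- sum(inside & cl$class == paste0("twin_", cls))
    if (n_in %% 2L != 0L) {
      stop("unsupported loop: a twin pair straddles the loop boundary")
    }
    n_in %/% 2L
  }, integer(1))
  out <- structure_counts(pick("affected"), pick("obligate"),
                          pick("childless"), trees = trees, twins = twins)
  attr(out, "classification") <- cl[inside, , drop = FALSE]
  attr(out, "origin") <- attr(counts, "origin")
  out
}

#' Decompose a pedigree, resolving consanguineous loops
#'
#' Runs loop detection and configuration splitting, and separates the counts
#' of the common (non-inbred) part from the per-loop configuration counts.
#' The common part must not depend on which configuration is assumed; if it
#' does, the loop pattern is outside the supported taxonomy and an error is
#' raised.
#'
#' @param ped a \code{pen_pedigree}.
#' @return list with components \code{common} (a \code{pen_counts} over the
#'   individuals outside every loop) and \code{loops} (list of
#'   \code{consanguineous_tree} objects with their \code{configurations}
#'   filled).
#' @export
decompose_pedigree <- function(ped) {
  loops <- detect_consanguineous_loops(ped)
  if (length(loops) == 0L) {
    return(list(common = extract_structures_noloop(ped), loops = list()))
  }
  n_comb <- prod(vapply(loops, function(l) 2L, integer(1)))
  all_members <- unlist(lapply(loops, function(l) l$members))
  commons <- list()
  for (l in seq_along(loops)) {
    cfgs <- split_configurations(loops[[l]], ped)
    loops[[l]]$configurations <- cfgs
    # common part as seen when this loop is cut either way
    for (side in seq_along(cfgs)) {
      cut_ped <- cut_loop(ped, loops[[l]], keep_side = side)
      for (ot in loops[-l]) cut_ped <- cut_loop(cut_ped, ot, keep_side = 1L)
      full <- extract_structures_noloop(cut_ped)
      commons[[length(commons) + 1L]] <- restrict_counts(full, all_members,
                                                         complement = TRUE)
    }
  }
  ref <- counts_signature(commons[[1]])
  for (cc in commons[-1]) {
    if (!identical(counts_signature(cc), ref)) {
      stop("unsupported loop: the classification of individuals outside ",
           "the loop depends on the assumed transmission route; this ",
           "inbreeding pattern is beyond the supported taxonomy")
    }
  }
  if (prod(vapply(loops, function(l) length(l$configurations),
                  integer(1))) > 64L) {
    warning("more than 64 configuration combinations; expect a ",
            "combinatorial slowdown")
  }
  list(common = commons[[1]], loops = loops)
}

counts_signature <- function(x) {
  list(x$n_affected, x$n_obligate, x$n_childless,
       sort(vapply(x$trees, tree_to_string, character(1))),
       unname(x$twins))
}
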