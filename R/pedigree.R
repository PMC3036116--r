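#' Construct a pedigree object
#'
#' A pedigree is a directed acyclic family graph of individuals with
#' phenotypes.  Individuals are identified by opaque string ids; the
#' roman-numeral generation labels often seen in published pedigrees
#' (\code{"II-4"}) are a display convention only and carry no meaning.
#'
#' @param individuals a data.frame with columns \code{id}, \code{father},
#'   \code{mother} (\code{NA} for founders), \code{sex}
#'   (\code{"male"}, \code{"female"} or \code{"unknown"}), \code{phenotype}
#'   (\code{"normal"}, \code{"affected"} or \code{"unknown"}), and optionally
#'   \code{twin} (twin-pair label, \code{NA} if not a twin) and
#'   \code{designated} (logical; \code{TRUE} marks the founder known to have
#'   introduced the pathogenic allele).
#' @param family_id single string naming the family.
#'
#' @return an object of class \code{pen_pedigree}.
#'
#' @details Validation enforces: unique non-empty ids; father and mother
#'   either both absent (founder) or both present and resolving to existing
#'   individuals; no individual is its own ancestor (the parent graph is a
#'   DAG); sexes of parents consistent with their role; each twin label
#'   occurs exactly twice and both members share the same parents; at most
#'   one member of a founder couple is designated as the carrier.
#'
#' @seealso [read_ped()], [extract_structures()], [estimate_penetrance()]
#' @export
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("F", "M", "C"),
#'   father = c(NA, NA, "F"),
#'   mother = c(NA, NA, "M"),
#'   sex = c("male", "female", "female"),
#'   phenotype = c("affected", "normal", "normal")
#' ))
#' ped
pedigree <- function(individuals, family_id = "FAM1") {
  stopifnot(is.data.frame(individuals))
  df <- as.data.frame(individuals, stringsAsFactors = FALSE)
  required <- c("id", "father", "mother", "sex", "phenotype")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("pedigree: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"twin" %in% names(df)) df$twin <- NA_character_
  if (!"designated" %in% names(df)) df$designated <- FALSE
  df <- df[, c(required, "twin", "designated")]
  for (col in c("id", "father", "mother", "sex", "phenotype", "twin")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$designated <- as.logical(df$designated)
  df$designated[is.na(df$designated)] <- FALSE
  rownames(df) <- NULL
  ped <- structure(
    list(family_id = as.character(family_id)[1], individuals = df),
    class = "pen_pedigree"
  )
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree object
#'
#' Checks the structural invariants documented in [pedigree()]; called by the
#' constructor and by the readers.  Errors name the offending individual.
#'
#' @param ped a \code{pen_pedigree}.
#' @return the pedigree, invisibly, if valid.
#' @export
validate_pedigree <- function(ped) {
  df <- ped$individuals
  if (nrow(df) == 0L) stop("pedigree is empty")
  if (anyNA(df$id) || any(!nzchar(df$id))) stop("pedigree: empty individual id")
  if (anyDuplicated(df$id)) {
    stop("pedigree: duplicated id '", df$id[duplicated(df$id)][1], "'")
  }
  bad_sex <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0L) stop("pedigree: invalid sex value '", bad_sex[1], "'")
  bad_phe <- setdiff(unique(df$phenotype), c("normal", "affected", "unknown"))
  if (length(bad_phe) > 0L) {
    stop("pedigree: invalid phenotype value '", bad_phe[1], "'")
  }
  one_parent <- xor(is.na(df$father), is.na(df$mother))
  if (any(one_parent)) {
    stop("pedigree: individual '", df$id[one_parent][1],
         "' has exactly one recorded parent; founders have none, ",
         "non-founders both")
  }
  for (col in c("father", "mother")) {
    ref <- df[[col]]
    dangling <- !is.na(ref) & !(ref %in% df$id)
    if (any(dangling)) {
      stop("pedigree: individual '", df$id[dangling][1], "' references ",
           col, " '", ref[dangling][1], "' which does not exist")
    }
  }
  self_parent <- !is.na(df$father) & (df$father == df$id | df$mother == df$id)
  if (any(self_parent)) {
    stop("pedigree: individual '", df$id[self_parent][1],
         "' is its own parent (cycle)")
  }
  sex_of <- stats::setNames(df$sex, df$id)
  bad_f <- !is.na(df$father) & sex_of[df$father] == "female"
  if (any(bad_f)) {
    stop("pedigree: father '", df$father[bad_f][1], "' of individual '",
         df$id[bad_f][1], "' is recorded as female")
  }
  bad_m <- !is.na(df$mother) & sex_of[df$mother] == "male"
  if (any(bad_m)) {
    stop("pedigree: mother '", df$mother[bad_m][1], "' of individual '",
         df$id[bad_m][1], "' is recorded as male")
  }
  g <- parent_graph(ped)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    v <- if (length(cyc) > 0L) igraph::ends(g, cyc[1])[1] else df$id[1]
    stop("pedigree: individual '", v, "' appears among its own ancestors (cycle)")
  }
  twins <- df$twin[!is.na(df$twin)]
  if (length(twins) > 0L) {
    tab <- table(twins)
    if (any(tab != 2L)) {
      stop("pedigree: twin pair '", names(tab)[tab != 2L][1],
           "' must have exactly two members")
    }
    for (pair in unique(twins)) {
      members <- df[!is.na(df$twin) & df$twin == pair, ]
      same <- identical(members$father[1], members$father[2]) &&
        identical(members$mother[1], members$mother[2]) &&
        !is.na(members$father[1])
      if (!same) {
        stop("pedigree: twin pair '", pair, "' members '", members$id[1],
             "' and '", members$id[2], "' do not share both parents")
      }
    }
  }
  des <- df[df$designated, , drop = FALSE]
  if (nrow(des) > 0L) {
    not_founder <- !is.na(des$father)
    if (any(not_founder)) {
      stop("pedigree: designated carrier '", des$id[not_founder][1],
           "' is not a founder")
    }
    # at most one designated member per founder couple
    for (i in seq_len(nrow(des))) {
      mates <- couple_partners(ped, des$id[i])
      both <- intersect(mates, des$id)
      if (length(both) > 0L) {
        stop("pedigree: both members of founder couple ('", des$id[i],
             "', '", both[1], "') are designated as the carrier; ",
             "designate exactly one")
      }
    }
  }
  invisible(ped)
}

# directed igraph of parent -> child edges over all individuals
parent_graph <- function(ped) {
  df <- ped$individuals
  has_par <- !is.na(df$father)
  edges <- rbind(
    cbind(df$father[has_par], df$id[has_par]),
    cbind(df$mother[has_par], df$id[has_par])
  )
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(df$id)
  if (nrow(edges) > 0L) g <- g + igraph::edges(t(edges))
  g
}

ped_ids <- function(ped) ped$individuals$id

ped_row <- function(ped, id) {
  i <- match(id, ped$individuals$id)
  if (is.na(i)) stop("unknown individual '", id, "'")
  ped$individuals[i, ]
}

phenotype_of <- function(ped, ids) {
  ped$individuals$phenotype[match(ids, ped$individuals$id)]
}

is_founder <- function(ped, id) is.na(ped_row(ped, id)$father)

#' Children of an individual
#' @param ped a \code{pen_pedigree}.
#' @param id individual id.
#' @return character vector of child ids (possibly empty).
#' @export
children_of <- function(ped, id) {
  df <- ped$individuals
  df$id[(!is.na(df$father) & df$father == id) |
          (!is.na(df$mother) & df$mother == id)]
}

parents_of <- function(ped, id) {
  r <- ped_row(ped, id)
  if (is.na(r$father)) character(0) else c(r$father, r$mother)
}

# ids this founder has children with
couple_partners <- function(ped, id) {
  kids <- children_of(ped, id)
  if (length(kids) == 0L) return(character(0))
  df <- ped$individuals
  rows <- df[df$id %in% kids, ]
  setdiff(unique(c(rows$father, rows$mother)), id)
}

descendants_of <- function(ped, id) {
  out <- character(0)
  frontier <- children_of(ped, id)
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, children_of, ped = ped))),
                        out)
  }
  out
}

ancestors_of <- function(ped, id) {
  out <- character(0)
  frontier <- parents_of(ped, id)
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, parents_of, ped = ped))),
                        out)
  }
  out
}

#' @export
print.pen_pedigree <- function(x, ...) {
  df <- x$individuals
  n_aff <- sum(df$phenotype == "affected")
  n_twin <- length(unique(df$twin[!is.na(df$twin)]))
  cat("Pedigree '", x$family_id, "': ", nrow(df), " individuals (",
      n_aff, " affected, ", sum(is.na(df$father)), " founders",
      if (n_twin > 0L) paste0(", ", n_twin, " twin pair(s)") else "",
      ")\n", sep = "")
  des <- df$id[df$designated]
  if (length(des) > 0L) {
    cat("Designated carrier founder:", paste(des, collapse = ", "), "\n")
  }
  invisible(x)
}
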