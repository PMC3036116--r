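#' Identify obligate carriers of the dominant allele
#'
#' Under the single-origin assumption (exactly one founder lineage introduced
#' the rare allele A; married-in spouses are aa), the individuals that must
#' carry A are: every affected individual, and every individual through whom
#' the allele demonstrably passed — i.e. every individual lying on all
#' transmission paths from the allele's origin down to some affected
#' descendant.  Normal individuals in that set are the obligate non-penetrant
#' carriers.
#'
#' The origin is the designated carrier founder when one is annotated.
#' Without a designation, the origin is taken as the unique topmost affected
#' individual that is an ancestor of every other affected individual; if no
#' such individual exists (e.g. affected siblings whose normal founder
#' parents could each have transmitted), the function stops and instructs the
#' user to designate the carrier founder, since guessing between the members
#' of a founder couple is unsafe.
#'
#' In a pedigree with a consanguineous loop, individuals that lie on only
#' some of the transmission paths are not obligate; they are resolved per
#' configuration by [split_configurations()].
#'
#' @param ped a \code{pen_pedigree}.
#' @return character vector of obligate-carrier ids (affected individuals
#'   included), with the origin id in attribute \code{"origin"}.
#' @export
#' @examples
#' obl <- identify_obligate_carriers(make_fixture("fig1"))
#' sort(obl)
identify_obligate_carriers <- function(ped) {
  df <- ped$individuals
  affected <- df$id[df$phenotype == "affected"]
  if (length(affected) == 0L) {
    stop("nothing to estimate: the pedigree contains no affected individuals")
  }
  designated <- df$id[df$designated]
  if (length(designated) > 1L) {
    stop("more than one designated carrier founder ('",
         paste(designated, collapse = "', '"),
         "'); the single-origin model admits exactly one")
  }
  if (length(designated) == 1L) {
    origin <- designated
    desc <- c(origin, descendants_of(ped, origin))
    outside <- setdiff(affected, desc)
    if (length(outside) > 0L) {
      stop("affected individual '", outside[1], "' is not a descendant of ",
           "the designated carrier founder '", origin,
           "', violating the single-origin assumption")
    }
  } else {
    # unique topmost affected individual covering all other affected?
    tops <- Filter(function(a) {
      all(setdiff(affected, a) %in% descendants_of(ped, a))
    }, affected)
    if (length(tops) != 1L) {
      stop("cannot resolve the origin of the allele: no single affected ",
           "individual is an ancestor of all others, so either member of ",
           "the top founder couple could have transmitted.  Designate the ",
           "carrier founder in the sidecar annotations (carrier: <id>)")
    }
    origin <- tops
  }
  g <- parent_graph(ped)
  obligate <- union(origin, affected)
  for (x in setdiff(affected, origin)) {
    paths <- igraph::all_simple_paths(g, from = origin, to = x, mode = "out")
    if (length(paths) == 0L) {
      stop("affected individual '", x, "' is not connected to the origin '",
           origin, "'")
    }
    on_all <- Reduce(intersect, lapply(paths, function(p) names(p)))
    obligate <- union(obligate, on_all)
  }
  structure(obligate, origin = origin)
}
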