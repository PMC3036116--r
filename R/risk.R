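#' Per-individual heterozygosity probabilities and offspring risks
#'
#' For every individual of the filtered pedigree, computes the posterior
#' probability of carrying the dominant allele (heterozygosity probability)
#' given all observed phenotypes at penetrance K, and the offspring risk —
#' the probability that a future child with a non-carrier mate is affected,
#' \eqn{P(\mathrm{het}) \times K/2}.
#'
#' Rules: affected individuals and obligate carriers have heterozygosity 1;
#' a married-in non-descendant has 0 (rare-allele assumption); a childless
#' normal child of an obligate carrier has \eqn{(1-K)/(2-K)}; a member x of
#' a tree of normal individuals has
#' \eqn{P(\mathrm{parent\ carrier}) \cdot
#'   \tfrac12 (1-K) \prod_{c} f(c) / f(x)}
#' applied top-down from the tree root (whose parent is an obligate carrier),
#' with f as in [tree_term()].  Normal members of twin pairs use the
#' zygosity-mixture posterior consistent with [twin_term()].
#'
#' Risks are evaluated at the point estimate \code{k} supplied (by default
#' the MLE from the same pedigree); pass e.g. a posterior mean to use another
#' summary.
#'
#' @param ped a \code{pen_pedigree} without consanguineous loops.
#' @param k penetrance value; defaults to the MLE estimated from \code{ped}.
#' @param mz_prob twin monozygosity probability.
#' @return a data.frame (id, classification, heterozygosity, offspring_risk),
#'   one row per filtered individual; married-in spouses are absent.
#' @seealso [heterozygosity_probability()], [offspring_risk()]
#' @export
#' @examples
#' risk_table(make_fixture("fig1"), k = 0.5)
risk_table <- function(ped, k = NULL, mz_prob = 0.5) {
  counts <- extract_structures(ped)
  if (is.null(k)) {
    k <- estimate_penetrance(ped, mz_prob = mz_prob)$k_hat
  }
  stopifnot(k >= 0, k <= 1)
  cl <- attr(counts, "classification")
  het <- stats::setNames(rep(NA_real_, nrow(cl)), cl$id)
  het[cl$class %in% c("affected", "obligate")] <- 1
  het[cl$class == "childless"] <- (1 - k) / (2 - k)
  het[cl$class == "twin_both_affected"] <- 1
  for (tw in c("twin_both_normal", "twin_discordant")) {
    ids <- cl$id[cl$class == tw]
    for (id in ids) {
      phe <- phenotype_of(ped, id)
      het[id] <- if (phe == "affected") 1 else {
        twin_normal_het(sub("twin_", "", tw), k, mz_prob)
      }
    }
  }
  for (tr in counts$trees) {
    th <- tree_het(tr, k, parent_prob = 1)
    het[names(th)] <- th
  }
  het <- het[!(cl$class == "obligate_unknown")]
  cl2 <- cl[cl$class != "obligate_unknown", , drop = FALSE]
  data.frame(
    id = cl2$id,
    classification = cl2$class,
    heterozygosity = unname(het[cl2$id]),
    offspring_risk = unname(het[cl2$id]) * k / 2,
    stringsAsFactors = FALSE
  )
}

# top-down carrier posteriors over a normal tree; parent_prob is the
# posterior carrier probability of the node's parent given all data
tree_het <- function(tree, k, parent_prob) {
  f_x <- tree_term(tree, k)
  prod_f <- if (length(tree$children) == 0L) 1 else {
    Reduce(`*`, lapply(tree$children, tree_term, k = k))
  }
  p_x <- parent_prob * 0.5 * (1 - k) * prod_f / f_x
  out <- stats::setNames(p_x, tree$id)
  for (ch in tree$children) out <- c(out, tree_het(ch, k, parent_prob = p_x))
  out
}

# posterior P(carrier) for the normal member of a same-sex twin pair,
# mixing over zygosity (MZ twins share the genotype)
twin_normal_het <- function(class, k, m) {
  if (class == "both_normal") {
    num <- m * 0.5 * (1 - k)^2 + (1 - m) * 0.5 * (1 - k) * (2 - k) / 2
    den <- twin_term("both_normal", k, m)
  } else {
    num <- m * 0.5 * k * (1 - k) + (1 - m) * 0.5 * (1 - k) * k / 2
    den <- m * 0.5 * k * (1 - k) + (1 - m) * (k / 2) * ((2 - k) / 2)
  }
  if (den == 0) return(NaN)
  num / den
}

#' @rdname risk_table
#' @param id individual id.
#' @return \code{heterozygosity_probability}: the posterior carrier
#'   probability for one individual.  Individuals of unknown phenotype, or
#'   blood relatives outside the filtered pedigree, raise an error; a
#'   married-in spouse returns 0.
#' @export
heterozygosity_probability <- function(id, ped, k, mz_prob = 0.5) {
  row <- ped_row(ped, id)  # errors on unknown id
  tab <- risk_table(ped, k = k, mz_prob = mz_prob)
  i <- match(id, tab$id)
  if (!is.na(i)) return(tab$heterozygosity[i])
  if (row$phenotype == "unknown") {
    stop("individual '", id, "' is not in the filtered pedigree ",
         "(unknown phenotype)")
  }
  counts <- extract_structures(ped)
  origin <- attr(counts, "origin")
  blood <- c(origin, descendants_of(ped, origin))
  if (!(id %in% blood)) return(0)  # married-in: non-carrier by assumption
  stop("individual '", id, "' is not in the filtered pedigree")
}

#' @rdname risk_table
#' @export
offspring_risk <- function(id, ped, k, mz_prob = 0.5) {
  heterozygosity_probability(id, ped, k, mz_prob) * k / 2
}

#' Write a risk table to TSV or JSON
#'
#' @param table a data.frame from [risk_table()].
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_risk_table <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
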