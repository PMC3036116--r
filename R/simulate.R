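#' Random pedigree topology for simulation studies
#'
#' Builds a loop-free pedigree skeleton: a founder couple whose first member
#' is the designated carrier, with every blood individual of the
#' non-terminal generations marrying a new founder spouse and producing a
#' sibship of 1 + Poisson(\code{sibship_mean - 1}) children.  All phenotypes
#' are initialized to normal; [gene_drop()] overwrites them.
#'
#' @param generations number of generations (default 4).
#' @param sibship_mean mean sibship size (default 3, i.e. 1 + Poisson(2)).
#' @param family_id family label.
#' @return a \code{pen_pedigree} skeleton with the carrier founder
#'   designated.
#' @export
random_topology <- function(generations = 4, sibship_mean = 3,
                            family_id = "SIM") {
  stopifnot(generations >= 2, sibship_mean >= 1)
  rows <- list()
  add <- function(id, father, mother, sex, designated = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex,
      phenotype = "normal", twin = NA_character_, designated = designated,
      stringsAsFactors = FALSE
    )
  }
  add("G1-1", NA_character_, NA_character_, "male", designated = TRUE)
  add("G1-2", NA_character_, NA_character_, "female")
  blood <- "G1-1"
  spouse <- stats::setNames("G1-2", "G1-1")
  counter <- 0L
  for (g in 2:generations) {
    next_blood <- character(0)
    for (b in blood) {
      n_kids <- 1L + stats::rpois(1, sibship_mean - 1)
      for (j in seq_len(n_kids)) {
        counter <- counter + 1L
        kid <- paste0("G", g, "-", counter)
        sex <- sample(c("male", "female"), 1L)
        par <- c(b, spouse[[b]])
        sexes <- c(ped_sex_of(rows, par[1]), ped_sex_of(rows, par[2]))
        father <- par[sexes == "male"][1]
        mother <- par[sexes == "female"][1]
        add(kid, father, mother, sex)
        if (g < generations) {
          counter <- counter + 1L
          sp <- paste0("G", g, "-", counter, "s")
          add(sp, NA_character_, NA_character_,
              if (sex == "male") "female" else "male")
          spouse[[kid]] <- sp
        }
        next_blood <- c(next_blood, kid)
      }
    }
    blood <- next_blood
  }
  pedigree(do.call(rbind, rows), family_id = family_id)
}

ped_sex_of <- function(rows, id) {
  for (r in rows) if (r$id == id) return(r$sex)
  stop("internal: unknown id ", id)
}

#' Gene-drop simulation of allele transmission and phenotypes
#'
#' Forward simulation of the single-locus dominant model through a fixed
#' pedigree topology: the designated carrier founder is Aa; every child of a
#' carrier parent receives the allele with probability 1/2 (independently
#' per carrier parent; married-in founders are aa); every carrier is
#' affected with probability \code{k_true} and every non-carrier is normal.
#'
#' @param topology a \code{pen_pedigree} skeleton with a designated carrier
#'   founder (see [random_topology()] or [make_fixture()]).
#' @param k_true true penetrance in [0, 1].
#' @param n number of replicates.
#' @param seed optional RNG seed; the seed fixes the full output stream.
#' @return list of \code{n} \code{pen_pedigree} objects with simulated
#'   phenotypes; each carries the logical carrier vector in attribute
#'   \code{"carriers"}.
#' @export
#' @examples
#' peds <- gene_drop(random_topology(), k_true = 0.7, n = 2, seed = 1)
#' sapply(peds, function(p) sum(p$individuals$phenotype == "affected"))
gene_drop <- function(topology, k_true, n = 1, seed = NULL) {
  stopifnot(inherits(topology, "pen_pedigree"), k_true >= 0, k_true <= 1,
            n >= 1)
  df <- topology$individuals
  if (!any(df$designated)) {
    stop("gene_drop needs a designated carrier founder in the topology")
  }
  if (!is.null(seed)) set.seed(seed)
  # topological order: parents before children
  g <- parent_graph(topology)
  ord <- names(igraph::topo_sort(g, mode = "out"))
  ord <- match(ord, df$id)
  out <- vector("list", n)
  for (r in seq_len(n)) {
    carrier <- stats::setNames(rep(FALSE, nrow(df)), df$id)
    carrier[df$id[df$designated]] <- TRUE
    for (i in ord) {
      if (is.na(df$father[i])) next
      ncp <- carrier[df$father[i]] + carrier[df$mother[i]]
      if (ncp > 0) {
        carrier[df$id[i]] <- stats::runif(1) < 1 - 0.5^ncp
      }
    }
    phe <- ifelse(carrier & stats::runif(nrow(df)) < k_true,
                  "affected", "normal")
    ped_r <- topology
    ped_r$individuals$phenotype <- unname(phe)
    attr(ped_r, "carriers") <- carrier
    out[[r]] <- ped_r
  }
  out
}

#' Write gene-drop replicates to PED files with a manifest
#'
#' Writes one PED file per replicate plus a shared sidecar annotation file
#' (carrying the designated carrier) and a tab-separated manifest with an
#' md5 checksum per file; identical seeds give byte-identical output.
#'
#' @param peds list of pedigrees from [gene_drop()].
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_replicates <- function(peds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann_path <- file.path(dir, "annotations.yml")
  files <- character(length(peds))
  for (r in seq_along(peds)) {
    files[r] <- file.path(dir, sprintf("rep%04d.ped", r))
    # all replicates share one topology, hence one annotation file
    write_ped(peds[[r]], files[r], annotations = ann_path)
  }
  all_files <- c(files, ann_path)
  manifest <- data.frame(
    file = basename(all_files),
    md5 = unname(tools::md5sum(all_files)),
    stringsAsFactors = FALSE
  )
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man_path)
}
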